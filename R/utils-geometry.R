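# Small 3-vector helpers used throughout the geometry code. All coordinates
# are in Angstrom.

vnorm <- function(v) sqrt(sum(v^2))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Any unit vector perpendicular to v (deterministic choice).
vperp <- function(v) {
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  vunit(vcross(v, ref))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rigid superposition of two equal-length coordinate sets via
#' the closed-form SVD solution. Returns the proper rotation (det = +1),
#' translation and RMSD of the superposed mobile set onto the reference.
#'
#' @param mobile n x 3 numeric matrix (or object coercible via
#'   [model_coords()]) to be moved.
#' @param reference n x 3 numeric matrix to stay fixed.
#' @return An object of class `superposition`: a list with `rotation` (3 x 3),
#'   `translation` (length 3), `rmsd` (Angstrom), and `n` (atoms used). The
#'   transform maps mobile coordinates as `x %*% rotation + translation`.
#' @examples
#' x <- matrix(rnorm(30), ncol = 3)
#' superpose(x, x)$rmsd  # 0
#' @export
superpose <- function(mobile, reference) {
  P <- as.matrix(mobile)
  Q <- as.matrix(reference)
  if (!all(dim(P) == dim(Q))) stop("selections differ in length")
  if (nrow(P) < 3) stop("need at least 3 atoms to superpose")
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  moved <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  structure(
    list(rotation = R, translation = cq - as.vector(cp %*% R),
         rmsd = rmsd, n = nrow(P)),
    class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Rigid superposition over %d atoms: RMSD %.4f A\n", x$n, x$rmsd))
  invisible(x)
}

# Apply a superposition transform to an n x 3 matrix.
apply_transform <- function(xyz, sup) {
  sweep(as.matrix(xyz) %*% sup$rotation, 2, sup$translation, `+`)
}

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Direct least-squares ellipse fit
#'
#' Fits an ellipse to 2-D points by the numerically stable direct conic fit
#' constrained to ellipses (Halir & Flusser variant of Fitzgibbon's method).
#'
#' @param x,y coordinates of the points (length >= 6 recommended).
#' @return list with `center` (length 2), `a` (semi-major), `b` (semi-minor),
#'   `angle` (radians, orientation of the major axis) and `eccentricity`
#'   `sqrt(1 - (b/a)^2)`.
#' @export
fit_ellipse <- function(x, y) {
  if (length(x) != length(y) || length(x) < 5)
    stop("need at least 5 points for an ellipse fit")
  mx <- mean(x); my <- mean(y)
  xs <- x - mx; ys <- y - my
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, rep(1, length(xs)))
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  qs3 <- tryCatch(solve(S3, t(S2)), error = function(e) stop("ellipse fit singular"))
  M <- S1 - S2 %*% qs3
  # premultiply by inv(C) where C is the ellipse constraint matrix
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) stop("ellipse fit singular: no elliptical solution")
  a1 <- evec[, ok[1]]
  a2 <- -as.vector(qs3 %*% a1)
  # conic: A x^2 + B xy + C y^2 + D x + E y + F = 0 (in centred coords)
  A <- a1[1]; B <- a1[2]; C <- a1[3]; D <- a2[1]; E <- a2[2]; F <- a2[3]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / -den
  cy <- (2 * A * E - B * D) / -den
  num <- 2 * (A * E^2 + C * D^2 + F * B^2 - B * D * E - 4 * A * C * F)
  s <- sqrt((A - C)^2 + B^2)
  axis1 <- sqrt(abs(num / (den * ((A + C) + s))))
  axis2 <- sqrt(abs(num / (den * ((A + C) - s))))
  semi_major <- max(axis1, axis2)
  semi_minor <- min(axis1, axis2)
  ang <- 0.5 * atan2(B, A - C)
  if (axis1 < axis2) ang <- ang + pi / 2
  list(center = c(cx + mx, cy + my), a = semi_major, b = semi_minor,
       angle = ang %% pi,
       eccentricity = sqrt(1 - (semi_minor / semi_major)^2))
}

# --- ellipse arc-length machinery -------------------------------------------
# Parametric ellipse (A cos t, B sin t). We need arc-length parameterisation
# to place strands at uniform wall spacing.

ellipse_arc_table <- function(A, B, n = 4000) {
  t <- seq(0, 2 * pi, length.out = n + 1)
  dx <- -A * sin(t)
  dy <- B * cos(t)
  sp <- sqrt(dx^2 + dy^2)
  # cumulative arc length by trapezoid rule
  s <- c(0, cumsum((sp[-1] + sp[-length(sp)]) / 2 * diff(t)))
  list(t = t, s = s, perimeter = s[length(s)])
}

ellipse_perimeter <- function(A, B) ellipse_arc_table(A, B)$perimeter

# Map arc length u (any real; wraps) to parametric angle t.
ellipse_t_of_arc <- function(arc_tab, u) {
  P <- arc_tab$perimeter
  u <- u %% P
  stats::approx(arc_tab$s, arc_tab$t, xout = u, rule = 2)$y
}

# 3-D embedding of wrapped coordinates (u = arc length along the wall,
# v = height along the barrel axis z, w = outward normal offset).
wrap_to_ellipse <- function(u, v, w, A, B, arc_tab = ellipse_arc_table(A, B)) {
  t <- ellipse_t_of_arc(arc_tab, u)
  nx <- B * cos(t)
  ny <- A * sin(t)
  nn <- sqrt(nx^2 + ny^2)
  cbind(A * cos(t) + w * nx / nn,
        B * sin(t) + w * ny / nn,
        v)
}

# Local wall frame at arc position u: tangent (direction of increasing u)
# and outward normal, both horizontal unit vectors.
wall_frame <- function(u, A, B, arc_tab = ellipse_arc_table(A, B)) {
  t <- ellipse_t_of_arc(arc_tab, u)
  tx <- -A * sin(t); ty <- B * cos(t)
  tn <- sqrt(tx^2 + ty^2)
  nx <- B * cos(t); ny <- A * sin(t)
  nn <- sqrt(nx^2 + ny^2)
  list(tangent = cbind(tx / tn, ty / tn, 0),
       normal = cbind(nx / nn, ny / nn, 0))
}
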