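# Parametric construction of idealized circular and ovoid barrel backbones
# from a blueprint, plus the generic autoregressive element-length search.
#
# The barrel is built in unrolled-sheet coordinates and wrapped onto an
# ellipse. In the unrolled plane, strands are parallel lines spaced by the
# interstrand distance b and tilted at angle alpha from the barrel axis,
# where tan(alpha) = S * a / (n * b) (S = shear, n = strands, a = rise per
# residue). This tilt is exactly the condition that the sheet closes onto
# itself with register offset S after one turn, and fixes the wall perimeter
# P = n * b / cos(alpha). The ellipse the wall is wrapped onto is scaled so
# its perimeter equals P; the supplied semi-axes set the aspect ratio only.

#' Barrel construction parameters
#'
#' @param semi_major_a,semi_minor_b target cross-section semi-axes (Angstrom).
#'   Only their ratio matters: the absolute size of the wall is fixed by the
#'   closure perimeter.
#' @param rise_per_residue rise along the strand per residue (Angstrom,
#'   3.0--3.6).
#' @param interstrand_spacing perpendicular distance between adjacent strand
#'   lines (Angstrom, 4.2--5.2).
#' @param helix_radial_offset outward offset of helix axes from the barrel
#'   wall (Angstrom).
#' @param pleat out-of-wall alternation amplitude of strand CA atoms,
#'   chosen so consecutive CA-CA distances are ~3.8 Angstrom.
#' @return List of class `barrel_params`.
#' @export
barrel_params <- function(semi_major_a = 13, semi_minor_b = 9,
                          rise_per_residue = 3.3, interstrand_spacing = 4.5,
                          helix_radial_offset = 6,
                          pleat = 0.5 * sqrt(3.8^2 - rise_per_residue^2)) {
  if (semi_major_a < semi_minor_b || semi_minor_b <= 0)
    stop("need semi_major_a >= semi_minor_b > 0")
  if (rise_per_residue < 3.0 || rise_per_residue > 3.6)
    stop("rise_per_residue outside [3.0, 3.6] Angstrom")
  if (interstrand_spacing < 4.2 || interstrand_spacing > 5.2)
    stop("interstrand_spacing outside [4.2, 5.2] Angstrom")
  structure(list(semi_major_a = semi_major_a, semi_minor_b = semi_minor_b,
                 rise_per_residue = rise_per_residue,
                 interstrand_spacing = interstrand_spacing,
                 helix_radial_offset = helix_radial_offset,
                 pleat = pleat),
            class = "barrel_params")
}

# Shared geometric setup for one blueprint + parameter set.
barrel_geometry <- function(bp, params) {
  S <- sum(bp$register_shifts)
  if (S != bp$shear)
    stop(sprintf("closure error: register shifts sum to %d but declared shear is %d (residual %d)",
                 S, bp$shear, S - bp$shear))
  n <- bp$n_strands
  a <- params$rise_per_residue
  b <- params$interstrand_spacing
  alpha <- atan2(S * a, n * b)
  P <- n * b / cos(alpha)
  rho <- params$semi_major_a / params$semi_minor_b
  B <- P / ellipse_perimeter(rho, 1)
  A <- rho * B
  arc_tab <- ellipse_arc_table(A, B)
  # rescale so the tabulated perimeter is exactly P
  sc <- P / arc_tab$perimeter
  A <- A * sc; B <- B * sc
  arc_tab <- ellipse_arc_table(A, B)
  list(S = S, n = n, a = a, b = b, alpha = alpha, P = P, A = A, B = B,
       arc_tab = arc_tab)
}

# Plane coordinates of the strand wall. Returns the strand position table
# with u (arc), v (height), and the pleat offset w.
wall_plane_coords <- function(bp, params, geo) {
  tab <- strand_position_table(bp)
  sa <- sin(geo$alpha); ca <- cos(geo$alpha)
  u <- (tab$strand - 1) * geo$b * ca + tab$ladder * geo$a * sa
  v <- -(tab$strand - 1) * geo$b * sa + tab$ladder * geo$a * ca
  # centre the wall: midline between strands 1 and 2, evaluated at the mean
  # height, maps to arc position 0 (a tight-curvature vertex of the ellipse)
  vbar <- mean(v)
  u_line <- function(i) (i - 1) * geo$b * ca + sa * (vbar + (i - 1) * geo$b * sa) / ca
  u0 <- -(u_line(1) + u_line(2)) / 2
  tab$u <- u + u0
  tab$v <- v - vbar
  tab$w <- ifelse(tab$core_facing, -params$pleat, params$pleat)
  tab
}

# In-wall unit vector perpendicular to the strand direction (pointing from
# strand i towards strand i+1) at given arc positions.
wall_perp <- function(u, geo) {
  fr <- wall_frame(u, geo$A, geo$B, geo$arc_tab)
  cos(geo$alpha) * fr$tangent - sin(geo$alpha) * cbind(0, 0, rep(1, length(u)))
}

# Place N, C, O collinearly along the CA trace of one contiguous chain and
# CB by a local-frame construction. `o_dir` optionally overrides the carbonyl
# direction per residue (rows of a matrix); NA rows fall back to the default
# outward-ish perpendicular.
build_backbone <- function(ca, o_dir = NULL, out_dir = NULL) {
  m <- nrow(ca)
  if (m == 1) stop("cannot build backbone for a single-residue chain")
  seg <- diff(ca)                     # m-1 segment vectors
  seglen <- sqrt(rowSums(seg^2))
  segu <- seg / seglen
  u_in <- rbind(segu[1, , drop = FALSE], segu)        # incoming dir per residue
  u_out <- rbind(segu, segu[m - 1, , drop = FALSE])   # outgoing dir per residue
  N <- ca - 1.35 * u_in
  C <- ca + 1.00 * u_out
  O <- matrix(NA_real_, m, 3)
  for (i in seq_len(m)) {
    d <- if (!is.null(o_dir) && !is.na(o_dir[i, 1])) o_dir[i, ] else {
      ref <- if (!is.null(out_dir)) out_dir[i, ] else vperp(u_out[i, ])
      pr <- ref - sum(ref * u_out[i, ]) * u_out[i, ]
      if (vnorm(pr) < 1e-6) vperp(u_out[i, ]) else vunit(pr)
    }
    O[i, ] <- C[i, ] + 1.23 * vunit(d - sum(d * u_out[i, ]) * u_out[i, ])
  }
  list(N = N, C = C, O = O, u_in = u_in, u_out = u_out)
}

# Default CB from local chain frame (used for helix/loop residues).
cb_from_frame <- function(ca, u_in, u_out, out_dir = NULL) {
  d1 <- u_in - u_out
  if (vnorm(d1) < 0.05) {
    base <- if (!is.null(out_dir)) out_dir else vperp(u_out)
    d1 <- base - sum(base * u_out) * u_out
  }
  side <- vcross(u_out, d1)
  dir <- d1 + 0.5 * side
  ca + 1.53 * vunit(dir)
}

#' Generate an idealized barrel wall from a blueprint
#'
#' Builds the beta-barrel wall only (strand residues; loops and helices in
#' the blueprint contribute residue numbering but no coordinates). Strand i
#' residue heights honour the cumulative register shifts, strands lie on an
#' elliptical cross-section with the tight-curvature (minor) faces between
#' strand pairs 1/2 and n/2+1 / n/2+2, the wall closes onto itself with
#' register offset equal to the shear, and CB directions alternate
#' interior / exterior with the core-facing parity.
#'
#' @param bp a [new_blueprint()].
#' @param params a [barrel_params()].
#' @param sequence optional named character vector of one-letter residues for
#'   the strand positions; defaults to Val at core-facing and Thr at
#'   exterior-facing positions.
#' @return A [new_barrel_model()] containing only strand residues.
#' @export
generate_barrel <- function(bp, params = barrel_params(), sequence = NULL) {
  geo <- barrel_geometry(bp, params)
  tab <- wall_plane_coords(bp, params, geo)
  ca3 <- wrap_to_ellipse(tab$u, tab$v, tab$w, geo$A, geo$B, geo$arc_tab)
  perp <- wall_perp(tab$u, geo)
  nrm <- wall_frame(tab$u, geo$A, geo$B, geo$arc_tab)$normal

  aa <- if (is.null(sequence)) ifelse(tab$core_facing, "V", "T") else
    unname(sequence[as.character(tab$residue)])

  rows <- vector("list", geo$n)
  for (i in seq_len(geo$n)) {
    idx <- which(tab$strand == i)
    ca_i <- ca3[idx, , drop = FALSE]
    eps_o <- ifelse(tab$ladder[idx] %% 2 == 0, 1, -1)
    od <- perp[idx, , drop = FALSE] * eps_o
    bb <- build_backbone(ca_i, o_dir = od, out_dir = nrm[idx, , drop = FALSE])
    cb_dir <- nrm[idx, , drop = FALSE] * ifelse(tab$core_facing[idx], -1, 1)
    cb <- ca_i + 1.53 * cb_dir
    cb[aa[idx] == "G", ] <- NA_real_
    rows[[i]] <- tibble::tibble(
      residue = tab$residue[idx], aa = aa[idx], element = "strand",
      element_id = i, strand = i,
      facing = ifelse(tab$core_facing[idx], "core", "exterior"),
      n_x = bb$N[, 1], n_y = bb$N[, 2], n_z = bb$N[, 3],
      ca_x = ca_i[, 1], ca_y = ca_i[, 2], ca_z = ca_i[, 3],
      c_x = bb$C[, 1], c_y = bb$C[, 2], c_z = bb$C[, 3],
      o_x = bb$O[, 1], o_y = bb$O[, 2], o_z = bb$O[, 3],
      cb_x = cb[, 1], cb_y = cb[, 2], cb_z = cb[, 3])
  }
  res_tab <- dplyr::bind_rows(rows)
  res_tab <- aim_strand_carbonyls(res_tab, bp, tab)
  m <- new_barrel_model(res_tab)
  attr(m, "blueprint") <- bp
  attr(m, "params") <- params
  m
}

# Deterministic local relaxation of loop CA positions: loop residues are
# pushed away from any CA they crowd (clearance violation, sequence
# separation >= 3) while consecutive CA-CA distances are projected back to
# 3.8 Angstrom (Jacobi-style constraint passes). Anchor (non-loop) residues
# never move.
relax_loop_cas <- function(ca, movable, clearance = 4.3, spacing = 3.8,
                           max_iter = 200) {
  n <- nrow(ca)
  idx <- seq_len(n)
  # loop residues keep a larger clearance from fixed (strand/helix) atoms,
  # whose N/C/O extremities stick out further than between two mobile loops
  cm <- matrix(clearance - 0.4, n, n)   # two mobile loops may pass close
  cm[outer(movable, movable, `|`) & !outer(movable, movable, `&`)] <-
    clearance + 0.4
  # virtual circular closure: the last residue neighbours the first
  pos2 <- idx; pos2[n] <- 0L
  sep <- pmin(abs(outer(idx, idx, `-`)), abs(outer(pos2, pos2, `-`)),
              abs(outer(pos2, idx, `-`)), abs(outer(idx, pos2, `-`)))
  cm[sep <= 4] <- 4.0      # near-chain neighbours may come closer (turns)
  cm[sep == 2] <- 5.2      # but backbone angles must stay open
  cm[sep <= 1] <- 0
  for (it in seq_len(max_iter)) {
    d <- as.matrix(stats::dist(ca))
    diag(d) <- Inf
    inv <- d < cm & (outer(movable, movable, `|`))
    pairs <- which(inv & upper.tri(inv), arr.ind = TRUE)
    seg <- ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE]
    len <- sqrt(rowSums(seg^2))
    spacing_bad <- (movable[-1] | movable[-n]) & abs(len - spacing) > 0.05
    if (nrow(pairs) == 0 && !any(spacing_bad)) break
    # repulsion
    if (nrow(pairs) > 0) {
      for (p in seq_len(nrow(pairs))) {
        i <- pairs[p, 1]; j <- pairs[p, 2]
        dv <- ca[j, ] - ca[i, ]
        dn <- vnorm(dv)
        if (dn < 1e-6) dv <- c(0, 0, 1) else dv <- dv / dn
        target <- if (j - i == 2) 5.2 else cm[i, j]
        push <- (target - dn) * 0.6
        if (movable[i] && movable[j]) {
          ca[i, ] <- ca[i, ] - dv * push / 2
          ca[j, ] <- ca[j, ] + dv * push / 2
        } else if (movable[i]) {
          ca[i, ] <- ca[i, ] - dv * push
        } else if (movable[j]) {
          ca[j, ] <- ca[j, ] + dv * push
        }
      }
    }
    # spacing projection
    for (pass in 1:15) {
      seg <- ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE]
      len <- sqrt(rowSums(seg^2))
      err <- len - spacing
      act <- which(abs(err) > 1e-3 & (movable[-1] | movable[-n]))
      if (length(act) == 0) break
      for (s in act) {
        u <- seg[s, ] / len[s]
        corr <- err[s]
        mA <- movable[s]; mB <- movable[s + 1]
        if (mA && mB) {
          ca[s, ] <- ca[s, ] + u * corr / 2
          ca[s + 1, ] <- ca[s + 1, ] - u * corr / 2
        } else if (mA) {
          ca[s, ] <- ca[s, ] + u * corr
        } else if (mB) {
          ca[s + 1, ] <- ca[s + 1, ] - u * corr
        }
      }
    }
  }
  ca
}

# Re-aim strand carbonyl oxygens at their ladder partner amides: a residue
# on an even ladder rung donates its carbonyl across the junction towards
# the next strand, an odd-rung residue towards the previous strand (the
# pleated-sheet alternation); O sits 1.23 Angstrom from C along the line to
# the partner N. Residues whose partner is absent keep the default
# perpendicular carbonyl.
aim_strand_carbonyls <- function(res_tab, bp, tab) {
  shifts <- bp$register_shifts
  n <- bp$n_strands
  key <- paste(tab$strand, tab$local)
  row_of <- stats::setNames(match(tab$residue, res_tab$residue), key)
  for (q in seq_len(nrow(tab))) {
    j <- tab$strand[q]; l <- tab$local[q]
    if (tab$ladder[q] %% 2 == 0) {
      tj <- if (j == n) 1L else j + 1L
      tl <- l - shifts[j] + 1L
    } else {
      pj <- if (j == 1) n else j - 1L
      tl <- l + shifts[pj] + 1L
      tj <- pj
    }
    tr <- row_of[paste(tj, tl)]
    r <- row_of[paste(j, l)]
    Cpos <- c(res_tab$c_x[r], res_tab$c_y[r], res_tab$c_z[r])
    if (!is.na(tr)) {
      Npos <- c(res_tab$n_x[tr], res_tab$n_y[tr], res_tab$n_z[tr])
      o <- Cpos + 1.23 * vunit(Npos - Cpos)
    } else {
      # no ladder partner on this rung: point the carbonyl outward so it
      # does not poke into the neighbouring strand
      h <- c(Cpos[1], Cpos[2], 0)
      if (vnorm(h) < 1e-6) h <- c(1, 0, 0)
      nb <- row_of[paste(j, l + 1)]
      if (is.na(nb)) nb <- row_of[paste(j, l - 1)]
      if (!is.na(nb)) {
        dvec <- c(res_tab$ca_x[nb] - res_tab$ca_x[r],
                  res_tab$ca_y[nb] - res_tab$ca_y[r],
                  res_tab$ca_z[nb] - res_tab$ca_z[r])
        dvec <- vunit(dvec)
        h <- h - sum(h * dvec) * dvec
        if (vnorm(h) < 1e-6) h <- vperp(dvec)
      }
      o <- Cpos + 1.23 * vunit(h)
    }
    res_tab$o_x[r] <- o[1]; res_tab$o_y[r] <- o[2]; res_tab$o_z[r] <- o[3]
  }
  res_tab
}

# Interior points of a circular arc from A to B bulging towards mdir, with
# equal chord steps of `step` between n+2 points (A, interior..., B).
arc_loop_points <- function(A, B, mdir, n, step = 3.8) {
  d <- vnorm(B - A)
  need <- step * (n + 1)
  if (d > need + 1e-9)
    stop(sprintf("loop of %d residues cannot span %.1f Angstrom", n, d))
  if (d > need - 1e-6) {     # essentially straight
    f <- seq_len(n) / (n + 1)
    return(A + outer(f, B - A))
  }
  e1 <- vunit(B - A)
  mp <- mdir - sum(mdir * e1) * e1
  if (vnorm(mp) < 1e-6) mp <- vperp(e1)
  mp <- vunit(mp)
  # chord of each of the n+1 sub-arcs must equal `step`:
  # d * sin(theta / (2(n+1))) / sin(theta/2) = step, theta = total arc angle
  f <- function(th) d * sin(th / (2 * (n + 1))) / sin(th / 2) - step
  th <- stats::uniroot(f, c(1e-6, 2 * pi * 0.98), tol = 1e-10)$root
  R <- d / (2 * sin(th / 2))
  # signed offset: for th > pi the centre sits on the bulge side
  center <- (A + B) / 2 - mp * R * cos(th / 2)
  ex <- vunit(A - center)
  if (abs(sin(th)) > 1e-6) {
    ey <- (B - center - R * cos(th) * ex) / (R * sin(th))
  } else {
    ey <- vunit(mp - sum(mp * ex) * ex)
  }
  phi <- th * seq_len(n) / (n + 1)
  t(vapply(phi, function(p) center + R * (cos(p) * ex + sin(p) * ey),
           numeric(3)))
}

#' Generate a full idealized TIM barrel from a blueprint
#'
#' Builds the barrel wall as in [generate_barrel()], places each helix
#' outside the wall at `helix_radial_offset`, antiparallel to its preceding
#' strand, and closes all loops with smooth equal-spaced arcs, yielding a
#' single connected backbone. Fails if any non-bonded backbone atom pair
#' comes closer than 2.5 Angstrom.
#'
#' @inheritParams generate_barrel
#' @param sequence optional full-length named character vector; defaults to a
#'   simple element-based pattern (see [design_sequence()] for the preset
#'   designed sequences).
#' @return A [new_barrel_model()] with all residues of the blueprint.
#' @export
generate_full_timb <- function(bp, params = barrel_params(), sequence = NULL) {
  geo <- barrel_geometry(bp, params)
  tab <- wall_plane_coords(bp, params, geo)
  wall_ca <- wrap_to_ellipse(tab$u, tab$v, tab$w, geo$A, geo$B, geo$arc_tab)
  sa <- sin(geo$alpha); ca_a <- cos(geo$alpha)
  vbar0 <- 0 # heights already centred in wall_plane_coords

  total <- bp$total_residues
  ca <- matrix(NA_real_, total, 3)
  element <- character(total); element_id <- integer(total)
  strand_of <- rep(NA_integer_, total); facing <- rep(NA_character_, total)
  ca[tab$residue, ] <- wall_ca
  element[tab$residue] <- "strand"
  strand_of[tab$residue] <- tab$strand
  facing[tab$residue] <- ifelse(tab$core_facing, "core", "exterior")

  # arc position of the midline between strand lines i and i+1 at height v
  u_mid <- function(i, v) {
    ul <- function(j) (j - 1) * geo$b * ca_a +
      sa * ((v + mean_v_offset) + (j - 1) * geo$b * sa) / ca_a
    (ul(i) + ul(i + 1)) / 2 + u_offset
  }
  # recover the centring constants used in wall_plane_coords
  raw_v <- -(tab$strand - 1) * geo$b * sa + tab$ladder * geo$a * ca_a
  mean_v_offset <- mean(raw_v)
  raw_u <- (tab$strand - 1) * geo$b * ca_a + tab$ladder * geo$a * sa
  u_offset <- mean(tab$u - raw_u)

  els <- bp$elements
  n_seen_strands <- 0L
  for (e in seq_len(nrow(els))) {
    kind <- els$kind[e]; L <- els$length[e]
    res <- seq(els$start[e], els$end[e])
    element[res] <- kind
    element_id[res] <- e
    if (kind == "strand") {
      n_seen_strands <- n_seen_strands + 1L
    } else if (kind == "helix") {
      i <- max(n_seen_strands, 1L)
      stop_at <- which(tab$strand == i)
      v_top <- max(tab$v[stop_at])
      v_start <- v_top - 3.0
      vs <- v_start - 1.5 * (seq_len(L) - 1)
      uh <- u_mid(i, 0)   # common reference height keeps helix spacing uniform
      fr <- wall_frame(uh, geo$A, geo$B, geo$arc_tab)
      base <- wrap_to_ellipse(uh, 0, params$helix_radial_offset,
                              geo$A, geo$B, geo$arc_tab)
      phi <- -(seq_len(L) - 1) * (100 * pi / 180)
      hx <- base[rep(1, L), , drop = FALSE] +
        2.3 * (cos(phi) %o% fr$normal[1, ] + sin(phi) %o% fr$tangent[1, ])
      hx[, 3] <- vs
      ca[res, ] <- hx
    }
  }

  # fill loops with equal-spaced arcs between the flanking anchors
  v_med <- stats::median(ca[, 3], na.rm = TRUE)
  for (e in which(els$kind == "loop")) {
    res <- seq(els$start[e], els$end[e]); L <- length(res)
    before <- els$start[e] - 1L; after <- els$end[e] + 1L
    if (before >= 1 && after <= total) {
      A <- ca[before, ]; B <- ca[after, ]
      rdir <- c((A[1:2] + B[1:2]) / 2, 0)
      rdir <- if (vnorm(rdir) < 1e-6) c(1, 0, 0) else vunit(rdir)
      sgn <- if (mean(c(A[3], B[3])) > v_med) 1 else -1
      mdir <- if (sgn > 0) vunit(rdir + 0.4 * c(0, 0, 1)) else
        vunit(0.4 * rdir - 1.2 * c(0, 0, 1))
      ca[res, ] <- arc_loop_points(A, B, mdir, L)
    } else if (before >= 1) {        # trailing tail: outward and down
      anchor <- ca[before, ]
      dirv <- vunit(vunit(c(anchor[1], anchor[2], 0)) * 0.6 - c(0, 0, 1))
      ca[res, ] <- matrix(rep(anchor, each = L), L) +
        3.8 * outer(seq_len(L), dirv)
    } else {                          # leading tail: outward and up
      anchor <- ca[after, ]
      dirv <- vunit(vunit(c(anchor[1], anchor[2], 0)) * 0.6 + c(0, 0, 1))
      ca[res, ] <- matrix(rep(anchor, each = L), L) +
        3.8 * outer(rev(seq_len(L)), dirv)
    }
  }

  # the dangling C-terminal loop mirrors its repeat-partner loop where the
  # blueprint is rotationally repetitive (the cross-section must be invariant
  # under the repeat rotation: twofold always is, higher orders need a
  # circular section)
  rc <- bp$repeat_count
  symmetric_wrap <- rc >= 2 && (rc == 2 || abs(geo$A - geo$B) < 1e-9)
  rpr <- bp$residues_per_repeat
  rot_z <- function(x, ang) {
    R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
                3, 3)
    x %*% t(R)
  }
  # propagate repeat 1 to the later repeats (the C-terminal tail thereby
  # inherits the shape of its anchored repeat-partner loop)
  symmetrize <- function(ca) {
    for (k in seq_len(rc - 1))
      ca[k * rpr + seq_len(rpr), ] <- rot_z(ca[seq_len(rpr), , drop = FALSE],
                                            2 * pi * k / rc)
    ca
  }
  if (symmetric_wrap) {
    # propagate repeat 1 to the later repeats by the repeat rotation; this
    # also gives the dangling C-terminal loop the shape of its repeat
    # partner
    for (k in seq_len(rc - 1))
      ca[k * rpr + seq_len(rpr), ] <- rot_z(ca[seq_len(rpr), , drop = FALSE],
                                            2 * pi * k / rc)
  }

  # relax loop residues away from crowded regions, keeping chain spacing;
  # alternate with re-imposing exact repeat symmetry until both hold
  ca <- relax_loop_cas(ca, element == "loop")
  if (symmetric_wrap) {
    for (round in 1:8) {
      ca <- symmetrize(ca)
      ca2 <- relax_loop_cas(ca, element == "loop", max_iter = 50)
      if (max(abs(ca2 - ca)) < 1e-9) { ca <- ca2; break }
      ca <- ca2
    }
    ca <- symmetrize(ca)
  }

  # sequence
  aa <- if (!is.null(sequence)) unname(sequence[as.character(seq_len(total))])
        else default_element_sequence(element, facing)

  # backbone for the whole connected chain; strand carbonyls follow the
  # pleated-sheet alternation, others point outward
  od <- matrix(NA_real_, total, 3)
  outd <- matrix(NA_real_, total, 3)
  horiz <- cbind(ca[, 1], ca[, 2], 0)
  hn <- sqrt(rowSums(horiz^2)); hn[hn < 1e-6] <- 1
  outd <- horiz / hn
  sidx <- tab$residue
  perp <- wall_perp(tab$u, geo)
  od[sidx, ] <- perp * ifelse(tab$ladder %% 2 == 0, 1, -1)
  # terminal carbonyl points away from the chain start, which the symmetric
  # dangling tail approaches (virtual circular closure)
  od[total, ] <- vunit(ca[total, ] - ca[1, ])
  bb <- build_backbone(ca, o_dir = od, out_dir = outd)

  cb <- matrix(NA_real_, total, 3)
  nrm_wall <- wall_frame(tab$u, geo$A, geo$B, geo$arc_tab)$normal
  cb[sidx, ] <- ca[sidx, , drop = FALSE] +
    1.53 * nrm_wall * ifelse(tab$core_facing, -1, 1)
  for (r in seq_len(total)) {
    if (element[r] != "strand")
      cb[r, ] <- cb_from_frame(ca[r, ], bb$u_in[r, ], bb$u_out[r, ], outd[r, ])
  }
  cb[aa == "G", ] <- NA_real_

  res_tab <- tibble::tibble(
    residue = seq_len(total), aa = aa, element = element,
    element_id = element_id, strand = strand_of, facing = facing,
    n_x = bb$N[, 1], n_y = bb$N[, 2], n_z = bb$N[, 3],
    ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
    c_x = bb$C[, 1], c_y = bb$C[, 2], c_z = bb$C[, 3],
    o_x = bb$O[, 1], o_y = bb$O[, 2], o_z = bb$O[, 3],
    cb_x = cb[, 1], cb_y = cb[, 2], cb_z = cb[, 3])
  res_tab <- aim_strand_carbonyls(res_tab, bp, tab)
  res_tab <- redirect_clashing_carbonyls(res_tab, element, bb$u_out)
  m <- new_barrel_model(res_tab)
  check_backbone_clashes(m)
  attr(m, "blueprint") <- bp
  attr(m, "params") <- params
  m
}

default_element_sequence <- function(element, facing) {
  aa <- rep("A", length(element))
  aa[element == "strand" & facing == "core"] <- "V"
  aa[element == "strand" & facing == "exterior"] <- "T"
  aa[element == "loop"] <- "G"
  hel <- which(element == "helix")
  aa[hel] <- c("L", "A", "E", "A")[(seq_along(hel) - 1) %% 4 + 1]
  aa
}

# Helix/loop carbonyl azimuths are free in the idealized backbone; when one
# ends up poking another backbone atom, rotate it about its chain axis to
# point away from the offending partner.
redirect_clashing_carbonyls <- function(res_tab, element, u_out,
                                        cutoff = 2.5) {
  bbcols <- list(N = "n", CA = "ca", C = "c", O = "o")
  for (iter in 1:25) {
    at <- do.call(rbind, lapply(names(bbcols), function(a) {
      cc <- coord_cols(bbcols[[a]])
      data.frame(residue = res_tab$residue, atom = a,
                 x = res_tab[[cc[1]]], y = res_tab[[cc[2]]],
                 z = res_tab[[cc[3]]])
    }))
    d <- as.matrix(stats::dist(as.matrix(at[, c("x", "y", "z")])))
    diag(d) <- Inf
    rmin <- min(res_tab$residue); rmax <- max(res_tab$residue)
    wrapped <- at$residue
    wrapped[wrapped == rmax] <- rmin - 1L
    sep <- pmin(abs(outer(at$residue, at$residue, `-`)),
                abs(outer(wrapped, wrapped, `-`)),
                abs(outer(wrapped, at$residue, `-`)),
                abs(outer(at$residue, wrapped, `-`)))
    no_pair <- outer(at$atom == "N", at$atom == "O", `&`) |
      outer(at$atom == "O", at$atom == "N", `&`)
    lim <- matrix(cutoff, nrow(at), nrow(at))
    lim[no_pair] <- 2.3
    bad <- which(d < lim & sep >= 2, arr.ind = TRUE)
    if (nrow(bad) == 0) break
    fixed_any <- FALSE
    for (p in seq_len(nrow(bad))) {
      i <- bad[p, 1]; j <- bad[p, 2]
      # pick an O on a non-strand residue to re-aim
      cand <- c(i, j)
      is_o <- at$atom[cand] == "O"
      row_r <- match(at$residue[cand], res_tab$residue)
      nonstrand <- element[row_r] != "strand"
      k <- cand[which(is_o & nonstrand)[1]]
      if (is.na(k)) next
      other <- setdiff(cand, k)[1]
      r <- match(at$residue[k], res_tab$residue)
      Cpos <- c(res_tab$c_x[r], res_tab$c_y[r], res_tab$c_z[r])
      axis <- u_out[r, ]
      awayv <- Cpos - c(at$x[other], at$y[other], at$z[other])
      awayv <- awayv - sum(awayv * axis) * axis
      if (vnorm(awayv) < 1e-6) awayv <- vperp(axis)
      o <- Cpos + 1.23 * vunit(awayv)
      res_tab$o_x[r] <- o[1]; res_tab$o_y[r] <- o[2]; res_tab$o_z[r] <- o[3]
      fixed_any <- TRUE
      break
    }
    if (!fixed_any) break
  }
  res_tab
}

# Error if any non-bonded backbone atom pair (sequence separation >= 2) is
# closer than 2.5 Angstrom. Amide-carbonyl N/O pairs are hydrogen-bond
# donor-acceptor contacts and only count as clashes below 2.3 Angstrom.
# In a rotationally repetitive design the dangling C-terminal loop ends one
# virtual bond before the chain start (circular closure), so the terminal
# residue pair is treated as bonded.
check_backbone_clashes <- function(model, cutoff = 2.5, hbond_cutoff = 2.3) {
  at <- model_atom_table(model)
  at <- at[at$atom %in% c("N", "CA", "C", "O"), ]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  res_wrap <- at$residue
  rng <- range(model$residue)
  res_wrap[at$residue == rng[2]] <- rng[1] - 1L   # virtual closure
  sep <- pmin(abs(outer(at$residue, at$residue, `-`)),
              abs(outer(res_wrap, res_wrap, `-`)),
              abs(outer(res_wrap, at$residue, `-`)),
              abs(outer(at$residue, res_wrap, `-`)))
  no_pair <- outer(at$atom == "N", at$atom == "O", `&`) |
    outer(at$atom == "O", at$atom == "N", `&`)
  lim <- matrix(cutoff, nrow(at), nrow(at))
  lim[no_pair] <- hbond_cutoff
  bad <- d < lim & sep >= 2
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("backbone clash: %s %d and %s %d at %.2f Angstrom",
                 at$atom[ij[1]], at$residue[ij[1]],
                 at$atom[ij[2]], at$residue[ij[2]], d[ij[1], ij[2]]))
  }
  invisible(TRUE)
}

#' Autoregressive element-length search
#'
#' Greedy phase-wise search over element lengths: for each phase in order all
#' candidate lengths for that slot are scored conditioned on the already
#' fixed slots, the argmax is frozen, and the search proceeds to the next
#' slot. Ties are broken towards the smallest length (with a warning).
#'
#' @param state list with `fixed` (named list of already-fixed slot lengths,
#'   may be empty) and `grid` (named list of candidate length vectors, one
#'   per slot still open).
#' @param scorer function taking a named list of slot lengths and returning a
#'   finite numeric score (larger is better).
#' @param phases character vector of slot names giving the sampling order;
#'   defaults to the order of `state$grid`.
#' @return List with `lengths` (named list, all slots fixed) and `trace`
#'   (tibble: phase, candidate, score, chosen).
#' @export
autoregressive_search <- function(state, scorer, phases = names(state$grid)) {
  fixed <- as.list(state$fixed %||% list())
  if (length(phases) == 0 || is.null(state$grid)) stop("empty candidate grid")
  trace <- list()
  for (ph in phases) {
    cand <- sort(state$grid[[ph]])
    if (length(cand) == 0) stop(sprintf("empty candidate grid for slot '%s'", ph))
    scores <- vapply(cand, function(len) {
      scorer(utils::modifyList(fixed, stats::setNames(list(len), ph)))
    }, numeric(1))
    if (any(!is.finite(scores))) stop("scorer returned a non-finite value")
    best <- which(scores == max(scores))
    if (length(best) > 1)
      warning(sprintf("tie in phase '%s'; choosing smallest length %d",
                      ph, cand[best[1]]))
    pick <- cand[best[1]]
    fixed[[ph]] <- pick
    trace[[ph]] <- tibble::tibble(phase = ph, candidate = cand,
                                  score = scores, chosen = cand == pick)
  }
  list(lengths = fixed, trace = dplyr::bind_rows(trace))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
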