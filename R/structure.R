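# Quantitative barrel geometry: strand assignment from hydrogen-bond
# ladders, axis and ellipse fitting, face classification, shear measurement,
# repeat symmetry.

# Backbone amide-carbonyl contacts: N(i)...O(j) pairs within `cutoff`,
# sequence separation >= 3.
hbond_pairs <- function(model, cutoff = 3.5) {
  N <- model_coords(model, "n")
  O <- model_coords(model, "o")
  res <- model$residue
  ok <- stats::complete.cases(N) & stats::complete.cases(O)
  d2 <- outer(rowSums(N^2), rowSums(O^2), `+`) - 2 * N %*% t(O)
  d2[!ok, ] <- Inf; d2[, !ok] <- Inf
  sep <- abs(outer(res, res, `-`))
  hit <- which(d2 <= cutoff^2 & sep >= 3, arr.ind = TRUE)
  tibble::tibble(donor = res[hit[, 1]], acceptor = res[hit[, 2]])
}

#' Assign beta strands from the hydrogen-bond ladder
#'
#' Beta residues are identified by the DSSP-style parallel/antiparallel
#' bridge criterion on backbone N...O contacts (<= 3.5 Angstrom, sequence
#' separation >= 5): residues i, j form a bridge when the two ladder
#' hydrogen bonds of either bridge pattern are present. Strands are maximal
#' consecutive runs of bridge-forming residues, extended by one residue at
#' each end when a single cross-strand hydrogen bond supports it. A
#' user-supplied assignment overrides detection.
#'
#' @param model a `barrel_model`.
#' @param cutoff N...O hydrogen-bond distance cutoff (Angstrom).
#' @param override optional tibble with columns `residue`, `strand`
#'   (and optionally a precomputed `ladder`); returned as-is.
#' @return Object of class `strand_assignment`: list with `residues`
#'   (tibble: residue, strand), `ladder` (tibble: res_i, res_j, strand_i,
#'   strand_j bridge pairs), and `n_strands`.
#' @export
assign_strands <- function(model, cutoff = 3.5, override = NULL) {
  if (!is.null(override)) {
    out <- list(residues = tibble::as_tibble(override[, c("residue", "strand")]),
                ladder = if ("ladder" %in% names(override)) override$ladder
                         else tibble::tibble(),
                n_strands = length(unique(override$strand)))
    class(out) <- "strand_assignment"
    return(out)
  }
  hb <- hbond_pairs(model, cutoff)
  has_bond <- function(d, a) paste(d, a) %in% paste(hb$donor, hb$acceptor)
  # candidate bridge pairs: both residues appear in some hydrogen bond
  cand <- unique(rbind(
    data.frame(i = hb$donor, j = hb$acceptor),
    data.frame(i = hb$acceptor, j = hb$donor)))
  cand <- cand[cand$i < cand$j & abs(cand$i - cand$j) >= 5, , drop = FALSE]
  # widen: partners of nearby bonds (bridge patterns involve j-1/j+1)
  widen <- unique(do.call(rbind, lapply(-1:1, function(s)
    transform(cand, j = j + s))))
  widen <- widen[widen$i < widen$j & abs(widen$i - widen$j) >= 5, ]
  cand <- unique(rbind(cand, widen))
  is_bridge <- with(cand,
    (has_bond(j + 1, i) & has_bond(i, j - 1)) |   # parallel
    (has_bond(i + 1, j) & has_bond(j, i - 1)) |   # parallel (mirror)
    (has_bond(i, j) & has_bond(j, i)) |           # antiparallel
    (has_bond(i + 1, j - 1) & has_bond(j + 1, i - 1)))
  bridges <- cand[is_bridge, , drop = FALSE]
  beta <- sort(unique(c(bridges$i, bridges$j)))
  beta <- beta[beta %in% model$residue]
  # close single-residue gaps: only alternate ladder rungs carry the full
  # two-bond bridge pattern, so a residue flanked by bridge residues is beta
  gaps <- intersect(beta + 1L, beta - 1L)
  beta <- sort(union(beta, setdiff(intersect(gaps, model$residue), beta)))

  # strand segments: maximal consecutive runs
  strand_id <- integer(0); seg_res <- integer(0)
  if (length(beta)) {
    brk <- cumsum(c(1, diff(beta) != 1))
    seg_res <- beta; strand_id <- brk
  }
  resmap <- stats::setNames(strand_id, seg_res)
  core_set <- seg_res

  # single-H-bond extension at strand termini
  all_hb <- rbind(data.frame(a = hb$donor, b = hb$acceptor),
                  data.frame(a = hb$acceptor, b = hb$donor))
  repeat {
    grew <- FALSE
    for (r in as.integer(names(resmap))) {
      for (nb in c(r - 1L, r + 1L)) {
        if (!(nb %in% model$residue)) next
        if (as.character(nb) %in% names(resmap)) next
        partners <- all_hb$b[all_hb$a == nb]
        ps <- resmap[as.character(partners)]
        if (any(!is.na(ps) & ps != resmap[as.character(r)] &
                abs(partners - nb) >= 5)) {
          resmap[as.character(nb)] <- resmap[as.character(r)]
          grew <- TRUE
        }
      }
    }
    if (!grew) break
  }
  res_tab <- tibble::tibble(residue = as.integer(names(resmap)),
                            strand = as.integer(resmap),
                            core = as.integer(names(resmap)) %in% core_set) |>
    dplyr::arrange(.data$residue)
  # isolated bridges are not strands: drop runs shorter than 3 residues
  keep <- res_tab |>
    dplyr::count(.data$strand) |>
    dplyr::filter(.data$n >= 3) |>
    dplyr::pull(.data$strand)
  res_tab <- res_tab[res_tab$strand %in% keep, ]
  # renumber strands in sequence order
  lev <- unique(res_tab$strand)
  res_tab$strand <- match(res_tab$strand, lev)
  n_str <- length(unique(res_tab$strand))
  if (n_str < 3) stop("barrel error: fewer than 3 strands detected")

  smap <- stats::setNames(res_tab$strand, res_tab$residue)
  ladder <- bridges |>
    dplyr::mutate(strand_i = unname(smap[as.character(.data$i)]),
                  strand_j = unname(smap[as.character(.data$j)])) |>
    dplyr::filter(!is.na(.data$strand_i), !is.na(.data$strand_j),
                  .data$strand_i != .data$strand_j) |>
    dplyr::rename(res_i = "i", res_j = "j") |>
    tibble::as_tibble()
  structure(list(residues = res_tab, ladder = ladder, n_strands = n_str),
            class = "strand_assignment")
}

#' @export
print.strand_assignment <- function(x, ...) {
  lens <- table(x$residues$strand)
  cat(sprintf("%d strands (lengths %s), %d ladder bridge pairs\n",
              x$n_strands, paste(lens, collapse = ","), nrow(x$ladder)))
  invisible(x)
}

# Barrel-order cycle of strands from ladder adjacency. Returns the ordered
# strand ids; errors if the adjacency does not close into a single cycle.
strand_cycle <- function(strands) {
  lad <- strands$ladder
  adj <- lapply(seq_len(strands$n_strands), function(s) {
    nb <- c(lad$strand_j[lad$strand_i == s], lad$strand_i[lad$strand_j == s])
    cnt <- sort(table(nb), decreasing = TRUE)
    as.integer(names(cnt))[seq_len(min(2, length(cnt)))]
  })
  cyc <- 1L
  prev <- NA_integer_
  repeat {
    cur <- cyc[length(cyc)]
    nxt <- setdiff(adj[[cur]], prev)
    if (length(nxt) == 0) stop("open barrel: strand adjacency does not close")
    nxt <- nxt[1]
    if (nxt == 1L) break
    if (nxt %in% cyc) stop("open barrel: strand adjacency does not close")
    prev <- cur
    cyc <- c(cyc, nxt)
  }
  if (length(cyc) != strands$n_strands)
    stop("open barrel: not all strands lie on one cycle")
  cyc
}

#' Measure the shear number from a structure
#'
#' Traverses the hydrogen-bond ladder once around the closed barrel and
#' returns the accumulated residue register offset: for each adjacent-strand
#' junction the offset is the median difference of residue numbers over that
#' junction's bridge pairs, and the cyclic sum of the junction offsets (whose
#' strand-boundary terms telescope away) is the shear. The absolute value is
#' returned.
#'
#' @param model a `barrel_model`.
#' @param strands a [assign_strands()] result; computed if missing.
#' @return Integer shear number.
#' @export
measure_shear_from_structure <- function(model, strands = NULL) {
  if (is.null(strands)) strands <- assign_strands(model)
  cyc <- strand_cycle(strands)
  lad <- strands$ladder
  n <- length(cyc)
  offsets <- vapply(seq_len(n), function(k) {
    s1 <- cyc[k]; s2 <- cyc[if (k == n) 1 else k + 1]
    sel12 <- lad$strand_i == s1 & lad$strand_j == s2
    sel21 <- lad$strand_i == s2 & lad$strand_j == s1
    diffs <- c(lad$res_i[sel12] - lad$res_j[sel12],
               lad$res_j[sel21] - lad$res_i[sel21])
    if (length(diffs) == 0) stop("open barrel: junction without bridge pairs")
    stats::median(diffs)
  }, numeric(1))
  as.integer(round(abs(sum(offsets))))
}

#' Fit the barrel axis
#'
#' The axis is the sign-aligned mean of the per-strand principal directions
#' of strand CA atoms; the centroid of all strand CA atoms anchors it. Both
#' are equivariant under rigid motion of the input.
#'
#' @param model a `barrel_model`.
#' @param strands a [assign_strands()] result; computed if missing.
#' @return List of class `barrel_axis` with `direction` (unit 3-vector) and
#'   `center`.
#' @export
fit_barrel_axis <- function(model, strands = NULL) {
  if (is.null(strands)) strands <- assign_strands(model)
  if (strands$n_strands < 3) stop("need at least 3 strands")
  rtab <- strands$residues
  if ("core" %in% names(rtab) && any(rtab$core)) rtab <- rtab[rtab$core, ]
  dirs <- lapply(sort(unique(rtab$strand)), function(s) {
    res <- rtab$residue[rtab$strand == s]
    xyz <- model_coords(model, "ca", res)
    xyz <- xyz[stats::complete.cases(xyz), , drop = FALSE]
    if (nrow(xyz) < 2) return(NULL)
    pc <- prcomp(xyz)
    pc$rotation[, 1]
  })
  dirs <- Filter(Negate(is.null), dirs)
  ref <- dirs[[1]]
  aligned <- t(vapply(dirs, function(d) d * sign(sum(d * ref)), numeric(3)))
  mdir <- colMeans(aligned)
  if (vnorm(mdir) < 0.1) stop("degenerate strand directions: no common axis")
  res_all <- strands$residues$residue
  xyz <- model_coords(model, "ca", res_all)
  structure(list(direction = vunit(mdir),
                 center = colMeans(xyz[stats::complete.cases(xyz), , drop = FALSE])),
            class = "barrel_axis")
}

#' Fit the barrel cross-section ellipse
#'
#' Projects strand-wall CA atoms onto the plane normal to the barrel axis
#' and fits an ellipse by direct least squares. Faces follow the curvature
#' convention: the minor faces are the two 90-degree arcs of tightest
#' curvature, centred on the vertices of the fitted major axis; the flat
#' major faces are centred on the minor-axis vertices.
#'
#' @param model a `barrel_model`.
#' @param strands a [assign_strands()] result; computed if missing.
#' @param axis a [fit_barrel_axis()] result; computed if missing.
#' @return Object of class `barrel_shape_fit`: list with `semi_major_a`,
#'   `semi_minor_b`, `eccentricity`, `axis`, `center2d`, and `strands`
#'   (tibble: strand, radius, face, angle).
#' @export
fit_cross_section <- function(model, strands = NULL, axis = NULL) {
  if (is.null(strands)) strands <- assign_strands(model)
  if (is.null(axis)) axis <- fit_barrel_axis(model, strands)
  e3 <- axis$direction
  e1 <- vperp(e3)
  e2 <- vcross(e3, e1)
  tab <- strands$residues
  xyz <- model_coords(model, "ca", tab$residue)
  keep <- stats::complete.cases(xyz)
  xyz <- sweep(xyz[keep, , drop = FALSE], 2, axis$center)
  tab <- tab[keep, ]
  px <- xyz %*% e1
  py <- xyz %*% e2
  fit <- fit_ellipse(px, py)
  # parametric angle of the nearest ellipse point, in the ellipse frame
  ct <- cos(fit$angle); st <- sin(fit$angle)
  rx <- (px - fit$center[1]) * ct + (py - fit$center[2]) * st
  ry <- -(px - fit$center[1]) * st + (py - fit$center[2]) * ct
  theta <- atan2(ry / fit$b, rx / fit$a)
  rad <- sqrt((px - fit$center[1])^2 + (py - fit$center[2])^2)
  per_strand <- tibble::tibble(strand = tab$strand, radius = as.vector(rad),
                               theta = as.vector(theta)) |>
    dplyr::group_by(.data$strand) |>
    dplyr::summarise(
      radius = stats::median(.data$radius),
      angle = atan2(mean(sin(.data$theta)), mean(cos(.data$theta))),
      .groups = "drop") |>
    dplyr::mutate(
      face = ifelse(pmin(abs(.data$angle), pi - abs(.data$angle)) < pi / 4,
                    "minor", "major"))
  structure(list(semi_major_a = fit$a, semi_minor_b = fit$b,
                 eccentricity = fit$eccentricity,
                 axis = axis, center2d = fit$center,
                 strands = per_strand),
            class = "barrel_shape_fit")
}

#' @export
print.barrel_shape_fit <- function(x, ...) {
  cat(sprintf("Barrel cross-section: a = %.2f, b = %.2f A, e = %.3f\n",
              x$semi_major_a, x$semi_minor_b, x$eccentricity))
  print(x$strands)
  invisible(x)
}

#' Repeat-symmetry RMSD
#'
#' Superposes the CA atoms of the first repeat onto the second and returns
#' the RMSD, the self-consistency measure of a twofold-repeat design.
#'
#' @param model a `barrel_model` with `2 * residues_per_repeat` residues.
#' @param residues_per_repeat repeat length (residues).
#' @return RMSD in Angstrom.
#' @export
repeat_symmetry_rmsd <- function(model, residues_per_repeat) {
  if (nrow(model) != 2 * residues_per_repeat)
    stop("model length must equal 2 * residues_per_repeat")
  r1 <- model$residue[seq_len(residues_per_repeat)]
  r2 <- model$residue[residues_per_repeat + seq_len(residues_per_repeat)]
  ca1 <- model_coords(model, "ca", r1)
  ca2 <- model_coords(model, "ca", r2)
  keep <- stats::complete.cases(ca1) & stats::complete.cases(ca2)
  superpose(ca1[keep, , drop = FALSE], ca2[keep, , drop = FALSE])$rmsd
}

#' Steric-size enrichment on C-beta strip faces
#'
#' Tests whether the residues at minor-face strip positions are sterically
#' smaller than the strip positions overall, using mean residue volumes as
#' the size proxy and a label-permutation test (residue identities shuffled
#' over strip positions).
#'
#' @param model a `barrel_model` (its sequence is used).
#' @param strips tibble from [enumerate_cbeta_strips()] (columns `strand`,
#'   `residue`).
#' @param faces tibble mapping `strand` to `face` ("minor"/"major"), e.g.
#'   the `strands` component of [fit_cross_section()].
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutation draw.
#' @return Tibble with `mean_minor`, `mean_all`, `difference` (minor minus
#'   all, cubic Angstrom) and one-sided `p_value` for the "smaller at the
#'   minor face" alternative.
#' @export
small_residue_enrichment <- function(model, strips, faces, n_perm = 1000,
                                     seed = 1) {
  vol <- residue_volumes()
  seqv <- model_sequence(model)
  strips <- dplyr::left_join(strips, faces[, c("strand", "face")], by = "strand")
  strips$volume <- unname(vol[seqv[as.character(strips$residue)]])
  strips <- strips[!is.na(strips$volume), ]
  minor <- strips$face == "minor"
  if (!any(minor)) stop("no minor-face strip positions")
  obs <- mean(strips$volume[minor]) - mean(strips$volume)
  set.seed(seed)
  perm <- replicate(n_perm, {
    v <- sample(strips$volume)
    mean(v[minor]) - mean(v)
  })
  p <- (1 + sum(perm <= obs)) / (n_perm + 1)
  tibble::tibble(mean_minor = mean(strips$volume[minor]),
                 mean_all = mean(strips$volume),
                 difference = obs,
                 p_value = p,
                 n_minor = sum(minor),
                 n_total = nrow(strips))
}
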