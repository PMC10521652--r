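# Deterministic Shrake-Rupley solvent-accessible surface area. Sphere
# points come from a golden-spiral construction, so results are exactly
# reproducible without a random seed.

# xyz: n x 3 matrix; radius: length-n vdW radii. Returns per-atom SASA in
# square Angstrom for a probe of `probe` Angstrom.
sasa_atoms <- function(xyz, radius, probe = 1.4, n_points = 960) {
  n <- nrow(xyz)
  pts <- golden_spiral(n_points)
  R <- radius + probe
  out <- numeric(n)
  # neighbour prefilter
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    surf <- sweep(pts * R[i], 2, xyz[i, ], `+`)
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        dj <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
          (surf[, 3] - xyz[j, 3])^2
        acc <- acc & dj > R[j]^2
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else frac <- 1
    out[i] <- 4 * pi * R[i]^2 * frac
  }
  out
}

#' Per-residue relative side-chain solvent accessibility
#'
#' Shrake-Rupley SASA (1.4 Angstrom probe, deterministic golden-spiral
#' sphere points) of each residue's side-chain heavy atoms (CB and beyond;
#' CA for glycine), in the context of all heavy atoms of the model. The
#' relative value normalises by the same side-chain atoms' SASA in the
#' residue's own isolated context (its backbone plus side chain only), so
#' burial is measured consistently whether side chains are full or
#' truncated pseudo-atom sets.
#'
#' @param model a `barrel_model`.
#' @param n_points sphere points per atom.
#' @return Tibble with `residue`, `aa`, `sasa` (square Angstrom) and
#'   `rel_sasa` (0 = fully buried, 1 = as exposed as in the free residue).
#' @export
residue_sasa <- function(model, n_points = 960) {
  at <- model_atom_table(model)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  a <- sasa_atoms(xyz, at$radius, n_points = n_points)
  side <- !(at$atom %in% c("N", "CA", "C", "O")) |
    (at$atom == "CA" & at$aa == "G")
  ref <- vapply(unique(at$residue), function(r) {
    sel <- at$residue == r
    iso <- sasa_atoms(xyz[sel, , drop = FALSE], at$radius[sel],
                      n_points = n_points)
    sum(iso[side[sel]])
  }, numeric(1))
  names(ref) <- unique(at$residue)
  tibble::tibble(residue = at$residue, aa = at$aa, area = a, side = side) |>
    dplyr::group_by(.data$residue, .data$aa) |>
    dplyr::summarise(sasa = sum(.data$area[.data$side]), .groups = "drop") |>
    dplyr::mutate(rel_sasa = pmin(.data$sasa /
                                    pmax(ref[as.character(.data$residue)], 1),
                                  1))
}
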