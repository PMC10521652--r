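# Deterministic fixture generators: preset barrels with designed sequences,
# decoys (noise / flipped strand / deleted strand), named mutation variants,
# and denaturation-curve panels.

#' Designed default sequence for a preset blueprint
#'
#' Deterministic rule-based sequence: core-facing strand positions carry
#' small residues (Ala/Val) on the tight-curvature minor-face strands and
#' large ones (Ile/Leu) on the flat major-face strands; exterior strand
#' positions are Thr; helices cycle Leu/Ala/Glu/Ala; loops cycle
#' Gly/Ser/Asp. For the twofold ovoid blueprint a few positions are pinned
#' (C4, L34, I60, A93 and their repeat partners) so the named polar-variant
#' mutation sets apply cleanly.
#'
#' @param bp a `blueprint`.
#' @param minor_strands strand indices on the minor (tight) faces.
#' @return Character vector of one-letter residues, length
#'   `bp$total_residues`.
#' @export
design_sequence <- function(bp, minor_strands = c(1, 2, 5, 6)) {
  total <- bp$total_residues
  aa <- rep("A", total)
  els <- bp$elements
  for (e in seq_len(nrow(els))) {
    res <- seq(els$start[e], els$end[e])
    k <- seq_along(res)
    aa[res] <- switch(els$kind[e],
      helix = c("L", "A", "E", "A")[(k - 1) %% 4 + 1],
      loop = c("G", "S", "D")[(k - 1) %% 3 + 1],
      strand = "T")
  }
  tab <- strand_position_table(bp)
  core <- tab[tab$core_facing, ]
  minor <- core$strand %in% minor_strands
  aa[core$residue[minor]] <- c("A", "V")[(core$local[minor] %% 2) + 1]
  aa[core$residue[!minor]] <- c("I", "L")[(core$local[!minor] %% 2) + 1]
  if (bp$repeat_count == 2 && bp$residues_per_repeat == 114) {
    pin <- c("4" = "C", "34" = "L", "60" = "I", "93" = "A")
    for (p in names(pin)) {
      i <- as.integer(p)
      aa[i] <- pin[[p]]
      aa[repeat_partner(i, bp)] <- pin[[p]]
    }
  }
  aa
}

# Idealized side-chain pseudo-atoms beyond CB for Ile/Leu/Val, placed along
# the CA->CB direction with small lateral spread. Enough heavy atoms for
# contact-area statistics; not rotamer chemistry.
ilv_pseudo_atoms <- function(model) {
  ca <- model_coords(model, "ca")
  cb <- model_coords(model, "cb")
  n <- model_coords(model, "n")
  sc <- model$sc
  for (r in which(model$aa %in% ILV_AA)) {
    if (is.na(cb[r, 1])) next
    dir <- vunit(cb[r, ] - ca[r, ])
    lat0 <- n[r, ] - ca[r, ]
    lat <- lat0 - sum(lat0 * dir) * dir
    lat <- if (vnorm(lat) < 1e-6) vperp(dir) else vunit(lat)
    g1 <- cb[r, ] + 1.52 * vunit(dir + 0.55 * lat)
    g2 <- cb[r, ] + 1.52 * vunit(dir - 0.55 * lat)
    sc[[r]] <- switch(model$aa[r],
      V = tibble::tibble(atom = c("CG1", "CG2"),
                         x = c(g1[1], g2[1]), y = c(g1[2], g2[2]),
                         z = c(g1[3], g2[3])),
      I = {
        d1 <- g1 + 1.52 * dir
        tibble::tibble(atom = c("CG1", "CG2", "CD1"),
                       x = c(g1[1], g2[1], d1[1]), y = c(g1[2], g2[2], d1[2]),
                       z = c(g1[3], g2[3], d1[3]))
      },
      L = {
        g <- cb[r, ] + 1.52 * dir
        d1 <- g + 1.52 * vunit(dir + 0.55 * lat)
        d2 <- g + 1.52 * vunit(dir - 0.55 * lat)
        tibble::tibble(atom = c("CG", "CD1", "CD2"),
                       x = c(g[1], d1[1], d2[1]), y = c(g[2], d1[2], d2[2]),
                       z = c(g[3], d1[3], d2[3]))
      })
  }
  model$sc <- sc
  model
}

#' Preset synthetic structures
#'
#' Deterministic generated models covering the study conditions:
#' \describe{
#'   \item{ovoid}{228-residue twofold TIM barrel from
#'     [make_ovoid_blueprint()] with 13:9 cross-section aspect and the
#'     designed default sequence.}
#'   \item{circular}{184-residue fourfold circular TIM barrel, eight equal
#'     strands of length 5, all register shifts 1 (shear 8).}
#'   \item{zero_shear_toy}{single-wall barrel with all register shifts 0.}
#'   \item{porin_like}{single-wall ovoid barrel (no helices), eight strands
#'     of length 7.}
#' }
#' ILV residues carry idealized side-chain pseudo-atoms so contact-area
#' statistics are computable.
#'
#' @param name preset name.
#' @return A `barrel_model`.
#' @export
preset <- function(name = c("ovoid", "circular", "zero_shear_toy",
                            "porin_like")) {
  name <- match.arg(name)
  m <- switch(name,
    ovoid = {
      bp <- make_ovoid_blueprint()
      generate_full_timb(bp, barrel_params(13, 9),
                         sequence = stats::setNames(design_sequence(bp),
                                                    seq_len(bp$total_residues)))
    },
    circular = {
      bp <- make_circular_blueprint()
      generate_full_timb(bp, barrel_params(9, 9),
                         sequence = stats::setNames(
                           design_sequence(bp, minor_strands = integer(0)),
                           seq_len(bp$total_residues)))
    },
    zero_shear_toy = {
      els <- data.frame(kind = rep(c("strand", "loop"), 8),
                        length = rep(c(6L, 3L), 8))
      bp <- new_blueprint(els, rep(0L, 8))
      generate_barrel(bp, barrel_params(9, 9))
    },
    porin_like = {
      els <- data.frame(kind = rep(c("strand", "loop"), 8),
                        length = rep(c(7L, 3L), 8))
      bp <- new_blueprint(els, rep(1L, 8))
      generate_barrel(bp, barrel_params(13, 9))
    })
  ilv_pseudo_atoms(m)
}

#' Structural decoys
#'
#' \describe{
#'   \item{noise}{i.i.d. Gaussian displacement (sd `sigma`) of every atom
#'     coordinate.}
#'   \item{flipped_strand}{facing parity of strand `strand` inverted: the
#'     amino acids at its core and exterior positions are swapped, so
#'     residues designed inward now face the helices (coordinates keep the
#'     original geometry).}
#'   \item{deleted_strand}{residues of strand `strand` removed.}
#' }
#'
#' @param model a `barrel_model` with strand annotations.
#' @param kind decoy kind.
#' @param sigma noise standard deviation (Angstrom).
#' @param strand strand index for flip/delete.
#' @param seed RNG seed for the noise decoy.
#' @return A `barrel_model`.
#' @export
make_decoy <- function(model, kind = c("noise", "flipped_strand",
                                       "deleted_strand"),
                       sigma = 0.3, strand = 3, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "noise") {
    if (sigma == 0) return(model)
    set.seed(seed)
    cc <- unlist(lapply(BB_ATOMS, coord_cols))
    for (col in cc) {
      v <- model[[col]]
      ok <- !is.na(v)
      model[[col]][ok] <- v[ok] + stats::rnorm(sum(ok), sd = sigma)
    }
    model$sc <- lapply(model$sc, function(s) {
      if (is.null(s)) return(NULL)
      s$x <- s$x + stats::rnorm(nrow(s), sd = sigma)
      s$y <- s$y + stats::rnorm(nrow(s), sd = sigma)
      s$z <- s$z + stats::rnorm(nrow(s), sd = sigma)
      s
    })
    return(as_barrel_model(model))
  }
  if (is.na(strand) || !strand %in% model$strand)
    stop("invalid strand index")
  if (kind == "deleted_strand") {
    out <- model[is.na(model$strand) | model$strand != strand, ]
    return(as_barrel_model(out))
  }
  # flipped strand: swap the sequence between core and exterior positions
  idx <- which(!is.na(model$strand) & model$strand == strand)
  core <- idx[model$facing[idx] == "core"]
  ext <- idx[model$facing[idx] == "exterior"]
  k <- min(length(core), length(ext))
  aa <- model$aa
  tmp <- aa[core[seq_len(k)]]
  aa[core[seq_len(k)]] <- aa[ext[seq_len(k)]]
  aa[ext[seq_len(k)]] <- tmp
  model$aa <- aa
  model <- rebuild_mutated_sidechains(model, model$residue[idx])
  as_barrel_model(model)
}

# Rebuild CB and pseudo side-chain atoms after sequence edits: CB is placed
# (or removed) from the local backbone frame; ILV pseudo-atoms regenerated.
rebuild_mutated_sidechains <- function(model, residues) {
  ca <- model_coords(model, "ca")
  for (r in residues) {
    i <- which(model$residue == r)
    if (model$aa[i] == "G") {
      model$cb_x[i] <- NA_real_; model$cb_y[i] <- NA_real_
      model$cb_z[i] <- NA_real_
      model$sc[i] <- list(NULL)
      next
    }
    if (is.na(model$cb_x[i])) {
      # residue gained a side chain: place CB from the chain frame
      prev <- if (i > 1) ca[i - 1, ] else NULL
      nxt <- if (i < nrow(model)) ca[i + 1, ] else NULL
      u_in <- if (!is.null(prev)) vunit(ca[i, ] - prev) else vunit(nxt - ca[i, ])
      u_out <- if (!is.null(nxt)) vunit(nxt - ca[i, ]) else u_in
      cb <- cb_from_frame(ca[i, ], u_in, u_out)
      model$cb_x[i] <- cb[1]; model$cb_y[i] <- cb[2]; model$cb_z[i] <- cb[3]
    }
    model$sc[i] <- list(NULL)
  }
  ilv_pseudo_atoms(as_barrel_model(model))
}

#' Named mutation variants of the ovoid design
#'
#' Applies a mutation set to a model. Named polar variants follow the
#' published set on the ovoid numbering: PV1 = I60K + I174A, PV2 = I174E,
#' PV3 = I60K + I174E (modelled as a buried salt bridge), PV4 = C4S,
#' PV5 = A93K + L148A. Named hollow variants (HV1--HV7) mutate core layers
#' to alanine; with the `symmetric` flag (default for HV) every mutation at
#' position i is mirrored at its repeat partner i + 114. Explicit mutation
#' tables are accepted in place of a name.
#'
#' @param model a `barrel_model` (ovoid preset numbering for named
#'   variants).
#' @param variant variant name (`"PV1"`..`"PV5"`, `"HV1"`..`"HV7"`) or a
#'   tibble with columns `position`, `from`, `to`.
#' @param bp blueprint for layer enumeration / repeat partners (default the
#'   ovoid blueprint).
#' @param symmetric auto-apply repeat partners to every mutation.
#' @param hv_positions optional explicit first-repeat position list
#'   overriding the layer rule for HV variants.
#' @return List with `model` (mutated) and `mutations` (tibble: position,
#'   from, to).
#' @export
apply_variant <- function(model, variant, bp = make_ovoid_blueprint(),
                          symmetric = NULL, hv_positions = NULL) {
  seqv <- model_sequence(model)
  if (is.character(variant) && length(variant) == 1) {
    name <- variant
    if (grepl("^PV[1-5]$", name)) {
      muts <- switch(name,
        PV1 = data.frame(position = c(60, 174), to = c("K", "A")),
        PV2 = data.frame(position = 174, to = "E"),
        PV3 = data.frame(position = c(60, 174), to = c("K", "E")),
        PV4 = data.frame(position = 4, to = "S"),
        PV5 = data.frame(position = c(93, 148), to = c("K", "A")))
      if (is.null(symmetric)) symmetric <- FALSE
    } else if (grepl("^HV[1-7]$", name)) {
      lay <- enumerate_layers(bp)
      lay <- lay[lay$residue <= bp$residues_per_repeat, ]
      lay$layer <- match(lay$layer, sort(unique(lay$layer)))
      n_lay <- max(lay$layer)
      sel <- switch(name,
        HV1 = 1:2, HV2 = 1:3, HV3 = (n_lay - 1):n_lay,
        HV4 = 1, HV5 = 2, HV6 = 3, HV7 = 2:3)
      pos <- if (!is.null(hv_positions)) hv_positions else
        lay$residue[lay$layer %in% sel]
      pos <- pos[seqv[as.character(pos)] != "A"]
      muts <- data.frame(position = pos, to = "A")
      if (is.null(symmetric)) symmetric <- TRUE
    } else stop("unknown variant: ", name)
  } else {
    muts <- as.data.frame(variant)
    if (is.null(symmetric)) symmetric <- FALSE
    if (nrow(muts) == 0) {
      return(list(model = model,
                  mutations = tibble::tibble(position = integer(0),
                                             from = character(0),
                                             to = character(0))))
    }
  }
  if (symmetric) {
    partner <- data.frame(position = repeat_partner(muts$position, bp),
                          to = muts$to)
    muts <- unique(rbind(muts[, c("position", "to")],
                         partner[, c("position", "to")]))
  }
  muts$from_model <- unname(seqv[as.character(muts$position)])
  if ("from" %in% names(muts)) {
    bad <- muts$from != muts$from_model
    if (any(bad))
      stop(sprintf("mutation from-residue mismatch at position %d: model has %s, expected %s",
                   muts$position[bad][1], muts$from_model[bad][1],
                   muts$from[bad][1]))
  }
  muts$from <- muts$from_model
  model$aa[match(muts$position, model$residue)] <- muts$to
  model <- rebuild_mutated_sidechains(model, muts$position)
  list(model = as_barrel_model(model),
       mutations = tibble::as_tibble(muts[, c("position", "from", "to")]))
}

#' Panel of synthetic denaturation curves
#'
#' A deterministic grid of two-state curves over (dG, m) parameter sets --
#' including the published guanidine-unfolding parameters of the first
#' ovoid design (dG = 8.4 kcal/mol, m = 1.6 kcal/mol/M, Cm = 5.25 M) --
#' crossed with noise levels and baseline-slope settings.
#'
#' @param seed integer seed; each curve gets a distinct deterministic
#'   sub-seed.
#' @param n_points points per curve, over 0--7.5 M.
#' @return Tibble with parameter columns and a `curve` list-column of
#'   [simulate_curve()] tibbles.
#' @export
make_curve_panel <- function(seed = 1, n_points = 30) {
  grid <- tidyr::expand_grid(
    params = list(c(dG = 8.4, m = 1.6), c(dG = 6, m = 2), c(dG = 10, m = 1.3)),
    noise = c(0, 0.005, 0.01),
    slopes = list(c(b_f = 0, b_u = 0), c(b_f = -0.01, b_u = -0.004)))
  x <- seq(0, 7.5, length.out = n_points)
  grid |>
    dplyr::mutate(
      dG = purrr::map_dbl(.data$params, "dG"),
      m = purrr::map_dbl(.data$params, "m"),
      curve_id = dplyr::row_number(),
      curve = purrr::pmap(list(.data$params, .data$noise, .data$slopes,
                               .data$curve_id),
        function(p, nz, sl, id) {
          simulate_curve(p[["dG"]], p[["m"]],
                         baselines = list(a_f = 1, b_f = sl[["b_f"]],
                                          a_u = 0.1, b_u = sl[["b_u"]]),
                         x = x, noise_sd = nz, seed = seed * 1000 + id)
        })) |>
    dplyr::select("curve_id", "dG", "m", "noise", "curve")
}
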