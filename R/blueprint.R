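# Barrel blueprint "syntax": ordered secondary-structure elements, per
# strand-junction register shifts, shear arithmetic, repeats, core layers and
# C-beta strips.

#' Construct a barrel blueprint
#'
#' A blueprint is the residue-level syntax of a (beta/alpha) barrel: an ordered
#' collection of secondary-structure elements (`strand`, `helix`, `loop`) with
#' lengths, plus one integer register shift per adjacent-strand junction
#' (cyclic, so `n_strands` junctions in total). The cyclic sum of the register
#' shifts is the barrel's shear number, stored at construction as the declared
#' shear of the design.
#'
#' @param elements data frame with columns `kind` (one of `"strand"`,
#'   `"helix"`, `"loop"`) and `length` (integer >= 1), in chain order.
#' @param register_shifts integer vector of per-junction shifts; junction `i`
#'   sits between strand `i` and strand `i + 1` (cyclically back to strand 1).
#' @param repeat_count number of identical sequence repeats (1 for none).
#' @return An object of class `blueprint`: list with `elements` (tibble with
#'   added `element_id`, `index_within_kind`, `start`, `end` residue ranges),
#'   `register_shifts`, `n_strands`, `repeat_count`, `residues_per_repeat`,
#'   `total_residues` and the declared `shear`.
#' @examples
#' bp <- make_ovoid_blueprint()
#' compute_shear(bp)
#' @export
new_blueprint <- function(elements, register_shifts, repeat_count = 1L) {
  elements <- tibble::as_tibble(elements)
  stopifnot(all(c("kind", "length") %in% names(elements)))
  if (!all(elements$kind %in% c("strand", "helix", "loop")))
    stop("element kinds must be strand, helix or loop")
  if (any(elements$length < 1)) stop("element lengths must be >= 1")
  n_strands <- sum(elements$kind == "strand")
  if (length(register_shifts) != n_strands)
    stop(sprintf("need one register shift per strand junction (%d), got %d",
                 n_strands, length(register_shifts)))
  if (anyNA(register_shifts)) stop("register shifts missing for some junction")
  elements <- elements |>
    dplyr::mutate(
      element_id = dplyr::row_number(),
      index_within_kind = stats::ave(seq_along(.data$kind), .data$kind,
                                     FUN = seq_along),
      end = cumsum(.data$length),
      start = .data$end - .data$length + 1L)
  total <- sum(elements$length)
  if (total %% repeat_count != 0)
    stop("total residue count is not divisible by repeat_count")
  structure(
    list(elements = elements,
         register_shifts = as.integer(register_shifts),
         n_strands = n_strands,
         repeat_count = as.integer(repeat_count),
         residues_per_repeat = total %/% repeat_count,
         total_residues = total,
         shear = as.integer(sum(register_shifts))),
    class = "blueprint")
}

#' @export
print.blueprint <- function(x, ...) {
  cat(sprintf(
    "Barrel blueprint: %d strands, shear %d, %d residues (%d repeat%s of %d)\n",
    x$n_strands, x$shear, x$total_residues, x$repeat_count,
    if (x$repeat_count > 1) "s" else "", x$residues_per_repeat))
  cat("strand lengths:", paste(strand_lengths(x), collapse = ","), "\n")
  cat("register shifts:", paste(x$register_shifts, collapse = ","), "\n")
  invisible(x)
}

strand_elements <- function(bp) dplyr::filter(bp$elements, .data$kind == "strand")

#' Strand lengths of a blueprint
#' @param bp a [new_blueprint()] object.
#' @return Integer vector of strand lengths in barrel order.
#' @export
strand_lengths <- function(bp) strand_elements(bp)$length

# Cumulative register shift "before" each strand (C_1 = 0).
cumulative_shifts <- function(bp) {
  c(0L, cumsum(bp$register_shifts))[seq_len(bp$n_strands)]
}

#' The final ovoid TIM-barrel blueprint
#'
#' Builds the twofold-repeat blueprint of the ovoid TIM barrel: per repeat,
#' four strands of lengths 5, 5, 7, 7 with register shifts of 2 at the
#' junctions following the third and fourth strand (and symmetrically in the
#' second repeat), alpha-beta turns of length 3, and helix / beta-alpha-loop
#' lengths that close a 114-residue repeat (228 residues total). The cyclic
#' shift sum gives shear number 8; each repeat contributes a shift of 4.
#'
#' Strand and turn lengths are fixed by the design syntax; helix lengths
#' (default 14) and beta-alpha loop lengths (default 6, 5, 6, 5 per repeat)
#' are the free part of the budget and exposed as arguments. The defaults are
#' chosen so that the repeat closes at exactly 114 residues with residue 60
#' falling mid-strand in the third strand.
#'
#' @param helix_length length of each alpha helix (residues).
#' @param ba_loops integer vector of the four beta-alpha loop lengths per
#'   repeat (the fourth is the loop following the last helix of the repeat).
#' @param ab_turn length of each alpha-beta turn (residues).
#' @return A `blueprint` with `repeat_count = 2`.
#' @export
make_ovoid_blueprint <- function(helix_length = 14L, ba_loops = c(6L, 5L, 6L, 5L),
                                 ab_turn = 3L) {
  stopifnot(length(ba_loops) == 4)
  strand_len <- c(5L, 5L, 7L, 7L)
  one_repeat <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(kind = c("strand", "loop", "helix", "loop"),
               length = c(strand_len[i], ab_turn, helix_length, ba_loops[i]))
  }))
  elements <- rbind(one_repeat, one_repeat)
  shifts <- rep(c(0L, 0L, 2L, 2L), 2)
  new_blueprint(elements, shifts, repeat_count = 2L)
}

#' A circular TIM-barrel blueprint
#'
#' Fourfold-repeat circular counterpart: eight equal strands of length 5, all
#' junction shifts equal to 1 (shear 8), uniform helices and loops.
#'
#' @param helix_length,ba_loop,ab_turn element lengths per repeat.
#' @return A `blueprint` with `repeat_count = 4`.
#' @export
make_circular_blueprint <- function(helix_length = 10L, ba_loop = 5L, ab_turn = 3L) {
  one_repeat <- data.frame(
    kind = rep(c("strand", "loop", "helix", "loop"), 2),
    length = rep(c(5L, ab_turn, helix_length, ba_loop), 2))
  elements <- do.call(rbind, replicate(4, one_repeat, simplify = FALSE))
  new_blueprint(elements, rep(1L, 8), repeat_count = 4L)
}

#' Shear number of a blueprint
#'
#' The shear number is the total residue register offset accumulated when the
#' hydrogen-bond ladder is traversed once around the closed barrel; for a
#' blueprint it is the cyclic sum of the per-junction register shifts.
#'
#' @param bp a `blueprint`.
#' @return Integer shear number.
#' @export
compute_shear <- function(bp) {
  stopifnot(inherits(bp, "blueprint"))
  if (bp$n_strands < 2) stop("need at least 2 strands")
  sum(bp$register_shifts)
}

#' Register shift contributed by one repeat
#'
#' For a perfectly repetitive blueprint, the sum of register shifts within one
#' repeat: the number of residues the barrel "shifts" between repeats. Equals
#' `compute_shear(bp) / repeat_count`.
#'
#' @param bp a `blueprint` with `repeat_count >= 2` and identical repeats.
#' @return Integer per-repeat shift.
#' @export
repeat_shift <- function(bp) {
  stopifnot(inherits(bp, "blueprint"))
  if (bp$repeat_count < 2) stop("blueprint has no repeats")
  per <- bp$n_strands / bp$repeat_count
  if (per != round(per)) stop("strand count not divisible by repeat count")
  groups <- matrix(bp$register_shifts, nrow = per)
  if (!all(apply(groups, 1, function(r) length(unique(r)) == 1)))
    stop("register shifts are not repeat-periodic")
  reps <- split(bp$elements$length, rep(seq_len(bp$repeat_count),
                each = nrow(bp$elements) / bp$repeat_count))
  if (!all(vapply(reps, identical, logical(1), reps[[1]])))
    stop("element lengths are not repeat-periodic")
  sum(groups[, 1])
}

#' Symmetry-equivalent residue in the other repeat
#'
#' Maps a residue index to its twofold repeat partner (offset by
#' `residues_per_repeat`, wrapping around the chain), e.g. residue 2 of the
#' ovoid design maps to residue 116 and vice versa.
#'
#' @param residue_index 1-based residue index (vectorised).
#' @param bp a `blueprint`.
#' @return 1-based partner index (same length as `residue_index`).
#' @export
repeat_partner <- function(residue_index, bp) {
  stopifnot(inherits(bp, "blueprint"))
  if (any(residue_index < 1 | residue_index > bp$total_residues))
    stop("residue index out of range")
  ((residue_index - 1L + bp$residues_per_repeat) %% bp$total_residues) + 1L
}

# Per-strand-residue arithmetic table: for strand i, local index k,
# ladder coordinate t = k + C_i (constant along a hydrogen-bond rung within
# the unrolled sheet), axial height h = t - (i - 1) * S / n, and core-facing
# parity (first residue of strand 1 is core-facing; facing propagates across
# junctions because rung partners share t).
strand_position_table <- function(bp) {
  se <- strand_elements(bp)
  C <- cumulative_shifts(bp)
  S <- compute_shear(bp)
  n <- bp$n_strands
  purrr::map_dfr(seq_len(n), function(i) {
    L <- se$length[i]
    k <- seq_len(L)
    t <- k + C[i]
    tibble::tibble(
      strand = i,
      local = k,
      residue = se$start[i] + k - 1L,
      ladder = t,
      height = t - (i - 1) * S / n,
      core_facing = (t %% 2L) == 1L)
  })
}

#' Core layers of a barrel blueprint
#'
#' Partitions the core-facing strand positions into horizontal layers: sets of
#' positions that share the same height along the barrel axis once the
#' register shifts are accounted for. Members of one layer come from
#' alternating strands.
#'
#' @param bp a `blueprint`.
#' @return Tibble with columns `layer` (1 = topmost), `strand`, `local`
#'   (position within the strand), `residue` (global index) and `height`.
#' @export
enumerate_layers <- function(bp) {
  tab <- strand_position_table(bp) |> dplyr::filter(.data$core_facing)
  # group heights exactly (heights are multiples of 1/n)
  h <- round(tab$height, 9)
  lev <- sort(unique(h), decreasing = TRUE)
  tab |>
    dplyr::mutate(layer = match(round(.data$height, 9), lev)) |>
    dplyr::arrange(.data$layer, .data$strand) |>
    dplyr::select("layer", "strand", "local", "residue", "height")
}

#' C-beta strips of a barrel blueprint
#'
#' Strips of interior-facing positions winding around the barrel
#' perpendicular to the strand direction: consecutive strip members lie on
#' adjacent strands and their local residue indices differ by the junction's
#' register shift (they share a ladder coordinate in the unrolled sheet).
#'
#' @param bp a `blueprint`.
#' @return Tibble with columns `strip`, `strand`, `local`, `residue`,
#'   `ladder`; rows ordered along each strip.
#' @export
enumerate_cbeta_strips <- function(bp) {
  tab <- strand_position_table(bp) |> dplyr::filter(.data$core_facing)
  lev <- sort(unique(tab$ladder))
  tab |>
    dplyr::mutate(strip = match(.data$ladder, lev)) |>
    dplyr::arrange(.data$strip, .data$strand) |>
    dplyr::select("strip", "strand", "local", "residue", "ladder")
}

#' Write / read a blueprint as JSON
#'
#' Plain-text serialisation: ordered elements with kind and length, junction
#' register shifts and repeat count.
#'
#' @param bp a `blueprint`.
#' @param path file path.
#' @return `write_blueprint_json` returns `path` invisibly;
#'   `read_blueprint_json` returns a `blueprint`.
#' @export
write_blueprint_json <- function(bp, path) {
  jsonlite::write_json(
    list(elements = bp$elements[, c("kind", "length")],
         register_shifts = bp$register_shifts,
         repeat_count = bp$repeat_count),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_blueprint_json
#' @export
read_blueprint_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_blueprint(x$elements, x$register_shifts, x$repeat_count)
}
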