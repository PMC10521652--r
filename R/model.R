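# The residue-level structure container. A `barrel_model` is a tibble with
# one row per residue: identity, element annotation, facing flag, backbone
# coordinates (N, CA, C, O), CB (NA for glycine) and a list-column `sc` of
# further side-chain heavy atoms (tibbles with atom, x, y, z).

BB_ATOMS <- c("n", "ca", "c", "o", "cb")

coord_cols <- function(atom) paste0(atom, c("_x", "_y", "_z"))

#' Assemble a barrel model tibble
#'
#' @param residues tibble with at least `residue`, `aa`, `element` and the
#'   coordinate columns `n_x ... cb_z`; `chain`, `strand`, `facing`, `sc` are
#'   filled with defaults when absent.
#' @param validate check the backbone invariants (consecutive CA-CA distances
#'   within 3.6--4.1 Angstrom inside contiguous chains, CB present iff not
#'   glycine).
#' @return A tibble of class `barrel_model`.
#' @export
new_barrel_model <- function(residues, validate = TRUE) {
  m <- tibble::as_tibble(residues)
  if (!"chain" %in% names(m)) m$chain <- "A"
  if (!"strand" %in% names(m)) m$strand <- NA_integer_
  if (!"facing" %in% names(m)) m$facing <- NA_character_
  if (!"element" %in% names(m)) m$element <- NA_character_
  if (!"element_id" %in% names(m)) m$element_id <- NA_integer_
  if (!"sc" %in% names(m)) m$sc <- vector("list", nrow(m))
  m <- m[order(m$residue), ]
  class(m) <- c("barrel_model", class(tibble::tibble()))
  if (validate) validate_barrel_model(m)
  m
}

validate_barrel_model <- function(m) {
  gly <- m$aa == "G"
  has_cb <- !is.na(m$cb_x)
  if (any(gly & has_cb)) stop("glycine residues must not carry a CB atom")
  if (any(!gly & !has_cb)) stop("non-glycine residues must carry a CB atom")
  ca <- model_coords(m, "ca")
  consecutive <- which(diff(m$residue) == 1)
  if (length(consecutive)) {
    d <- sqrt(rowSums((ca[consecutive + 1, , drop = FALSE] -
                       ca[consecutive, , drop = FALSE])^2))
    bad <- d < 3.6 | d > 4.1
    if (any(bad))
      stop(sprintf("consecutive CA-CA distance out of [3.6, 4.1] A at residue %d (%.2f A)",
                   m$residue[consecutive[which(bad)[1]]], d[which(bad)[1]]))
  }
  invisible(m)
}

#' Extract atom coordinates from a model
#'
#' @param model a `barrel_model`.
#' @param atom one of `"n"`, `"ca"`, `"c"`, `"o"`, `"cb"`.
#' @param residues optional residue indices to select.
#' @return n x 3 numeric matrix (rows may contain NA for missing CB).
#' @export
model_coords <- function(model, atom = "ca", residues = NULL) {
  if (!is.null(residues)) model <- model[model$residue %in% residues, ]
  as.matrix(model[, coord_cols(atom)])
}

#' Model sequence as a one-letter character vector
#' @param model a `barrel_model`.
#' @return Character vector named by residue index.
#' @export
model_sequence <- function(model) stats::setNames(model$aa, model$residue)

# Long table of all heavy atoms (backbone + CB + side-chain pseudo/real
# atoms) with element and residue bookkeeping.
model_atom_table <- function(model, backbone = TRUE) {
  bb <- purrr::map_dfr(if (backbone) c("n", "ca", "c", "o", "cb") else "cb",
    function(a) {
      xyz <- model_coords(model, a)
      tibble::tibble(residue = model$residue, aa = model$aa,
                     atom = toupper(a), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    }) |> dplyr::filter(!is.na(.data$x))
  sc <- purrr::map_dfr(seq_len(nrow(model)), function(i) {
    s <- model$sc[[i]]
    if (is.null(s) || nrow(s) == 0) return(NULL)
    tibble::tibble(residue = model$residue[i], aa = model$aa[i],
                   atom = s$atom, x = s$x, y = s$y, z = s$z)
  })
  out <- dplyr::bind_rows(bb, sc)
  out$element <- atom_element(out$atom)
  out$radius <- VDW_RADII[out$element]
  out
}

# Side-chain heavy atoms (CB + beyond) for one residue as a matrix + radii.
sidechain_atoms <- function(model, i) {
  row <- model[model$residue == i, ]
  if (nrow(row) == 0) return(NULL)
  at <- character(0); xyz <- NULL
  if (!is.na(row$cb_x)) {
    at <- "CB"; xyz <- matrix(unlist(row[, coord_cols("cb")]), ncol = 3)
  }
  s <- row$sc[[1]]
  if (!is.null(s) && nrow(s) > 0) {
    at <- c(at, s$atom)
    xyz <- rbind(xyz, as.matrix(s[, c("x", "y", "z")]))
  }
  if (is.null(xyz)) return(NULL)
  list(atom = at, xyz = xyz, radius = VDW_RADII[atom_element(at)])
}

#' @export
print.barrel_model <- function(x, ...) {
  ns <- length(unique(stats::na.omit(x$strand)))
  cat(sprintf("Barrel model: %d residues, %d annotated strands\n", nrow(x), ns))
  NextMethod()
}

# dplyr operations drop the subclass; keep a light re-class helper.
as_barrel_model <- function(m) {
  class(m) <- unique(c("barrel_model", class(tibble::tibble())))
  m
}
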