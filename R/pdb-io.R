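# PDB-format input/output for barrel models (via bio3d).

#' Write a barrel model to a PDB file
#'
#' Atom ordering per residue is N, CA, C, O, CB, then any further side-chain
#' atoms; occupancy 1.00. Coordinates round-trip through [read_structure()]
#' at the format's 3-decimal precision.
#'
#' @param model a `barrel_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  at <- model_atom_table(model)
  ord <- match(at$atom, c("N", "CA", "C", "O", "CB"))
  ord[is.na(ord)] <- 6L
  at <- at[order(at$residue, ord, at$atom), ]
  chain <- model$chain[match(at$residue, model$residue)]
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$residue,
                   resid = AA3[at$aa],
                   eleno = seq_len(nrow(at)),
                   elety = at$atom,
                   chain = chain,
                   o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  invisible(path)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records into a residue-level `barrel_model`: backbone N, CA,
#' C, O, CB per residue, all further side-chain heavy atoms in the `sc`
#' list-column. Alternate locations are resolved to the highest-occupancy
#' conformer; insertion codes are rejected; residues with missing backbone
#' atoms trigger a warning. Hydrogens are dropped.
#'
#' @param path PDB file.
#' @param chain chain identifier to read; default the first chain in file.
#' @return A `barrel_model` (element / strand / facing annotations are `NA`;
#'   use [assign_strands()] to recover strands).
#' @export
read_structure <- function(path, chain = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("parse error: ", conditionMessage(e)))
  a <- pdb$atom
  a <- a[a$type == "ATOM", ]
  if (nrow(a) == 0) stop("no ATOM records in file")
  if (is.null(chain)) chain <- a$chain[1]
  a <- a[a$chain == chain, ]
  if (any(!is.na(a$insert) & a$insert != ""))
    stop("insertion codes are not supported")
  a <- a[is.na(a$elesy) | a$elesy != "H", ]
  a <- a[atom_element(a$elety) != "H", ]
  # resolve altlocs: keep the highest-occupancy conformer per atom
  if (any(!is.na(a$alt) & a$alt != "")) {
    key <- paste(a$resno, a$elety)
    occ <- ifelse(is.na(a$o), 1, a$o)
    keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(ix) {
      ix[order(-occ[ix], a$alt[ix])][1]
    }))
    a <- a[sort(keep), ]
  }
  res_ids <- unique(a$resno)
  rows <- lapply(res_ids, function(r) {
    ar <- a[a$resno == r, ]
    aa3 <- ar$resid[1]
    aa1 <- AA1[aa3]
    if (is.na(aa1)) return(NULL)
    get <- function(name) {
      i <- which(ar$elety == name)[1]
      if (is.na(i)) c(NA_real_, NA_real_, NA_real_)
      else c(ar$x[i], ar$y[i], ar$z[i])
    }
    bb <- lapply(c("N", "CA", "C", "O", "CB"), get)
    sc_rows <- ar[!ar$elety %in% c("N", "CA", "C", "O", "CB", "OXT"), ]
    sc <- if (nrow(sc_rows)) tibble::tibble(atom = sc_rows$elety,
                                            x = sc_rows$x, y = sc_rows$y,
                                            z = sc_rows$z) else NULL
    tibble::tibble(residue = r, chain = chain, aa = unname(aa1),
                   n_x = bb[[1]][1], n_y = bb[[1]][2], n_z = bb[[1]][3],
                   ca_x = bb[[2]][1], ca_y = bb[[2]][2], ca_z = bb[[2]][3],
                   c_x = bb[[3]][1], c_y = bb[[3]][2], c_z = bb[[3]][3],
                   o_x = bb[[4]][1], o_y = bb[[4]][2], o_z = bb[[4]][3],
                   cb_x = bb[[5]][1], cb_y = bb[[5]][2], cb_z = bb[[5]][3],
                   sc = list(sc))
  })
  m <- dplyr::bind_rows(rows)
  if (nrow(m) == 0) stop("no standard amino-acid residues found")
  miss <- is.na(m$ca_x) | is.na(m$n_x) | is.na(m$c_x) | is.na(m$o_x)
  if (any(miss))
    warning(sprintf("%d residue(s) with missing backbone atoms", sum(miss)))
  new_barrel_model(m, validate = FALSE)
}
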