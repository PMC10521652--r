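# ILV hydrophobic-cluster machinery: residue-residue side-chain contacts
# with pairwise buried surface areas, connected-component clusters, summary
# totals.

#' Side-chain contacts between hydrophobic residues
#'
#' Finds residue pairs whose side-chain heavy atoms are in contact. A pair
#' is a contact when the closest side-chain heavy-atom distance is within
#' `max_dist` or the pairwise buried area reaches `area_min`. Buried area is
#' the two-body solvent-accessible-surface difference (probe 1.4 Angstrom):
#' the area each partner loses when the other is present, summed over both.
#'
#' @param model a `barrel_model` with side-chain heavy atoms (CB alone is
#'   rejected when `area_min > 0` and no residue has atoms beyond CB).
#' @param mode `"ilv"` restricts to Ile/Leu/Val; `"hydrophobic"` adds
#'   Ala/Met/Phe.
#' @param max_dist heavy-atom contact distance (Angstrom).
#' @param area_min buried-area alternative criterion (square Angstrom).
#' @param n_points sphere points per atom for the SASA computation.
#' @return Tibble of class `contact_records`: `res_i < res_j`, `min_dist`,
#'   `area` (square Angstrom), `n_atom_pairs` (atom pairs within
#'   `max_dist`).
#' @export
pairwise_contacts <- function(model, mode = c("ilv", "hydrophobic"),
                              max_dist = 4.5, area_min = 10, n_points = 960) {
  mode <- match.arg(mode)
  sel <- if (mode == "ilv") ILV_AA else c(ILV_AA, "A", "M", "F")
  res <- model$residue[model$aa %in% sel]
  atoms <- lapply(res, function(r) sidechain_atoms(model, r))
  names(atoms) <- res
  have <- !vapply(atoms, is.null, logical(1))
  if (any(!have)) {
    warning(sprintf("skipping %d residue(s) with no side-chain atoms",
                    sum(!have)))
    res <- res[have]; atoms <- atoms[have]
  }
  if (length(res) < 2)
    return(structure(tibble::tibble(res_i = integer(0), res_j = integer(0),
                                    min_dist = numeric(0), area = numeric(0),
                                    n_atom_pairs = integer(0)),
                     class = c("contact_records", class(tibble::tibble()))))
  beyond_cb <- any(vapply(atoms, function(a) length(a$atom) > 1, logical(1)))
  if (!beyond_cb && area_min > 0)
    warning("side chains truncated at CB: buried areas will be underestimates")
  cent <- t(vapply(atoms, function(a) colMeans(a$xyz), numeric(3)))
  prefilter <- 12
  out <- list()
  for (ii in seq_along(res)) {
    for (jj in seq_along(res)) {
      if (jj <= ii) next
      if (sqrt(sum((cent[ii, ] - cent[jj, ])^2)) > prefilter) next
      ai <- atoms[[ii]]; aj <- atoms[[jj]]
      dm <- sqrt(outer(rowSums(ai$xyz^2), rowSums(aj$xyz^2), `+`) -
                 2 * ai$xyz %*% t(aj$xyz))
      mind <- min(dm)
      if (mind > ai$radius[1] + 2 * 1.4 + max(VDW_RADII)) next
      # two-body buried area
      xi <- ai$xyz; xj <- aj$xyz
      si_alone <- sum(sasa_atoms(xi, ai$radius, n_points = n_points))
      sj_alone <- sum(sasa_atoms(xj, aj$radius, n_points = n_points))
      spair <- sum(sasa_atoms(rbind(xi, xj), c(ai$radius, aj$radius),
                              n_points = n_points))
      buried <- si_alone + sj_alone - spair
      if (mind <= max_dist || buried >= area_min) {
        out[[length(out) + 1]] <- tibble::tibble(
          res_i = res[ii], res_j = res[jj], min_dist = mind,
          area = max(buried, 0), n_atom_pairs = sum(dm <= max_dist))
      }
    }
  }
  structure(dplyr::bind_rows(
    tibble::tibble(res_i = integer(0), res_j = integer(0),
                   min_dist = numeric(0), area = numeric(0),
                   n_atom_pairs = integer(0)), out),
    class = c("contact_records", class(tibble::tibble())))
}

#' Build hydrophobic clusters from contacts
#'
#' Connected components of the residue contact graph, restricted to edges
#' with buried area at or above `area_threshold`; per-cluster and total
#' contact counts and buried areas.
#'
#' @param contacts a [pairwise_contacts()] tibble.
#' @param area_threshold minimum edge buried area (square Angstrom).
#' @return Object of class `cluster_set`: list with `members` (tibble:
#'   residue, cluster), `clusters` (tibble: cluster, n_residues, n_contacts,
#'   area) and `totals` (tibble: n_clusters, total_contacts, total_area,
#'   area_per_contact).
#' @export
build_clusters <- function(contacts, area_threshold = 0) {
  edges <- contacts[contacts$area >= area_threshold, , drop = FALSE]
  if (nrow(edges) == 0) {
    return(structure(list(
      members = tibble::tibble(residue = integer(0), cluster = integer(0)),
      clusters = tibble::tibble(cluster = integer(0), n_residues = integer(0),
                                n_contacts = integer(0), area = numeric(0)),
      totals = tibble::tibble(n_clusters = 0L, total_contacts = 0L,
                              total_area = 0, area_per_contact = NA_real_)),
      class = "cluster_set"))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$res_i), to = as.character(edges$res_j)),
    directed = FALSE)
  comp <- igraph::components(g)
  members <- tibble::tibble(residue = as.integer(names(comp$membership)),
                            cluster = as.integer(comp$membership)) |>
    dplyr::arrange(.data$residue)
  cl_of <- stats::setNames(members$cluster, members$residue)
  edges$cluster <- unname(cl_of[as.character(edges$res_i)])
  clusters <- edges |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n_contacts = dplyr::n(), area = sum(.data$area),
                     .groups = "drop") |>
    dplyr::left_join(members |> dplyr::count(.data$cluster, name = "n_residues"),
                     by = "cluster") |>
    dplyr::select("cluster", "n_residues", "n_contacts", "area") |>
    dplyr::arrange(dplyr::desc(.data$n_contacts))
  totals <- tibble::tibble(
    n_clusters = nrow(clusters),
    total_contacts = sum(clusters$n_contacts),
    total_area = sum(clusters$area),
    area_per_contact = sum(clusters$area) / sum(clusters$n_contacts))
  structure(list(members = members, clusters = clusters, totals = totals),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  with(x$totals, cat(sprintf(
    "%d clusters: %d contacts, %.1f A^2 buried (%.1f A^2/contact)\n",
    n_clusters, total_contacts, total_area,
    ifelse(is.na(area_per_contact), 0, area_per_contact))))
  print(x$clusters)
  invisible(x)
}

#' Compare two cluster sets
#'
#' Side-by-side tabulation of cluster count, total contacts, total buried
#' area and area per contact for two structures.
#'
#' @param a,b [build_clusters()] results.
#' @param labels column labels for the two sets.
#' @return Tibble with one row per metric and a `difference` column
#'   (`a - b`).
#' @export
compare_cluster_sets <- function(a, b, labels = c("a", "b")) {
  ta <- unlist(a$totals); tb <- unlist(b$totals)
  out <- tibble::tibble(metric = names(ta), !!labels[1] := unname(ta),
                        !!labels[2] := unname(tb),
                        difference = unname(ta) - unname(tb))
  out
}
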