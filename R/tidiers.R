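# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy glance
NULL

#' Tidy a two-state unfolding fit
#' @param x a `two_state_fit`.
#' @param ... unused.
#' @return Tibble with `term`, `estimate`, `std_error`.
#' @export
tidy.two_state_fit <- function(x, ...) x$estimates

#' One-row summary of a two-state unfolding fit
#' @param x a `two_state_fit`.
#' @param ... unused.
#' @return Tibble with `dG`, `m_value`, `Cm`, `RT`, `sigma`, `n`.
#' @export
glance.two_state_fit <- function(x, ...) {
  tibble::tibble(dG = x$dG, m_value = x$m_value, Cm = x$Cm, RT = x$RT,
                 sigma = x$sigma, n = nrow(x$data))
}

#' Tidy a barrel cross-section fit (per-strand table)
#' @param x a `barrel_shape_fit`.
#' @param ... unused.
#' @return Tibble with `strand`, `radius`, `angle`, `face`.
#' @export
tidy.barrel_shape_fit <- function(x, ...) x$strands

#' One-row summary of a barrel cross-section fit
#' @param x a `barrel_shape_fit`.
#' @param ... unused.
#' @return Tibble with `semi_major_a`, `semi_minor_b`, `eccentricity`.
#' @export
glance.barrel_shape_fit <- function(x, ...) {
  tibble::tibble(semi_major_a = x$semi_major_a, semi_minor_b = x$semi_minor_b,
                 eccentricity = x$eccentricity)
}

#' Tidy a strand assignment (per-residue table)
#' @param x a `strand_assignment`.
#' @param ... unused.
#' @return Tibble with `residue`, `strand`.
#' @export
tidy.strand_assignment <- function(x, ...) x$residues

#' Tidy a cluster set (per-cluster table)
#' @param x a `cluster_set`.
#' @param ... unused.
#' @return Tibble with `cluster`, `n_residues`, `n_contacts`, `area`.
#' @export
tidy.cluster_set <- function(x, ...) x$clusters

#' One-row totals of a cluster set
#' @param x a `cluster_set`.
#' @param ... unused.
#' @return Tibble with `n_clusters`, `total_contacts`, `total_area`,
#'   `area_per_contact`.
#' @export
glance.cluster_set <- function(x, ...) x$totals

#' Tidy a design profile (position frequencies)
#' @param x a `design_profile`.
#' @param ... unused.
#' @return Tibble with `position`, `aa`, `freq`.
#' @export
tidy.design_profile <- function(x, ...) x$profile
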