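#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-read error rates
#'
#' @param x An `error_report` from [measure_error()].
#' @param ... Unused.
#' @return The per-read tibble.
#' @export
tidy.error_report <- function(x, ...) x$per_read

#' One-row error-report summary
#'
#' @param x An `error_report`.
#' @param ... Unused.
#' @return A one-row tibble: read counts, mean/sd error rate, mean/sd
#'   read length.
#' @export
glance.error_report <- function(x, ...) x$summary

#' Tidy a clonotype table into long member form
#'
#' @param x A `tcr_clones` object.
#' @param ... Unused.
#' @return A tibble with one row per (clone, member CDR3).
#' @export
tidy.tcr_clones <- function(x, ...) {
  tibble(
    clone_id = rep(x$clone_id, lengths(x$members)),
    locus = rep(x$locus, lengths(x$members)),
    representative_cdr3_aa = rep(x$representative_cdr3_aa, lengths(x$members)),
    cdr3_aa = unlist(x$members)
  )
}

#' One-row repertoire summary
#'
#' @param x A `tcr_clones` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_clones`, `n_member_cdr3s`, `total_umis`,
#'   `mean_spots_per_clone`.
#' @export
glance.tcr_clones <- function(x, ...) {
  tibble(
    n_clones = nrow(x),
    n_member_cdr3s = sum(lengths(x$members)),
    total_umis = sum(x$total_umis),
    mean_spots_per_clone = mean(x$n_spots)
  )
}
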