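#' Read an AIRR Rearrangement TSV
#'
#' Accepts the community-standard AIRR Rearrangement dialect (columns
#' `sequence_id`, `v_call`, `d_call`, `j_call`, `c_call`, `junction`,
#' `junction_aa`, `v_identity`, `j_identity`, `cell_id`, `umi`, `locus`).
#' Missing optional columns default to empty; unknown columns are passed
#' through untouched. When `junction` is present but `junction_aa` is not,
#' the amino-acid junction is computed by standard-codon translation.
#'
#' @param path Path to a tab-separated Rearrangement file with a header row.
#' @return A tibble with the canonical columns above (missing ones filled)
#'   followed by any extra columns from the file.
#' @export
read_airr <- function(path) {
  tbl <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!"sequence_id" %in% names(tbl)) {
    abort("AIRR file lacks required column 'sequence_id'",
      class = "clonospace_schema_error"
    )
  }
  chr_cols <- c(
    "v_call", "d_call", "j_call", "c_call", "junction", "junction_aa",
    "cell_id", "umi", "locus"
  )
  for (col in chr_cols) {
    if (!col %in% names(tbl)) tbl[[col]] <- ""
    tbl[[col]][is.na(tbl[[col]])] <- ""
  }
  for (col in c("v_identity", "j_identity")) {
    tbl[[col]] <- if (col %in% names(tbl)) {
      suppressWarnings(as.numeric(tbl[[col]]))
    } else {
      NA_real_
    }
  }
  need_aa <- !nzchar(tbl$junction_aa) & nzchar(tbl$junction) &
    nchar(tbl$junction) %% 3 == 0
  if (any(need_aa)) {
    tbl$junction_aa[need_aa] <- translate_nt(tbl$junction[need_aa])
    tbl$junction_aa[is.na(tbl$junction_aa)] <- ""
  }
  if ("complete_vdj" %in% names(tbl)) {
    tbl$complete_vdj <- tbl$complete_vdj %in% c("T", "TRUE", "true", "1")
  } else {
    tbl$complete_vdj <- nzchar(tbl$v_call) & nzchar(tbl$j_call)
  }
  canonical <- c(
    "sequence_id", chr_cols, "v_identity", "j_identity", "complete_vdj"
  )
  dplyr::relocate(tbl, dplyr::all_of(canonical))
}

#' Write annotation records as AIRR Rearrangement TSV
#'
#' @param records Tibble of TCR records (as returned by [annotate_inserts()]
#'   or [read_airr()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(records, path) {
  stopifnot("sequence_id" %in% names(records))
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}
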