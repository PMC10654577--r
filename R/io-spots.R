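#' Read a spot-position table
#'
#' Two dialects are detected from the header: the Visium-style
#' `tissue_positions` CSV (`barcode,in_tissue,array_row,array_col,
#' pxl_row_in_fullres,pxl_col_in_fullres`; planar coordinates are taken from
#' the pixel columns) and a simple `barcode,x,y[,in_tissue][,n_cells]
#' [,total_umis]` CSV. Coordinates are abstract planar floats; no unit
#' conversion is applied.
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble with columns `barcode`, `x`, `y`, `in_tissue`,
#'   `n_cells`, `total_umis`. If fewer than 3 in-tissue spots are present a
#'   warning is raised and the attribute `geometry_warning` is set, since
#'   triangulation-based consumers need at least 3 non-collinear spots.
#' @export
read_spot_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  nm <- names(tbl)
  pxl_row <- grep("^pxl_row", nm, value = TRUE)
  pxl_col <- grep("^pxl_col", nm, value = TRUE)
  if ("barcode" %in% nm && length(pxl_row) == 1 && length(pxl_col) == 1) {
    out <- tibble(
      barcode = as.character(tbl$barcode),
      x = as.numeric(tbl[[pxl_col]]),
      y = as.numeric(tbl[[pxl_row]]),
      in_tissue = if ("in_tissue" %in% nm) as.integer(tbl$in_tissue) == 1L else TRUE,
      n_cells = NA_integer_,
      total_umis = NA_integer_
    )
  } else if (all(c("barcode", "x", "y") %in% nm)) {
    out <- tibble(
      barcode = as.character(tbl$barcode),
      x = as.numeric(tbl$x),
      y = as.numeric(tbl$y),
      in_tissue = if ("in_tissue" %in% nm) {
        as.logical(tbl$in_tissue) | tbl$in_tissue == 1
      } else {
        TRUE
      },
      n_cells = if ("n_cells" %in% nm) as.integer(tbl$n_cells) else NA_integer_,
      total_umis = if ("total_umis" %in% nm) {
        as.integer(tbl$total_umis)
      } else {
        NA_integer_
      }
    )
  } else {
    abort(
      "unrecognised spot-table header: need barcode,x,y or a Visium tissue_positions layout",
      class = "clonospace_schema_error"
    )
  }
  dup <- out$barcode[duplicated(out$barcode)]
  if (length(dup)) {
    abort(paste0("duplicate spot barcode: ", dup[1]),
      class = "clonospace_schema_error"
    )
  }
  if (sum(out$in_tissue) < 3) {
    warn("fewer than 3 in-tissue spots; triangulation-based metrics unavailable")
    attr(out, "geometry_warning") <- TRUE
  }
  out
}

#' Write a spot table in the simple CSV dialect
#'
#' @param spots Spot tibble (see [read_spot_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(spots, path) {
  readr::write_csv(spots, path, progress = FALSE)
  invisible(path)
}
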