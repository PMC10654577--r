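#' Read a FASTQ file
#'
#' Strict 4-line FASTQ (Phred+33). Gzip input is detected by magic bytes,
#' not file extension. Malformed records abort with the offending line
#' number.
#'
#' @param path Path to a FASTQ file, optionally gzip-compressed.
#' @return A tibble with columns `read_id`, `seq`, `qual`, in file order.
#' @export
read_fastq <- function(path) {
  lines <- read_text_lines(path)
  if (length(lines) == 0) {
    return(tibble(read_id = character(), seq = character(), qual = character()))
  }
  if (length(lines) %% 4 != 0) {
    abort(
      paste0("truncated FASTQ record starting at line ", 4 * (length(lines) %/% 4) + 1),
      class = "clonospace_parse_error"
    )
  }
  idx <- seq(1, length(lines), by = 4)
  hdr <- lines[idx]
  seq <- lines[idx + 1]
  plus <- lines[idx + 2]
  qual <- lines[idx + 3]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    abort(paste0("FASTQ header does not start with '@' at line ", idx[bad[1]]),
      class = "clonospace_parse_error"
    )
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    abort(paste0("missing '+' separator at line ", idx[bad[1]] + 2),
      class = "clonospace_parse_error"
    )
  }
  bad <- which(nchar(qual) != nchar(seq))
  if (length(bad)) {
    abort(
      paste0(
        "quality length differs from sequence length at line ",
        idx[bad[1]] + 3
      ),
      class = "clonospace_parse_error"
    )
  }
  bad <- which(!nzchar(seq) | grepl("[^ACGTNacgtn]", seq))
  if (length(bad)) {
    abort(paste0("invalid sequence characters at line ", idx[bad[1]] + 1),
      class = "clonospace_parse_error"
    )
  }
  ids <- sub("^@", "", hdr)
  if (anyDuplicated(ids)) {
    abort(
      paste0("duplicate read_id: ", ids[duplicated(ids)][1]),
      class = "clonospace_parse_error"
    )
  }
  tibble(read_id = ids, seq = toupper(seq), qual = qual)
}

#' Write reads to FASTQ
#'
#' @param reads Tibble with columns `read_id`, `seq`, `qual`.
#' @param path Output path; a `.gz` suffix selects gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)))
  lines <- as.vector(rbind(
    paste0("@", reads$read_id), reads$seq, "+", reads$qual
  ))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
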