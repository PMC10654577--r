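#' Read a V/J/C segment reference FASTA
#'
#' Description lines carry `key=value` tags: `locus=`, `role=` (V, J, C or
#' UTR), `cys_offset=` (V segments: 0-based offset of the conserved Cys
#' codon), `motif_offset=` (J segments: 0-based offset of the conserved
#' Phe/Trp-Gly motif), `utr_of=` (UTR entries: the V segment they precede).
#'
#' @param path Path to the reference FASTA.
#' @return A tibble with columns `segment_id`, `locus`, `role`, `seq`,
#'   `cys_offset`, `motif_offset`, `utr_of`.
#' @export
read_segment_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  parse_tag <- function(tag) {
    m <- regmatches(hdr, regexpr(paste0(tag, "=[^ ]+"), hdr))
    out <- rep(NA_character_, length(hdr))
    hit <- grepl(paste0(tag, "="), hdr)
    out[hit] <- sub(paste0("^", tag, "="), "", regmatches(
      hdr,
      regexpr(paste0(tag, "=[^ ]+"), hdr)
    ))
    out
  }
  refs <- tibble(
    segment_id = sub(" .*$", "", hdr),
    locus = parse_tag("locus"),
    role = parse_tag("role"),
    seq = unname(as.character(ss)),
    cys_offset = suppressWarnings(as.integer(parse_tag("cys_offset"))),
    motif_offset = suppressWarnings(as.integer(parse_tag("motif_offset"))),
    utr_of = parse_tag("utr_of")
  )
  if (anyNA(refs$role)) {
    abort("reference FASTA entry lacks a role= tag",
      class = "clonospace_schema_error"
    )
  }
  if (anyDuplicated(refs$segment_id)) {
    abort("duplicate segment_id in reference FASTA",
      class = "clonospace_schema_error"
    )
  }
  bad <- with(refs, !is.na(cys_offset) & (cys_offset < 0 | cys_offset > nchar(seq) - 3))
  if (any(bad)) {
    abort(paste0("cys_offset outside sequence for ", refs$segment_id[bad][1]),
      class = "clonospace_schema_error"
    )
  }
  refs
}

#' Write a segment reference tibble as FASTA
#'
#' @param refs Reference tibble (see [read_segment_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segment_fasta <- function(refs, path) {
  hdr <- paste0(
    ">", refs$segment_id,
    " locus=", refs$locus,
    " role=", refs$role,
    ifelse(!is.na(refs$cys_offset), paste0(" cys_offset=", refs$cys_offset), ""),
    ifelse(!is.na(refs$motif_offset), paste0(" motif_offset=", refs$motif_offset), ""),
    ifelse(!is.na(refs$utr_of), paste0(" utr_of=", refs$utr_of), "")
  )
  writeLines(as.vector(rbind(hdr, refs$seq)), path)
  invisible(path)
}
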