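#' Reorient reads, split adapter fusions, and extract transcript inserts
#'
#' Finds all semi-global matches of the Read 1 adapter and the TSO on both
#' strands (edit distance <= `max_dist`, non-overlapping, greedy
#' best-first). A valid segment is `R1 ... revcomp(TSO)` read left to
#' right, or its mirror `TSO ... revcomp(R1)` which is emitted
#' reverse-complemented so every insert starts 5' of the transcript.
#' Synthetic sequence is trimmed: the adapter/TSO footprints and the
#' 28 nt barcode + UMI block adjacent to the R1 adapter. Reads with no
#' valid segment yield no rows.
#'
#' @param reads Tibble with `read_id` and `seq`.
#' @param r1,tso Adapter sequences.
#' @param max_dist Maximum adapter edit distance (default 4).
#' @param trim_bc_umi Trim the 28 nt barcode+UMI block after R1 (default
#'   TRUE).
#' @return A tibble of inserts: `parent_read_id`, `segment_index`,
#'   `insert_id` (`<read_id>/seg<k>`), `seq`, `strand_applied`
#'   (`as-is` or `revcomp`).
#' @export
orient_and_split <- function(reads, r1 = r1_adapter(), tso = tso_sequence(),
                             max_dist = 4, trim_bc_umi = TRUE) {
  if (!nzchar(r1) || !nzchar(tso)) {
    abort("adapters must be non-empty", class = "clonospace_config_error")
  }
  pats <- list(
    r1f = r1, r1r = revcomp(r1), tsof = tso, tsor = revcomp(tso)
  )
  bcu <- if (trim_bc_umi) 28L else 0L
  acc_parent <- character(0)
  acc_seq <- character(0)
  acc_strand <- character(0)
  acc_index <- integer(0)
  rc_pending <- logical(0) # revcomp applied in one vectorised call at the end
  # Strand canonicalisation: anchors are scanned on the lexicographically
  # smaller of (read, revcomp(read)), which makes the output an exact
  # function of the strand-free molecule — orient_and_split(revcomp(r))
  # always equals orient_and_split(r).
  rc_all <- revcomp(reads$seq)
  for (i in seq_len(nrow(reads))) {
    flipped <- reads$seq[i] > rc_all[i]
    seq <- if (flipped) rc_all[i] else reads$seq[i]
    kind <- integer(0) # 1 r1f, 2 r1r, 3 tsof, 4 tsor
    hstart <- integer(0)
    hend <- integer(0)
    hdist <- integer(0)
    for (p in 1:4) {
      h <- adapter_scan_cpp(seq, pats[[p]], max_dist)
      if (nrow(h)) {
        kind <- c(kind, rep(p, nrow(h)))
        hstart <- c(hstart, h[, 1])
        hend <- c(hend, h[, 2])
        hdist <- c(hdist, h[, 3])
      }
    }
    if (!length(kind)) next
    # resolve overlaps across the four patterns: greedy by distance, then
    # leftmost
    o <- order(hdist, hstart)
    kind <- kind[o]; hstart <- hstart[o]; hend <- hend[o]
    keep <- rep(TRUE, length(kind))
    for (a in seq_along(kind)) {
      if (!keep[a]) next
      later <- which(keep & seq_along(kind) > a)
      ov <- later[hstart[later] <= hend[a] & hend[later] >= hstart[a]]
      keep[ov] <- FALSE
    }
    kind <- kind[keep]; hstart <- hstart[keep]; hend <- hend[keep]
    o <- order(hstart)
    kind <- kind[o]; hstart <- hstart[o]; hend <- hend[o]
    seg_seq <- character(0)
    seg_rc <- logical(0) # insert needs revcomp (in canonical orientation)
    a <- 1
    while (a <= length(kind)) {
      if (a < length(kind) && kind[a] == 1L && kind[a + 1] == 4L) {
        from <- hend[a] + 1L + bcu
        to <- hstart[a + 1] - 1L
        if (to >= from) {
          seg_seq <- c(seg_seq, substr(seq, from, to))
          seg_rc <- c(seg_rc, FALSE)
        }
        a <- a + 2
      } else if (a < length(kind) && kind[a] == 3L && kind[a + 1] == 2L) {
        from <- hend[a] + 1L
        to <- hstart[a + 1] - 1L - bcu
        if (to >= from) {
          seg_seq <- c(seg_seq, substr(seq, from, to))
          seg_rc <- c(seg_rc, TRUE)
        }
        a <- a + 2
      } else {
        a <- a + 1
      }
    }
    if (!length(seg_seq)) next
    if (flipped) {
      # report segments in input-read order with input-relative strands
      seg_seq <- rev(seg_seq)
      seg_rc <- rev(seg_rc)
    }
    acc_parent <- c(acc_parent, rep(reads$read_id[i], length(seg_seq)))
    acc_seq <- c(acc_seq, seg_seq)
    acc_strand <- c(acc_strand, ifelse(xor(seg_rc, flipped), "revcomp", "as-is"))
    acc_index <- c(acc_index, seq_along(seg_seq) - 1L)
    rc_pending <- c(rc_pending, seg_rc)
  }
  if (any(rc_pending)) acc_seq[rc_pending] <- revcomp(acc_seq[rc_pending])
  tibble(
    parent_read_id = acc_parent,
    segment_index = acc_index,
    insert_id = paste0(acc_parent, "/seg", acc_index),
    seq = acc_seq,
    strand_applied = acc_strand
  )
}
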