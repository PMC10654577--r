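#' Assign one read to a spot barcode via the adapter anchor
#'
#' Locates the Read 1 adapter on either strand (best semi-global match at
#' edit distance <= `max_adapter_dist`, ties resolved leftmost, forward
#' strand preferred on cross-strand ties), takes the 16 bases after the
#' match as the candidate barcode and the following 12 as the UMI, and
#' assigns the whitelist barcode with minimal edit distance when that
#' minimum is <= `max_dist` and unique. Ambiguous ties and reads too short
#' to carry barcode + UMI are left unassigned.
#'
#' @param seq A single read sequence.
#' @param whitelist Character vector of 16-mer spot barcodes.
#' @param max_dist Maximum barcode edit distance (default 2).
#' @param adapter Anchor sequence (default [r1_adapter()]).
#' @param max_adapter_dist Maximum adapter edit distance (default 4).
#' @return A one-row tibble: `barcode` (NA when unassigned), `umi`,
#'   `edit_distance`, `anchor_strand`.
#' @export
extract_barcode_umi <- function(seq, whitelist, max_dist = 2,
                                adapter = r1_adapter(), max_adapter_dist = 4) {
  check_whitelist(whitelist)
  res <- demux_reads(
    tibble(read_id = "r", seq = seq, qual = strrep("I", nchar(seq))),
    whitelist,
    max_dist = max_dist, adapter = adapter,
    max_adapter_dist = max_adapter_dist
  )
  res[, c("barcode", "umi", "edit_distance", "anchor_strand")]
}

check_whitelist <- function(whitelist) {
  if (length(whitelist) == 0) {
    abort("whitelist is empty", class = "clonospace_config_error")
  }
  if (any(nchar(whitelist) != 16)) {
    abort("whitelist barcodes must all be 16-mers",
      class = "clonospace_config_error"
    )
  }
}

#' Demultiplex reads against a barcode whitelist
#'
#' Vectorised form of [extract_barcode_umi()] over a read table.
#'
#' @param reads Tibble with `read_id` and `seq`.
#' @inheritParams extract_barcode_umi
#' @return A tibble with one row per read: `read_id`, `barcode` (NA when
#'   unassigned), `umi` (empty when unassigned), `edit_distance` (NA when
#'   unassigned), `anchor_strand` (`fwd`, `rev`, or NA when no anchor).
#' @export
demux_reads <- function(reads, whitelist, max_dist = 2,
                        adapter = r1_adapter(), max_adapter_dist = 4) {
  check_whitelist(whitelist)
  n <- nrow(reads)
  cand_bc <- rep(NA_character_, n)
  umi <- rep(NA_character_, n)
  strand <- rep(NA_character_, n)
  rc_seqs <- revcomp(reads$seq)
  for (i in seq_len(n)) {
    hit <- best_anchor(reads$seq[i], rc_seqs[i], adapter, max_adapter_dist)
    if (is.null(hit)) next
    oriented <- if (hit$strand == "fwd") reads$seq[i] else rc_seqs[i]
    if (nchar(oriented) < hit$end + 28) next
    cand_bc[i] <- substr(oriented, hit$end + 1, hit$end + 16)
    umi[i] <- substr(oriented, hit$end + 17, hit$end + 28)
    strand[i] <- hit$strand
  }
  barcode <- rep(NA_character_, n)
  edit_distance <- rep(NA_integer_, n)
  has_cand <- !is.na(cand_bc)
  if (any(has_cand)) {
    uniq <- unique(cand_bc[has_cand])
    d <- lev_cross_cpp(uniq, whitelist)
    best <- apply(d, 1, min)
    n_best <- rowSums(d == best)
    assign_ok <- best <= max_dist & n_best == 1
    best_bc <- whitelist[apply(d, 1, which.min)]
    lookup_bc <- ifelse(assign_ok, best_bc, NA_character_)
    lookup_d <- ifelse(assign_ok, best, NA_integer_)
    idx <- match(cand_bc[has_cand], uniq)
    barcode[has_cand] <- lookup_bc[idx]
    edit_distance[has_cand] <- lookup_d[idx]
  }
  umi[is.na(barcode)] <- ""
  tibble(
    read_id = reads$read_id, barcode = barcode, umi = umi,
    edit_distance = as.integer(edit_distance), anchor_strand = strand
  )
}

# Best adapter hit over both strands; ties -> lower distance, then forward
# strand, then leftmost.
best_anchor <- function(seq, rc_seq, adapter, max_dist) {
  f <- adapter_scan_cpp(seq, adapter, max_dist)
  r <- adapter_scan_cpp(rc_seq, adapter, max_dist)
  cand <- list()
  if (nrow(f)) cand[[1]] <- list(strand = "fwd", start = f[1, 1], end = f[1, 2], dist = f[1, 3])
  if (nrow(r)) cand[[length(cand) + 1]] <- list(strand = "rev", start = r[1, 1], end = r[1, 2], dist = r[1, 3])
  if (!length(cand)) return(NULL)
  if (length(cand) == 1) return(cand[[1]])
  if (cand[[1]]$dist <= cand[[2]]$dist) cand[[1]] else cand[[2]]
}

#' Directional UMI clustering
#'
#' The directional algorithm of the UMI-tools family: a directed edge
#' `u -> v` exists when `Hamming(u, v) == 1` and `count(u) >= 2*count(v) - 1`;
#' clusters are the nodes reachable from local maxima processed in
#' descending count order (count ties broken lexicographically); every UMI
#' belongs to exactly one cluster and the representative is the
#' highest-count member.
#'
#' @param umi_counts Named integer vector (names = UMIs, all the same
#'   length, counts >= 1), or a tibble with columns `umi` and `count`.
#' @return A tibble with one row per cluster: `representative`,
#'   `merged_count`, `n_members`, `members` (list column).
#' @export
directional_umi_cluster <- function(umi_counts) {
  if (is.data.frame(umi_counts)) {
    umis <- umi_counts$umi
    counts <- umi_counts$count
  } else {
    umis <- names(umi_counts)
    counts <- as.integer(umi_counts)
  }
  if (length(umis) == 0) {
    return(tibble(
      representative = character(), merged_count = integer(),
      n_members = integer(), members = list()
    ))
  }
  if (length(unique(nchar(umis))) != 1) {
    abort("UMIs must all have the same length", class = "clonospace_input_error")
  }
  if (any(counts < 1)) {
    abort("UMI counts must be >= 1", class = "clonospace_input_error")
  }
  ord <- order(-counts, umis)
  umis <- umis[ord]
  counts <- counts[ord]
  m <- length(umis)
  chars <- do.call(rbind, strsplit(umis, "", fixed = TRUE))
  assigned <- rep(NA_integer_, m)
  n_clusters <- 0L
  for (i in seq_len(m)) {
    if (!is.na(assigned[i])) next
    n_clusters <- n_clusters + 1L
    queue <- i
    assigned[i] <- n_clusters
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      ham1 <- which(is.na(assigned) &
        rowSums(chars != matrix(chars[u, ], m, ncol(chars), byrow = TRUE)) == 1)
      reach <- ham1[counts[u] >= 2L * counts[ham1] - 1L]
      if (length(reach)) {
        assigned[reach] <- n_clusters
        queue <- c(queue, reach)
      }
    }
  }
  tibble(umi = umis, count = counts, cluster = assigned) |>
    group_by(.data$cluster) |>
    summarise(
      representative = .data$umi[1],
      merged_count = as.integer(sum(.data$count)),
      n_members = dplyr::n(),
      members = list(.data$umi),
      .groups = "drop"
    ) |>
    select(-"cluster")
}

#' Collapse reads to UMI-corrected counts per barcode and CDR3
#'
#' Joins barcode assignments with annotations on `read_id`, groups reads by
#' (barcode, locus, CDR3 nucleotide sequence), directional-clusters each
#' group's UMIs, and reports the cluster count as the molecule count.
#'
#' @param assignments Output of [demux_reads()].
#' @param annotations Annotation tibble (e.g. from [annotate_inserts()])
#'   with `sequence_id`, `locus`, `junction`, `junction_aa`, `v_call`,
#'   `j_call`, `c_call`, `v_identity`, `j_identity`. `sequence_id` is
#'   matched to the parent `read_id` of each assignment.
#' @return A tibble with one row per (barcode, locus, cdr3_nt):
#'   `barcode`, `locus`, `cdr3_nt`, `cdr3_aa`, `v_call`, `j_call`, `c_call`,
#'   `v_identity`, `j_identity`, `umi_count`, `n_reads`.
#' @export
collapse_to_umis <- function(assignments, annotations) {
  ann <- annotations |>
    mutate(read_id = sub("/seg[0-9]+$", "", .data$sequence_id)) |>
    filter(nzchar(.data$junction))
  joined <- assignments |>
    filter(!is.na(.data$barcode)) |>
    inner_join(ann, by = "read_id")
  if (nrow(joined) == 0) {
    return(tibble(
      barcode = character(), locus = character(), cdr3_nt = character(),
      cdr3_aa = character(), v_call = character(), j_call = character(),
      c_call = character(), v_identity = numeric(), j_identity = numeric(),
      umi_count = integer(), n_reads = integer()
    ))
  }
  joined |>
    group_by(.data$barcode, .data$locus, cdr3_nt = .data$junction) |>
    summarise(
      cdr3_aa = names(which.max(table(.data$junction_aa))),
      v_call = names(which.max(table(.data$v_call))),
      j_call = names(which.max(table(.data$j_call))),
      c_call = names(which.max(table(.data$c_call))),
      v_identity = mean(.data$v_identity, na.rm = TRUE),
      j_identity = mean(.data$j_identity, na.rm = TRUE),
      umi_count = nrow(directional_umi_cluster(table(.data$umi))),
      n_reads = dplyr::n(),
      .groups = "drop"
    )
}
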