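#' Annotate transcript inserts against V/J/C segment references
#'
#' A lightweight long-read V(D)J annotator. Candidate V segments are
#' preselected per insert by shared 8-mer content (top `prescreen_top`
#' references, an IgBLAST-like seeding step); candidates are then locally
#' aligned (affine gaps; match 2, mismatch -4, open 4, extend 2) and in the
#' 3' remainder every J and then C segment is aligned. A call is made when
#' the best alignment score reaches `min_score` (default 50, a 25 nt
#' perfect match). `v_identity` is matches over alignment columns of the V
#' alignment. The CDR3 junction is the span from the aligned conserved Cys
#' codon of the V segment up to (not including) the Phe/Trp-Gly motif of
#' the J segment — i.e. the IMGT junction minus the J anchor. D segments
#' are never aligned; `d_call` stays empty (externally produced AIRR files
#' are the bypass for D annotation).
#'
#' @param inserts Tibble with `insert_id` (or `read_id`) and `seq`.
#' @param refs Segment reference tibble (see [read_segment_fasta()] /
#'   [toy_references()]).
#' @param min_score Minimum local alignment score for a call.
#' @param match,mismatch,gap_open,gap_ext Alignment scoring parameters.
#' @param prescreen_top Number of k-mer-preselected V candidates to align
#'   (0 aligns every V reference).
#' @return An AIRR-style tibble: `sequence_id`, `locus`, `v_call`,
#'   `d_call`, `j_call`, `c_call`, `v_identity`, `j_identity`, `junction`,
#'   `junction_aa`, `complete_vdj`. Off-target inserts (no segment reaches
#'   `min_score`) keep empty calls.
#' @export
annotate_inserts <- function(inserts, refs, min_score = 50,
                             match = 2, mismatch = -4,
                             gap_open = 4, gap_ext = 2,
                             prescreen_top = 2) {
  stopifnot(nrow(refs) > 0)
  id_col <- intersect(c("insert_id", "sequence_id", "read_id"), names(inserts))[1]
  ids <- inserts[[id_col]]
  seqs <- inserts$seq
  n <- length(seqs)
  out <- tibble(
    sequence_id = ids, locus = "", v_call = "", d_call = "", j_call = "",
    c_call = "", v_identity = NA_real_, j_identity = NA_real_,
    junction = "", junction_aa = "", complete_vdj = FALSE
  )
  if (n == 0) return(out)

  vs <- refs[refs$role == "V", ]
  js <- refs[refs$role == "J", ]
  cs <- refs[refs$role == "C", ]
  sw <- function(a, b) sw_affine_cpp(a, b, match, mismatch, gap_open, gap_ext)

  # ---- V candidate prescreen by shared 8-mers ------------------------
  nv <- nrow(vs)
  if (prescreen_top > 0 && prescreen_top < nv) {
    vkeys <- lapply(vs$seq, kmer_keys, k = 8)
    shared <- vapply(seq_len(n), function(i) {
      keys <- kmer_keys(seqs[i], 8)
      vapply(vkeys, function(rk) sum(keys %in% rk), numeric(1))
    }, numeric(nv))
    shared <- matrix(shared, nrow = nv) # nv x n
    cand <- apply(shared, 2, function(cl) {
      head(order(-cl, seq_along(cl)), prescreen_top)
    })
    cand <- matrix(cand, ncol = n)
  } else {
    cand <- matrix(rep(seq_len(nv), n), ncol = n)
  }

  # ---- V alignment ---------------------------------------------------
  v_aln <- vector("list", n)
  vbest <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    best <- NULL
    best_vi <- NA_integer_
    for (vi in cand[, i]) {
      al <- sw(seqs[i], vs$seq[vi])
      if (is.null(best) || al$score > best$score) {
        best <- al
        best_vi <- vi
      }
    }
    if (!is.null(best) && best$score >= min_score) {
      v_aln[[i]] <- best
      vbest[i] <- best_vi
    }
  }
  has_v <- !is.na(vbest)
  v_end <- rep(NA_integer_, n)
  cys_ins <- rep(NA_integer_, n)
  for (i in which(has_v)) {
    al <- v_aln[[i]]
    vi <- vbest[i]
    out$v_call[i] <- vs$segment_id[vi]
    out$locus[i] <- vs$locus[vi]
    out$v_identity[i] <- al$nmatch / al$columns
    v_end[i] <- al$a_end
    cys_pos <- vs$cys_offset[vi] + 1L
    if (!is.na(cys_pos)) {
      cys_ins[i] <- if (al$b_end < cys_pos) {
        # alignment clipped before the Cys codon; extrapolate
        al$a_end + (cys_pos - al$b_end)
      } else if (al$b_start <= cys_pos) {
        map_ref_pos(al$aligned_a, al$aligned_b, al$a_start, al$b_start, cys_pos)
      } else {
        NA_integer_
      }
    }
  }

  # ---- J calls in the 3' remainder -----------------------------------
  rem_from <- ifelse(!is.na(cys_ins), cys_ins + 3L,
    ifelse(!is.na(v_end), v_end + 1L, NA_integer_)
  )
  j_end <- rep(NA_integer_, n)
  for (i in which(has_v & !is.na(rem_from) & rem_from <= nchar(seqs))) {
    jrem <- substr(seqs[i], rem_from[i], nchar(seqs[i]))
    best <- NULL
    best_ji <- NA_integer_
    for (ji in seq_len(nrow(js))) {
      al <- sw(jrem, js$seq[ji])
      if (is.null(best) || al$score > best$score) {
        best <- al
        best_ji <- ji
      }
    }
    if (is.null(best) || best$score < min_score) next
    out$j_call[i] <- js$segment_id[best_ji]
    out$j_identity[i] <- best$nmatch / best$columns
    j_end[i] <- rem_from[i] - 1L + best$a_end
    motif_pos <- js$motif_offset[best_ji] + 1L
    motif_rem <- if (best$b_start > motif_pos) {
      # alignment starts past the motif; extrapolate backwards
      best$a_start - (best$b_start - motif_pos)
    } else {
      map_ref_pos(
        best$aligned_a, best$aligned_b, best$a_start, best$b_start, motif_pos
      )
    }
    if (!is.na(motif_rem) && !is.na(cys_ins[i])) {
      motif_ins <- rem_from[i] - 1L + motif_rem
      if (motif_ins > cys_ins[i]) {
        out$junction[i] <- substr(seqs[i], cys_ins[i], motif_ins - 1L)
      }
    }
  }

  # ---- C calls after the J (or V; C-only reads keep the whole seq) ---
  crem_from <- ifelse(!is.na(j_end), j_end + 1L,
    ifelse(!is.na(v_end), v_end + 1L, 1L)
  )
  for (i in seq_len(n)) {
    if (crem_from[i] > nchar(seqs[i])) next
    crem <- substr(seqs[i], crem_from[i], nchar(seqs[i]))
    best_sc <- -Inf
    best_ci <- NA_integer_
    for (ci in seq_len(nrow(cs))) {
      al <- sw(crem, cs$seq[ci])
      if (al$score > best_sc) {
        best_sc <- al$score
        best_ci <- ci
      }
    }
    if (!is.na(best_ci) && best_sc >= min_score) {
      out$c_call[i] <- cs$segment_id[best_ci]
      if (!nzchar(out$locus[i])) out$locus[i] <- cs$locus[best_ci]
    }
  }

  aa <- translate_nt(out$junction)
  out$junction_aa <- ifelse(is.na(aa), "", aa)
  out$complete_vdj <- nzchar(out$v_call) & nzchar(out$j_call)
  out
}

# Map a reference (subject) position to a query (pattern) position through
# one local alignment, given the gapped strings and the 1-based start of
# each aligned range. Returns the query position aligned to `ref_pos` (the
# next query base when `ref_pos` sits opposite a gap).
map_ref_pos <- function(aligned_pattern, aligned_subject, pattern_start,
                        subject_start, ref_pos) {
  pch <- strsplit(aligned_pattern, "", fixed = TRUE)[[1]]
  sch <- strsplit(aligned_subject, "", fixed = TRUE)[[1]]
  scum <- cumsum(sch != "-")
  col <- which(scum == ref_pos - subject_start + 1 & sch != "-")[1]
  if (is.na(col)) return(NA_integer_)
  pcum <- cumsum(pch != "-")
  qpos <- pattern_start - 1L + pcum[col]
  if (pch[col] == "-") qpos <- qpos + 1L
  as.integer(qpos)
}

#' Group annotated records by (V, C) segment pair
#'
#' Records lacking a V call (off-target) are dropped; records with a V but
#' no C call are grouped under `(v_call, "none")`.
#'
#' @param records Annotation tibble from [annotate_inserts()] or
#'   [read_airr()].
#' @return A tibble with one row per partition: `v_call`, `c_call`,
#'   `n_members`, `sequence_ids` (list column).
#' @export
group_by_vc <- function(records) {
  records |>
    filter(nzchar(.data$v_call)) |>
    mutate(c_call = ifelse(nzchar(.data$c_call), .data$c_call, "none")) |>
    group_by(.data$v_call, .data$c_call) |>
    summarise(
      n_members = dplyr::n(),
      sequence_ids = list(.data$sequence_id),
      .groups = "drop"
    )
}
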