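#' Greedy k-mer clustering of a read partition
#'
#' Within one (V, C) partition, reads are sorted by length (descending) and
#' each read joins the first existing cluster whose founding centroid
#' shares k-mer Jaccard similarity >= `min_jaccard`, otherwise it founds a
#' new cluster. When per-read CDR3 junctions are supplied, each k-mer
#' cluster is then refined by single-linkage clustering of the junctions at
#' Levenshtein distance <= `max_cdr3_dist`: transcripts of clones that
#' share V, J and C segments differ only inside the junction, which
#' full-length k-mer content cannot resolve. Reads without a junction stay
#' as singletons (they are not corrected), mirroring the practice of
#' dropping reads without V and J annotation before correction.
#'
#' @param partition Tibble with `read_id` and `seq`; an optional `cdr3_nt`
#'   column enables junction refinement.
#' @param k k-mer size (default 8).
#' @param min_jaccard Jaccard threshold (default 0.2; see the methods
#'   vignette for the calibration at a ~5% per-base error rate).
#' @param max_cdr3_dist Junction edit-distance radius for refinement.
#' @return A tibble `read_id`, `cluster` (string id, deterministic).
#' @export
cluster_partition <- function(partition, k = 8, min_jaccard = 0.2,
                              max_cdr3_dist = 10) {
  stopifnot(nrow(partition) > 0)
  ord <- order(-nchar(partition$seq), partition$read_id)
  p <- partition[ord, ]
  keys <- lapply(p$seq, kmer_keys, k = k)
  centroid_keys <- list()
  cluster <- integer(nrow(p))
  for (i in seq_len(nrow(p))) {
    hit <- 0L
    for (cc in seq_along(centroid_keys)) {
      if (jaccard_keys(keys[[i]], centroid_keys[[cc]]) >= min_jaccard) {
        hit <- cc
        break
      }
    }
    if (hit == 0L) {
      centroid_keys[[length(centroid_keys) + 1]] <- keys[[i]]
      hit <- length(centroid_keys)
    }
    cluster[i] <- hit
  }
  res <- tibble(read_id = p$read_id, cluster = as.character(cluster))
  if ("cdr3_nt" %in% names(partition)) {
    res$cdr3_nt <- p$cdr3_nt
    res <- res |>
      group_by(.data$cluster) |>
      dplyr::group_modify(~ refine_by_cdr3(.x, max_cdr3_dist)) |>
      ungroup() |>
      mutate(cluster = paste0(.data$cluster, ".", .data$sub)) |>
      select("read_id", "cluster")
  }
  res[order(match(res$read_id, partition$read_id)), ]
}

# Single-linkage split of one k-mer cluster by junction edit distance.
refine_by_cdr3 <- function(members, max_cdr3_dist) {
  has <- !is.na(members$cdr3_nt) & nzchar(members$cdr3_nt)
  sub <- rep(NA_character_, nrow(members))
  if (any(has)) {
    cdr3 <- members$cdr3_nt[has]
    uq <- sort(unique(cdr3))
    d <- lev_cross_cpp(uq, uq)
    g <- igraph::graph_from_adjacency_matrix(d <= max_cdr3_dist, mode = "undirected")
    comp <- igraph::components(g)$membership
    sub[has] <- as.character(comp[match(cdr3, uq)])
  }
  # junction-less reads become singletons
  if (any(!has)) {
    base <- if (any(has)) max(as.integer(sub[has])) else 0L
    sub[!has] <- paste0("s", base + seq_len(sum(!has)))
  }
  tibble(read_id = members$read_id, sub = sub)
}

#' Build a cluster consensus by iterative alignment and column voting
#'
#' The longest member seeds the consensus; every member is then globally
#' aligned (affine gaps) to the running consensus and a per-column
#' plurality vote over `{A, C, G, T, gap}` is taken. A gap never wins a
#' tie; ties between bases keep the current consensus base when it is among
#' the tied, otherwise the lexicographically smallest base. Insertions
#' relative to the consensus are added where a strict majority of members
#' insert, using the most common inserted string. Two refinement passes are
#' run; singleton clusters pass through unchanged.
#'
#' @param seqs Character vector of member sequences (length >= 1).
#' @param passes Number of align-and-vote passes (default 2).
#' @param match,mismatch,gap_open,gap_ext Alignment scoring parameters.
#' @param max_voters Vote with at most this many members (default 24,
#'   taken in length-descending order); the plurality vote is already
#'   saturated well below that at long-read error rates, so further
#'   members only add cost.
#' @return The consensus sequence (length-1 character).
#' @export
build_consensus <- function(seqs, passes = 2, match = 2, mismatch = -4,
                            gap_open = 4, gap_ext = 2, max_voters = 24) {
  stopifnot(length(seqs) >= 1)
  if (length(seqs) == 1) return(seqs)
  ord <- order(-nchar(seqs), seqs)
  seed <- seqs[ord[1]]
  cons <- seed
  seqs <- seqs[ord[seq_len(min(length(seqs), max_voters))]]
  n <- length(seqs)
  for (p in seq_len(passes)) {
    L <- nchar(cons)
    base_mat <- matrix("-", n, L)
    ins_list <- vector("list", n)
    for (m in seq_len(n)) {
      al <- nw_affine_cpp(seqs[m], cons, match, mismatch, gap_open, gap_ext)
      pch <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
      sch <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
      ccol <- cumsum(sch != "-")
      on_col <- sch != "-"
      base_mat[m, ccol[on_col]] <- pch[on_col]
      ins_at <- which(!on_col)
      if (length(ins_at)) {
        junction <- ccol[ins_at] # 0 = before first consensus column
        ins_list[[m]] <- vapply(
          split(pch[ins_at], junction),
          paste, character(1), collapse = ""
        )
      }
    }
    counts <- vapply(
      c("A", "C", "G", "T", "-"),
      function(b) .colSums(base_mat == b, n, L),
      numeric(L)
    )
    counts <- matrix(counts, nrow = L)
    cons_ch <- strsplit(cons, "", fixed = TRUE)[[1]]
    new_ch <- character(L)
    for (j in seq_len(L)) {
      cj <- counts[j, ]
      mx <- max(cj)
      tied <- c("A", "C", "G", "T", "-")[cj == mx]
      if (length(tied) > 1 && "-" %in% tied) tied <- setdiff(tied, "-")
      new_ch[j] <- if (length(tied) == 1) {
        tied
      } else if (cons_ch[j] %in% tied) {
        cons_ch[j]
      } else {
        sort(tied)[1]
      }
    }
    # majority insertions between consensus columns
    ins_all <- unlist(lapply(seq_len(n), function(m) {
      x <- ins_list[[m]]
      if (is.null(x)) character(0) else paste0(names(x), ":", x)
    }))
    ins_ins <- rep("", L + 1) # slot j+1 = after column j
    if (length(ins_all)) {
      tab <- table(ins_all)
      junctions <- as.integer(sub(":.*$", "", names(tab)))
      strings <- sub("^[0-9]+:", "", names(tab))
      for (jn in unique(junctions)) {
        sel <- junctions == jn
        total_here <- sum(tab[sel])
        if (total_here > n / 2) {
          best <- which(sel)[order(-tab[sel], strings[sel])][1]
          if (tab[best] > n / 2) ins_ins[jn + 1] <- strings[best]
        }
      }
    }
    keep <- new_ch != "-"
    body <- paste0(ins_ins[seq_len(L)], ifelse(keep, new_ch, ""))
    new_cons <- paste0(paste(body, collapse = ""), ins_ins[L + 1])
    if (identical(new_cons, cons)) break
    cons <- new_cons
  }
  cons
}

#' Replace clustered reads by their cluster consensus
#'
#' @param partition Tibble with `read_id` and `seq`.
#' @param clusters Tibble `read_id`, `cluster` from [cluster_partition()].
#' @return A tibble `read_id`, `cluster`, `seq` (the consensus the read was
#'   replaced by; singleton members pass through unchanged).
#' @export
correct_clusters <- function(partition, clusters) {
  joined <- inner_join(partition, clusters, by = "read_id")
  joined |>
    group_by(.data$cluster) |>
    mutate(seq = build_consensus(.data$seq)) |>
    ungroup() |>
    select("read_id", "cluster", "seq")
}

#' Measure per-read error rates against constant-region references
#'
#' Each read is locally aligned to every C-role segment; for its best C
#' alignment the error rate is `(mismatches + inserted + deleted bases) /
#' alignment columns`. Indels are counted because long-read error is
#' indel-rich. Reads whose best C score falls below `min_score` are
#' excluded and tallied.
#'
#' @param reads Tibble with `read_id` and `seq`.
#' @param refs Segment reference tibble containing C-role rows.
#' @param min_score Minimum local alignment score (default 50).
#' @param match,mismatch,gap_open,gap_ext Alignment scoring parameters.
#' @return An `error_report` object: list with `per_read` (tibble
#'   `read_id`, `c_call`, `error_rate`, `alignment_columns`, `read_length`)
#'   and `summary` (one-row tibble with `n_reads`, `n_aligned`,
#'   `n_excluded`, `mean_error`, `sd_error`, `mean_length`, `sd_length`).
#' @export
measure_error <- function(reads, refs, min_score = 50, match = 2,
                          mismatch = -4, gap_open = 4, gap_ext = 2) {
  cs <- refs[refs$role == "C", ]
  if (nrow(cs) == 0) {
    abort("reference set contains no C-role segments",
      class = "clonospace_config_error"
    )
  }
  n <- nrow(reads)
  per <- tibble(
    read_id = reads$read_id, c_call = NA_character_,
    error_rate = NA_real_, alignment_columns = NA_integer_,
    read_length = nchar(reads$seq)
  )
  for (i in seq_len(n)) {
    best <- NULL
    best_ci <- NA_integer_
    for (ci in seq_len(nrow(cs))) {
      al <- sw_affine_cpp(reads$seq[i], cs$seq[ci], match, mismatch, gap_open, gap_ext)
      if (is.null(best) || al$score > best$score) {
        best <- al
        best_ci <- ci
      }
    }
    if (!is.null(best) && best$score >= min_score) {
      per$c_call[i] <- cs$segment_id[best_ci]
      per$alignment_columns[i] <- best$columns
      per$error_rate[i] <- (best$nmismatch + best$nins + best$ndel) / best$columns
    }
  }
  ok <- !is.na(per$error_rate)
  summary <- tibble(
    n_reads = n, n_aligned = sum(ok), n_excluded = n - sum(ok),
    mean_error = mean(per$error_rate[ok]),
    sd_error = sd(per$error_rate[ok]),
    mean_length = mean(per$read_length),
    sd_length = sd(per$read_length)
  )
  structure(list(per_read = per, summary = summary), class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<error_report> %d reads (%d aligned to a C segment, %d excluded)\n",
    s$n_reads, s$n_aligned, s$n_excluded
  ))
  cat(sprintf(
    "  mean error %.3f%% (sd %.3f%%), mean length %.0f nt (sd %.0f)\n",
    100 * s$mean_error, 100 * s$sd_error, s$mean_length, s$sd_length
  ))
  invisible(x)
}

#' Run grouping, clustering and consensus correction over annotated inserts
#'
#' Convenience wrapper chaining [group_by_vc()], [cluster_partition()] and
#' [correct_clusters()] over every (V, C) partition.
#'
#' @param inserts Tibble with `insert_id`/`read_id` and `seq`.
#' @param records Annotation tibble matching `inserts` by `sequence_id`.
#' @param ... Passed to [cluster_partition()].
#' @return A tibble `read_id`, `partition`, `cluster`, `seq` (corrected).
#' @export
correct_partitions <- function(inserts, records, ...) {
  id_col <- intersect(c("insert_id", "sequence_id", "read_id"), names(inserts))[1]
  seq_lookup <- setNames(inserts$seq, inserts[[id_col]])
  cdr3_lookup <- setNames(records$junction, records$sequence_id)
  parts <- group_by_vc(records)
  out <- vector("list", nrow(parts))
  for (i in seq_len(nrow(parts))) {
    ids <- parts$sequence_ids[[i]]
    part <- tibble(
      read_id = ids, seq = unname(seq_lookup[ids]),
      cdr3_nt = unname(cdr3_lookup[ids])
    )
    cl <- cluster_partition(part, ...)
    corrected <- correct_clusters(part[, c("read_id", "seq")], cl)
    corrected$partition <- paste0(parts$v_call[i], "|", parts$c_call[i])
    out[[i]] <- corrected
  }
  bind_rows(out) |> select("read_id", "partition", "cluster", "seq")
}
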