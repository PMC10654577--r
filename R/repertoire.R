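#' Levenshtein edit distance
#'
#' Standard unit-cost edit distance (insertion, deletion, substitution) by
#' dynamic programming; the primitive behind clonotype merging and the
#' spot-wise CDR3 diversity index.
#'
#' @param a,b Character vectors (recycled to a common length). Empty
#'   strings are allowed: `levenshtein("", y)` is `nchar(y)`.
#' @return Integer vector of distances.
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  lev_pair_cpp(rep_len(as.character(a), n), rep_len(as.character(b), n))
}

#' Filter annotated TCR records before clonotype clustering
#'
#' Keeps records whose CDR3 amino-acid length lies in
#' `[min_len, max_len]`, whose UMI count reaches `min_umi`, and (when
#' `require_vj`) that carry both a V and a J call. CDR3s containing a stop
#' (`*`) or ambiguous residue (`X`) are dropped.
#'
#' @param records Tibble with at least `cdr3_aa`, `umi_count`, `v_call`,
#'   `j_call` (e.g. from [collapse_to_umis()]).
#' @param min_len,max_len CDR3 amino-acid length bounds (defaults 5, 30).
#' @param min_umi Minimum UMI count (default 1).
#' @param require_vj Require both V and J calls (default TRUE).
#' @return The filtered tibble.
#' @export
preprocess_tcr <- function(records, min_len = 5, max_len = 30, min_umi = 1,
                           require_vj = TRUE) {
  out <- records |>
    filter(
      !is.na(.data$cdr3_aa), nzchar(.data$cdr3_aa),
      nchar(.data$cdr3_aa) >= min_len, nchar(.data$cdr3_aa) <= max_len,
      !grepl("[*X]", .data$cdr3_aa),
      .data$umi_count >= min_umi
    )
  if (require_vj) {
    out <- filter(out, nzchar(.data$v_call), nzchar(.data$j_call))
  }
  out
}

#' Merge CDR3s into clonotypes by Levenshtein distance
#'
#' Builds, per locus, a graph on distinct CDR3 amino-acid sequences with
#' edges wherever the edit distance is strictly below `min_dist`; connected
#' components are the clones. With the default `min_dist = 2`, CDR3s are
#' merged at distance <= 1 and sequences at distance >= 2 stay distinct.
#' The representative is the longest member (ties broken
#' lexicographically); V/J identities are averaged over member records and
#' per-spot UMI counts are summed.
#'
#' @param records Filtered record tibble (see [preprocess_tcr()]) with
#'   columns `barcode`, `locus`, `cdr3_aa`, `umi_count` and optionally
#'   `v_identity`, `j_identity`.
#' @param min_dist Distinctness threshold (default 2; sequences at distance
#'   >= `min_dist` are never merged).
#' @param require_same_v Merge only CDR3s observed with identical V calls
#'   (default FALSE, merging on CDR3 alone).
#' @return A `tcr_clones` object: a tibble with one row per clone
#'   (`clone_id`, `locus`, `representative_cdr3_aa`, `members` list column,
#'   `mean_v_identity`, `mean_j_identity`, `total_umis`, `n_spots`) with
#'   the long per-spot count table in `attr(, "spot_counts")`
#'   (`clone_id`, `barcode`, `umi_count`).
#' @export
cluster_cdr3 <- function(records, min_dist = 2, require_same_v = FALSE) {
  if (nrow(records) == 0) {
    clones <- tibble(
      clone_id = character(), locus = character(),
      representative_cdr3_aa = character(), members = list(),
      mean_v_identity = numeric(), mean_j_identity = numeric(),
      total_umis = integer(), n_spots = integer()
    )
    attr(clones, "spot_counts") <- tibble(
      clone_id = character(), barcode = character(), umi_count = integer()
    )
    class(clones) <- c("tcr_clones", class(clones))
    return(clones)
  }
  if (!"v_identity" %in% names(records)) records$v_identity <- NA_real_
  if (!"j_identity" %in% names(records)) records$j_identity <- NA_real_
  group_cols <- if (require_same_v) c("locus", "v_call") else "locus"
  records$.grp <- do.call(paste, c(records[group_cols], sep = "\r"))
  all_rows <- list()
  counts_rows <- list()
  clone_no <- 0L
  for (g in sort(unique(records$.grp))) {
    sub <- records[records$.grp == g, ]
    uq <- sort(unique(sub$cdr3_aa))
    d <- lev_cross_cpp(uq, uq)
    gcomp <- igraph::components(
      igraph::graph_from_adjacency_matrix(d < min_dist, mode = "undirected")
    )$membership
    sub$.comp <- gcomp[match(sub$cdr3_aa, uq)]
    for (comp in sort(unique(sub$.comp))) {
      clone_no <- clone_no + 1L
      cid <- sprintf("CL%04d", clone_no)
      rows <- sub[sub$.comp == comp, ]
      members <- sort(unique(rows$cdr3_aa))
      rep_cdr3 <- members[order(-nchar(members), members)[1]]
      spot <- rows |>
        group_by(.data$barcode) |>
        summarise(umi_count = as.integer(sum(.data$umi_count)), .groups = "drop")
      all_rows[[clone_no]] <- tibble(
        clone_id = cid, locus = rows$locus[1],
        representative_cdr3_aa = rep_cdr3, members = list(members),
        mean_v_identity = mean(rows$v_identity, na.rm = TRUE),
        mean_j_identity = mean(rows$j_identity, na.rm = TRUE),
        total_umis = as.integer(sum(spot$umi_count)),
        n_spots = nrow(spot)
      )
      counts_rows[[clone_no]] <- tibble(
        clone_id = cid, barcode = spot$barcode, umi_count = spot$umi_count
      )
    }
  }
  clones <- bind_rows(all_rows)
  attr(clones, "spot_counts") <- bind_rows(counts_rows)
  class(clones) <- c("tcr_clones", class(clones))
  clones
}

#' Per-spot clone counts of a clonotype table
#'
#' @param clones A `tcr_clones` object from [cluster_cdr3()].
#' @return The long tibble `clone_id`, `barcode`, `umi_count`.
#' @export
clone_spot_counts <- function(clones) {
  attr(clones, "spot_counts")
}

#' Normalise clone UMI counts by per-spot UMIs per cell
#'
#' The per-spot normalisation factor is `UMI_c(b) = total_umis(b) /
#' n_cells(b)` (total UMIs from the companion short-read expression
#' library, divided by the cell count of the spot); each raw clone count is
#' divided by it. Spots with raw count below `min_expr` are excluded;
#' spots with zero cells are excluded and tallied in
#' `attr(, "n_zero_cell_spots")`.
#'
#' @param clones A `tcr_clones` object (or a long `clone_id`, `barcode`,
#'   `umi_count` tibble).
#' @param spot_table Spot tibble with `barcode`, `total_umis`, `n_cells`.
#' @param min_expr Minimum raw count (default 1).
#' @return A tibble `clone_id`, `barcode`, `umi_count`, `umi_per_cell`,
#'   `normalized_count`.
#' @export
normalize_tcr <- function(clones, spot_table, min_expr = 1) {
  counts <- if (inherits(clones, "tcr_clones")) clone_spot_counts(clones) else clones
  missing <- setdiff(counts$barcode, spot_table$barcode)
  if (length(missing)) {
    abort(paste0("barcode missing from spot table: ", missing[1]),
      class = "clonospace_join_error"
    )
  }
  joined <- counts |>
    filter(.data$umi_count >= min_expr) |>
    left_join(
      spot_table[, c("barcode", "total_umis", "n_cells")],
      by = "barcode"
    )
  n_zero <- sum(joined$n_cells == 0, na.rm = TRUE)
  out <- joined |>
    filter(.data$n_cells > 0) |>
    mutate(
      umi_per_cell = .data$total_umis / .data$n_cells,
      normalized_count = .data$umi_count / .data$umi_per_cell
    ) |>
    select("clone_id", "barcode", "umi_count", "umi_per_cell", "normalized_count")
  attr(out, "n_zero_cell_spots") <- n_zero
  out
}
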