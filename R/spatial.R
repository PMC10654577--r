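#' Delaunay graph over in-tissue spots
#'
#' Edges are the unique triangle edges of the Delaunay triangulation of the
#' in-tissue spot coordinates. Edges longer than `prune_factor` times the
#' median nearest-neighbour distance are removed as border artifacts.
#' Duplicate coordinates are jittered by `1e-9` of the coordinate span
#' before triangulation.
#'
#' @param spot_table Spot tibble with `barcode`, `x`, `y`, `in_tissue`.
#' @param prune_factor Edge-pruning multiplier (default 3; `Inf` disables
#'   pruning).
#' @return A `spot_graph` object: list with `nodes` (tibble `barcode`,
#'   `x`, `y`) and `edges` (tibble `from`, `to`, `length`; `from < to`).
#' @export
delaunay_graph <- function(spot_table, prune_factor = 3.0) {
  spots <- spot_table[spot_table$in_tissue %in% TRUE, ]
  if (nrow(spots) < 3) {
    abort("need at least 3 in-tissue spots", class = "clonospace_geometry_error")
  }
  x <- spots$x
  y <- spots$y
  dup <- duplicated(cbind(x, y))
  if (any(dup)) {
    span <- max(diff(range(x)), diff(range(y)), 1)
    x[dup] <- x[dup] + stats::runif(sum(dup), -1, 1) * 1e-9 * span
    y[dup] <- y[dup] + stats::runif(sum(dup), -1, 1) * 1e-9 * span
  }
  tri <- tryCatch(
    suppressMessages(deldir::deldir(x, y)),
    error = function(e) NULL
  )
  if (is.null(tri) || nrow(tri$delsgs) == 0) {
    abort(
      "Delaunay triangulation failed (collinear spots?); consider a k-nearest neighbour graph instead",
      class = "clonospace_geometry_error"
    )
  }
  seg <- tri$delsgs
  i1 <- pmin(seg$ind1, seg$ind2)
  i2 <- pmax(seg$ind1, seg$ind2)
  len <- sqrt((x[i1] - x[i2])^2 + (y[i1] - y[i2])^2)
  edges <- tibble(
    from = spots$barcode[i1], to = spots$barcode[i2], length = len
  ) |> distinct(.data$from, .data$to, .keep_all = TRUE)
  if (is.finite(prune_factor)) {
    nn <- c(tapply(c(len, len), c(i1, i2), min))
    cutoff <- prune_factor * median(nn)
    edges <- edges[edges$length <= cutoff, ]
  }
  structure(
    list(
      nodes = tibble(barcode = spots$barcode, x = spots$x, y = spots$y),
      edges = edges
    ),
    class = "spot_graph"
  )
}

#' @export
print.spot_graph <- function(x, ...) {
  cat(sprintf(
    "<spot_graph> %d nodes, %d Delaunay edges\n",
    nrow(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' Neighbour sets of a spot graph
#'
#' @param graph A `spot_graph`.
#' @return Named list mapping each barcode to its neighbour barcodes.
#' @export
graph_neighbors <- function(graph) {
  nb <- split(
    c(graph$edges$to, graph$edges$from),
    c(graph$edges$from, graph$edges$to)
  )
  out <- setNames(vector("list", nrow(graph$nodes)), graph$nodes$barcode)
  out[names(nb)] <- lapply(nb, unique)
  out[vapply(out, is.null, logical(1))] <- list(character(0))
  out
}

#' Per-clone clonality index over the spot graph
#'
#' For each clone and each occupied spot `b`, the co-clonal neighbour count
#' `m_b` is the number of Delaunay neighbours of `b` that also carry the
#' clone (0 when there is no intersection). The clonality index is the
#' mean of `m_b` over the clone's occupied spots; the sum is also reported.
#'
#' @param graph A `spot_graph` whose nodes cover all clone support spots.
#' @param clones A `tcr_clones` object or a long tibble `clone_id`,
#'   `barcode`.
#' @return A tibble `clone_id`, `n_spots`, `clonality_index`,
#'   `clonality_sum`.
#' @export
clonality_index <- function(graph, clones) {
  counts <- if (inherits(clones, "tcr_clones")) clone_spot_counts(clones) else clones
  outside <- setdiff(counts$barcode, graph$nodes$barcode)
  if (length(outside)) {
    abort(paste0("clone support outside graph: ", outside[1]),
      class = "clonospace_join_error"
    )
  }
  nb <- graph_neighbors(graph)
  counts |>
    group_by(.data$clone_id) |>
    summarise(
      n_spots = dplyr::n_distinct(.data$barcode),
      clonality_index = {
        support <- unique(.data$barcode)
        m <- vapply(
          support,
          function(b) length(intersect(nb[[b]], support)), numeric(1)
        )
        mean(m)
      },
      clonality_sum = clonality_index * n_spots,
      .groups = "drop"
    )
}

#' Spot-wise CDR3 diversity index
#'
#' For each CDR3 `j` present at a spot, the mean edit distance to every
#' other CDR3 at that spot is taken; the diversity index DI is the mean of
#' these per-sequence means. DI is 0 with fewer than two distinct CDR3s.
#'
#' @param cdr3s Character vector of CDR3 amino-acid sequences at one spot.
#' @param reciprocal Use mean reciprocal distances (`1/d`) instead of plain
#'   distances (default FALSE, the plain-distance definition).
#' @return The diversity index (length-1 numeric).
#' @export
spot_diversity <- function(cdr3s, reciprocal = FALSE) {
  uq <- unique(cdr3s)
  k <- length(uq)
  if (k < 2) return(0)
  d <- lev_cross_cpp(uq, uq)
  if (reciprocal) {
    d <- ifelse(d > 0, 1 / d, 0)
  }
  per_seq <- (rowSums(d)) / (k - 1)
  mean(per_seq)
}

#' Per-spot totals, clone counts, and diversity
#'
#' `total_tcr_umis` is the sum of clone UMIs at the spot; `n_clones` counts
#' clones with at least `min_umi` UMIs there; `diversity_index` applies
#' [spot_diversity()] to the representative CDR3s of all clones present.
#'
#' @param clones A `tcr_clones` object.
#' @param spot_table Spot tibble (all barcodes are reported, including
#'   TCR-free spots).
#' @param min_umi UMI threshold for counting a clone at a spot (default 5).
#' @param reciprocal Passed to [spot_diversity()].
#' @return A tibble `barcode`, `total_tcr_umis`, `n_clones`,
#'   `diversity_index`.
#' @export
spot_summaries <- function(clones, spot_table, min_umi = 5, reciprocal = FALSE) {
  counts <- clone_spot_counts(clones) |>
    left_join(
      clones[, c("clone_id", "representative_cdr3_aa")],
      by = "clone_id"
    )
  per_spot <- counts |>
    group_by(.data$barcode) |>
    summarise(
      total_tcr_umis = as.integer(sum(.data$umi_count)),
      n_clones = as.integer(sum(.data$umi_count >= min_umi)),
      diversity_index = spot_diversity(.data$representative_cdr3_aa, reciprocal),
      .groups = "drop"
    )
  spot_table |>
    select("barcode") |>
    left_join(per_spot, by = "barcode") |>
    mutate(
      total_tcr_umis = dplyr::coalesce(.data$total_tcr_umis, 0L),
      n_clones = dplyr::coalesce(.data$n_clones, 0L),
      diversity_index = dplyr::coalesce(.data$diversity_index, 0)
    )
}

#' Classify spots as expansion or diversity niches
#'
#' A spot with no TCR UMIs is `none`. A spot is an `expansion` niche when
#' it carries at least one clone whose total UMI count exceeds
#' `umi_threshold` and whose clonality index exceeds `clonality_threshold`.
#' Otherwise it is a `diversity` niche when it hosts at least
#' `min_clones_diverse` clones and its diversity index reaches
#' `diversity_threshold`; remaining TCR-bearing spots are `ambiguous`.
#'
#' @param spot_metrics Output of [spot_summaries()].
#' @param clone_stats Output of [clonality_index()].
#' @param clones A `tcr_clones` object (for clone totals and spot support).
#' @param umi_threshold Clone-total UMI threshold (default 5).
#' @param clonality_threshold Clonality-index threshold (default 1).
#' @param diversity_threshold DI threshold (default 3).
#' @param min_clones_diverse Minimum clones for a diversity call (default 2).
#' @return `spot_metrics` with an added `label` column, one of `none`,
#'   `expansion`, `diversity`, `ambiguous`.
#' @export
classify_spots <- function(spot_metrics, clone_stats, clones,
                           umi_threshold = 5, clonality_threshold = 1,
                           diversity_threshold = 3.0, min_clones_diverse = 2) {
  expanded_clones <- clones$clone_id[
    clones$total_umis > umi_threshold &
      clones$clone_id %in% clone_stats$clone_id[
        clone_stats$clonality_index > clonality_threshold
      ]
  ]
  counts <- clone_spot_counts(clones)
  expansion_spots <- unique(counts$barcode[counts$clone_id %in% expanded_clones])
  spot_metrics |>
    mutate(label = dplyr::case_when(
      .data$total_tcr_umis == 0 ~ "none",
      .data$barcode %in% expansion_spots ~ "expansion",
      .data$n_clones >= min_clones_diverse &
        .data$diversity_index >= diversity_threshold ~ "diversity",
      TRUE ~ "ambiguous"
    ))
}
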