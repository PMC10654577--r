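#' Delaunay cell graph
#'
#' Builds an undirected Delaunay edge list over cell (or deconvolved-cell)
#' positions, optionally restricted to a set of feature labels; each edge
#' carries its pair of cell barcodes.
#'
#' @param cell_positions Tibble with `barcode`, `x`, `y` and optionally
#'   `feature` (a cell-type or state label).
#' @param features Optional character vector of feature labels to keep.
#' @param prune_factor Passed to [delaunay_graph()].
#' @return A `spot_graph` over the selected cells.
#' @export
create_cell_graph <- function(cell_positions, features = NULL,
                              prune_factor = Inf) {
  cells <- cell_positions
  if (!is.null(features)) {
    if (!"feature" %in% names(cells)) {
      abort("cell_positions lacks a feature column",
        class = "clonospace_config_error"
      )
    }
    cells <- cells[cells$feature %in% features, ]
  }
  if (nrow(cells) < 3) {
    abort("need at least 3 cells after feature selection",
      class = "clonospace_geometry_error"
    )
  }
  cells$in_tissue <- TRUE
  delaunay_graph(cells, prune_factor = prune_factor)
}

#' Enhance cell-type-specific gene expression
#'
#' Two-step multiplicative enhancement of a genes-by-spots matrix. Step 1:
#' every significant gene `g` gets `M[g, s] <- M[g, s] + |M[g, s]| * e_g`
#' with `e_g = avg_log2FC_g + 1`. Step 2: a per-spot factor
#' `f_s = exp(x_s)` (in `multi` mode the mean of `exp` over cell types) is
#' sharpened to `f'_s = f_s + (f_s - 1) * mean(e)` and applied to all
#' genes as `M[g, s] <- M[g, s] + |M[g, s]| * (f'_s - 1)`. The neutral
#' specification (`avg_log2FC = -1`, i.e. `e = 0`, and `x = 0`) leaves the
#' matrix unchanged exactly. Results are clipped at zero.
#'
#' @param m Numeric genes-by-spots matrix with dimnames.
#' @param spec Tibble with `gene` and `avg_log2FC` for the significant
#'   genes of the cell type.
#' @param celltype_scores Numeric vector of per-spot cell-type scores
#'   (`single` mode), or a spots-by-celltypes matrix (`multi` mode); order
#'   must match `colnames(m)`.
#' @param mode `"single"` or `"multi"`.
#' @return The enhanced matrix, same shape as `m`.
#' @export
enhance_celltype_expression <- function(m, spec, celltype_scores,
                                        mode = c("single", "multi")) {
  mode <- match.arg(mode)
  missing <- setdiff(spec$gene, rownames(m))
  if (length(missing)) {
    abort(
      paste0(
        "enhancer genes absent from matrix: ",
        paste(head(missing, 10), collapse = ", ")
      ),
      class = "clonospace_config_error"
    )
  }
  e <- spec$avg_log2FC + 1
  out <- m
  idx <- match(spec$gene, rownames(m))
  out[idx, ] <- out[idx, , drop = FALSE] + abs(out[idx, , drop = FALSE]) * e
  f <- if (mode == "single") {
    exp(as.numeric(celltype_scores))
  } else {
    rowMeans(exp(as.matrix(celltype_scores)))
  }
  if (length(f) != ncol(m)) {
    abort("celltype_scores length must match the number of spots",
      class = "clonospace_config_error"
    )
  }
  fp <- f + (f - 1) * mean(e)
  out <- out + sweep(abs(out), 2, fp - 1, `*`)
  out[out < 0] <- 0
  out
}

#' Clone-by-state score matrix
#'
#' For each clone, state scores are taken at its single spot when it
#' occupies one spot, and summed over its spots otherwise.
#'
#' @param state_scores Numeric states-by-spots matrix (non-negative) with
#'   dimnames.
#' @param clones A `tcr_clones` object or long tibble `clone_id`,
#'   `barcode`.
#' @return A states-by-clones numeric matrix.
#' @export
clone_state_matrix <- function(state_scores, clones) {
  counts <- if (inherits(clones, "tcr_clones")) clone_spot_counts(clones) else clones
  outside <- setdiff(counts$barcode, colnames(state_scores))
  if (length(outside)) {
    abort(paste0("clone support spot not scored: ", outside[1]),
      class = "clonospace_join_error"
    )
  }
  clone_ids <- unique(counts$clone_id)
  support <- Matrix::sparseMatrix(
    i = match(counts$barcode, colnames(state_scores)),
    j = match(counts$clone_id, clone_ids),
    x = 1,
    dims = c(ncol(state_scores), length(clone_ids))
  )
  out <- as.matrix(state_scores %*% support)
  dimnames(out) <- list(rownames(state_scores), clone_ids)
  out
}

#' Kullback-Leibler divergence between two spatial expression profiles
#'
#' Profiles are shifted by a pseudocount, normalised to sum to one, and
#' compared as `sum(p * log(p / q))` in nats with the ligand as `p`.
#'
#' @param ligand_profile,receptor_profile Non-negative numeric vectors over
#'   the same spots.
#' @param pseudocount Added to every entry before normalisation.
#' @return KLD in nats (0 iff the normalised profiles are identical).
#' @export
rl_kld <- function(ligand_profile, receptor_profile, pseudocount = 1e-9) {
  stopifnot(length(ligand_profile) == length(receptor_profile))
  if (all(ligand_profile == 0) || all(receptor_profile == 0)) {
    abort("all-zero spatial profile", class = "clonospace_profile_error")
  }
  p <- ligand_profile + pseudocount
  q <- receptor_profile + pseudocount
  p <- p / sum(p)
  q <- q / sum(q)
  sum(p * log(p / q))
}

#' Rank receptor-ligand pairs by spatial KLD
#'
#' Computes [rl_kld()] for every (ligand, receptor) pair over the
#' expression matrix and returns the `top_n` lowest-divergence (most
#' co-localised) pairs, ascending, ties broken lexicographically.
#'
#' @param pairs Tibble with columns `ligand` and `receptor` (gene ids).
#' @param m Genes-by-spots expression matrix containing all pair genes.
#' @param top_n Number of pairs to keep (default 100; all if fewer).
#' @param pseudocount Passed to [rl_kld()].
#' @return A tibble `ligand`, `receptor`, `kld`, ascending in `kld`.
#' @export
rank_rl <- function(pairs, m, top_n = 100, pseudocount = 1e-9) {
  missing <- setdiff(unique(c(pairs$ligand, pairs$receptor)), rownames(m))
  if (length(missing)) {
    abort(
      paste0("pair genes absent from matrix: ", paste(head(missing, 10), collapse = ", ")),
      class = "clonospace_config_error"
    )
  }
  kld <- vapply(seq_len(nrow(pairs)), function(i) {
    rl_kld(m[pairs$ligand[i], ], m[pairs$receptor[i], ], pseudocount)
  }, numeric(1))
  pairs |>
    mutate(kld = kld) |>
    arrange(.data$kld, .data$ligand, .data$receptor) |>
    slice_head(n = top_n)
}

#' Clonal (cytotoxic) CD8 marker genes
#' @return Character vector of gene symbols.
#' @export
clonal_markers <- function() {
  c("IL2", "IFNG", "PRF1", "GZMB", "GZMK", "GZMA", "CD69", "CD25", "CD38")
}

#' Exhaustion marker genes
#' @return Character vector of gene symbols.
#' @export
exhaustion_markers <- function() {
  c(
    "HAVCR2", "PDCD1", "CTLA4", "CXCL8", "LAG3", "EOMES", "TOX", "TIGIT",
    "CD244", "NR4A1"
  )
}

#' Composite cytotoxic/exhausted spot score
#'
#' Marker rows are z-scored across spots (constant rows are skipped and
#' tallied); the clonal score is the mean z over the clonal marker panel
#' and the exhaustion score the mean z over the exhaustion panel. Spots
#' without TCR presence are `unscored`; the rest are `productive` when the
#' clonal score strictly exceeds the exhaustion score and `exhausted`
#' otherwise (ties included).
#'
#' @param m Genes-by-spots expression matrix.
#' @param tcr_presence Logical (or 0/1) vector per spot, order matching
#'   `colnames(m)`.
#' @param clonal,exhaustion Marker panels (defaults [clonal_markers()],
#'   [exhaustion_markers()]). Markers absent from `m` are skipped with a
#'   warning.
#' @return A tibble `barcode`, `clonal_score`, `exhaustion_score`,
#'   `label`; skipped constant markers in `attr(, "skipped_markers")`.
#' @export
composite_tcell_score <- function(m, tcr_presence,
                                  clonal = clonal_markers(),
                                  exhaustion = exhaustion_markers()) {
  stopifnot(length(tcr_presence) == ncol(m))
  use_clonal <- intersect(clonal, rownames(m))
  use_exh <- intersect(exhaustion, rownames(m))
  absent <- setdiff(c(clonal, exhaustion), rownames(m))
  if (length(absent)) {
    warn(paste0(
      "markers absent from matrix, skipped: ",
      paste(absent, collapse = ", ")
    ))
  }
  if (length(use_clonal) == 0 || length(use_exh) == 0) {
    abort("no markers from one of the panels found in the matrix",
      class = "clonospace_config_error"
    )
  }
  z_rows <- function(genes) {
    sub <- m[genes, , drop = FALSE]
    sds <- apply(sub, 1, sd)
    keep <- sds > 0
    list(
      z = sweep(
        sweep(sub[keep, , drop = FALSE], 1, rowMeans(sub[keep, , drop = FALSE])),
        1, sds[keep], `/`
      ),
      skipped = genes[!keep]
    )
  }
  zc <- z_rows(use_clonal)
  ze <- z_rows(use_exh)
  if (nrow(zc$z) == 0 || nrow(ze$z) == 0) {
    abort("all markers of one panel are constant across spots",
      class = "clonospace_config_error"
    )
  }
  clonal_score <- colMeans(zc$z)
  exhaustion_score <- colMeans(ze$z)
  present <- as.logical(tcr_presence)
  out <- tibble(
    barcode = colnames(m),
    clonal_score = clonal_score,
    exhaustion_score = exhaustion_score,
    label = dplyr::case_when(
      !present ~ "unscored",
      clonal_score > exhaustion_score ~ "productive",
      TRUE ~ "exhausted"
    )
  )
  attr(out, "skipped_markers") <- c(zc$skipped, ze$skipped)
  out
}
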