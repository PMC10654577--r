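test_that("hand-checked fixtures: triangle, square, hexagon", {
  tri <- delaunay_graph(triangle_spots(), prune_factor = Inf)
  expect_equal(nrow(tri$edges), 3)

  sq <- delaunay_graph(square_spots(), prune_factor = Inf)
  expect_equal(nrow(sq$edges), 5) # 4 sides + one diagonal

  hx <- delaunay_graph(hexagon_spots(), prune_factor = Inf)
  nb <- graph_neighbors(hx)
  expect_equal(length(nb[["C0"]]), 6) # centre connects to every vertex
})

test_that("collinear spots raise a geometry error", {
  line <- tibble::tibble(
    barcode = paste0("S", 1:5), x = 1:5, y = 0,
    in_tissue = TRUE, n_cells = 1L, total_umis = 1L
  )
  expect_error(delaunay_graph(line), class = "clonospace_geometry_error")
})

test_that("Delaunay edges match the brute-force empty-circumcircle oracle", {
  set.seed(99)
  for (rep in 1:12) {
    xy <- cbind(runif(8), runif(8))
    spots <- tibble::tibble(
      barcode = paste0("P", 1:8), x = xy[, 1], y = xy[, 2],
      in_tissue = TRUE, n_cells = 1L, total_umis = 1L
    )
    g <- delaunay_graph(spots, prune_factor = Inf)
    expect_equal(graph_edge_keys(g), brute_delaunay_edges(xy))
  }
})

test_that("graph is symmetric, self-loop free, and within the Euler bound", {
  set.seed(41)
  spots <- tibble::tibble(
    barcode = paste0("S", 1:40), x = runif(40), y = runif(40),
    in_tissue = TRUE, n_cells = 1L, total_umis = 1L
  )
  g <- delaunay_graph(spots, prune_factor = Inf)
  expect_true(all(g$edges$from != g$edges$to))
  expect_lte(nrow(g$edges), 3 * nrow(g$nodes) - 6)
  nb <- graph_neighbors(g)
  for (b in names(nb)) {
    for (v in nb[[b]]) expect_true(b %in% nb[[v]])
  }
})

test_that("edge pruning removes border artifacts only", {
  spots <- dplyr::bind_rows(
    triangle_spots(),
    tibble::tibble(
      barcode = "FAR", x = 50, y = 50,
      in_tissue = TRUE, n_cells = 1L, total_umis = 1L
    )
  )
  unpruned <- delaunay_graph(spots, prune_factor = Inf)
  pruned <- delaunay_graph(spots, prune_factor = 3)
  expect_gt(nrow(unpruned$edges), nrow(pruned$edges))
  expect_false("FAR" %in% c(pruned$edges$from, pruned$edges$to))
})

clone_at <- function(barcodes) {
  tibble::tibble(clone_id = "CL1", barcode = barcodes)
}

test_that("clonality index on the triangle fixture matches hand counts", {
  g <- delaunay_graph(triangle_spots(), prune_factor = Inf)
  # isolated single spot: no co-clonal neighbours, m = 0
  expect_equal(clonality_index(g, clone_at("S1"))$clonality_index, 0)
  # two adjacent spots: m = 1 at each
  expect_equal(clonality_index(g, clone_at(c("S1", "S2")))$clonality_index, 1)
  # all three spots of the triangle: m = 2 each
  st <- clonality_index(g, clone_at(c("S1", "S2", "S3")))
  expect_equal(st$clonality_index, 2)
  expect_equal(st$clonality_sum, 6)
  expect_error(clonality_index(g, clone_at("NOPE")), class = "clonospace_join_error")
})

test_that("clonality index is invariant to translation and rotation", {
  set.seed(15)
  spots <- tibble::tibble(
    barcode = paste0("S", 1:30), x = runif(30), y = runif(30),
    in_tissue = TRUE, n_cells = 1L, total_umis = 1L
  )
  support <- clone_at(sample(spots$barcode, 8))
  base <- clonality_index(delaunay_graph(spots, Inf), support)
  th <- 0.7
  rotated <- dplyr::mutate(spots,
    x2 = 3 + cos(th) * x - sin(th) * y,
    y2 = -1 + sin(th) * x + cos(th) * y, x = x2, y = y2
  )
  rot <- clonality_index(delaunay_graph(rotated, Inf), support)
  expect_equal(base$clonality_index, rot$clonality_index)
})

test_that("diversity index reproduces the worked examples", {
  expect_equal(spot_diversity("CASSLGF"), 0)
  # two CDR3s at distance 4 -> DI 4
  a <- "AAAAAA"
  b <- "AAAACC"
  c3 <- "CCCCAA"
  expect_equal(levenshtein(a, "CCAAAA"), 2L)
  expect_equal(spot_diversity(c("CASSAAAA", "CASSCCCC")), 4)
  # pairwise distances {2, 4, 6}: per-sequence means {3, 4, 5} -> DI 4
  expect_equal(levenshtein(a, b), 2L)
  expect_equal(levenshtein(a, c3), 4L)
  expect_equal(levenshtein(b, c3), 6L)
  expect_equal(spot_diversity(c(a, b, c3)), 4)
})

test_that("DI equals the mean over ordered off-diagonal pairs (identity check)", {
  set.seed(77)
  for (rep in 1:10) {
    cdr3s <- unique(random_peptides(sample(2:7, 1), 8, LETTERS[1:6]))
    if (length(cdr3s) < 2) next
    direct <- {
      s <- 0
      n <- 0
      for (i in seq_along(cdr3s)) {
        for (j in seq_along(cdr3s)) {
          if (i != j) {
            s <- s + levenshtein(cdr3s[i], cdr3s[j])
            n <- n + 1
          }
        }
      }
      s / n
    }
    expect_equal(spot_diversity(cdr3s), direct)
  }
})

test_that("spot summaries count UMIs and thresholded clones", {
  df <- tibble::tibble(
    clone_id = c("a", "b", "c"), locus = "TRB",
    cdr3_aa = c("CASSAAAAGG", "CATTCCCCGG", "CQQQGGGGTT"),
    barcode = c("S1", "S1", "S2"), umi_count = c(6L, 2L, 1L)
  )
  clones <- make_clones(df)
  spots <- triangle_spots()
  sm <- spot_summaries(clones, spots, min_umi = 5)
  expect_equal(sm$total_tcr_umis[sm$barcode == "S1"], 8L)
  expect_equal(sm$n_clones[sm$barcode == "S1"], 1L)
  expect_equal(sm$total_tcr_umis[sm$barcode == "S3"], 0L)
  expect_equal(sm$n_clones[sm$barcode == "S3"], 0L)
  sm1 <- spot_summaries(clones, spots, min_umi = 1)
  expect_equal(sm1$n_clones[sm1$barcode == "S1"], 2L)
})

test_that("spot classification is exhaustive, exclusive, and rule-faithful", {
  df <- tibble::tibble(
    clone_id = "big", locus = "TRB", cdr3_aa = "CASSAAAAGG",
    barcode = c("S1", "S2"), umi_count = c(10L, 4L)
  )
  clones <- make_clones(df)
  g <- delaunay_graph(triangle_spots(), prune_factor = Inf)
  stats <- clonality_index(g, clones)
  expect_equal(stats$clonality_index, 1) # two adjacent spots
  sm <- spot_summaries(clones, triangle_spots(), min_umi = 5)
  lab <- classify_spots(sm, stats, clones)
  # clone has 14 UMIs (> 5) and index 1... not > 1: not expansion
  expect_false(any(lab$label == "expansion"))
  expect_equal(lab$label[lab$barcode == "S3"], "none")

  # with a lower clonality threshold the occupied spots become expansion
  lab2 <- classify_spots(sm, stats, clones, clonality_threshold = 0.5)
  expect_equal(sort(lab2$label[lab2$barcode %in% c("S1", "S2")]), rep("expansion", 2))
  expect_true(all(lab2$label %in% c("none", "expansion", "diversity", "ambiguous")))

  # diversity label: many distinct clones, no expanded one
  df2 <- tibble::tibble(
    clone_id = paste0("c", 1:4), locus = "TRB",
    cdr3_aa = c("CAAAAAAAGG", "CTTTTTTTGG", "CGGGGGGGGG", "CCCCCCCCGG"),
    barcode = "S1", umi_count = 1L
  )
  clones2 <- make_clones(df2)
  sm2 <- spot_summaries(clones2, triangle_spots(), min_umi = 1)
  expect_gt(sm2$diversity_index[sm2$barcode == "S1"], 3)
  lab3 <- classify_spots(
    sm2, clonality_index(g, clones2), clones2
  )
  expect_equal(lab3$label[lab3$barcode == "S1"], "diversity")
})
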