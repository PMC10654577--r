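test_that("cell graph matches spot-level Delaunay on shared coordinates", {
  cells3 <- tibble::tibble(
    barcode = paste0("c", 1:3), x = c(0, 1, 0.5), y = c(0, 0, 1),
    feature = "Tcell"
  )
  g <- create_cell_graph(cells3)
  expect_equal(nrow(g$edges), 3)
  expect_setequal(
    unique(c(g$edges$from, g$edges$to)), cells3$barcode
  )

  expect_error(
    create_cell_graph(cells3, features = "Bcell"),
    class = "clonospace_geometry_error"
  )
  expect_error(
    create_cell_graph(cells3[, c("barcode", "x", "y")], features = "Tcell"),
    class = "clonospace_config_error"
  )

  set.seed(5)
  grid <- tibble::tibble(
    barcode = paste0("g", 1:16),
    x = rep(1:4, 4) + runif(16, -0.1, 0.1),
    y = rep(1:4, each = 4) + runif(16, -0.1, 0.1)
  )
  cg <- create_cell_graph(grid)
  sg <- delaunay_graph(dplyr::mutate(grid, in_tissue = TRUE), prune_factor = Inf)
  expect_equal(graph_edge_keys(cg), graph_edge_keys(sg))
})

test_that("expression enhancement: neutral element, worked example, clipping", {
  m <- matrix(c(2, 1, 0, 3), 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  spec0 <- tibble::tibble(gene = c("g1", "g2"), avg_log2FC = -1) # e = 0
  expect_equal(
    enhance_celltype_expression(m, spec0, c(0, 0)), m # x = 0 -> identity
  )

  # single gene, single spot: M = 2, e = 0.5, x = 0 -> step 1 gives 3.0
  m1 <- matrix(2, 1, 1, dimnames = list("g1", "s1"))
  spec <- tibble::tibble(gene = "g1", avg_log2FC = -0.5)
  expect_equal(enhance_celltype_expression(m1, spec, 0)[1, 1], 3.0)

  # a negative entry with e = 1: -1 + |-1| * 1 = 0
  mneg <- matrix(-1, 1, 1, dimnames = list("g1", "s1"))
  specneg <- tibble::tibble(gene = "g1", avg_log2FC = 0)
  expect_equal(enhance_celltype_expression(mneg, specneg, 0)[1, 1], 0)

  expect_error(
    enhance_celltype_expression(m, tibble::tibble(gene = "nope", avg_log2FC = 1), c(0, 0)),
    class = "clonospace_config_error"
  )
})

test_that("enhancement is monotone in the enhancer factor", {
  # monotonicity holds for non-negative cell-type scores (f = exp(x) >= 1);
  # with f < 1 the sharpening term (f - 1) * mean(e) reverses sign
  set.seed(9)
  m <- matrix(runif(20, 0, 5), 4, 5,
    dimnames = list(paste0("g", 1:4), paste0("s", 1:5))
  )
  x <- runif(5, 0, 0.5)
  lo <- enhance_celltype_expression(
    m, tibble::tibble(gene = "g2", avg_log2FC = 0.2), x
  )
  hi <- enhance_celltype_expression(
    m, tibble::tibble(gene = "g2", avg_log2FC = 0.8), x
  )
  expect_true(all(hi["g2", ] >= lo["g2", ]))
})

test_that("multi-celltype mode averages the exponential factors", {
  m <- matrix(1, 1, 2, dimnames = list("g1", c("s1", "s2")))
  spec0 <- tibble::tibble(gene = "g1", avg_log2FC = -1)
  scores <- cbind(a = c(0, log(2)), b = c(0, log(4)))
  out <- enhance_celltype_expression(m, spec0, scores, mode = "multi")
  # spot 2: f = mean(2, 4) = 3, e-bar = 0 -> f unchanged; M = 1 * 3
  expect_equal(out[1, ], c(s1 = 1, s2 = 3))
})

test_that("clone-state matrix follows f(s, n): single-spot copy, multi-spot sum", {
  scores <- matrix(
    c(0.2, 0.7, 0.3, 0.1, 0.5, 0.4), 2, 3,
    dimnames = list(c("effector", "exhausted"), c("B1", "B2", "B3"))
  )
  counts <- tibble::tibble(
    clone_id = c("one", "two", "two", "zero"),
    barcode = c("B1", "B1", "B2", "B3")
  )
  out <- clone_state_matrix(scores, counts)
  expect_equal(out[, "one"], scores[, "B1"]) # n = 1 branch
  expect_equal(out["effector", "two"], 0.2 + 0.3) # summation branch
  # conservation of total mass
  support_mass <- sum(scores[, "B1"]) * 2 + sum(scores[, "B2"]) + sum(scores[, "B3"])
  expect_equal(sum(out), support_mass)

  zero <- matrix(0, 2, 1, dimnames = list(rownames(scores), "B1"))
  expect_equal(
    unname(clone_state_matrix(zero, counts[1, ])[, 1]), c(0, 0)
  )
  expect_error(
    clone_state_matrix(scores, tibble::tibble(clone_id = "x", barcode = "B9")),
    class = "clonospace_join_error"
  )
})

test_that("KLD: zero at identity, closed-form value, non-negativity, reorder invariance", {
  expect_equal(rl_kld(c(1, 2, 3), c(1, 2, 3)), 0)
  want <- 0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1)
  expect_equal(rl_kld(c(0.5, 0.5), c(0.9, 0.1)), want, tolerance = 1e-6)
  expect_equal(round(want, 4), 0.5108)

  set.seed(10)
  for (i in 1:20) {
    p <- runif(6)
    q <- runif(6)
    expect_gte(rl_kld(p, q), 0)
    o <- sample(6)
    expect_equal(rl_kld(p, q), rl_kld(p[o], q[o]))
  }
  expect_error(rl_kld(c(0, 0), c(1, 2)), class = "clonospace_profile_error")
})

test_that("receptor-ligand ranking returns ascending KLD, all pairs when < 100", {
  set.seed(11)
  genes <- paste0("G", 1:12)
  m <- matrix(runif(12 * 8), 12, 8, dimnames = list(genes, paste0("s", 1:8)))
  pairs <- tidyr::crossing(ligand = genes[1:6], receptor = genes[7:11])
  out <- rank_rl(pairs, m)
  expect_equal(nrow(out), 30)
  expect_true(!is.unsorted(out$kld))
  expect_error(
    rank_rl(tibble::tibble(ligand = "G1", receptor = "NOPE"), m),
    class = "clonospace_config_error"
  )
})

test_that("composite score: marker panels, TCR gating, and label rules", {
  set.seed(12)
  spots <- paste0("s", 1:6)
  genes <- c(clonal_markers(), exhaustion_markers(), "FLAT")
  m <- matrix(runif(length(genes) * 6, 1, 5), length(genes), 6,
    dimnames = list(genes, spots)
  )
  m["FLAT", ] <- 2
  # spot 1 dominated by clonal markers, spot 2 by exhaustion markers
  m[clonal_markers(), 1] <- 50
  m[exhaustion_markers(), 2] <- 50
  tcr <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  out <- composite_tcell_score(m, tcr)
  expect_equal(out$label[1], "productive")
  expect_equal(out$label[2], "exhausted")
  expect_equal(out$label[3], "unscored")

  # constant marker row is skipped and tallied
  m2 <- m
  m2["IL2", ] <- 1
  out2 <- composite_tcell_score(m2, tcr)
  expect_true("IL2" %in% attr(out2, "skipped_markers"))

  # affine per-gene rescaling leaves labels unchanged (z-score invariance)
  m3 <- m * 7 + 3
  out3 <- composite_tcell_score(m3, tcr)
  expect_equal(out$label, out3$label)

  suppressWarnings(expect_error(
    composite_tcell_score(m[1:3, ], tcr),
    class = "clonospace_config_error"
  ))
})
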