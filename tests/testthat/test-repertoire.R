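test_that("levenshtein matches hand and recursion values", {
  expect_equal(levenshtein("", "CASS"), 4L)
  expect_equal(levenshtein("CASSLG", "CASSLG"), 0L)
  expect_equal(levenshtein("KITTEN", "SITTING"), lev_recursive("KITTEN", "SITTING"))
  expect_equal(levenshtein("KITTEN", "SITTING"), 3L)
})

test_that("levenshtein is a metric and agrees with oracles on random peptides", {
  set.seed(6)
  a <- random_peptides(120, 6)
  b <- random_peptides(120, 6)
  c <- random_peptides(120, 6)
  dab <- levenshtein(a, b)
  # identity and symmetry
  expect_true(all(levenshtein(a, a) == 0L))
  expect_equal(dab, levenshtein(b, a))
  # triangle inequality
  expect_true(all(dab <= levenshtein(a, c) + levenshtein(c, b)))
  # recursion oracle on a subsample, base-R adist on everything
  for (i in seq(1, 120, by = 6)) {
    expect_equal(dab[i], lev_recursive(a[i], b[i]))
  }
  expect_equal(dab, as.integer(mapply(utils::adist, a, b)))
})

test_that("preprocess_tcr applies length, UMI, V/J and residue filters", {
  rec <- tibble::tibble(
    cdr3_aa = c("CASS", "CASSLGDF", "CASSLGDF", "CASSLG*F", "CASSXLGF", "CASSLGDF"),
    umi_count = c(5L, 5L, 0L, 5L, 5L, 5L),
    v_call = c("V1", "V1", "V1", "V1", "V1", ""),
    j_call = "J1", barcode = "B1", locus = "TRB"
  )
  out <- preprocess_tcr(rec, min_umi = 1)
  expect_equal(nrow(out), 1) # length-4, zero-UMI, stop, X, V-less all dropped
  out2 <- preprocess_tcr(rec, require_vj = FALSE, min_umi = 1)
  expect_equal(nrow(out2), 2)
})

test_that("clonotype merging follows the distance-2 uniqueness rule", {
  rec <- tibble::tibble(
    barcode = "B1", locus = "TRB",
    cdr3_aa = c("CASSLF", "CASSLY", "CATTRG"),
    umi_count = c(3L, 2L, 4L),
    v_call = "V1", j_call = "J1", v_identity = 0.9, j_identity = 0.8
  )
  expect_equal(levenshtein("CASSLF", "CASSLY"), 1L) # DP oracle: merged
  expect_gte(levenshtein("CASSLF", "CATTRG"), 2L) # stays distinct
  clones <- cluster_cdr3(rec, min_dist = 2)
  expect_equal(nrow(clones), 2)
  merged <- clones[vapply(clones$members, length, integer(1)) == 2, ]
  expect_equal(merged$representative_cdr3_aa, "CASSLF") # length tie -> lexicographic
  expect_equal(merged$total_umis, 5L)

  # min_dist = 1 never merges anything
  expect_equal(nrow(cluster_cdr3(rec, min_dist = 1)), 3)
})

test_that("clone totals conserve record counts and spots", {
  set.seed(14)
  rec <- tibble::tibble(
    barcode = sample(paste0("B", 1:6), 30, TRUE),
    locus = sample(c("TRA", "TRB"), 30, TRUE),
    cdr3_aa = sample(c("CASSLF", "CASSLY", "CATTRG", "CQQQQF"), 30, TRUE),
    umi_count = sample(1:5, 30, TRUE),
    v_call = "V1", j_call = "J1", v_identity = 1, j_identity = 1
  ) |> dplyr::distinct(barcode, locus, cdr3_aa, .keep_all = TRUE)
  clones <- cluster_cdr3(rec)
  expect_equal(sum(clones$total_umis), sum(rec$umi_count))
  counts <- clone_spot_counts(clones)
  expect_equal(sum(counts$umi_count), sum(rec$umi_count))
  expect_equal(clones$n_spots, unname(vapply(
    clones$clone_id,
    function(id) length(unique(counts$barcode[counts$clone_id == id])),
    integer(1)
  )))
})

test_that("clustering is per-locus: identical CDR3s in TRA and TRB stay apart", {
  rec <- tibble::tibble(
    barcode = "B1", locus = c("TRA", "TRB"), cdr3_aa = "CASSLGF",
    umi_count = 1L, v_call = "V1", j_call = "J1",
    v_identity = 1, j_identity = 1
  )
  clones <- cluster_cdr3(rec)
  expect_equal(nrow(clones), 2)
  expect_setequal(clones$locus, c("TRA", "TRB"))
})

test_that("single-substitution CDR3 variants merge; distance >= 2 never merges", {
  b <- simulate_repertoire(n_spots = 25, n_clones = 8, seed = 3)
  planted <- b$clones$cdr3_aa
  # plant one single-substitution variant of the first CDR3
  variant <- planted[1]
  substr(variant, 3, 3) <- ifelse(substr(variant, 3, 3) == "A", "G", "A")
  rec <- tibble::tibble(
    barcode = "B1", locus = b$clones$locus[1],
    cdr3_aa = c(planted[b$clones$locus == b$clones$locus[1]], variant),
    umi_count = 2L, v_call = "V", j_call = "J",
    v_identity = 1, j_identity = 1
  )
  clones <- cluster_cdr3(rec)
  # the variant merged into its parent, every planted CDR3 still distinct
  expect_equal(nrow(clones), sum(b$clones$locus == b$clones$locus[1]))
  parent <- clones[vapply(clones$members, function(m) variant %in% m, logical(1)), ]
  expect_true(planted[1] %in% parent$members[[1]])
})

test_that("normalisation divides by per-spot UMIs per cell", {
  spots <- tibble::tibble(
    barcode = c("B1", "B2", "B3"), x = c(0, 1, 2), y = 0,
    in_tissue = TRUE, n_cells = c(10L, 0L, 4L),
    total_umis = c(2000L, 500L, 400L)
  )
  counts <- tibble::tibble(
    clone_id = c("CL1", "CL1", "CL1"),
    barcode = c("B1", "B2", "B3"),
    umi_count = c(4L, 2L, 0L)
  )
  out <- normalize_tcr(counts, spots, min_expr = 1)
  # raw 4 at UMI_c = 2000/10 = 200 -> 0.02
  expect_equal(out$normalized_count[out$barcode == "B1"], 0.02)
  # zero-cell spot excluded and tallied; sub-threshold spot excluded
  expect_false("B2" %in% out$barcode)
  expect_false("B3" %in% out$barcode)
  expect_equal(attr(out, "n_zero_cell_spots"), 1)

  bad <- dplyr::mutate(counts, barcode = c("B1", "B9", "B3"))
  expect_error(normalize_tcr(bad, spots), "B9", class = "clonospace_join_error")
})
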