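test_that("identical inserts form one cluster; disjoint families two; singleton one", {
  five <- tibble::tibble(
    read_id = paste0("r", 1:5), seq = rep(strrep("ACGTGGTACC", 30), 5)
  )
  cl <- cluster_partition(five)
  expect_equal(length(unique(cl$cluster)), 1)
  expect_equal(nrow(cl), 5)

  set.seed(8)
  fam1 <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  fam2 <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  # k-mer Jaccard of unrelated sequences is ~0 (set oracle)
  k1 <- unique(substring(fam1, 1:293, 8:300))
  k2 <- unique(substring(fam2, 1:293, 8:300))
  expect_lt(length(intersect(k1, k2)) / length(union(k1, k2)), 0.2)
  two <- tibble::tibble(
    read_id = paste0("r", 1:6), seq = c(rep(fam1, 3), rep(fam2, 3))
  )
  cl <- cluster_partition(two)
  expect_equal(length(unique(cl$cluster)), 2)

  single <- cluster_partition(tibble::tibble(read_id = "r1", seq = fam1))
  expect_equal(nrow(single), 1)
})

test_that("junction refinement splits clones sharing V/J/C and isolates junction-less reads", {
  set.seed(12)
  backbone_a <- paste(sample(c("A", "C", "G", "T"), 350, TRUE), collapse = "")
  backbone_b <- paste(sample(c("A", "C", "G", "T"), 350, TRUE), collapse = "")
  cdr1 <- "TGTGCAAGCAGCTTGGGC"
  cdr2 <- "TGTTACTCGAGGAAATTC"
  part <- tibble::tibble(
    read_id = paste0("r", 1:5),
    seq = c(
      rep(paste0(backbone_a, cdr1, backbone_b), 2),
      rep(paste0(backbone_a, cdr2, backbone_b), 2),
      paste0(backbone_a, cdr1, backbone_b)
    ),
    cdr3_nt = c(cdr1, cdr1, cdr2, cdr2, NA)
  )
  cl <- cluster_partition(part)
  expect_equal(length(unique(cl$cluster)), 3) # cdr1 pair, cdr2 pair, NA singleton
  by_cdr <- split(cl$cluster, part$cdr3_nt[match(cl$read_id, part$read_id)])
  expect_equal(length(unique(by_cdr$TGTGCAAGCAGCTTGGGC)), 1)
  expect_equal(length(unique(by_cdr$TGTTACTCGAGGAAATTC)), 1)
})

test_that("consensus of identical members is the member; singletons pass through", {
  expect_equal(build_consensus(rep("ACGTACGT", 4)), "ACGTACGT")
  expect_equal(build_consensus("TTTTAAAA"), "TTTTAAAA")
})

test_that("consensus recovers the truth from 7 independently corrupted copies", {
  set.seed(13)
  truth <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  members <- corrupt_seqs(rep(truth, 7), sub = 0.05, ins = 0, del = 0)$seq
  expect_equal(build_consensus(members), truth)
  # and with the full indel channel
  members2 <- corrupt_seqs(rep(truth, 9), sub = 0.026, ins = 0.0095, del = 0.0119)$seq
  expect_equal(build_consensus(members2), truth)
})

test_that("error measurement against C references follows the stated formula", {
  refs <- toy_references(seed = 2)
  cseg <- refs$seq[refs$role == "C"][1]
  flank <- strrep("ACGTT", 40)
  clean <- tibble::tibble(read_id = "r1", seq = paste0(flank, cseg))
  er <- measure_error(clean, refs)
  expect_equal(er$per_read$error_rate, 0)

  # exactly 3 substitutions inside the 150 nt C segment -> 3/150 = 0.02
  ch <- strsplit(cseg, "")[[1]]
  for (pos in c(30, 75, 120)) ch[pos] <- setdiff(c("A", "C", "G", "T"), ch[pos])[1]
  noisy <- tibble::tibble(read_id = "r1", seq = paste0(flank, paste(ch, collapse = "")))
  er <- measure_error(noisy, refs)
  expect_equal(er$per_read$alignment_columns, 150L)
  expect_equal(er$per_read$error_rate, 0.02)

  # a read with no C content is excluded and tallied
  set.seed(5)
  junk <- tibble::tibble(
    read_id = "r1",
    seq = paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  )
  er <- measure_error(junk, refs)
  expect_equal(er$summary$n_excluded, 1)
  expect_true(is.na(er$per_read$error_rate))

  expect_error(
    measure_error(clean, refs[refs$role != "C", ]),
    class = "clonospace_config_error"
  )
})

test_that("tidy/glance accessors expose the error report", {
  refs <- toy_references(seed = 2)
  cseg <- refs$seq[refs$role == "C"][1]
  er <- measure_error(tibble::tibble(read_id = "r", seq = cseg), refs)
  expect_equal(nrow(tidy(er)), 1)
  expect_equal(glance(er)$n_aligned, 1)
})

test_that("correction error decreases with cluster size (paired seeds)", {
  refs <- toy_references(seed = 2)
  truth <- paste0(
    refs$seq[refs$role == "V"][1], "TGTGCAAGCAGCTTG",
    refs$seq[refs$role == "J"][1], refs$seq[refs$role == "C"][1]
  )
  post_rate <- function(n_members, seed) {
    set.seed(seed)
    members <- corrupt_seqs(rep(truth, n_members),
      sub = 0.026, ins = 0.0095, del = 0.0119
    )$seq
    cons <- build_consensus(members)
    er <- measure_error(tibble::tibble(read_id = "c", seq = cons), refs)
    er$per_read$error_rate
  }
  rates5 <- vapply(1:6, function(s) post_rate(5, s), numeric(1))
  rates20 <- vapply(1:6, function(s) post_rate(20, s), numeric(1))
  expect_lte(mean(rates20), mean(rates5))
})

test_that("cluster purity: >= 99% of clusters hold a single true clone", {
  b <- simulate_repertoire(n_spots = 36, n_clones = 12, seed = 23)
  em <- emit_reads(b, mean_reads_per_umi = 2)
  ins <- orient_and_split(em$reads)
  ann <- annotate_inserts(ins, b$refs)
  corr <- correct_partitions(ins, ann)
  truth_clone <- em$truth$clone_id[
    match(sub("/seg[0-9]+$", "", corr$read_id), em$truth$read_id)
  ]
  purity <- tapply(truth_clone, paste(corr$partition, corr$cluster),
    function(x) length(unique(x)) == 1
  )
  expect_gte(mean(purity), 0.99)
})
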