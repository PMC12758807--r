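test_that("pileup depth counts aligned reference columns only", {
  a <- make_alignment("r1", 0L, "100=", rand_dna(100))
  d <- pileup_depth(a, 150L)
  expect_equal(d[1:100], rep(1L, 100))
  expect_equal(d[101:150], rep(0L, 50))
  expect_equal(sum(d), 100L)
  expect_equal(pileup_depth(a[0, ], 80L), integer(80))
  expect_error(pileup_depth(a, 90L), "bounds|ref_length")
})

test_that("depth and counts match a naive per-column recount on gapped records", {
  aln <- random_alignments(300, ref_len = 400, seed = 21)
  oracle <- naive_pileup(aln, 400L)
  expect_equal(pileup_depth(aln, 400L), oracle$depth)
  cm <- count_nucleotides(aln, rand_dna(400), "ref", "lib", "0B")
  expect_equal(unname(cm$counts), unname(oracle$counts))
  # conservation: sum of depth equals total aligned read bases
  expect_equal(sum(oracle$depth), sum(aln$n_match + aln$n_mismatch))
})

test_that("control-interval normalization sets the control mean to 1", {
  p1 <- make_profile(rep(30L, 200), "l1", "0B")
  p2 <- make_profile(rep(3L, 200), "l2", "1B")
  np <- normalize_profiles(list(p1, p2), c(50L, 150L))
  expect_equal(np[[1]]$normalizer, 30)
  expect_equal(np[[2]]$normalizer, 3)
  expect_equal(mean(bretro:::normalized_depth(np[[1]])[51:150]), 1)
  expect_error(normalize_profiles(list(make_profile(rep(0L, 200), "z", "0B")),
                                  c(0L, 200L)), "zero")
})

test_that("normalized profiles are scale invariant", {
  set.seed(22)
  shape <- rpois(300, 20)
  a <- make_profile(shape, "a", "0B")
  b <- make_profile(shape * 10L, "b", "0B")
  np <- normalize_profiles(list(a, b), c(0L, 300L))
  expect_equal(bretro:::normalized_depth(np[[1]]),
               bretro:::normalized_depth(np[[2]]))
})

test_that("a noise-free coverage step is called within the smoothing window", {
  L <- 2000L
  d0 <- rep(20L, L)
  d1 <- ifelse(seq_len(L) - 1L >= 500L & seq_len(L) - 1L < 1500L, 200L, 20L)
  g0 <- list(make_profile(d0, "a", "0B", normalizer = 20),
             make_profile(d0, "b", "0B", normalizer = 20))
  g1 <- list(make_profile(d1, "c", "1B", normalizer = 20),
             make_profile(d1, "d", "1B", normalizer = 20))
  calls <- detect_amplified_region(g0, g1)
  expect_equal(nrow(calls), 1L)
  expect_lt(abs(calls$start - 500L), 25L)
  expect_lt(abs(calls$end - 1500L), 25L)
  # identical groups: no call
  expect_equal(nrow(detect_amplified_region(g0, g0)), 0L)
})

test_that("copy-number estimator follows the closed form a*(r1 - r0)", {
  g0 <- list(make_profile(rep(10L, 300), "a", "0B", normalizer = 10))
  g1 <- list(make_profile(rep(25L, 300), "b", "1B", normalizer = 10))
  call <- data.frame(ref_id = "ref", start = 50L, end = 250L)
  est <- estimate_b_copy_number(call, g0, g1, a_copies = 2L)
  expect_equal(est$n_b, 3)          # 2 * (2.5 - 1)
  est0 <- estimate_b_copy_number(call, g0, g0, a_copies = 2L)
  expect_equal(est0$n_b, 0)
  expect_error(estimate_b_copy_number(data.frame(start = 5L, end = 5L),
                                      g0, g1), "empty")
})

test_that("0B-zero positions are masked, not infinite ratios", {
  d0 <- c(rep(0L, 50), rep(10L, 150))
  d1 <- rep(30L, 200)
  g0 <- list(make_profile(d0, "a", "0B", normalizer = 10))
  g1 <- list(make_profile(d1, "b", "1B", normalizer = 10))
  calls <- detect_amplified_region(g0, g1, min_length = 50L)
  expect_true(all(calls$start >= 40L))
  ex <- expression_ratio_profile(g0, g1)
  expect_true(all(is.na(ex$ratio[1:50])))
  expect_equal(ex$n_masked, 50L)
})

test_that("expression ratio recovers trivial contrasts", {
  g0 <- list(make_profile(rep(40L, 100), "a", "0B", assay = "mRNA",
                          normalizer = 40))
  ex1 <- expression_ratio_profile(g0, g0)
  expect_equal(ex1$mean_ratio, 1)
  gz <- list(make_profile(rep(0L, 100), "b", "1B", assay = "mRNA",
                          normalizer = 40))
  expect_equal(expression_ratio_profile(g0, gz)$mean_ratio, 0)
})

test_that("two-pass region calling recovers a simulated truncation", {
  cfg <- simulation_config(n_exons = 6L, trunc_exons = c(3L, 6L), n_b = 4L,
                           depth = 12, libs_per_group = 2L,
                           b_background = 1200L)
  ds <- simulate_bchrom_dataset(cfg, seed = 5, include = "gdna")
  refs <- c(gene_spliced = ds$spliced)
  prof <- lapply(ds$gdna, function(lib) {
    a <- align_reads(lib$reads, refs, library_id = lib$library_id,
                     group = lib$group)
    coverage_profile(a, "gene_spliced", nchar(ds$spliced), lib$library_id,
                     lib$group)
  })
  is0 <- vapply(prof, function(p) p$group == "0B", logical(1))
  res <- call_b_region(prof[is0], prof[!is0])
  expect_gt(nrow(res$calls), 0L)
  main <- res$calls[which.max(res$calls$length), ]
  tr <- ds$truth$trunc_interval
  jac <- interval_jaccard_test(c(main$start, main$end), unname(tr))
  expect_gt(jac, 0.85)
  expect_lt(abs(res$copy_number$n_b - 4), 1.2)
})

test_that("median copy-number estimate is monotone in the true copy number", {
  est <- vapply(c(0L, 2L, 8L), function(nb) {
    cfg <- simulation_config(n_exons = 6L, trunc_exons = c(3L, 6L), n_b = nb,
                             depth = 10, libs_per_group = 1L,
                             b_background = 800L)
    ds <- simulate_bchrom_dataset(cfg, seed = 31, include = "gdna")
    refs <- c(gene_spliced = ds$spliced)
    prof <- lapply(ds$gdna, function(lib) {
      a <- align_reads(lib$reads, refs, library_id = lib$library_id,
                       group = lib$group)
      coverage_profile(a, "gene_spliced", nchar(ds$spliced), lib$library_id,
                       lib$group)
    })
    is0 <- vapply(prof, function(p) p$group == "0B", logical(1))
    res <- call_b_region(prof[is0], prof[!is0])
    if (is.null(res$copy_number)) 0 else res$copy_number$n_b
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})
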