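# one-position count matrices for hand-worked filter checks
one_pos <- function(counts, lib, group, ref = "A") {
  m <- matrix(0L, 1, 6)
  m[1, ] <- counts
  make_counts(m, ref, lib, group)
}

test_that("the two stated filters call a hand-worked B-specific SNP", {
  # 0B libs (A:30), (A:34); 1B libs (A:30, G:18), (A:28, G:20)
  c0 <- list(one_pos(c(30L, 0L, 0L, 0L, 0L, 0L), "ob1", "0B"),
             one_pos(c(34L, 0L, 0L, 0L, 0L, 0L), "ob2", "0B"))
  c1 <- list(one_pos(c(30L, 0L, 18L, 0L, 0L, 0L), "bb1", "1B"),
             one_pos(c(28L, 0L, 20L, 0L, 0L, 0L), "bb2", "1B"))
  snps <- call_b_specific_snps(c1, c0)
  expect_equal(nrow(snps), 1L)
  expect_equal(snps$alt, "G")
  expect_equal(snps$mean_total_0b, 32)   # m0
  expect_equal(snps$mean_alt_1b, 19)     # >= 16 = half of the 0B mean
})

test_that("filter 1 rejects alleles missing from any 1B library", {
  c0 <- list(one_pos(c(30L, 0L, 0L, 0L, 0L, 0L), "ob1", "0B"),
             one_pos(c(34L, 0L, 0L, 0L, 0L, 0L), "ob2", "0B"))
  c1 <- list(one_pos(c(30L, 0L, 18L, 0L, 0L, 0L), "bb1", "1B"),
             one_pos(c(48L, 0L, 0L, 0L, 0L, 0L), "bb2", "1B"))
  expect_equal(nrow(call_b_specific_snps(c1, c0)), 0L)
})

test_that("filter 2 rejects alleles below half the 0B mean", {
  c0 <- list(one_pos(c(30L, 0L, 0L, 0L, 0L, 0L), "ob1", "0B"),
             one_pos(c(34L, 0L, 0L, 0L, 0L, 0L), "ob2", "0B"))
  c1 <- list(one_pos(c(30L, 0L, 3L, 0L, 0L, 0L), "bb1", "1B"),
             one_pos(c(28L, 0L, 2L, 0L, 0L, 0L), "bb2", "1B"))
  expect_equal(nrow(call_b_specific_snps(c1, c0)), 0L)  # mean 2.5 < 16
})

test_that("alleles present in any 0B library are never reported (exclusivity)", {
  c0 <- list(one_pos(c(30L, 0L, 1L, 0L, 0L, 0L), "ob1", "0B"),
             one_pos(c(34L, 0L, 0L, 0L, 0L, 0L), "ob2", "0B"))
  c1 <- list(one_pos(c(30L, 0L, 18L, 0L, 0L, 0L), "bb1", "1B"),
             one_pos(c(28L, 0L, 20L, 0L, 0L, 0L), "bb2", "1B"))
  expect_equal(nrow(call_b_specific_snps(c1, c0)), 0L)
})

test_that("zero-coverage 0B positions are skipped and logged", {
  c0 <- list(one_pos(c(0L, 0L, 0L, 0L, 0L, 0L), "ob1", "0B"))
  c1 <- list(one_pos(c(0L, 0L, 18L, 0L, 0L, 0L), "bb1", "1B"))
  snps <- call_b_specific_snps(c1, c0)
  expect_equal(nrow(snps), 0L)
  expect_equal(attr(snps, "skipped_zero_0b"), 1L)
})

test_that("group merging is cell-wise, linear and permutation invariant", {
  set.seed(70)
  mk <- function(lib) make_counts(matrix(rpois(60, 5), 10, 6),
                                  sample(c("A", "C", "G", "T"), 10, TRUE),
                                  lib, "0B")
  ms <- lapply(sprintf("l%d", 1:10), mk)
  expect_equal(merge_group_counts(ms[1])$counts, ms[[1]]$counts)
  expect_equal(merge_group_counts(list(ms[[1]], ms[[1]], ms[[1]]))$counts,
               3L * ms[[1]]$counts)
  p <- sample(10)
  expect_equal(merge_group_counts(ms)$counts,
               merge_group_counts(ms[p])$counts)
  bad <- mk("x"); bad$ref_id <- "other"
  expect_error(merge_group_counts(list(ms[[1]], bad)), "reference")
})

test_that("raising either threshold never enlarges the call set", {
  set.seed(71)
  L <- 60L
  ref <- sample(c("A", "C", "G", "T"), L, TRUE)
  mk <- function(lib, group) make_counts(matrix(rpois(L * 6, 3), L, 6),
                                         ref, lib, group)
  c0 <- list(mk("o1", "0B"), mk("o2", "0B"))
  c1 <- list(mk("b1", "1B"), mk("b2", "1B"))
  key <- function(s) paste(s$pos, s$alt)
  prev <- NULL
  for (occ in c(1L, 2L, 4L)) {
    cur <- key(call_b_specific_snps(c1, c0, min_alt_occurrence = occ))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  prev <- NULL
  for (ratio in c(0.1, 0.5, 1)) {
    cur <- key(call_b_specific_snps(c1, c0, ratio = ratio))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("merged-group filter 2 is available and more permissive on sums", {
  c0 <- list(one_pos(c(30L, 0L, 0L, 0L, 0L, 0L), "ob1", "0B"),
             one_pos(c(34L, 0L, 0L, 0L, 0L, 0L), "ob2", "0B"))
  c1 <- list(one_pos(c(30L, 0L, 9L, 0L, 0L, 0L), "bb1", "1B"),
             one_pos(c(28L, 0L, 8L, 0L, 0L, 0L), "bb2", "1B"))
  # per-library mean 8.5 < 16 fails; merged sum 17 >= 16 passes
  expect_equal(nrow(call_b_specific_snps(c1, c0)), 0L)
  expect_equal(nrow(call_b_specific_snps(c1, c0, filter2 = "merged")), 1L)
})

test_that("sharing table equals brute-force membership enumeration", {
  set.seed(72)
  universe <- sprintf("ref:%d:%s", 1:60, sample(c("A", "C", "G", "T"), 60, TRUE))
  sets <- lapply(1:4, function(k) sample(universe, sample(10:40, 1)))
  names(sets) <- sprintf("v%d", 1:4)
  sh <- intersect_snps_across_variants(sets)
  # brute force over all membership vectors
  for (r in seq_len(nrow(sh$table))) {
    ss <- strsplit(sh$table$subset[r], ",")[[1]]
    inter <- Reduce(intersect, sets[ss])
    expect_equal(sh$table$n_intersection[r], length(inter))
    excl <- inter
    for (v in setdiff(names(sets), ss)) excl <- setdiff(excl, sets[[v]])
    expect_equal(sh$table$n_exclusive[r], length(excl))
  }
  # exclusive regions partition the union
  expect_equal(sum(sh$table$n_exclusive), sh$n_union)
  # per-variant totals
  expect_equal(unname(sh$totals), lengths(sets), ignore_attr = TRUE)
  # disjoint and identical edge cases
  dj <- intersect_snps_across_variants(list(a = c("r:1:A"), b = c("r:2:C")))
  expect_equal(dj$table$n_intersection[dj$table$subset == "a,b"], 0L)
  id <- intersect_snps_across_variants(list(a = universe, b = universe))
  expect_equal(id$table$n_intersection[id$table$subset == "a,b"], 60L)
})

test_that("RNA identical to the 0B consensus yields no expressed B-SNPs", {
  set.seed(73)
  L <- 40L
  ref <- sample(c("A", "C", "G", "T"), L, TRUE)
  clean <- function(lib, group) {
    m <- matrix(0L, L, 6)
    m[cbind(seq_len(L), match(ref, c("A", "C", "G", "T")))] <- 25L
    make_counts(m, ref, lib, group, assay = "mRNA")
  }
  r0 <- list(clean("r0a", "0B"), clean("r0b", "0B"))
  r1 <- list(clean("r1a", "1B"), clean("r1b", "1B"))
  gdna <- call_b_specific_snps(r1, r0)  # empty
  out <- call_expressed_b_snps(r1, r0, gdna)
  expect_equal(nrow(out$rna_calls), 0L)
  # with alt support in all 1B RNA libs, the gDNA SNP is annotated expressed
  r1b <- lapply(r1, function(m) { m$counts[5, "G"] <- 12L; m })
  gdna2 <- data.frame(ref_id = "ref", pos = 4L, ref = ref[5], alt = "G",
                      mean_alt_1b = 15, mean_total_0b = 25,
                      filter1_pass = TRUE, filter2_pass = TRUE)
  out2 <- call_expressed_b_snps(r1b, r0, gdna2)
  expect_true(out2$gdna_annotated$rna_supported)
  expect_equal(out2$gdna_annotated$rna_alt_mean_1b, 12)
})

test_that("SNP exports write valid TSV and VCF", {
  dir <- withr::local_tempdir()
  snps <- data.frame(ref_id = "gene", pos = c(4L, 9L), ref = c("A", "C"),
                     alt = c("G", "ins"), mean_alt_1b = c(15, 12),
                     mean_total_0b = c(30, 28),
                     filter1_pass = TRUE, filter2_pass = TRUE)
  tsv <- file.path(dir, "s.tsv"); vcf <- file.path(dir, "s.vcf")
  write_snp_tsv(snps, tsv)
  expect_equal(read.delim(tsv)$pos1, c(5L, 10L))
  write_snp_vcf(snps, vcf)
  v <- VariantAnnotation::readVcf(vcf)
  expect_equal(unname(BiocGenerics::start(SummarizedExperiment::rowRanges(v))),
               c(5L, 10L))
})
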