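hit_row <- function(read_id, start, end, strand = "+", read_length = 20000L) {
  data.frame(read_id = read_id, read_length = read_length, strand = strand,
             read_start = start, read_end = end, q_start = 0L,
             q_end = end - start, identity = 0.97, score = end - start,
             query_cover = 1)
}

test_that("flank extraction returns the bases beside the hit span", {
  set.seed(80)
  read <- rand_dna(20000)
  hits <- hit_row("lr1", 5000L, 6500L)
  fl <- extract_flanks(hits, c(lr1 = read), flank_len = 1000L)
  expect_equal(nrow(fl), 2L)
  expect_equal(fl$seq[fl$side == "left"], substring(read, 4001, 5000))
  expect_equal(fl$seq[fl$side == "right"], substring(read, 6501, 7500))
  expect_false(any(fl$truncated))
})

test_that("flanks truncate at read ends and never overlap the hit", {
  set.seed(81)
  read <- rand_dna(5000)
  hits <- hit_row("lr1", 300L, 1800L, read_length = 5000L)
  fl <- extract_flanks(hits, c(lr1 = read), flank_len = 1000L)
  left <- fl[fl$side == "left", ]
  expect_equal(left$length, 300L)
  expect_true(left$truncated)
  expect_equal(left$seq, substring(read, 1, 300))
  hitseq <- substring(read, 301, 1800)
  expect_false(grepl(fl$seq[1], hitseq, fixed = TRUE))
})

test_that("a tandem array yields exactly two array-external flanks", {
  set.seed(82)
  read <- rand_dna(12000)
  hits <- rbind(hit_row("lr1", 3000L, 4500L, read_length = 12000L),
                hit_row("lr1", 4550L, 6050L, read_length = 12000L),
                hit_row("lr1", 6100L, 7600L, read_length = 12000L))
  fl <- extract_flanks(hits, c(lr1 = read), flank_len = 1000L)
  expect_equal(nrow(fl), 2L)
  expect_equal(fl$seq[fl$side == "left"], substring(read, 2001, 3000))
  expect_equal(fl$seq[fl$side == "right"], substring(read, 7601, 8600))
})

test_that("minus-strand arrays orient flanks to the pseudogene-forward strand", {
  set.seed(83)
  read <- rand_dna(10000)
  hits <- hit_row("lr1", 4000L, 5500L, strand = "-", read_length = 10000L)
  fl <- extract_flanks(hits, c(lr1 = read), flank_len = 500L)
  rcomp <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  expect_equal(fl$seq[fl$side == "left"], rcomp(substring(read, 5501, 6000)))
  expect_equal(fl$seq[fl$side == "right"], rcomp(substring(read, 3501, 4000)))
})

test_that("tandem chaining follows the gap rule", {
  single <- hit_row("a", 5000L, 6500L)
  t1 <- detect_tandem(single)
  expect_equal(t1$n_copies, 1L)
  arr <- rbind(hit_row("a", 1000L, 2500L), hit_row("a", 2550L, 4050L),
               hit_row("a", 4100L, 5600L))
  t3 <- detect_tandem(arr)
  expect_equal(nrow(t3), 1L)
  expect_equal(t3$n_copies, 3L)
  expect_equal(attr(t3, "modal_copies"), 3L)
  far <- rbind(hit_row("a", 0L, 1500L), hit_row("a", 18000L, 19500L))
  t2 <- detect_tandem(far, max_gap = 2000L)
  expect_equal(t2$n_copies, c(1L, 1L))
  # strand switches break chains
  mix <- rbind(hit_row("a", 1000L, 2500L),
               hit_row("a", 2550L, 4050L, strand = "-"))
  expect_equal(nrow(detect_tandem(mix)), 2L)
})

test_that("identical flanks form one cluster; divergent loci separate", {
  set.seed(84)
  same <- data.frame(read_id = sprintf("r%d", 1:5), array = 1L,
                     side = "left", seq = rand_dna(1000),
                     length = 1000L, truncated = FALSE)
  cl <- cluster_flanks(same)
  expect_equal(cl$n_left, 1L)
  loci <- lapply(1:3, function(k) list(l = rand_dna(1000), r = rand_dna(1000)))
  fl <- do.call(rbind, lapply(1:3, function(k)
    do.call(rbind, lapply(1:4, function(rd)
      data.frame(read_id = sprintf("l%d_r%d", k, rd), array = 1L,
                 side = c("left", "right"),
                 seq = c(loci[[k]]$l, loci[[k]]$r),
                 length = 1000L, truncated = FALSE)))))
  cl3 <- cluster_flanks(fl)
  expect_equal(cl3$n_left, 3L)
  expect_equal(cl3$n_right, 3L)
  expect_equal(cl3$locus_count, 3L)
})

test_that("cluster count never increases when the link threshold is lowered", {
  set.seed(85)
  base <- rand_dna(800)
  noisy <- vapply(1:6, function(k) {
    chars <- strsplit(base, "")[[1]]
    flip <- sample(800, 60)
    for (p in flip) chars[p] <- sample(c("A", "C", "G", "T"), 1)
    paste(chars, collapse = "")
  }, character(1))
  fl <- data.frame(read_id = sprintf("r%d", 1:6), array = 1L, side = "left",
                   seq = noisy, length = 800L, truncated = FALSE)
  counts <- vapply(c(0.98, 0.92, 0.85, 0.7, 0.5), function(th)
    cluster_flanks(fl, link_identity = th)$n_left, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("arrangement labels combine locus count and modal copies", {
  cl1 <- structure(list(locus_count = 1L), class = "flank_clusters")
  cl70 <- structure(list(locus_count = 70L), class = "flank_clusters")
  arr3 <- detect_tandem(rbind(hit_row("a", 1000L, 2500L),
                              hit_row("a", 2550L, 4050L),
                              hit_row("a", 4100L, 5600L)))
  arr1 <- detect_tandem(hit_row("a", 5000L, 6500L))
  expect_equal(classify_arrangement(cl1, arr3)$class, "tandem")
  expect_equal(classify_arrangement(cl70, arr1)$class, "dispersed")
  expect_equal(classify_arrangement(cl1, arr1)$class, "single-locus")
  none <- detect_tandem(hit_row("x", 1L, 2L)[0, ])
  expect_equal(classify_arrangement(cl1, none)$class, "no-call")
})

test_that("generator arrangements are recovered from simulated long reads", {
  cfg <- simulation_config(n_b = 4L, arrangement = "dispersed",
                           long_read_n = 16L)
  ds <- simulate_bchrom_dataset(cfg, seed = 42, include = "long")
  hits <- scan_long_reads(ds$long_reads$reads, ds$b$retrocopy)
  expect_gt(nrow(hits), 0L)
  arrays <- detect_tandem(hits)
  fl <- extract_flanks(hits, ds$long_reads$reads)
  # flanks never contain retrocopy sequence (non-overlap with the hit span)
  core <- substring(ds$b$retrocopy, 200, 1000)
  expect_false(any(vapply(fl$seq[fl$length >= 900], function(s)
    grepl(core, s, fixed = TRUE), logical(1))))
  ar <- classify_arrangement(cluster_flanks(fl), arrays)
  expect_equal(ar$class, "dispersed")
  expect_equal(ar$locus_count, 4L)

  cfg2 <- simulation_config(n_b = 3L, arrangement = "tandem",
                            long_read_n = 12L)
  ds2 <- simulate_bchrom_dataset(cfg2, seed = 43, include = "long")
  hits2 <- scan_long_reads(ds2$long_reads$reads, ds2$b$retrocopy)
  a2 <- detect_tandem(hits2)
  ar2 <- classify_arrangement(cluster_flanks(
    extract_flanks(hits2, ds2$long_reads$reads)), a2)
  expect_equal(ar2$class, "tandem")
  expect_equal(attr(a2, "modal_copies"), 3L)
})
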