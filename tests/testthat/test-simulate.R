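test_that("the generator is a pure function of (config, seed)", {
  cfg <- simulation_config(n_exons = 5L, n_b = 2L, depth = 5,
                           libs_per_group = 1L, long_read_n = 4L,
                           rna_reads = 300L)
  d1 <- simulate_bchrom_dataset(cfg, seed = 9)
  d2 <- simulate_bchrom_dataset(cfg, seed = 9)
  expect_identical(d1$gene$sequence, d2$gene$sequence)
  expect_identical(d1$b$b_hap, d2$b$b_hap)
  expect_identical(d1$gdna[[1]]$reads, d2$gdna[[1]]$reads)
  expect_identical(d1$long_reads$reads, d2$long_reads$reads)
  expect_identical(d1$rna[[1]]$reads, d2$rna[[1]]$reads)
  expect_identical(d1$cq$cq, d2$cq$cq)
  d3 <- simulate_bchrom_dataset(cfg, seed = 10)
  expect_false(identical(d1$gene$sequence, d3$gene$sequence))
})

test_that("gene structure echoes the configuration", {
  cfg <- simulation_config(n_exons = 10L)
  g <- simulate_gene(cfg, seed = 3)
  expect_equal(n_exons(g), 10L)
  lens <- g$exons[, 2] - g$exons[, 1]
  expect_true(all(lens >= cfg$exon_len[1] & lens <= cfg$exon_len[2]))
  introns <- g$exons[-1, 1] - g$exons[-10, 2]
  expect_length(introns, 9L)
  expect_true(all(introns >= cfg$intron_len[1] & introns <= cfg$intron_len[2]))
  expect_error(simulation_config(bogus = 1), "unknown")
  expect_error(simulation_config(trunc_exons = c(8L, 20L)), "truncation")
})

test_that("realized GC content is within binomial tolerance of the target", {
  set.seed(30)
  s <- bretro:::random_dna(50000, 0.45)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / 50000
  expect_lt(abs(gc - 0.45), 0.02)
})

test_that("zero divergence embeds exact retrocopies; tandem counts match", {
  cfg <- simulation_config(n_exons = 6L, trunc_exons = c(3L, 6L),
                           b_divergence = 0, n_b = 3L, arrangement = "tandem")
  g <- simulate_gene(cfg, seed = 5)
  b <- simulate_b_haplotype(g, cfg, seed = 6)
  expect_equal(nrow(b$variants), 0L)
  spl <- spliced_sequence(g)
  expect_identical(b$retrocopy,
                   substring(spl, b$trunc_interval["start"] + 1L,
                             b$trunc_interval["end"]))
  hits <- gregexpr(b$retrocopy, b$b_hap, fixed = TRUE)[[1]]
  expect_length(hits, 3L)
  # locus table coordinates point at the copies
  for (k in seq_len(nrow(b$loci)))
    expect_identical(substring(b$b_hap, b$loci$start[k] + 1L, b$loci$end[k]),
                     b$retrocopy)
})

test_that("realized divergence matches the configured rate within 3 sigma", {
  cfg <- simulation_config(b_divergence = 0.01, n_b = 20L)
  g <- simulate_gene(cfg, seed = 7)
  b <- simulate_b_haplotype(g, cfg, seed = 8)
  L <- nchar(b$retrocopy)
  expected <- L * 0.01
  expect_lt(abs(nrow(b$variants) - expected), 3 * sqrt(L * 0.01 * 0.99) + 1)
  # every recorded variant differs from the gene at that position
  spl <- spliced_sequence(g)
  for (k in seq_len(nrow(b$variants))) {
    p <- b$variants$spliced_pos[k]
    expect_identical(substring(spl, p + 1L, p + 1L), b$variants$ref[k])
    expect_false(b$variants$alt[k] == b$variants$ref[k])
    expect_identical(substring(b$retrocopy, b$variants$retro_pos[k] + 1L,
                               b$variants$retro_pos[k] + 1L),
                     b$variants$alt[k])
  }
})

test_that("error-free short reads are exact template substrings at ~the configured depth", {
  cfg <- simulation_config(error_rate = 0, depth = 20, n_exons = 5L)
  g <- simulate_gene(cfg, seed = 11)
  lib <- simulate_short_reads(list(chrA = list(seq = g$sequence, weight = 2)),
                              cfg, seed = 12, "l1")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(lib$reads)))
  ok <- vapply(seq_along(lib$reads), function(k)
    grepl(lib$reads[[k]], g$sequence, fixed = TRUE) ||
      grepl(rc[[k]], g$sequence, fixed = TRUE), logical(1))
  expect_true(all(ok))
  realized <- sum(nchar(lib$reads)) / nchar(g$sequence)
  expect_lt(abs(realized - 20) / 20, 0.1)
})

test_that("1B libraries carry the (2 + n_B) : 2 depth contrast in expectation", {
  cfg <- simulation_config(n_exons = 6L, trunc_exons = c(3L, 6L), n_b = 3L,
                           depth = 25, error_rate = 0, b_divergence = 0)
  ds <- simulate_bchrom_dataset(cfg, seed = 13, include = "gdna")
  # pool the three 1B libraries to tame regional sampling noise
  d <- integer(nchar(ds$spliced))
  for (lib in ds$gdna[grepl("^1B", names(ds$gdna))]) {
    a <- align_reads(lib$reads, c(g = ds$spliced))
    d <- d + pileup_depth(a, nchar(ds$spliced))
  }
  tr <- ds$truth$trunc_interval
  # interior windows, clear of edge effects
  flank <- mean(d[60:(tr["start"] - 60)])
  inside <- mean(d[(tr["start"] + 60):(tr["end"] - 60)])
  expect_lt(abs(inside / flank - 2.5) / 2.5, 0.12)
})

test_that("long reads have the configured count and error-free reads are substrings", {
  cfg <- simulation_config(long_read_error = 0, long_read_n = 25L, n_b = 2L)
  g <- simulate_gene(cfg, seed = 14)
  b <- simulate_b_haplotype(g, cfg, seed = 15)
  lr <- simulate_long_reads(b$b_hap, cfg, seed = 16, loci = b$loci)
  expect_length(lr$reads, 25L)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(lr$reads)))
  ok <- vapply(seq_along(lr$reads), function(k)
    grepl(lr$reads[[k]], b$b_hap, fixed = TRUE) ||
      grepl(rc[[k]], b$b_hap, fixed = TRUE), logical(1))
  expect_true(all(ok))
})

test_that("RNA libraries scale the 1B target by the expression factor", {
  cfg <- simulation_config(expression_factor = 0.2, rna_reads = 4000L,
                           n_exons = 6L)
  ds <- simulate_bchrom_dataset(cfg, seed = 17, include = "rna")
  frac <- vapply(ds$rna, function(lib)
    mean(lib$truth$transcript == "gene"), numeric(1))
  grp <- vapply(ds$rna, `[[`, character(1), "group")
  Lg <- nchar(ds$spliced); Lr <- nchar(ds$ref_transcript)
  exp0 <- Lg / (Lg + Lr)
  exp1 <- 0.2 * Lg / (0.2 * Lg + Lr)
  expect_lt(max(abs(frac[grp == "0B"] - exp0)), 0.03)
  expect_lt(max(abs(frac[grp == "1B"] - exp1)), 0.03)
})

test_that("datasets write to standard formats and truth JSON round-trips", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_exons = 5L, n_b = 2L, depth = 4,
                           libs_per_group = 1L, long_read_n = 3L,
                           rna_reads = 200L)
  ds <- simulate_bchrom_dataset(cfg, seed = 18)
  write_bchrom_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "genome.fasta")))
  g2 <- load_gene_model(file.path(dir, "gene.gff3"),
                        file.path(dir, "genome.fasta"), "geneA")
  expect_equal(g2$exons, ds$gene$exons, ignore_attr = TRUE)
  fq <- read_fastq(file.path(dir, "0B_gdna1.fastq"))
  expect_identical(unname(fq), unname(ds$gdna[["0B_gdna1"]]$reads))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$n_b, 2L)
})
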