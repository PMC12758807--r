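make_gene_for_junctions <- function(seed = 50) {
  set.seed(seed)
  gene_model("g", "c", "+",
             rbind(c(0L, 200L), c(500L, 700L), c(1000L, 1200L)),
             sequence = rand_dna(1500))
}

test_that("a constructed junction-spanning read supports exactly its junction", {
  g <- make_gene_for_junctions()
  cat <- junction_catalog(g, arm_length = 100L)
  spl <- spliced_sequence(g)
  # last 50 bp of exon 2 + first 50 bp of exon 3 (boundary at 400)
  read <- c(jread = substring(spl, 351, 450))
  ev <- find_junction_spanning_reads(read, cat)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$i, 2L)
  expect_equal(ev$left_overhang, 50L)
  expect_equal(ev$right_overhang, 50L)
  # a read wholly inside one exon supports nothing
  inner <- c(e = substring(g$sequence, 21, 120))
  expect_equal(nrow(find_junction_spanning_reads(inner, cat)), 0L)
  # overhang larger than the arm is a configuration error
  expect_error(find_junction_spanning_reads(read, cat, min_overhang = 150L),
               "arm")
})

test_that("intron-containing genomes produce zero junction evidence", {
  for (s in 1:5) {
    cfg <- simulation_config(n_exons = 5L, intron_len = c(220L, 320L),
                             depth = 10, libs_per_group = 1L, n_b = 0L)
    gene <- simulate_gene(cfg, seed = 200 + s)
    lib <- simulate_short_reads(list(chrA = list(seq = gene$sequence,
                                                 weight = 2)),
                                cfg, seed = 300 + s, "ob")
    cat <- junction_catalog(gene, arm_length = cfg$read_length)
    ev <- find_junction_spanning_reads(lib$reads, cat)
    expect_equal(nrow(ev), 0L)
  }
})

test_that("junction table labels reproduce the all/none/list notation", {
  cat <- data.frame(gene_id = "g", i = 1:9, j = 2:10,
                    id = sprintf("j%d", 1:9), sequence = "",
                    boundary_offset = 100L, arm_length = 100L,
                    spliced_pos = (1:9) * 200L)
  region <- data.frame(ref_id = "r", start = 1350L, end = 2050L)
  # in-region junctions (strictly interior with 25 bp margin): 7-8, 8-9, 9-10
  ev_all <- data.frame(i = c(7L, 8L, 9L), j = c(8L, 9L, 10L))
  expect_equal(summarize_junction_table(ev_all, cat, region)$label, "all")
  ev_some <- data.frame(i = c(7L, 8L), j = c(8L, 9L))
  expect_equal(summarize_junction_table(ev_some, cat, region)$label,
               "7-8, 8-9")
  ev_none <- data.frame(i = integer(0), j = integer(0))
  expect_equal(summarize_junction_table(ev_none, cat, region)$label, "none")
  # support outside the region does not change "none"
  ev_out <- data.frame(i = 1L, j = 2L)
  expect_equal(summarize_junction_table(ev_out, cat, region)$label, "none")
})

test_that("in-silico PCR predicts product size end minus start", {
  set.seed(51)
  tmpl <- rand_dna(80)
  ps <- primer_set(data.frame(
    assay_id = "a", role = c("forward", "reverse_exonic"),
    name = c("F", "R"),
    sequence = c(substring(tmpl, 1, 20),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(substring(tmpl, 61, 80)))))))
  amp <- insilico_pcr(tmpl, ps)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$size, 80L)
  expect_equal(amp$end - amp$start, amp$size)
})

test_that("the 3' anchor rule vetoes mismatched primer ends", {
  set.seed(52)
  tmpl <- rand_dna(100)
  fw <- substring(tmpl, 11, 30)
  rv <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substring(tmpl, 71, 90))))
  ps <- primer_set(data.frame(assay_id = "a",
                              role = c("forward", "reverse_exonic"),
                              name = c("F", "R"), sequence = c(fw, rv)))
  expect_equal(nrow(insilico_pcr(tmpl, ps)), 1L)
  # mutate the template base under the forward primer's 3' end
  t2 <- tmpl
  b <- substr(t2, 30, 30)
  substr(t2, 30, 30) <- setdiff(c("A", "C", "G", "T"), b)[1]
  expect_equal(nrow(insilico_pcr(t2, ps)), 0L)
  # but a mismatch away from the 3' end is tolerated (<= 2 allowed)
  t3 <- tmpl
  b <- substr(t3, 12, 12)
  substr(t3, 12, 12) <- setdiff(c("A", "C", "G", "T"), b)[1]
  expect_equal(nrow(insilico_pcr(t3, ps)), 1L)
})

test_that("junction-spanning primers amplify only intronless templates", {
  cfg <- simulation_config(n_exons = 6L, trunc_exons = c(3L, 6L), n_b = 2L)
  gene <- simulate_gene(cfg, seed = 60)
  b <- simulate_b_haplotype(gene, cfg, seed = 61)
  ps <- simulate_primer_set(gene, junction = 4L)
  amp_genomic <- insilico_pcr(gene$sequence, ps)
  amp_spliced <- insilico_pcr(spliced_sequence(gene), ps)
  expect_equal(sort(unique(amp_genomic$reverse_role)), "reverse_exonic")
  expect_setequal(unique(amp_spliced$reverse_role),
                  c("reverse_exonic", "reverse_junction"))
  # B haplotype carries the junction product n_b times
  amp_b <- insilico_pcr(b$b_hap, ps)
  expect_equal(sum(amp_b$reverse_role == "reverse_junction"), 2L)
})

test_that("amplicon predictions are invariant under template reverse complement", {
  cfg <- simulation_config(n_exons = 6L)
  gene <- simulate_gene(cfg, seed = 62)
  ps <- simulate_primer_set(gene, junction = 3L)
  a1 <- insilico_pcr(gene$sequence, ps)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(gene$sequence)))
  a2 <- insilico_pcr(rc, ps)
  expect_equal(sort(a1$size), sort(a2$size))
  L <- nchar(gene$sequence)
  expect_setequal(paste(L - a1$end, L - a1$start), paste(a2$start, a2$end))
})

test_that("multiplex genotyping mirrors the gel logic", {
  cfg <- simulation_config(n_exons = 6L, trunc_exons = c(3L, 6L), n_b = 2L)
  gene <- simulate_gene(cfg, seed = 63)
  b <- simulate_b_haplotype(gene, cfg, seed = 64)
  ps <- simulate_primer_set(gene, junction = 4L)
  calls <- genotype_b(list(s_0b = c(gene$sequence),
                           s_1b = c(gene$sequence, b$b_hap),
                           s_fail = c(rand_dna(500))), ps)
  expect_equal(calls$call, c("0B", "1B", "fail"))
})
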