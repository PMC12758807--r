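#' Run the full 0B-versus-1B analysis on a dataset
#'
#' Executes the stages in dependency order on an in-memory
#' `bchrom_dataset` (or any list with the same components): map gDNA reads
#' to the spliced gene sequence; call the amplified (high-coverage B)
#' region and estimate copy number; collect exon-exon junction evidence
#' per group; call B-specific SNPs; scan long reads with the called
#' region's spliced sequence as query and classify the arrangement;
#' contrast RNA coverage and analyze the qPCR table. Stages whose inputs
#' are absent are skipped (long reads absent leaves arrangement
#' `"no-call"`); the report records seeds and parameters, and identical
#' inputs yield identical reports.
#'
#' @param dataset A [simulate_bchrom_dataset()] result or equivalently
#'   shaped list.
#' @param params [mapping_params()] for short-read mapping.
#' @param ratio_threshold,smooth_window,min_length Region-calling knobs,
#'   see [detect_amplified_region()].
#' @param a_copies A-chromosome copy baseline for the copy-number
#'   estimator.
#' @param min_overhang,junction_identity Junction-evidence knobs.
#' @param link_identity Flank-clustering threshold for long reads.
#' @param n_boot,seed Bootstrap settings for the qPCR stage.
#' @return A `bchrom_report` object.
#' @export
run_full_analysis <- function(dataset, params = mapping_params(),
                              ratio_threshold = 1.5, smooth_window = 25L,
                              min_length = 100L, a_copies = 2L,
                              min_overhang = 15L, junction_identity = 0.90,
                              link_identity = 0.85, n_boot = 5000L,
                              seed = 1L) {
  gene <- dataset$gene
  spliced <- dataset$spliced %||% spliced_sequence(gene)
  refs <- c(gene_spliced = spliced)
  L <- nchar(spliced)
  report <- list(gene_id = gene$gene_id, spliced_length = L)

  # --- gDNA mapping and coverage -------------------------------------
  profiles <- list(); aln_by_lib <- list()
  for (lib in dataset$gdna) {
    a <- align_reads(lib$reads, refs, params, library_id = lib$library_id,
                     group = lib$group)
    aln_by_lib[[lib$library_id]] <- a
    profiles[[lib$library_id]] <-
      coverage_profile(a, "gene_spliced", L, lib$library_id, lib$group, "gDNA")
  }
  g0 <- profiles[vapply(profiles, function(p) p$group == "0B", logical(1))]
  g1 <- profiles[vapply(profiles, function(p) p$group == "1B", logical(1))]
  region <- call_b_region(g0, g1, ratio_threshold, smooth_window,
                          min_length, a_copies)
  report$amplified_region <- region$calls
  report$copy_number <- region$copy_number
  report$control_interval <- region$control_interval

  # --- junction evidence ---------------------------------------------
  catalog <- junction_catalog(gene, arm_length = nchar(dataset$gdna[[1]]$reads[1]))
  jparams <- params
  jev <- list(); jtab <- list()
  for (lib in dataset$gdna) {
    jev[[lib$library_id]] <- find_junction_spanning_reads(
      dataset$gdna[[lib$library_id]]$reads, catalog,
      min_overhang = min_overhang, min_identity = junction_identity,
      params = jparams, library_id = lib$library_id, group = lib$group,
      region = region$calls)
  }
  all_ev <- do.call(rbind, jev)
  for (g in c("0B", "1B")) {
    ev <- all_ev[all_ev$group == g, , drop = FALSE]
    jtab[[g]] <- summarize_junction_table(ev, catalog, region$calls)
  }
  report$junction_evidence <- all_ev
  report$junction_table <- data.frame(
    group = names(jtab),
    label = vapply(jtab, `[[`, character(1), "label"))
  report$junction_detail <- jtab

  # --- B-specific SNPs -------------------------------------------------
  mk_counts <- function(libs) lapply(libs, function(lib)
    count_nucleotides(aln_by_lib[[lib$library_id]], spliced, "gene_spliced",
                      lib$library_id, lib$group, "gDNA"))
  is0 <- vapply(dataset$gdna, function(l) l$group == "0B", logical(1))
  counts0 <- mk_counts(dataset$gdna[is0])
  counts1 <- mk_counts(dataset$gdna[!is0])
  report$snps <- call_b_specific_snps(counts1, counts0)

  # --- long reads ------------------------------------------------------
  if (!is.null(dataset$long_reads) && nrow(report$amplified_region) > 0L) {
    main <- report$amplified_region[which.max(report$amplified_region$length), ]
    query <- substring(spliced, main$start + 1L, main$end)
    hits <- scan_long_reads(dataset$long_reads$reads, query)
    arrays <- detect_tandem(hits)
    flanks <- extract_flanks(hits, dataset$long_reads$reads)
    clusters <- cluster_flanks(flanks, link_identity = link_identity)
    report$long_read_hits <- hits
    report$tandem_calls <- arrays
    report$flank_clusters <- clusters
    report$arrangement <- classify_arrangement(clusters, arrays)
  } else {
    report$arrangement <- structure(
      list(class = "no-call", locus_count = 0L, modal_copies = NA_integer_,
           n_reads = 0L), class = "arrangement_call")
  }

  # --- expression ------------------------------------------------------
  if (!is.null(dataset$rna)) {
    rrefs <- c(gene_spliced = spliced, reference = dataset$ref_transcript)
    rprof <- list()
    for (lib in dataset$rna) {
      a <- align_reads(lib$reads, rrefs, params, library_id = lib$library_id,
                       group = lib$group)
      rprof[[paste0(lib$library_id, "_g")]] <-
        coverage_profile(a, "gene_spliced", L, lib$library_id, lib$group, "mRNA")
      rprof[[paste0(lib$library_id, "_r")]] <-
        coverage_profile(a, "reference", nchar(dataset$ref_transcript),
                         lib$library_id, lib$group, "mRNA")
    }
    rprof <- normalize_profiles(rprof,
                                c(0L, nchar(dataset$ref_transcript)),
                                control_ref = "reference")
    on_gene <- vapply(rprof, function(p) p$ref_id == "gene_spliced", logical(1))
    r0 <- rprof[on_gene & vapply(rprof, function(p) p$group == "0B", logical(1))]
    r1 <- rprof[on_gene & vapply(rprof, function(p) p$group == "1B", logical(1))]
    report$expression_ratio <- expression_ratio_profile(r0, r1)
  }
  if (!is.null(dataset$cq)) {
    report$qpcr <- rtqpcr_analysis(dataset$cq, "target", "reference",
                                   n_boot = n_boot, seed = seed)
  }

  report$provenance <- list(
    package_version = as.character(utils::packageVersion("bretro")),
    seed = seed,
    params = unclass(params),
    ratio_threshold = ratio_threshold, smooth_window = smooth_window,
    min_length = min_length, a_copies = a_copies,
    min_overhang = min_overhang, junction_identity = junction_identity,
    link_identity = link_identity, n_boot = n_boot)
  class(report) <- "bchrom_report"
  report
}

#' @export
print.bchrom_report <- function(x, ...) {
  cat(sprintf("<bchrom_report> gene %s (spliced %d bp)\n",
              x$gene_id, x$spliced_length))
  if (nrow(x$amplified_region) > 0L) {
    m <- x$amplified_region[which.max(x$amplified_region$length), ]
    cat(sprintf("  amplified region: [%d, %d) mean ratio %.2f\n",
                m$start, m$end, m$mean_ratio))
    if (!is.null(x$copy_number))
      cat(sprintf("  estimated B copy number: %.2f\n", x$copy_number$n_b))
  } else cat("  amplified region: none called\n")
  if (!is.null(x$junction_table)) {
    for (k in seq_len(nrow(x$junction_table)))
      cat(sprintf("  junctions (%s): %s\n", x$junction_table$group[k],
                  x$junction_table$label[k]))
  }
  cat(sprintf("  B-specific SNPs: %d\n", nrow(x$snps)))
  cat(sprintf("  arrangement: %s\n", x$arrangement$class))
  if (!is.null(x$expression_ratio))
    cat(sprintf("  RNA 1B/0B mean coverage ratio: %.3f\n",
                x$expression_ratio$mean_ratio))
  if (!is.null(x$qpcr))
    cat(sprintf("  qPCR fold change 0B/1B: %.2f (effect %.3f, CI [%.3f, %.3f])\n",
                x$qpcr$fc, x$qpcr$effect$effect, x$qpcr$effect$ci[1],
                x$qpcr$effect$ci[2]))
  invisible(x)
}

#' Export a report as JSON
#'
#' @param report A `bchrom_report`.
#' @param path Output path.
#' @export
report_to_json <- function(report, path) {
  obj <- list(
    gene_id = report$gene_id,
    spliced_length = report$spliced_length,
    amplified_region = as.data.frame(report$amplified_region),
    copy_number = if (!is.null(report$copy_number))
      list(n_b = report$copy_number$n_b, r0 = report$copy_number$r0,
           r1 = report$copy_number$r1,
           per_library = as.list(report$copy_number$per_library)),
    junction_table = report$junction_table,
    n_snps = nrow(report$snps),
    snps = as.data.frame(report$snps),
    arrangement = unclass(report$arrangement),
    expression_ratio = report$expression_ratio$mean_ratio,
    qpcr = if (!is.null(report$qpcr))
      list(fc = report$qpcr$fc, effect = report$qpcr$effect$effect,
           ci = report$qpcr$effect$ci),
    provenance = report$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Genotype samples for B-chromosome carriage by in-silico multiplex PCR
#'
#' The computational twin of the multiplex genotyping gel: a sample is
#' called `1B` when both the control amplicon (exonic reverse primer; A
#' and B copies) and the junction amplicon (junction-spanning reverse
#' primer; intronless B copies only) are predicted, `0B` when only the
#' control amplicon is, and `fail` when not even the control amplicon
#' amplifies.
#'
#' @param samples Named list; each element is a character vector of the
#'   sample's template sequences (e.g. A chromosome, plus the B haplotype
#'   for carriers), or an `amplicon_predictions` data frame already
#'   computed for the sample.
#' @param primers A `primer_set` with the three multiplex roles.
#' @param ... Passed to [insilico_pcr()].
#' @return Data frame with `sample` and `call`.
#' @export
genotype_b <- function(samples, primers, ...) {
  calls <- vapply(names(samples), function(sm) {
    x <- samples[[sm]]
    amp <- if (is.data.frame(x)) x else {
      do.call(rbind, lapply(seq_along(x), function(k)
        insilico_pcr(x[[k]], primers, template_id = sprintf("%s_t%d", sm, k),
                     ...)))
    }
    has_control <- !is.null(amp) && any(amp$reverse_role == "reverse_exonic")
    has_junction <- !is.null(amp) && any(amp$reverse_role == "reverse_junction")
    if (!has_control) "fail" else if (has_junction) "1B" else "0B"
  }, character(1))
  data.frame(sample = names(samples), call = unname(calls))
}

#' Commands for the non-desk-scale external checks
#'
#' The headline numbers of the original fish study (qPCR fold changes,
#' B-specific SNP counts per variant, long-read counts per pseudogene)
#' derive from its sequencing libraries and supplementary tables, which
#' are not shipped here. This function returns, for each published value,
#' the exact command to reproduce the comparison once the external inputs
#' (the SRA long-read accession and the supplementary XLSX tables) are
#' available locally. Nothing is downloaded.
#'
#' @return Data frame with `check`, `expected`, `inputs`, `command`.
#' @export
external_data_checks <- function() {
  data.frame(
    check = c("fold_change_sbno2", "fold_change_simc1",
              "bsnp_count_sbno2_ppar", "bsnp_count_simc1_ppar",
              "long_reads_sbno2", "long_reads_simc1"),
    expected = c(25.4, 18.2, 24, 33, 169, 5),
    inputs = c("supplementary Cq table (XLSX -> TSV: sample_id, group, gene, rep, cq)",
               "supplementary Cq table (XLSX -> TSV)",
               "0B/1B gDNA FASTQ libraries + sbno2 mRNA FASTA",
               "0B/1B gDNA FASTQ libraries + simc1 mRNA FASTA",
               "SRA SRR11678219 (PacBio) + sbno2-B sequence",
               "SRA SRR11678219 (PacBio) + simc1-B sequence"),
    command = c(
      "rtqpcr_analysis(read_cq_table('sbno2_cq.tsv'), 'sbno2', 'hprt1')$fc",
      "rtqpcr_analysis(read_cq_table('simc1_cq.tsv'), 'simc1', 'hprt1')$fc",
      "nrow(call_b_specific_snps(<1B count matrices>, <0B count matrices>))",
      "nrow(call_b_specific_snps(<1B count matrices>, <0B count matrices>))",
      "length(unique(scan_long_reads(read_fasta('SRR11678219.fasta'), <sbno2-B>)$read_id))",
      "length(unique(scan_long_reads(read_fasta('SRR11678219.fasta'), <simc1-B>)$read_id))"))
}
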