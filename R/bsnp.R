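ALLELES <- c("A", "C", "G", "T", "ins", "del")

#' Per-position nucleotide counts of one library
#'
#' Walks every aligned column of the alignments: match/mismatch columns
#' increment the matching base cell, read deletions increment `del`, and
#' insertions are attributed to the reference position left of the
#' insertion point. This matrix of A/C/G/T/ins/del counts per position is
#' the substrate of the B-specific SNP caller.
#'
#' @param alignments An `alignment_set` on a single reference.
#' @param reference Reference sequence (plain character).
#' @param ref_id Reference name (records on other references are dropped).
#' @param library_id,group,assay Labels.
#' @return A `ncount_matrix`: `counts` (L x 6), `depth`, `ref` (per-position
#'   reference base), labels.
#' @export
count_nucleotides <- function(alignments, reference, ref_id,
                              library_id, group = c("0B", "1B"),
                              assay = c("gDNA", "mRNA", "lncRNA")) {
  group <- match.arg(group); assay <- match.arg(assay)
  L <- nchar(reference)
  a <- alignments[alignments$ref_id == ref_id, , drop = FALSE]
  p <- if (nrow(a) > 0L)
    cpp_pileup(L, a$ref_start, a$read_start, a$cigar, a$seq)
  else list(depth = integer(L), counts = matrix(0L, L, 6))
  colnames(p$counts) <- ALLELES
  structure(list(ref_id = ref_id, library_id = library_id, group = group,
                 assay = assay, counts = p$counts, depth = p$depth,
                 ref = strsplit(toupper(reference), "")[[1]]),
            class = "ncount_matrix")
}

#' @export
print.ncount_matrix <- function(x, ...) {
  cat(sprintf("<ncount_matrix> %s | %s (%s, %s): %d positions, total %d counted bases\n",
              x$library_id, x$ref_id, x$group, x$assay, nrow(x$counts),
              sum(x$counts[, 1:4])))
  invisible(x)
}

#' Merge per-library count matrices into a group matrix
#'
#' Cell-wise sums over libraries of the same group (e.g. all 1B gDNA
#' libraries); the per-library inputs are preserved in `$libraries` so
#' that the per-library filter of the SNP caller remains applicable.
#'
#' @param matrices List of `ncount_matrix` objects on the same reference.
#' @return A merged `ncount_matrix` with `library_id = "merged"`.
#' @export
merge_group_counts <- function(matrices) {
  if (length(matrices) == 0L) stopf("nothing to merge")
  ref_ids <- unique(vapply(matrices, `[[`, character(1), "ref_id"))
  lens <- unique(vapply(matrices, function(m) nrow(m$counts), integer(1)))
  if (length(ref_ids) != 1L || length(lens) != 1L)
    stopf("count matrices disagree on reference")
  m <- matrices[[1]]
  out <- structure(list(
    ref_id = m$ref_id, library_id = "merged", group = m$group,
    assay = m$assay,
    counts = Reduce(`+`, lapply(matrices, `[[`, "counts")),
    depth = Reduce(`+`, lapply(matrices, `[[`, "depth")),
    ref = m$ref), class = "ncount_matrix")
  out$libraries <- matrices
  out
}

# occurrence of reads at a position: aligned base columns plus spanning
# deletions (a read deleting the base still covers the locus)
total_occurrence <- function(m) m$depth + m$counts[, "del"]

#' Call B-specific SNPs with the two-filter procedure
#'
#' For every position and every non-reference allele (the four bases plus
#' insertion and deletion): \strong{filter 1} requires the alternative
#' allele to occur (count at least `min_alt_occurrence`) in \emph{every} 1B
#' library; \strong{filter 2} requires the allele's depth to be consistent
#' with at least one gene copy on the B chromosome — with two copies on the
#' A chromosomes, one B copy contributes about half the 0B depth, so the
#' mean per-library 1B alternative count must be at least `ratio` (default
#' 1/2) times the mean per-library 0B total occurrence at the position. A
#' SNP is reported only when both filters pass \emph{and} the allele is
#' absent (count below `min_alt_occurrence`) from every 0B library, making
#' the call exclusive to the B-carrying group.
#'
#' `filter2 = "merged"` applies the second filter on merged-group counts
#' instead (summed 1B alternative count versus the 0B per-library mean),
#' the literal reading of a merged-BAM workflow.
#'
#' @param counts_1b,counts_0b Lists of per-library `ncount_matrix` objects.
#' @param min_alt_occurrence Occurrence threshold for filter 1 and for the
#'   0B exclusivity clause (default 1).
#' @param ratio Filter-2 multiplier of the 0B mean (default 0.5).
#' @param filter2 `"per_library"` (default) or `"merged"`.
#' @return A `b_snp_calls` data frame with one row per reported SNP:
#'   position (0-based), ref and alt alleles, per-1B-library alt counts,
#'   `mean_alt_1b`, `mean_total_0b` and both filter flags (all `TRUE` by
#'   construction). Positions with zero 0B coverage are skipped; their
#'   count is in `attr(x, "skipped_zero_0b")`.
#' @export
call_b_specific_snps <- function(counts_1b, counts_0b,
                                 min_alt_occurrence = 1L, ratio = 0.5,
                                 filter2 = c("per_library", "merged")) {
  filter2 <- match.arg(filter2)
  if (length(counts_1b) < 1L || length(counts_0b) < 1L)
    stopf("need at least one library per group")
  ref <- counts_1b[[1]]$ref
  L <- length(ref)
  tot0 <- matrix(vapply(counts_0b, total_occurrence, numeric(L)), nrow = L)
  m0 <- rowMeans(tot0)
  skipped <- sum(m0 == 0)
  rows <- list()
  for (al in ALLELES) {
    not_ref <- if (al %in% c("ins", "del")) rep(TRUE, L) else ref != al
    c1 <- matrix(vapply(counts_1b, function(m) m$counts[, al], numeric(L)),
                 nrow = L)
    c0 <- matrix(vapply(counts_0b, function(m) m$counts[, al], numeric(L)),
                 nrow = L)
    f1 <- rowSums(c1 >= min_alt_occurrence) == length(counts_1b)
    excl <- rowSums(c0 >= min_alt_occurrence) == 0L
    mean_alt <- rowMeans(c1)
    f2 <- if (filter2 == "per_library") mean_alt >= ratio * m0
          else rowSums(c1) >= ratio * m0
    hit <- which(not_ref & f1 & excl & f2 & m0 > 0)
    if (length(hit)) {
      alt_counts <- c1[hit, , drop = FALSE]
      colnames(alt_counts) <- vapply(counts_1b, `[[`, character(1), "library_id")
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(ref_id = counts_1b[[1]]$ref_id, pos = hit - 1L,
                   ref = ref[hit], alt = al,
                   mean_alt_1b = mean_alt[hit], mean_total_0b = m0[hit],
                   filter1_pass = TRUE, filter2_pass = TRUE),
        as.data.frame(alt_counts))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ref_id = character(0), pos = integer(0), ref = character(0),
               alt = character(0), mean_alt_1b = numeric(0),
               mean_total_0b = numeric(0), filter1_pass = logical(0),
               filter2_pass = logical(0))
  out <- out[order(out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("b_snp_calls", "data.frame")
  attr(out, "skipped_zero_0b") <- skipped
  out
}

snp_keys <- function(snps) {
  if (nrow(snps) == 0L) return(character(0))
  sprintf("%s:%d:%s", snps$ref_id, snps$pos, snps$alt)
}

#' Cross-variant SNP sharing table
#'
#' Exact set intersections of B-specific SNP calls across B-chromosome
#' variants, keyed by (reference, position, alt allele): for every
#' non-empty subset of variants the table reports the size of the
#' intersection of those call sets and the number of SNPs found in exactly
#' that subset (the Venn-diagram region counts). Exclusive-region counts
#' over all subsets sum to the union; per-variant totals are included.
#'
#' @param snp_sets Named list of `b_snp_calls` data frames (or plain
#'   character key vectors), one per B variant.
#' @return A `snp_sharing` list: `table` (subset, n_intersection,
#'   n_exclusive), `totals` per variant, and the union size.
#' @export
intersect_snps_across_variants <- function(snp_sets) {
  if (is.null(names(snp_sets)) || any(!nzchar(names(snp_sets))))
    stopf("snp_sets must be a named list")
  keysets <- lapply(snp_sets, function(s)
    if (is.character(s)) unique(s) else unique(snp_keys(s)))
  vars <- names(keysets)
  universe <- unique(unlist(keysets))
  memb <- vapply(keysets, function(k) universe %in% k,
                 logical(length(universe)))
  memb <- matrix(memb, nrow = length(universe),
                 dimnames = list(NULL, vars))
  nv <- length(vars)
  subsets <- lapply(seq_len(2^nv - 1L), function(code)
    vars[bitwAnd(code, 2^(seq_len(nv) - 1L)) > 0L])
  tab <- do.call(rbind, lapply(subsets, function(ss) {
    inside <- memb[, ss, drop = FALSE]
    outside <- memb[, setdiff(vars, ss), drop = FALSE]
    data.frame(subset = paste(ss, collapse = ","),
               n_variants = length(ss),
               n_intersection = sum(rowSums(inside) == length(ss)),
               n_exclusive = sum(rowSums(inside) == length(ss) &
                                   rowSums(outside) == 0L))
  }))
  structure(list(table = tab,
                 totals = vapply(keysets, length, integer(1)),
                 n_union = length(universe)),
            class = "snp_sharing")
}

#' @export
print.snp_sharing <- function(x, ...) {
  cat(sprintf("<snp_sharing> %d variants, union %d SNPs\n",
              length(x$totals), x$n_union))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' B-specific SNP calling on RNA, annotated against gDNA calls
#'
#' Runs [call_b_specific_snps()] on RNA count matrices, then annotates the
#' supplied gDNA B-SNP list with RNA alternative-allele support: a gDNA
#' B-SNP whose alt allele appears in every 1B RNA library and in no 0B RNA
#' library is evidence that the B-chromosome copies are transcribed.
#'
#' @param rna_1b,rna_0b Lists of RNA `ncount_matrix` objects per group.
#' @param gdna_snps A `b_snp_calls` data frame from gDNA.
#' @param ... Passed to [call_b_specific_snps()].
#' @return List with `rna_calls` (a `b_snp_calls`) and `gdna_annotated`
#'   (the gDNA calls plus `rna_alt_mean_1b` and `rna_supported`).
#' @export
call_expressed_b_snps <- function(rna_1b, rna_0b, gdna_snps,
                                  min_alt_occurrence = 1L, ...) {
  rna_calls <- call_b_specific_snps(rna_1b, rna_0b,
                                    min_alt_occurrence = min_alt_occurrence, ...)
  g <- gdna_snps
  if (nrow(g) > 0L) {
    g$rna_alt_mean_1b <- vapply(seq_len(nrow(g)), function(k) {
      mean(vapply(rna_1b, function(m) m$counts[g$pos[k] + 1L, g$alt[k]],
                  numeric(1)))
    }, numeric(1))
    in_all_1b <- vapply(seq_len(nrow(g)), function(k)
      all(vapply(rna_1b, function(m)
        m$counts[g$pos[k] + 1L, g$alt[k]] >= min_alt_occurrence, logical(1))),
      logical(1))
    in_no_0b <- vapply(seq_len(nrow(g)), function(k)
      all(vapply(rna_0b, function(m)
        m$counts[g$pos[k] + 1L, g$alt[k]] < min_alt_occurrence, logical(1))),
      logical(1))
    g$rna_supported <- in_all_1b & in_no_0b
  } else {
    g$rna_alt_mean_1b <- numeric(0)
    g$rna_supported <- logical(0)
  }
  list(rna_calls = rna_calls, gdna_annotated = g)
}

#' Export SNP calls as TSV or minimal VCF 4.2
#'
#' The TSV carries the full per-library counts; the VCF uses 1-based `POS`
#' and symbolic `<INS>`/`<DEL>` alleles for indel calls (pileup counts do
#' not retain inserted sequences).
#'
#' @param snps A `b_snp_calls` data frame.
#' @param path Output path.
#' @export
write_snp_tsv <- function(snps, path) {
  df <- as.data.frame(snps)
  df$pos1 <- df$pos + 1L
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_tsv
#' @export
write_snp_vcf <- function(snps, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=bretro",
           "##ALT=<ID=INS,Description=\"Insertion relative to the reference\">",
           "##ALT=<ID=DEL,Description=\"Deletion relative to the reference\">",
           "##INFO=<ID=MA1B,Number=1,Type=Float,Description=\"Mean 1B alt count per library\">",
           "##INFO=<ID=MT0B,Number=1,Type=Float,Description=\"Mean 0B total count per library\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(snps) > 0L) {
    alt <- ifelse(snps$alt == "ins", "<INS>",
                  ifelse(snps$alt == "del", "<DEL>", snps$alt))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tMA1B=%.3f;MT0B=%.3f",
                    snps$ref_id, snps$pos + 1L, snps$ref, alt,
                    snps$mean_alt_1b, snps$mean_total_0b)
    writeLines(c(hdr, body), path)
  } else writeLines(hdr, path)
  invisible(path)
}
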