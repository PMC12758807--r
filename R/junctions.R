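#' Find genomic reads spanning exon-exon junctions
#'
#' Aligns reads against a junction reference catalog (built by
#' [junction_catalog()]); a read supports junction (i, i+1) when it aligns
#' to that junction reference with identity at least `min_identity`
#' (default 0.90, stricter than the 0.80 mapping floor, to suppress
#' mismatch-driven artifacts near the boundary) and its alignment covers at
#' least `min_overhang` bases of each exon arm. The identity threshold is
#' applied to the whole alignment \emph{and} to each side of the boundary
#' separately, so reads from an intron-containing genome cannot qualify: the
#' intron interrupts the match at the boundary, and a chance low-quality
#' extension into the other arm is not rescued by a long perfect arm.
#'
#' @param reads Named character vector of gDNA reads, or an existing
#'   `alignment_set` on the catalog (then `params` is ignored).
#' @param catalog A [junction_catalog()] data frame.
#' @param min_overhang Minimum aligned bases on each side of the boundary.
#' @param min_identity Minimum alignment identity for junction support.
#' @param params [mapping_params()] used when `reads` are raw sequences.
#' @param library_id,group Labels for raw-read input.
#' @param region Optional amplified-region call (`data.frame` with
#'   `start`/`end` in spliced coordinates) used to set
#'   `within_amplified_region` by the junction's boundary position.
#' @param edge_margin Bases a boundary must sit inside the region to count
#'   as within it; region edges are only resolved to the smoothing window
#'   of the caller, so the default matches its 25-bp window.
#' @return A `junction_evidence` data frame, one row per supporting read:
#'   gene, junction indices, read id, overhangs, identity, region flag.
#' @export
find_junction_spanning_reads <- function(reads, catalog, min_overhang = 15L,
                                         min_identity = 0.90,
                                         params = mapping_params(),
                                         library_id = NA_character_,
                                         group = NA_character_,
                                         region = NULL, edge_margin = 25L) {
  if (nrow(catalog) == 0L) return(empty_junction_evidence())
  if (min_overhang > min(catalog$arm_length))
    stopf("min_overhang exceeds the catalog arm length")
  if (is.data.frame(reads)) {
    aln <- reads
  } else {
    refs <- setNames(catalog$sequence, catalog$id)
    aln <- align_reads(reads, refs, params, library_id = library_id,
                       group = group, keep = "per_ref")
  }
  if (nrow(aln) == 0L) return(empty_junction_evidence())
  m <- match(aln$ref_id, catalog$id)
  bo <- catalog$boundary_offset[m]
  left <- bo - aln$ref_start
  right <- aln$ref_end - bo
  # identity is enforced on each side of the boundary separately: a long
  # perfect arm must not subsidize a low-quality chance overhang into the
  # other exon (the failure mode of intron-containing reads)
  side_id <- t(vapply(seq_len(nrow(aln)), function(k) {
    if (is.na(m[k])) return(c(0, 0))
    side_identities(aln$cigar[k], aln$ref_start[k], bo[k])
  }, numeric(2)))
  keep <- !is.na(m) & left >= min_overhang & right >= min_overhang &
    aln$identity >= min_identity &
    side_id[, 1] >= min_identity & side_id[, 2] >= min_identity
  aln <- aln[keep, , drop = FALSE]
  m <- m[keep]
  if (nrow(aln) == 0L) return(empty_junction_evidence())
  out <- data.frame(
    gene_id = catalog$gene_id[m], i = catalog$i[m], j = catalog$j[m],
    junction = sprintf("%d-%d", catalog$i[m], catalog$j[m]),
    spliced_pos = catalog$spliced_pos[m],
    read_id = aln$read_id, library_id = aln$library_id, group = aln$group,
    left_overhang = left[keep], right_overhang = right[keep],
    identity = aln$identity,
    within_amplified_region = NA)
  if (!is.null(region) && nrow(region) > 0L) {
    # strictly interior: the region must hold material on both sides of
    # the boundary, so an edge junction between a truncated and a
    # non-truncated exon does not count as inside
    out$within_amplified_region <- vapply(out$spliced_pos, function(p)
      any(p > region$start + edge_margin & p < region$end - edge_margin),
      logical(1))
  }
  rownames(out) <- NULL
  class(out) <- c("junction_evidence", "data.frame")
  out
}

# per-side identity of an alignment split at a reference boundary:
# matches / aligned columns left and right of the boundary (insertions
# count toward the side of the reference position they sit at)
side_identities <- function(cigar, ref_start, boundary) {
  ops <- parse_cigar(cigar)
  ml <- 0; cl <- 0; mr <- 0; cr <- 0
  rp <- ref_start
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op %in% c("=", "X", "D")) {
      n_left <- max(0L, min(len, boundary - rp))
      n_right <- len - n_left
      if (op == "=") { ml <- ml + n_left; mr <- mr + n_right }
      cl <- cl + n_left; cr <- cr + n_right
      rp <- rp + len
    } else if (op == "I") {
      if (rp <= boundary) cl <- cl + len else cr <- cr + len
    }
  }
  c(if (cl > 0) ml / cl else 0, if (cr > 0) mr / cr else 0)
}

empty_junction_evidence <- function() {
  out <- data.frame(gene_id = character(0), i = integer(0), j = integer(0),
                    junction = character(0), spliced_pos = integer(0),
                    read_id = character(0), library_id = character(0),
                    group = character(0), left_overhang = integer(0),
                    right_overhang = integer(0), identity = numeric(0),
                    within_amplified_region = logical(0))
  class(out) <- c("junction_evidence", "data.frame")
  out
}

#' Summarize junction support in the style of a presence/absence table
#'
#' For the junctions whose boundary lies inside the amplified (high-coverage
#' B) region: emits `"all"` when every one has at least `min_reads`
#' supporting reads, `"none"` when none has, and otherwise the explicit
#' comma-separated list of supported junction indices (e.g. `"8-9, 9-10"`).
#'
#' @param evidence A `junction_evidence` data frame (one gene, one group).
#' @param catalog The [junction_catalog()] the evidence was computed on.
#' @param region Amplified-region call(s) with `start`/`end` in spliced
#'   coordinates; a junction is in-region when its boundary position is.
#' @param min_reads Minimum supporting reads to score a junction present.
#' @param edge_margin Interior margin for region membership (see
#'   [find_junction_spanning_reads()]).
#' @return List with `label` (the table cell), `per_junction` counts for
#'   every catalog junction, and the in-region junction ids.
#' @export
summarize_junction_table <- function(evidence, catalog, region,
                                     min_reads = 1L, edge_margin = 25L) {
  counts <- vapply(seq_len(nrow(catalog)), function(k)
    sum(evidence$i == catalog$i[k] & evidence$j == catalog$j[k]), integer(1))
  in_region <- if (is.null(region) || nrow(region) == 0L)
    rep(FALSE, nrow(catalog))
  else vapply(catalog$spliced_pos, function(p)
    any(p > region$start + edge_margin & p < region$end - edge_margin),
    logical(1))
  jn <- sprintf("%d-%d", catalog$i, catalog$j)
  supported <- counts >= min_reads
  lab <- if (!any(in_region)) "none"
  else if (all(supported[in_region])) "all"
  else if (!any(supported[in_region])) "none"
  else paste(jn[in_region & supported], collapse = ", ")
  list(label = lab,
       per_junction = data.frame(junction = jn, n_reads = counts,
                                 in_region = in_region),
       in_region_junctions = jn[in_region])
}

#' Read a primer set from TSV
#'
#' Expected columns: `assay_id`, `role` (one of `forward`,
#' `reverse_exonic`, `reverse_junction`), `name`, `sequence`. Primer
#' lengths must be 15-35 bases.
#'
#' @param path TSV file.
#' @return A `primer_set` data frame.
#' @export
read_primer_set <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  primer_set(df)
}

#' @rdname read_primer_set
#' @param df Data frame with the columns above.
#' @export
primer_set <- function(df) {
  need <- c("assay_id", "role", "name", "sequence")
  if (!all(need %in% names(df))) stopf("primer set needs columns: %s",
                                       paste(need, collapse = ", "))
  if (!all(df$role %in% c("forward", "reverse_exonic", "reverse_junction")))
    stopf("unknown primer role")
  if (any(nchar(df$sequence) < 15L | nchar(df$sequence) > 35L))
    stopf("primer lengths must be 15-35 bases")
  class(df) <- c("primer_set", "data.frame")
  df
}

# binding sites of a primer (given in its 5'->3' orientation) on the +
# strand of the template, as it would anneal in `orientation` "forward"
# (primer equals template) or "reverse" (primer equals reverse complement).
# <= max_mismatches allowed but none within the `anchor` 3'-terminal bases.
primer_sites <- function(primer, template, orientation, max_mismatches, anchor) {
  pat <- if (orientation == "forward") primer else revcomp(primer)
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                   Biostrings::DNAString(template),
                                   max.mismatch = max_mismatches)
  if (length(hits) == 0L) return(integer(0))
  st <- Biostrings::start(hits); en <- Biostrings::end(hits)
  ok <- vapply(seq_along(st), function(k) {
    site <- substring(template, st[k], en[k])
    # 3' end of a forward primer sits at the site's right end, of a
    # reverse primer at the site's left end (on the + strand view)
    a <- min(anchor, nchar(pat))
    if (orientation == "forward")
      substring(site, nchar(site) - a + 1L) == substring(pat, nchar(pat) - a + 1L)
    else
      substring(site, 1L, a) == substring(pat, 1L, a)
  }, logical(1))
  st[ok] - 1L  # 0-based site starts
}

#' In-silico PCR amplicon prediction
#'
#' Finds binding sites of the forward primer and of each reverse primer
#' (annealing to opposite strands), allowing up to `max_mismatches`
#' mismatches per primer but none within the `anchor` 3'-terminal bases
#' (the primer-extension chemistry approximation), and reports every
#' forward x reverse product up to `max_product` bases. Products of a
#' junction-spanning reverse primer appear only on templates lacking the
#' intervening intron — the gel logic that distinguishes 1B from 0B
#' samples. Both template orientations are searched, so predictions are
#' invariant under reverse complementation of the template.
#'
#' @param template Template sequence (plain character).
#' @param primers A `primer_set` (one forward, one or more reverse rows).
#' @param max_mismatches Per-primer mismatch allowance (default 2).
#' @param anchor 3'-terminal bases that must match exactly (default 3).
#' @param max_product Maximum product size in bases (default 2000).
#' @param template_id Label for the output.
#' @return An `amplicon_predictions` data frame: primer pair, product
#'   interval (0-based half-open on the + strand of `template`), size,
#'   reverse-primer role. Zero rows is a valid result.
#' @export
insilico_pcr <- function(template, primers, max_mismatches = 2L, anchor = 3L,
                         max_product = 2000L, template_id = "template") {
  if (!nzchar(template)) stopf("empty template")
  fw <- primers[primers$role == "forward", , drop = FALSE]
  rv <- primers[primers$role != "forward", , drop = FALSE]
  out <- list()
  scan <- function(tmpl, flipped) {
    L <- nchar(tmpl)
    for (fk in seq_len(nrow(fw))) {
      fs <- primer_sites(fw$sequence[fk], tmpl, "forward", max_mismatches, anchor)
      if (length(fs) == 0L) next
      f_len <- nchar(fw$sequence[fk])
      for (rk in seq_len(nrow(rv))) {
        rs <- primer_sites(rv$sequence[rk], tmpl, "reverse", max_mismatches, anchor)
        r_len <- nchar(rv$sequence[rk])
        for (s in fs) for (r in rs) {
          if (s + f_len > r) next          # primers must not overlap
          size <- (r + r_len) - s
          if (size > max_product) next
          st <- s; en <- r + r_len
          if (flipped) { tmp <- L - en; en <- L - st; st <- tmp }
          out[[length(out) + 1L]] <<- data.frame(
            template_id = template_id,
            assay_id = fw$assay_id[fk],
            forward = fw$name[fk], reverse = rv$name[rk],
            reverse_role = rv$role[rk],
            start = st, end = en, size = size)
        }
      }
    }
  }
  scan(template, FALSE)
  scan(revcomp(template), TRUE)
  res <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(template_id = character(0), assay_id = character(0),
               forward = character(0), reverse = character(0),
               reverse_role = character(0), start = integer(0),
               end = integer(0), size = integer(0))
  res <- res[order(res$start, res$size), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("amplicon_predictions", "data.frame")
  res
}
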