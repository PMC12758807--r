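#' Construct a gene model
#'
#' A gene model holds the exon structure of a (canonical, A-chromosome) gene
#' in transcription orientation: exon intervals are 0-based, half-open on the
#' oriented genomic sequence, non-overlapping and sorted so exon 1 is the
#' 5'-most exon. Minus-strand genes are normalized into this orientation at
#' load time, so all downstream modules are strand-free.
#'
#' @param gene_id Gene identifier.
#' @param chrom Name of the source sequence.
#' @param strand `"+"` or `"-"` (orientation on the *original* source).
#' @param exons Two-column matrix or data frame of 0-based half-open
#'   `(start, end)` exon intervals in transcription orientation.
#' @param sequence Optional oriented genomic sequence (plain character).
#' @param source_length Length of the original source sequence; needed to
#'   write minus-strand models back to plus-strand GFF3 coordinates.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand = "+", exons,
                       sequence = NULL, source_length = NA_integer_) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-'")
  if (nrow(exons) == 0L) stopf("gene model needs at least one exon")
  if (any(exons[, "end"] - exons[, "start"] < 1L))
    stopf("every exon must have length >= 1")
  if (is.unsorted(exons[, "start"], strictly = TRUE) && nrow(exons) > 1L)
    stopf("exons must be sorted by start")
  if (nrow(exons) > 1L && any(exons[-nrow(exons), "end"] > exons[-1L, "start"]))
    stopf("exons must be non-overlapping (introns of length >= 0)")
  if (!is.null(sequence) && max(exons[, "end"]) > nchar(sequence))
    stopf("exon outside sequence bounds for gene '%s'", gene_id)
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, sequence = sequence,
                 source_length = as.integer(source_length %||% NA_integer_)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  lens <- x$exons[, "end"] - x$exons[, "start"]
  cat(sprintf("<gene_model> %s on %s (%s), %d exon(s), spliced length %d\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons), sum(lens)))
  invisible(x)
}

#' Number of exons and spliced length of a gene model
#' @param g A `gene_model`.
#' @return Integer.
#' @export
n_exons <- function(g) nrow(g$exons)

#' @rdname n_exons
#' @export
spliced_length <- function(g) sum(g$exons[, "end"] - g$exons[, "start"])

#' Load a gene model from GFF3 + FASTA
#'
#' Reads the exon records of `gene_id` from a GFF3 file and the named
#' sequence from a FASTA file. GFF3 1-based closed coordinates are converted
#' to internal 0-based half-open intervals. Minus-strand genes are
#' reverse-complemented into transcription orientation, so exon 1 is always
#' 5'-most and the returned model's `sequence` is the oriented chromosome.
#'
#' @param gff_path GFF3 file with `exon` features whose `Parent` (or `ID`)
#'   attribute names the gene.
#' @param fasta_path FASTA file containing the chromosome/contig sequence.
#' @param gene_id Gene to load.
#' @return A [gene_model()].
#' @export
load_gene_model <- function(gff_path, fasta_path, gene_id) {
  gr <- rtracklayer::import(gff_path)
  gr <- gr[gr$type == "exon"]
  parent <- as.character(vapply(as.list(gr$Parent %||% character(0)),
                                function(p) if (length(p)) p[[1]] else NA_character_,
                                character(1)))
  keep <- !is.na(parent) & parent == gene_id
  gr <- gr[keep]
  if (length(gr) == 0L) stopf("gene '%s' not found in %s", gene_id, gff_path)
  chrom <- as.character(GenomicRanges::seqnames(gr))[1]
  strand <- as.character(GenomicRanges::strand(gr))[1]
  if (!strand %in% c("+", "-")) strand <- "+"
  seqs <- read_fasta(fasta_path)
  if (!chrom %in% names(seqs))
    stopf("sequence '%s' not found in %s", chrom, fasta_path)
  genome <- seqs[[chrom]]
  L <- nchar(genome)
  s0 <- GenomicRanges::start(gr) - 1L   # to 0-based half-open
  e0 <- GenomicRanges::end(gr)
  if (any(s0 < 0L) || any(e0 > L))
    stopf("exon outside sequence bounds for gene '%s'", gene_id)
  if (strand == "-") {
    genome <- revcomp(genome)
    tmp <- L - e0
    e0 <- L - s0
    s0 <- tmp
  }
  o <- order(s0)
  gene_model(gene_id, chrom, strand, cbind(s0[o], e0[o]),
             sequence = genome, source_length = L)
}

#' Write a gene model back to GFF3
#'
#' Inverse of [load_gene_model()]: internal 0-based half-open transcription
#' coordinates are converted back to 1-based closed plus-strand GFF3 records.
#'
#' @param g A `gene_model`.
#' @param gff_path Output GFF3 path.
#' @export
write_gene_model <- function(g, gff_path) {
  s0 <- g$exons[, "start"]; e0 <- g$exons[, "end"]
  if (g$strand == "-") {
    L <- g$source_length
    if (is.na(L)) stopf("minus-strand model needs source_length to be written")
    tmp <- L - e0
    e0 <- L - s0
    s0 <- tmp
    o <- order(s0); s0 <- s0[o]; e0 <- e0[o]
  }
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = s0 + 1L, end = e0),
    strand = g$strand)
  gr$source <- "bretro"
  gr$type <- "exon"
  gr$ID <- sprintf("%s.exon%d", g$gene_id, seq_along(gr))
  gr$Parent <- g$gene_id
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(gff_path)
}

#' Spliced (intronless) sequence of a gene model
#'
#' Concatenates the exon sequences in transcription order; this is the
#' sequence a retrotransposed copy of the gene would carry, introns removed.
#'
#' @param g A `gene_model`.
#' @param genome Oriented genomic sequence (defaults to `g$sequence`).
#' @return Character scalar of length `spliced_length(g)`.
#' @export
spliced_sequence <- function(g, genome = g$sequence) {
  if (is.null(genome)) stopf("no genomic sequence available")
  if (max(g$exons[, "end"]) > nchar(genome))
    stopf("exon outside genome bounds")
  paste(substring(genome, g$exons[, "start"] + 1L, g$exons[, "end"]),
        collapse = "")
}

#' Exon-exon junction reference catalog
#'
#' Builds one junction reference per adjacent exon pair: the last
#' `arm_length` bases of exon i concatenated with the first `arm_length`
#' bases of exon i+1. Arms are truncated when an exon is shorter than
#' `arm_length`; `boundary_offset` is the position of the junction inside
#' the reference sequence. A genomic-DNA read aligning across the boundary
#' with sufficient overhang on both sides is the diagnostic signature of an
#' intronless (retrotransposed) gene copy.
#'
#' @param g A `gene_model`.
#' @param genome Oriented genomic sequence (defaults to `g$sequence`).
#' @param arm_length Bases taken from each exon; default 100 so that a fully
#'   contained read of typical short-read length can be placed.
#' @return Data frame with one row per junction (empty for single-exon
#'   genes): `gene_id, i, j, id, sequence, boundary_offset, arm_length,
#'   spliced_pos` where `spliced_pos` is the 0-based position of the
#'   boundary on the spliced sequence.
#' @export
junction_catalog <- function(g, genome = g$sequence, arm_length = 100L) {
  if (arm_length < 1L) stopf("arm_length must be >= 1")
  ne <- n_exons(g)
  if (ne < 2L) {
    return(data.frame(gene_id = character(0), i = integer(0), j = integer(0),
                      id = character(0), sequence = character(0),
                      boundary_offset = integer(0), arm_length = integer(0),
                      spliced_pos = integer(0)))
  }
  lens <- g$exons[, "end"] - g$exons[, "start"]
  cum <- cumsum(lens)
  out <- vector("list", ne - 1L)
  for (i in seq_len(ne - 1L)) {
    left_len <- min(arm_length, lens[i])
    right_len <- min(arm_length, lens[i + 1L])
    left <- substring(genome, g$exons[i, "end"] - left_len + 1L, g$exons[i, "end"])
    right <- substring(genome, g$exons[i + 1L, "start"] + 1L,
                       g$exons[i + 1L, "start"] + right_len)
    out[[i]] <- data.frame(
      gene_id = g$gene_id, i = i, j = i + 1L,
      id = sprintf("%s|junction|%d-%d|%d", g$gene_id, i, i + 1L, left_len),
      sequence = paste0(left, right),
      boundary_offset = left_len,
      arm_length = as.integer(arm_length),
      spliced_pos = cum[i])
  }
  do.call(rbind, out)
}

#' Export a junction catalog as FASTA
#'
#' Headers follow the `geneID|junction|i-j|offset` convention.
#'
#' @param catalog Output of [junction_catalog()].
#' @param path Output FASTA path.
#' @export
write_junction_fasta <- function(catalog, path) {
  write_fasta(setNames(catalog$sequence, catalog$id), path)
}
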