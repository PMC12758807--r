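#' Read and write FASTA / FASTQ files
#'
#' Thin wrappers around \pkg{Biostrings} that exchange plain named character
#' vectors with the rest of the package. FASTQ output carries a constant
#' Q30-equivalent quality string, matching the synthetic read generator's
#' error model (qualities carry no information there).
#'
#' @param path File path.
#' @param x Named character vector of sequences.
#' @return `read_fasta()`/`read_fastq()` return a named character vector.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fasta")
  setNames(as.character(s), sub("\\s.*$", "", names(s)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  s <- Biostrings::DNAStringSet(x)
  names(s) <- names(x)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(s), sub("\\s.*$", "", names(s)))
}

#' @rdname read_fasta
#' @export
write_fastq <- function(x, path) {
  s <- Biostrings::DNAStringSet(x)
  names(s) <- names(x)
  q <- Biostrings::PhredQuality(vapply(nchar(x), function(n)
    paste(rep("?", n), collapse = ""), character(1)))
  qs <- Biostrings::QualityScaledDNAStringSet(s, q)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Export a depth profile as TSV or bedGraph
#'
#' @param profile A `coverage_profile` object.
#' @param path Output file.
#' @param format `"tsv"` (ref, pos0, pos1, depth; one row per position) or
#'   `"bedgraph"` (run-length compressed).
#' @export
write_depth <- function(profile, path, format = c("tsv", "bedgraph")) {
  format <- match.arg(format)
  d <- profile$depth
  if (format == "tsv") {
    df <- data.frame(ref = profile$ref_id, pos0 = seq_along(d) - 1L,
                     pos1 = seq_along(d), depth = d)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    r <- rle(d)
    ends <- cumsum(r$lengths)
    df <- data.frame(ref = profile$ref_id, start = ends - r$lengths,
                     end = ends, depth = r$values)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Export amplified-region calls as BED and JSON
#'
#' @param calls An `amplified_region_calls` data frame.
#' @param bed_path,json_path Output paths (either may be `NULL`).
#' @param copy_number Optional copy-number estimate attached to the JSON.
#' @export
write_region_calls <- function(calls, bed_path = NULL, json_path = NULL,
                               copy_number = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(calls$ref_id, calls$start, calls$end,
                      sprintf("amplified_%d", seq_len(nrow(calls))),
                      round(calls$mean_ratio, 3), ".")
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(json_path)) {
    obj <- list(calls = calls)
    if (!is.null(copy_number)) obj$copy_number <- copy_number
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(calls)
}
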