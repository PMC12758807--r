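#' Chain per-read hits into tandem-array calls
#'
#' Consecutive same-strand hits on a read separated by less than `max_gap`
#' bases chain into one array; the chain length is the copy count. Reads
#' with a single hit report copy count 1 (no array). The pipeline-level
#' tandem copy number is the modal copy count over reads that fully contain
#' an array (array not truncated at a read end).
#'
#' @param hits A `long_read_hits` data frame from [scan_long_reads()].
#' @param max_gap Maximum inter-copy gap in bases (default 2000).
#' @param edge_margin Bases an array must keep clear of both read ends to
#'   count as fully contained.
#' @return A `tandem_calls` data frame, one row per array/chain: read id,
#'   array span on the read, `n_copies`, orientation, gap list, and
#'   `complete` (fully contained). `attr(x, "modal_copies")` holds the
#'   modal copy count over complete arrays (NA when none).
#' @export
detect_tandem <- function(hits, max_gap = 2000L, edge_margin = 100L) {
  out <- list()
  for (rid in unique(hits$read_id)) {
    h <- hits[hits$read_id == rid, , drop = FALSE]
    h <- h[order(h$read_start), , drop = FALSE]
    gap_prev <- c(Inf, h$read_start[-1L] - h$read_end[-nrow(h)])
    new_chain <- gap_prev >= max_gap |
      c(TRUE, h$strand[-1L] != h$strand[-nrow(h)])
    chain <- cumsum(new_chain)
    for (ci in unique(chain)) {
      hc <- h[chain == ci, , drop = FALSE]
      gaps <- if (nrow(hc) > 1L)
        hc$read_start[-1L] - hc$read_end[-nrow(hc)] else integer(0)
      out[[length(out) + 1L]] <- data.frame(
        read_id = rid, read_length = hc$read_length[1],
        array_start = min(hc$read_start), array_end = max(hc$read_end),
        n_copies = nrow(hc), strand = hc$strand[1],
        gaps = paste(gaps, collapse = ","),
        complete = min(hc$read_start) >= edge_margin &
          max(hc$read_end) <= hc$read_length[1] - edge_margin)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(0), read_length = integer(0),
               array_start = integer(0), array_end = integer(0),
               n_copies = integer(0), strand = character(0),
               gaps = character(0), complete = logical(0))
  rownames(res) <- NULL
  class(res) <- c("tandem_calls", "data.frame")
  cc <- res$n_copies[res$complete]
  attr(res, "modal_copies") <- if (length(cc)) {
    tb <- table(cc)
    as.integer(names(tb)[which.max(tb)])
  } else NA_integer_
  res
}

#' Extract genomic flanks around pseudogene hits on long reads
#'
#' Returns the `flank_len` bases on each side of every hit span. For a
#' tandem array the flanks are taken outside the \emph{whole} array span:
#' the sequence between copies is pseudogene, not genomic flank. Flanks are
#' oriented to the pseudogene-forward strand (for minus-strand arrays the
#' sides swap and the sequence is reverse-complemented), so flanks from
#' reads sequenced in either direction are directly comparable. Truncation
#' at read ends is recorded, never padded.
#'
#' @param hits A `long_read_hits` data frame.
#' @param reads Named character vector of the long reads.
#' @param flank_len Flank length in bases (1000 for locus clustering;
#'   10000 is the conventional span for annotation export).
#' @param max_gap Array chaining gap passed to [detect_tandem()].
#' @return A `flank_set` data frame: read id, array index, side
#'   (`left`/`right`, pseudogene-forward), sequence, length, `truncated`.
#' @export
extract_flanks <- function(hits, reads, flank_len = 1000L, max_gap = 2000L) {
  arrays <- detect_tandem(hits, max_gap = max_gap, edge_margin = 0L)
  out <- list()
  for (k in seq_len(nrow(arrays))) {
    a <- arrays[k, ]
    read <- reads[[a$read_id]]
    L <- nchar(read)
    ls <- max(0L, a$array_start - flank_len)
    left <- substring(read, ls + 1L, a$array_start)
    re <- min(L, a$array_end + flank_len)
    right <- substring(read, a$array_end + 1L, re)
    if (a$strand == "-") {
      tmp <- left
      left <- revcomp(right)
      right <- revcomp(tmp)
      if (!nzchar(left)) left <- ""
      if (!nzchar(right)) right <- ""
    }
    out[[length(out) + 1L]] <- data.frame(
      read_id = a$read_id, array = k,
      side = c("left", "right"),
      seq = c(left, right),
      length = c(nchar(left), nchar(right)),
      truncated = if (a$strand == "+")
        c(a$array_start < flank_len, L - a$array_end < flank_len)
      else c(L - a$array_end < flank_len, a$array_start < flank_len))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(0), array = integer(0),
               side = character(0), seq = character(0),
               length = integer(0), truncated = logical(0))
  rownames(res) <- NULL
  class(res) <- c("flank_set", "data.frame")
  res
}

# pairwise flank identity: local-alignment matches over the shorter flank
flank_identity <- function(a, b, params) {
  r <- cpp_sw_align(a, b, params$match, params$mismatch,
                    params$gap_open, params$gap_ext)
  r$n_match / min(nchar(a), nchar(b))
}

#' Cluster pseudogene flanks into insertion loci
#'
#' Greedy single-linkage clustering of flank sequences on pairwise
#' local-alignment identity (matched columns over the shorter flank): a
#' flank joins the first cluster whose representative it matches at
#' `link_identity` or better, after a shared-k-mer prefilter that skips
#' alignments between obviously unrelated flanks. Flanks from the same
#' genomic locus agree up to twice the read error rate, while flanks from
#' distinct loci are unrelated sequence, so the cluster count estimates the
#' number of insertion loci. Left and right flanks are clustered jointly
#' but never linked across sides; a locus is supported when a left cluster
#' and a right cluster co-occur on the same read.
#'
#' @param flanks A `flank_set` data frame.
#' @param link_identity Single-linkage threshold. Default 0.85: two reads
#'   with per-base error e share about (1-e)^2 identity (~0.90 at 5%
#'   error), while cross-locus identity stays below ~0.5.
#' @param min_len Minimum flank length to enter clustering (truncated
#'   stubs carry too little signal).
#' @param params Alignment weights.
#' @return A `flank_clusters` object: `members` (flank table plus cluster
#'   ids), `n_left`/`n_right` cluster counts, `locus_count` (distinct
#'   left-right cluster pairs co-occurring on reads, falling back to the
#'   larger side count when no read has both flanks).
#' @export
cluster_flanks <- function(flanks, link_identity = 0.85, min_len = 200L,
                           params = mapping_params()) {
  if (link_identity <= 0 || link_identity > 1)
    stopf("link_identity must be in (0, 1]")
  fl <- flanks[flanks$length >= min_len, , drop = FALSE]
  n <- nrow(fl)
  if (n == 0L)
    return(structure(list(members = fl, n_left = 0L, n_right = 0L,
                          locus_count = 0L), class = "flank_clusters"))
  # shared-k-mer prefilter: flanks from distinct loci are unrelated
  # sequence and share (essentially) no 13-mers, so the costly alignment
  # runs only against candidate same-locus representatives
  k <- params$seed_k
  kmers <- lapply(fl$seq, function(s) {
    if (nchar(s) < k) return(character(0))
    unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
  })
  cluster <- integer(n)
  reps <- list()   # per cluster: index of representative (first member)
  for (i in seq_len(n)) {
    assigned <- 0L
    for (ci in seq_along(reps)) {
      r <- reps[[ci]]
      if (fl$side[r] != fl$side[i]) next
      if (length(intersect(kmers[[i]], kmers[[r]])) < 5L) next
      if (flank_identity(fl$seq[i], fl$seq[r], params) >= link_identity) {
        assigned <- ci; break
      }
    }
    if (assigned == 0L) {
      reps[[length(reps) + 1L]] <- i
      assigned <- length(reps)
    }
    cluster[i] <- assigned
  }
  fl$cluster <- cluster
  n_left <- length(unique(fl$cluster[fl$side == "left"]))
  n_right <- length(unique(fl$cluster[fl$side == "right"]))
  # loci supported by a (left, right) cluster pair on the same read/array
  key <- paste(fl$read_id, fl$array)
  pairs <- unique(do.call(rbind, lapply(unique(key), function(kk) {
    sub <- fl[key == kk, ]
    l <- sub$cluster[sub$side == "left"]
    r <- sub$cluster[sub$side == "right"]
    if (length(l) == 1L && length(r) == 1L) data.frame(l = l, r = r) else NULL
  })))
  locus_count <- if (!is.null(pairs) && nrow(pairs) > 0L) nrow(pairs)
                 else max(n_left, n_right)
  structure(list(members = fl, n_left = n_left, n_right = n_right,
                 locus_count = locus_count, link_identity = link_identity),
            class = "flank_clusters")
}

#' @export
print.flank_clusters <- function(x, ...) {
  cat(sprintf("<flank_clusters> %d flanks -> %d left / %d right clusters, %d locus(i)\n",
              nrow(x$members), x$n_left, x$n_right, x$locus_count))
  invisible(x)
}

#' Classify the genomic arrangement of pseudogene copies
#'
#' Combines the locus count (flank clustering) with the modal tandem copy
#' count: \emph{tandem} when reads show arrays of two or more copies at a
#' single locus; \emph{dispersed} when single copies sit at
#' `dispersed_min` or more distinct loci; \emph{single-locus} for one
#' locus, one copy; \emph{mixed} otherwise; \emph{no-call} without hits.
#'
#' @param clusters A `flank_clusters` object.
#' @param arrays A `tandem_calls` data frame.
#' @param dispersed_min Minimum locus count to call dispersed (default 3).
#' @return An `arrangement_call` list: `class`, `locus_count`,
#'   `modal_copies`, `n_reads`.
#' @export
classify_arrangement <- function(clusters, arrays, dispersed_min = 3L) {
  n_reads <- length(unique(arrays$read_id))
  if (n_reads == 0L) {
    return(structure(list(class = "no-call", locus_count = 0L,
                          modal_copies = NA_integer_, n_reads = 0L),
                     class = "arrangement_call"))
  }
  modal <- attr(arrays, "modal_copies")
  if (is.na(modal)) {  # no complete array: fall back to all arrays
    tb <- table(arrays$n_copies)
    modal <- as.integer(names(tb)[which.max(tb)])
  }
  loci <- clusters$locus_count
  cls <- if (modal >= 2L && loci <= 1L) "tandem"
  else if (modal == 1L && loci >= dispersed_min) "dispersed"
  else if (modal == 1L && loci == 1L) "single-locus"
  else "mixed"
  structure(list(class = cls, locus_count = loci, modal_copies = modal,
                 n_reads = n_reads),
            class = "arrangement_call")
}

#' @export
print.arrangement_call <- function(x, ...) {
  cat(sprintf("<arrangement_call> %s (%d locus/loci, modal copy count %s, %d reads)\n",
              x$class, x$locus_count,
              ifelse(is.na(x$modal_copies), "NA", x$modal_copies), x$n_reads))
  invisible(x)
}

#' Export long-read hits and flanks
#'
#' `write_hits_paf()` writes a PAF-like TSV (read, read length, hit
#' interval, strand, query interval, identity, score);
#' `write_flank_fasta()` writes flanks with `read|side|len|truncated`
#' headers; `write_annotation_fasta()` exports each hit plus/minus
#' `span` bases of read context, the conventional unit for downstream
#' annotation.
#'
#' @param hits A `long_read_hits` data frame.
#' @param flanks A `flank_set` data frame.
#' @param reads Named character vector of long reads.
#' @param span Context bases around each hit (default 10000).
#' @param path Output path.
#' @export
write_hits_paf <- function(hits, path) {
  df <- data.frame(hits$read_id, hits$read_length, hits$read_start,
                   hits$read_end, hits$strand, hits$q_start, hits$q_end,
                   round(hits$identity, 4), hits$score)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_paf
#' @export
write_flank_fasta <- function(flanks, path) {
  ok <- nzchar(flanks$seq)
  write_fasta(setNames(flanks$seq[ok],
                       sprintf("%s|%s|%d|%s", flanks$read_id[ok],
                               flanks$side[ok], flanks$length[ok],
                               ifelse(flanks$truncated[ok], "truncated", "full"))),
              path)
}

#' @rdname write_hits_paf
#' @export
write_annotation_fasta <- function(hits, reads, path, span = 10000L) {
  seqs <- vapply(seq_len(nrow(hits)), function(k) {
    read <- reads[[hits$read_id[k]]]
    s <- max(0L, hits$read_start[k] - span)
    e <- min(nchar(read), hits$read_end[k] + span)
    substring(read, s + 1L, e)
  }, character(1))
  write_fasta(setNames(seqs, sprintf("%s|hit%d|%d-%d", hits$read_id,
                                     seq_len(nrow(hits)), hits$read_start,
                                     hits$read_end)), path)
}
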