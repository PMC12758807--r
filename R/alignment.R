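#' Mapping parameters
#'
#' Parameters for the internal k-mer-seeded local aligner. The retention
#' contract downstream stages depend on is `score >= min_score` and
#' `identity >= min_identity` (defaults 40 and 0.80). The scoring scheme is
#' fixed by default at match +1, mismatch -1, gap-open -2, gap-extend -1,
#' so a score of 40 corresponds to roughly 40 net matched bases; users
#' porting thresholds from other aligners should recalibrate `min_score`
#' if they change the weights.
#'
#' @param min_score Minimum retained alignment score.
#' @param min_identity Minimum retained identity, matches / aligned columns.
#' @param match,mismatch Per-column match/mismatch weights.
#' @param gap_open,gap_ext Positive gap penalties; a gap of length L costs
#'   `gap_open + L * gap_ext`.
#' @param seed_k Seed k-mer length.
#' @param band Extra reference bases on each side of the seeded window.
#' @param end_anchor Read mapping trims each alignment end back to a run of
#'   at least this many consecutive matches (0 disables). A local alignment
#'   happily gains a net-positive `=X=` overhang past a template junction
#'   (for instance from a retrocopy edge into its genomic flank), which
#'   would inject systematic false mismatch columns into the pileup;
#'   anchored ends make such chance extensions vanishingly rare.
#' @return A `mapping_params` list.
#' @export
mapping_params <- function(min_score = 40L, min_identity = 0.80,
                           match = 1L, mismatch = -1L,
                           gap_open = 2L, gap_ext = 1L,
                           seed_k = 13L, band = 32L, end_anchor = 5L) {
  if (min_identity <= 0 || min_identity > 1)
    stopf("min_identity must be in (0, 1]")
  structure(list(min_score = as.integer(min_score),
                 min_identity = min_identity,
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext),
                 seed_k = as.integer(seed_k), band = as.integer(band),
                 end_anchor = as.integer(end_anchor)),
            class = "mapping_params")
}

#' Optimal local alignment of a single sequence pair
#'
#' Full (unseeded) affine-gap Smith-Waterman alignment. Used directly for
#' small problems (flank comparison, oracle checks); bulk read mapping goes
#' through the seeded [align_reads()].
#'
#' @param query,subject Plain character DNA sequences.
#' @param params A [mapping_params()] object (only the weights are used).
#' @return List with `score`, 0-based half-open `q_start/q_end` and
#'   `s_start/s_end`, the column counts `n_match/n_mismatch/n_ins/n_del`,
#'   `identity` (matches / aligned columns) and a `cigar` over the ops
#'   `=`, `X`, `I` (insertion in query), `D` (deletion from query).
#' @export
align_pair <- function(query, subject, params = mapping_params()) {
  r <- cpp_sw_align(query, subject, params$match, params$mismatch,
                    params$gap_open, params$gap_ext)
  cols <- r$n_match + r$n_mismatch + r$n_ins + r$n_del
  r$identity <- if (cols > 0) r$n_match / cols else 0
  r
}

# k-mer index of a reference: environment mapping k-mer -> 0-based positions
kmer_index <- function(ref, k) {
  n <- nchar(ref)
  if (n < k) return(NULL)
  km <- substring(ref, 1:(n - k + 1L), k:n)
  list2env(split(0:(n - k), km), hash = TRUE, size = length(km))
}

# modal seed diagonal of one read against an index; NA when no seed matches
seed_diagonal <- function(read, idx, k, n_seeds = 6L) {
  len <- nchar(read)
  if (len < k || is.null(idx)) return(NA_integer_)
  offs <- unique(as.integer(round(seq(1L, len - k + 1L, length.out = n_seeds))))
  diags <- integer(0)
  for (o in offs) {
    pos <- idx[[substr(read, o, o + k - 1L)]]
    if (!is.null(pos)) diags <- c(diags, pos - (o - 1L))
  }
  if (length(diags) == 0L) return(NA_integer_)
  tab <- table(diags)
  cand <- as.integer(names(tab)[tab == max(tab)])
  min(cand)
}

align_one <- function(read, ref, diag, params) {
  len <- nchar(read)
  # fast path: exact ungapped placement at the seeded diagonal is optimal
  # under a positive match weight (score = length, unbeatable)
  if (diag >= 0L && diag + len <= nchar(ref) && params$match > 0L &&
      substr(ref, diag + 1L, diag + len) == read) {
    return(list(score = len * params$match, q_start = 0L, q_end = len,
                s_start = diag, s_end = diag + len,
                n_match = len, n_mismatch = 0L, n_ins = 0L, n_del = 0L,
                cigar = paste0(len, "="), identity = 1))
  }
  ws <- max(0L, diag - params$band)
  we <- min(nchar(ref), diag + len + params$band)
  if (we - ws < params$seed_k) return(NULL)
  r <- cpp_sw_align(read, substring(ref, ws + 1L, we),
                    params$match, params$mismatch,
                    params$gap_open, params$gap_ext)
  cols <- r$n_match + r$n_mismatch + r$n_ins + r$n_del
  if (cols == 0L) return(NULL)
  r$identity <- r$n_match / cols
  r$s_start <- r$s_start + ws
  r$s_end <- r$s_end + ws
  if (params$end_anchor > 0L) r <- anchor_ends(r, params)
  r
}

# trim alignment ends until each terminates in >= `end_anchor` consecutive
# matches; coordinates, column counts, score and identity are recomputed
# over the trimmed columns (score by the declared scheme)
anchor_ends <- function(a, params) {
  ops <- parse_cigar(a$cigar)
  if (is.null(ops) || nrow(ops) == 0L) return(NULL)
  anchored <- function(k) ops$op[k] == "=" && ops$len[k] >= params$end_anchor
  lo <- 1L; hi <- nrow(ops)
  while (lo <= hi && !anchored(lo)) lo <- lo + 1L
  while (hi >= lo && !anchored(hi)) hi <- hi - 1L
  if (lo > hi) return(NULL)
  if (lo == 1L && hi == nrow(ops)) return(a)
  qadv <- function(k) sum(ops$len[k][ops$op[k] %in% c("=", "X", "I")])
  sadv <- function(k) sum(ops$len[k][ops$op[k] %in% c("=", "X", "D")])
  pre <- seq_len(lo - 1L)
  post <- if (hi < nrow(ops)) (hi + 1L):nrow(ops) else integer(0)
  a$q_start <- a$q_start + qadv(pre); a$s_start <- a$s_start + sadv(pre)
  a$q_end <- a$q_end - qadv(post);    a$s_end <- a$s_end - sadv(post)
  keep <- ops[lo:hi, , drop = FALSE]
  a$n_match <- sum(keep$len[keep$op == "="])
  a$n_mismatch <- sum(keep$len[keep$op == "X"])
  a$n_ins <- sum(keep$len[keep$op == "I"])
  a$n_del <- sum(keep$len[keep$op == "D"])
  gap_runs <- keep$len[keep$op %in% c("I", "D")]
  a$score <- a$n_match * params$match + a$n_mismatch * params$mismatch -
    sum(params$gap_open + gap_runs * params$gap_ext)
  cols <- a$n_match + a$n_mismatch + a$n_ins + a$n_del
  a$identity <- a$n_match / cols
  a$cigar <- paste0(keep$len, keep$op, collapse = "")
  a
}

#' Map short reads to a set of small references
#'
#' k-mer-seeded, windowed affine-gap local alignment of every read (both
#' strands) against every reference. An alignment is retained only when
#' `score >= min_score` and `identity >= min_identity`. With
#' `keep = "best"` a single best placement per read is kept, ties broken by
#' leftmost reference start, then lexicographic reference id, then `+`
#' strand; `keep = "per_ref"` keeps the best placement on every reference a
#' read seeds on (used for junction catalogs, where one read may genuinely
#' support more than one reference); `keep = "all"` keeps every passing
#' candidate.
#'
#' @param reads Named character vector of reads (or a `DNAStringSet`).
#' @param reference Named character vector of reference sequences.
#' @param params A [mapping_params()].
#' @param library_id,group Labels stored on every record.
#' @param keep Placement policy, see above.
#' @return An `alignment_set` data frame. Reads shorter than the seed k-mer
#'   are skipped; their count is in `attr(x, "skipped_short")`.
#' @export
align_reads <- function(reads, reference, params = mapping_params(),
                        library_id = NA_character_, group = NA_character_,
                        keep = c("best", "per_ref", "all")) {
  keep <- match.arg(keep)
  if (methods::is(reads, "DNAStringSet"))
    reads <- setNames(as.character(reads), names(reads))
  if (length(reads) == 0L) stopf("no reads supplied")
  if (length(reference) == 0L || any(!nzchar(reference)))
    stopf("empty reference")
  if (is.null(names(reference)))
    names(reference) <- sprintf("ref%d", seq_along(reference))
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%d", seq_along(reads))
  k <- params$seed_k
  if (any(nchar(reference) < k)) stopf("reference shorter than seed k-mer")

  lens <- nchar(reads)
  short <- lens < k
  n_short <- sum(short)
  reads <- reads[!short]
  lens <- lens[!short]
  rc <- if (length(reads)) revcomp(reads) else character(0)

  idxs <- lapply(reference, kmer_index, k = k)
  cap <- 2048L; nr <- 0L
  col <- list(read_id = character(cap), ref_id = character(cap),
              strand = character(cap), ref_start = integer(cap),
              ref_end = integer(cap), read_start = integer(cap),
              read_end = integer(cap), read_length = integer(cap),
              score = integer(cap), identity = numeric(cap),
              n_match = integer(cap), n_mismatch = integer(cap),
              n_ins = integer(cap), n_del = integer(cap),
              cigar = character(cap), seq = character(cap))
  push <- function(ri, cd) {
    nr <<- nr + 1L
    if (nr > cap) {
      cap <<- 2L * cap
      col <<- lapply(col, function(v) { length(v) <- cap; v })
    }
    a <- cd$a
    col$read_id[nr] <<- names(reads)[ri]
    col$ref_id[nr] <<- names(reference)[cd$ref_i]
    col$strand[nr] <<- cd$strand
    col$ref_start[nr] <<- a$s_start; col$ref_end[nr] <<- a$s_end
    col$read_start[nr] <<- a$q_start; col$read_end[nr] <<- a$q_end
    col$read_length[nr] <<- lens[[ri]]
    col$score[nr] <<- a$score; col$identity[nr] <<- a$identity
    col$n_match[nr] <<- a$n_match; col$n_mismatch[nr] <<- a$n_mismatch
    col$n_ins[nr] <<- a$n_ins; col$n_del[nr] <<- a$n_del
    col$cigar[nr] <<- a$cigar; col$seq[nr] <<- cd$seq
  }

  for (ri in seq_along(reads)) {
    cand <- list()
    for (fi in seq_along(reference)) {
      ref <- reference[[fi]]
      for (st in c("+", "-")) {
        rd <- if (st == "+") reads[[ri]] else rc[[ri]]
        dg <- seed_diagonal(rd, idxs[[fi]], k)
        if (is.na(dg)) next
        a <- align_one(rd, ref, dg, params)
        if (is.null(a)) next
        if (a$score < params$min_score || a$identity < params$min_identity) next
        cand[[length(cand) + 1L]] <- list(a = a, ref_i = fi, strand = st, seq = rd)
      }
    }
    if (length(cand) == 0L) next
    if (keep == "best") {
      sc <- vapply(cand, function(x) x$a$score, numeric(1))
      ss <- vapply(cand, function(x) x$a$s_start, numeric(1))
      rn <- vapply(cand, function(x) names(reference)[x$ref_i], character(1))
      stp <- vapply(cand, function(x) x$strand == "-", logical(1))
      cand <- cand[order(-sc, ss, rn, stp)][1L]
    } else if (keep == "per_ref") {
      byref <- split(seq_along(cand),
                     vapply(cand, function(x) x$ref_i, integer(1)))
      sel <- vapply(byref, function(ii) {
        sc <- vapply(cand[ii], function(x) x$a$score, numeric(1))
        ss <- vapply(cand[ii], function(x) x$a$s_start, numeric(1))
        stp <- vapply(cand[ii], function(x) x$strand == "-", logical(1))
        ii[order(-sc, ss, stp)][1L]
      }, integer(1))
      cand <- cand[sel]
    }
    for (cd in cand) push(ri, cd)
  }
  out <- if (nr > 0L) {
    col <- lapply(col, function(v) { length(v) <- nr; v })
    df <- data.frame(read_id = col$read_id, library_id = library_id,
                     group = group, col[-1L], stringsAsFactors = FALSE)
    df
  } else empty_alignment_set()
  rownames(out) <- NULL
  class(out) <- c("alignment_set", "data.frame")
  attr(out, "skipped_short") <- n_short
  out
}

empty_alignment_set <- function() {
  data.frame(read_id = character(0), library_id = character(0),
             group = character(0), ref_id = character(0),
             strand = character(0), ref_start = integer(0),
             ref_end = integer(0), read_start = integer(0),
             read_end = integer(0), read_length = integer(0),
             score = integer(0), identity = numeric(0),
             n_match = integer(0), n_mismatch = integer(0),
             n_ins = integer(0), n_del = integer(0),
             cigar = character(0), seq = character(0))
}

#' Scan long reads for local copies of a query sequence
#'
#' Finds every local placement of `query` (both strands) on each long read
#' by k-mer seeding followed by windowed affine-gap alignment; diagonal
#' clusters of seeds separate tandem copies so each copy yields its own hit.
#' A read is reported only when the union of its hits covers at least
#' `min_query_cover` of the query and hit identity passes `min_identity`
#' (the identity + query-cover contract that replaces database e-values at
#' desk scale).
#'
#' @param long_reads Named character vector of long reads.
#' @param query Pseudogene (query) sequence.
#' @param min_identity Minimum per-hit identity (default 0.80).
#' @param min_query_cover Minimum per-read union query coverage (0.70).
#' @param params [mapping_params()]; only the weights and `seed_k` are used.
#' @param seed_step Spacing of query seed positions.
#' @param band Diagonal clustering tolerance / window padding in bases.
#' @return A `long_read_hits` data frame: one row per hit with read
#'   coordinates (`read_start`, `read_end`, 0-based half-open), strand,
#'   query interval, identity, score, per-read union `query_cover` and
#'   `read_length`.
#' @export
scan_long_reads <- function(long_reads, query, min_identity = 0.80,
                            min_query_cover = 0.70,
                            params = mapping_params(), seed_step = 25L,
                            band = 200L) {
  if (min_query_cover <= 0 || min_query_cover > 1)
    stopf("min_query_cover must be in (0, 1]")
  k <- params$seed_k
  qlen <- nchar(query)
  if (qlen < k) stopf("query shorter than seed k-mer")
  if (is.null(names(long_reads)))
    names(long_reads) <- sprintf("longread%d", seq_along(long_reads))
  qseqs <- c(`+` = query, `-` = revcomp(query))
  qidx <- lapply(qseqs, kmer_index, k = k)

  all_hits <- list()
  for (ri in seq_along(long_reads)) {
    read <- long_reads[[ri]]
    rlen <- nchar(read)
    if (rlen < k) next
    roffs <- seq(1L, rlen - k + 1L, by = seed_step)
    rkm <- substring(read, roffs, roffs + k - 1L)
    hits <- list()
    for (st in c("+", "-")) {
      idx <- qidx[[st]]
      q <- qseqs[[st]]
      mat <- list()
      for (oi in seq_along(roffs)) {
        qpos <- idx[[rkm[oi]]]
        if (!is.null(qpos))
          mat[[length(mat) + 1L]] <- cbind(roffs[oi] - 1L - qpos, qpos)
      }
      if (length(mat) == 0L) next
      mat <- do.call(rbind, mat)
      mat <- mat[order(mat[, 1]), , drop = FALSE]
      grp <- cumsum(c(1L, diff(mat[, 1]) > band))
      for (g in split(seq_len(nrow(mat)), grp)) {
        if (length(g) < 2L) next
        dgs <- mat[g, 1]
        ws <- max(0L, min(dgs) - band)
        we <- min(rlen, max(dgs) + qlen + band)
        a <- cpp_sw_align(q, substring(read, ws + 1L, we),
                          params$match, params$mismatch,
                          params$gap_open, params$gap_ext)
        cols <- a$n_match + a$n_mismatch + a$n_ins + a$n_del
        if (cols == 0L) next
        ident <- a$n_match / cols
        qs <- a$q_start; qe <- a$q_end
        if (st == "-") { tmp <- qlen - qe; qe <- qlen - qs; qs <- tmp }
        if (ident < min_identity) next
        if ((qe - qs) / qlen < 0.05) next
        hits[[length(hits) + 1L]] <- data.frame(
          read_id = names(long_reads)[ri], read_length = rlen, strand = st,
          read_start = a$s_start + ws, read_end = a$s_end + ws,
          q_start = qs, q_end = qe,
          identity = ident, score = a$score)
      }
    }
    if (length(hits) == 0L) next
    h <- do.call(rbind, hits)
    # de-duplicate: drop hits overlapping a better hit by > 50% on the read
    h <- h[order(-h$score), , drop = FALSE]
    keep <- rep(TRUE, nrow(h))
    for (a_i in seq_len(nrow(h))) {
      if (!keep[a_i]) next
      if (a_i < nrow(h)) for (b_i in (a_i + 1L):nrow(h)) {
        if (!keep[b_i]) next
        ov <- min(h$read_end[a_i], h$read_end[b_i]) -
              max(h$read_start[a_i], h$read_start[b_i])
        if (ov > 0.5 * (h$read_end[b_i] - h$read_start[b_i])) keep[b_i] <- FALSE
      }
    }
    h <- h[keep, , drop = FALSE]
    cover <- interval_union_length(cbind(h$q_start, h$q_end)) / qlen
    if (cover < min_query_cover) next
    h$query_cover <- cover
    h <- h[order(h$read_start), , drop = FALSE]
    all_hits[[length(all_hits) + 1L]] <- h
  }
  out <- if (length(all_hits)) do.call(rbind, all_hits) else
    data.frame(read_id = character(0), read_length = integer(0),
               strand = character(0), read_start = integer(0),
               read_end = integer(0), q_start = integer(0),
               q_end = integer(0), identity = numeric(0), score = integer(0),
               query_cover = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("long_read_hits", "data.frame")
  out
}

#' Write and read alignment records as SAM
#'
#' Lossless round trip for the package's alignment fields. Internal 0-based
#' `ref_start` becomes the 1-based SAM `POS`; unaligned read ends are
#' represented as soft clips; match/mismatch columns use the explicit
#' `=`/`X` CIGAR ops. Optional tags carry the score (`AS:i`), identity
#' (`XI:f`), library (`LB:Z`) and group label (`XG:Z`).
#'
#' @param alignments An `alignment_set` data frame.
#' @param refs Named character vector of reference sequences (for `@SQ`).
#' @param path Output path.
#' @export
write_sam <- function(alignments, refs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), nchar(refs)))
  a <- alignments
  lead <- ifelse(a$read_start > 0L, sprintf("%dS", a$read_start), "")
  trail_n <- a$read_length - a$read_end
  trail <- ifelse(trail_n > 0L, sprintf("%dS", trail_n), "")
  lines <- sprintf(
    "%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\tAS:i:%d\tXI:f:%.6f\tLB:Z:%s\tXG:Z:%s",
    a$read_id, ifelse(a$strand == "-", 16L, 0L), a$ref_id, a$ref_start + 1L,
    paste0(lead, a$cigar, trail), a$seq, a$score, a$identity,
    ifelse(is.na(a$library_id), "NA", a$library_id),
    ifelse(is.na(a$group), "NA", a$group))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' @rdname write_sam
#' @return `read_sam()` returns an `alignment_set`; unmapped records are
#'   skipped and counted in `attr(x, "skipped_unmapped")`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "@"))
  n_unmapped <- 0L
  rows <- vector("list", length(body_idx)); nr <- 0L
  for (li in body_idx) {
    f <- strsplit(lines[li], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L)
      stopf("malformed SAM line %d in %s", li, path)
    flag <- suppressWarnings(as.integer(f[2]))
    if (is.na(flag)) stopf("malformed SAM line %d in %s", li, path)
    if (bitwAnd(flag, 4L) > 0L || f[3] == "*") { n_unmapped <- n_unmapped + 1L; next }
    cg <- f[6]
    ops <- parse_cigar(cg)
    if (is.null(ops)) stopf("malformed SAM line %d in %s", li, path)
    lead <- if (nrow(ops) > 0L && ops$op[1] == "S") ops$len[1] else 0L
    trail <- if (nrow(ops) > 1L && ops$op[nrow(ops)] == "S") ops$len[nrow(ops)] else 0L
    core <- ops[ops$op != "S", , drop = FALSE]
    nm <- sum(core$len[core$op == "="])
    nx <- sum(core$len[core$op == "X"])
    ni <- sum(core$len[core$op == "I"])
    nd <- sum(core$len[core$op == "D"])
    cols <- nm + nx + ni + nd
    seq <- f[10]
    tags <- f[-(1:11)]
    tagval <- function(pre, def) {
      hit <- tags[startsWith(tags, pre)]
      if (length(hit)) sub(pre, "", hit[1]) else def
    }
    lb <- tagval("LB:Z:", NA_character_); if (identical(lb, "NA")) lb <- NA_character_
    xg <- tagval("XG:Z:", NA_character_); if (identical(xg, "NA")) xg <- NA_character_
    as_tag <- suppressWarnings(as.integer(tagval("AS:i:", NA)))
    nr <- nr + 1L
    rows[[nr]] <- data.frame(
      read_id = f[1], library_id = lb, group = xg, ref_id = f[3],
      strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
      ref_start = as.integer(f[4]) - 1L,
      ref_start_dummy = NA, read_start = lead,
      read_end = nchar(seq) - trail, read_length = nchar(seq),
      score = as_tag, identity = if (cols > 0) nm / cols else 0,
      n_match = nm, n_mismatch = nx, n_ins = ni, n_del = nd,
      cigar = paste0(vapply(seq_len(nrow(core)), function(i)
        sprintf("%d%s", core$len[i], core$op[i]), character(1)), collapse = ""),
      seq = seq)
  }
  out <- if (nr > 0L) do.call(rbind, rows[seq_len(nr)]) else empty_alignment_set()
  if (nr > 0L) {
    out$ref_end <- out$ref_start +
      vapply(out$cigar, cigar_ref_span, integer(1), USE.NAMES = FALSE)
    out$ref_start_dummy <- NULL
    out <- out[, names(empty_alignment_set())]
  }
  rownames(out) <- NULL
  class(out) <- c("alignment_set", "data.frame")
  attr(out, "skipped_unmapped") <- n_unmapped
  out
}

parse_cigar <- function(cg) {
  if (cg == "*" || !grepl("^([0-9]+[=XIDSM])+$", cg)) return(NULL)
  lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
  ops <- regmatches(cg, gregexpr("[=XIDSM]", cg))[[1]]
  data.frame(len = lens, op = ops)
}

cigar_ref_span <- function(cg) {
  ops <- parse_cigar(cg)
  sum(ops$len[ops$op %in% c("=", "X", "M", "D")])
}
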