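# Internal helpers shared across modules.

# reverse complement of plain character DNA (vectorized)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# centered moving average that tolerates NA (masked) positions: the mean of
# the available values inside the window; NA where the window holds none.
moving_average_na <- function(x, window) {
  if (window <= 1L) return(x)
  v <- ifelse(is.na(x), 0, x)
  n <- as.numeric(!is.na(x))
  num <- zoo::rollapply(v, width = window, FUN = sum, partial = TRUE, align = "center")
  den <- zoo::rollapply(n, width = window, FUN = sum, partial = TRUE, align = "center")
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# maximal runs of TRUE in a logical vector (NA treated as FALSE);
# returns matrix with 0-based half-open [start, end) rows
logical_runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(start = starts[r$values], end = ends[r$values])
}

# interval set operations on 0-based half-open interval matrices
interval_union_length <- function(iv) {
  if (nrow(iv) == 0L) return(0L)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  total <- 0L; cur_s <- iv[1, 1]; cur_e <- iv[1, 2]
  if (nrow(iv) > 1L) for (k in 2:nrow(iv)) {
    if (iv[k, 1] <= cur_e) cur_e <- max(cur_e, iv[k, 2])
    else { total <- total + (cur_e - cur_s); cur_s <- iv[k, 1]; cur_e <- iv[k, 2] }
  }
  total + (cur_e - cur_s)
}

# Jaccard index between two position sets given as interval matrices
interval_jaccard <- function(a, b) {
  pa <- unlist(apply(a, 1, function(r) if (r[2] > r[1]) seq.int(r[1], r[2] - 1L) else integer(0)))
  pb <- unlist(apply(b, 1, function(r) if (r[2] > r[1]) seq.int(r[1], r[2] - 1L) else integer(0)))
  if (length(pa) == 0L && length(pb) == 0L) return(1)
  length(intersect(pa, pb)) / length(union(pa, pb))
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}
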