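#' Per-position depth of an alignment set
#'
#' `depth[p]` counts alignments whose aligned reference columns (`=`/`X`)
#' cover position p; deletion columns do not cover and insertions add no
#' columns, so the sum of the depth vector equals the total number of
#' aligned read bases on the reference.
#'
#' @param alignments An `alignment_set` (rows on a single reference).
#' @param ref_length Reference length.
#' @return Integer vector of length `ref_length`.
#' @export
pileup_depth <- function(alignments, ref_length) {
  if (nrow(alignments) == 0L) return(integer(ref_length))
  if (any(alignments$ref_start < 0L) || any(alignments$ref_end > ref_length))
    stopf("alignment outside [0, ref_length)")
  cpp_pileup(as.integer(ref_length), alignments$ref_start,
             alignments$read_start, alignments$cigar, alignments$seq)$depth
}

#' Build a coverage profile for one library on one reference
#'
#' @param alignments `alignment_set` rows for this library.
#' @param ref_id Reference name (records on other references are dropped).
#' @param ref_length Reference length.
#' @param library_id,group,assay Labels; `group` is `"0B"` or `"1B"`,
#'   `assay` one of `"gDNA"`, `"mRNA"`, `"lncRNA"`.
#' @return A `coverage_profile` object (depth vector plus labels; the
#'   normalizer is `NA` until [normalize_profiles()] sets it).
#' @export
coverage_profile <- function(alignments, ref_id, ref_length,
                             library_id, group = c("0B", "1B"),
                             assay = c("gDNA", "mRNA", "lncRNA")) {
  group <- match.arg(group)
  assay <- match.arg(assay)
  a <- alignments[alignments$ref_id == ref_id, , drop = FALSE]
  structure(list(ref_id = ref_id, library_id = library_id, group = group,
                 assay = assay, depth = pileup_depth(a, ref_length),
                 normalizer = NA_real_),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s | %s (%s, %s): length %d, mean depth %.2f%s\n",
              x$library_id, x$ref_id, x$group, x$assay, length(x$depth),
              mean(x$depth),
              if (is.na(x$normalizer)) "" else sprintf(", normalizer %.3f", x$normalizer)))
  invisible(x)
}

normalized_depth <- function(p) {
  if (is.na(p$normalizer)) stopf("profile of library '%s' is not normalized",
                                 p$library_id)
  p$depth / p$normalizer
}

#' Normalize coverage profiles by a single-copy control interval
#'
#' Each library's normalizer is its mean depth over `control_interval` on
#' the control reference — a region carried only by the diploid A copies —
#' so the control-region normalized mean is exactly 1 in every library and
#' depth ratios become copy-number ratios. All profiles of a library (any
#' reference, any assay) receive that library's normalizer.
#'
#' @param profiles List of `coverage_profile` objects.
#' @param control_interval 0-based half-open `(start, end)` interval.
#' @param control_ref Reference the interval lives on (default: the ref of
#'   the first profile).
#' @return The profile list with normalizers set.
#' @export
normalize_profiles <- function(profiles, control_interval,
                               control_ref = profiles[[1]]$ref_id) {
  s <- control_interval[1]; e <- control_interval[2]
  if (e <= s) stopf("control interval must be non-empty")
  libs <- unique(vapply(profiles, `[[`, character(1), "library_id"))
  norm <- setNames(rep(NA_real_, length(libs)), libs)
  for (p in profiles) {
    if (p$ref_id != control_ref) next
    if (e > length(p$depth)) stopf("control interval outside reference")
    m <- mean(p$depth[(s + 1L):e])
    if (m <= 0) stopf("zero control-region depth in library '%s'", p$library_id)
    norm[[p$library_id]] <- m
  }
  if (any(is.na(norm)))
    stopf("no control-reference profile for library '%s'",
          names(norm)[which(is.na(norm))[1]])
  lapply(profiles, function(p) { p$normalizer <- norm[[p$library_id]]; p })
}

# set each library's normalizer to its own mean depth (library-size style,
# used for the first pass of region calling before a control is known)
normalize_by_mean <- function(profiles) {
  lapply(profiles, function(p) {
    m <- mean(p$depth)
    if (m <= 0) stopf("zero depth in library '%s'", p$library_id)
    p$normalizer <- m
    p
  })
}

group_mean_depth <- function(profiles) {
  mats <- vapply(profiles, normalized_depth, numeric(length(profiles[[1]]$depth)))
  rowMeans(as.matrix(mats))
}

# per-position 1B/0B ratio of group-mean normalized depth; 0B-zero masked
ratio_profile <- function(group0, group1) {
  m0 <- group_mean_depth(group0)
  m1 <- group_mean_depth(group1)
  if (length(m0) != length(m1)) stopf("reference lengths differ between groups")
  ratio <- ifelse(m0 > 0, m1 / m0, NA_real_)
  list(ratio = ratio, m0 = m0, m1 = m1)
}

#' Call amplified (high-coverage 1B) regions from 0B/1B profiles
#'
#' Computes the per-position ratio of group-mean normalized 1B depth to
#' group-mean normalized 0B depth (positions with zero 0B mean are masked,
#' not treated as infinite), smooths it with a centered moving average, and
#' reports maximal runs with smoothed ratio at or above `ratio_threshold`
#' and length at least `min_length`; adjacent runs separated by less than
#' `smooth_window` are merged. The default threshold of 1.5 makes a single
#' extra copy on a diploid background (expected ratio 1.5) detectable.
#'
#' @param group0,group1 Lists of normalized `coverage_profile`s (0B, 1B).
#' @param ratio_threshold Smoothed-ratio calling threshold.
#' @param smooth_window Moving-average window in bases.
#' @param min_length Minimum reported run length in bases.
#' @param baseline_correct Divide the smoothed ratio by a baseline estimate
#'   (median of its lowest quartile) before thresholding; used on the first
#'   pass of [call_b_region()] when profiles are only library-size
#'   normalized and the single-copy baseline ratio is not yet 1.
#' @return An `amplified_region_calls` data frame (possibly empty):
#'   `ref_id, start, end, length, mean_ratio` with 0-based half-open
#'   intervals.
#' @export
detect_amplified_region <- function(group0, group1, ratio_threshold = 1.5,
                                    smooth_window = 25L, min_length = 100L,
                                    baseline_correct = FALSE) {
  if (length(group0) < 1L || length(group1) < 1L)
    stopf("need at least one profile per group")
  rp <- ratio_profile(group0, group1)
  sm <- moving_average_na(rp$ratio, smooth_window)
  sm[is.na(rp$ratio)] <- NA_real_   # masked positions are never callable
  if (baseline_correct) {
    v <- sm[!is.na(sm)]
    if (length(v)) {
      low <- v[v <= quantile(v, 0.25)]
      b <- median(low)
      if (is.finite(b) && b > 0) sm <- sm / b
    }
  }
  runs <- logical_runs(!is.na(sm) & sm >= ratio_threshold)
  # merge runs separated by < smooth_window
  if (nrow(runs) > 1L) {
    merged <- list(runs[1, ])
    for (k in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      if (runs[k, 1] - last[2] < smooth_window)
        merged[[length(merged)]] <- c(last[1], runs[k, 2])
      else merged[[length(merged) + 1L]] <- runs[k, ]
    }
    runs <- do.call(rbind, merged)
  }
  if (nrow(runs) > 0L)
    runs <- runs[runs[, 2] - runs[, 1] >= min_length, , drop = FALSE]
  ref_id <- group0[[1]]$ref_id
  out <- if (nrow(runs) == 0L) {
    data.frame(ref_id = character(0), start = integer(0), end = integer(0),
               length = integer(0), mean_ratio = numeric(0))
  } else {
    data.frame(ref_id = ref_id, start = as.integer(runs[, 1]),
               end = as.integer(runs[, 2]),
               length = as.integer(runs[, 2] - runs[, 1]),
               mean_ratio = vapply(seq_len(nrow(runs)), function(k)
                 mean(rp$ratio[(runs[k, 1] + 1L):runs[k, 2]], na.rm = TRUE),
                 numeric(1)))
  }
  class(out) <- c("amplified_region_calls", "data.frame")
  out
}

#' Estimate B-chromosome copy number from an amplified-region call
#'
#' With control-normalized profiles, the mean normalized depth of the 0B
#' group over the amplified interval is ~1 (two A copies define the unit)
#' and the 1B excess is carried by the B chromosome: the estimate is
#' `n_B = a_copies * (r_1B - r_0B)`, clipped at zero, i.e. the number of
#' pseudogene copies per B-carrying genome given `a_copies` gene copies on
#' the A chromosomes (default 2, the diploid baseline).
#'
#' @param call One row of an `amplified_region_calls` data frame (or any
#'   list with `start`/`end`).
#' @param group0,group1 Normalized profile lists.
#' @param a_copies Copies of the gene on the A chromosomes (>= 1).
#' @return A `b_copy_estimate`: `n_b`, group means `r0`/`r1`, and
#'   `per_library` 1B estimates for dispersion reporting.
#' @export
estimate_b_copy_number <- function(call, group0, group1, a_copies = 2L) {
  if (a_copies < 1L) stopf("a_copies must be >= 1")
  s <- call$start[1]; e <- call$end[1]
  if (is.null(s) || is.null(e) || e <= s) stopf("empty amplified interval")
  iv <- (s + 1L):e
  r0 <- mean(vapply(group0, function(p) mean(normalized_depth(p)[iv]), numeric(1)))
  r1lib <- vapply(group1, function(p) mean(normalized_depth(p)[iv]), numeric(1))
  names(r1lib) <- vapply(group1, `[[`, character(1), "library_id")
  r1 <- mean(r1lib)
  structure(list(n_b = max(0, a_copies * (r1 - r0)),
                 r0 = r0, r1 = r1, a_copies = a_copies,
                 interval = c(start = s, end = e),
                 per_library = setNames(pmax(0, a_copies * (r1lib - r0)),
                                        names(r1lib))),
            class = "b_copy_estimate")
}

#' @export
print.b_copy_estimate <- function(x, ...) {
  cat(sprintf(paste0("<b_copy_estimate> %.2f copies per B genome ",
                     "(r0B = %.3f, r1B = %.3f, a_copies = %d, interval [%d, %d))\n"),
              x$n_b, x$r0, x$r1, x$a_copies, x$interval["start"], x$interval["end"]))
  cat("  per-library:", paste(sprintf("%s %.2f", names(x$per_library),
                                      x$per_library), collapse = ", "), "\n")
  invisible(x)
}

#' Two-pass amplified-region calling and copy-number estimation
#'
#' The single-copy control region needed for normalization is not known
#' before the amplified region has been called, so the pipeline proceeds in
#' two passes: (1) library-size normalization with baseline correction
#' yields a provisional region; (2) the longest non-amplified segment
#' becomes the control interval, profiles are renormalized against it, and
#' the region plus copy number are re-estimated on the calibrated scale.
#'
#' @param group0,group1 Lists of raw (unnormalized) `coverage_profile`s.
#' @param ratio_threshold,smooth_window,min_length See
#'   [detect_amplified_region()].
#' @param a_copies A-chromosome copy baseline for the estimator.
#' @return List with `calls`, `copy_number` (a `b_copy_estimate` for the
#'   longest call, or `NULL` when nothing is called), `control_interval`,
#'   and the renormalized `group0`/`group1` profile lists.
#' @export
call_b_region <- function(group0, group1, ratio_threshold = 1.5,
                          smooth_window = 25L, min_length = 100L,
                          a_copies = 2L) {
  L <- length(group0[[1]]$depth)
  p0 <- normalize_by_mean(group0)
  p1 <- normalize_by_mean(group1)
  prov <- detect_amplified_region(p0, p1, ratio_threshold, smooth_window,
                                  min_length, baseline_correct = TRUE)
  if (nrow(prov) == 0L) {
    return(list(calls = prov, copy_number = NULL, control_interval = NULL,
                group0 = p0, group1 = p1))
  }
  # longest complement segment = control
  amp <- rep(FALSE, L)
  for (k in seq_len(nrow(prov))) amp[(prov$start[k] + 1L):prov$end[k]] <- TRUE
  comp <- logical_runs(!amp)
  if (nrow(comp) == 0L)
    stopf("amplified region spans the whole reference; no control available")
  comp <- comp[which.max(comp[, 2] - comp[, 1]), ]
  # trim the control away from the fuzzy smoothed edges
  pad <- min(smooth_window, floor((comp[2] - comp[1]) / 4))
  control <- c(comp[1] + pad, comp[2] - pad)
  g0 <- normalize_profiles(group0, control)
  g1 <- normalize_profiles(group1, control)
  calls <- detect_amplified_region(g0, g1, ratio_threshold, smooth_window,
                                   min_length)
  cn <- NULL
  if (nrow(calls) > 0L) {
    main <- calls[which.max(calls$length), , drop = FALSE]
    cn <- estimate_b_copy_number(main, g0, g1, a_copies)
  }
  list(calls = calls, copy_number = cn, control_interval = control,
       group0 = g0, group1 = g1)
}

#' Expression ratio profile between RNA groups
#'
#' Same ratio machinery as the amplified-region caller, but reported as an
#' underexpression summary without region calling: the per-position 1B/0B
#' ratio of group-mean normalized RNA depth (0B-zero positions masked) and
#' the ratio of group-mean coverage over the reference.
#'
#' @param group0_rna,group1_rna Lists of normalized RNA `coverage_profile`s.
#' @return List with `ratio` (per-position vector, `NA` where masked) and
#'   `mean_ratio` (ratio of mean normalized depths over unmasked positions).
#' @export
expression_ratio_profile <- function(group0_rna, group1_rna) {
  rp <- ratio_profile(group0_rna, group1_rna)
  ok <- rp$m0 > 0
  mean_ratio <- if (any(ok)) mean(rp$m1[ok]) / mean(rp$m0[ok]) else NA_real_
  list(ratio = rp$ratio, mean_ratio = mean_ratio,
       n_masked = sum(!ok))
}
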