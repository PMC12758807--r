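#' Read a Cq table from TSV
#'
#' Expected columns: `sample_id`, `group` (`0B`/`1B`), `gene`, `rep`
#' (technical replicate index), `cq` (quantification cycle).
#'
#' @param path TSV path.
#' @return A `cq_table` data frame.
#' @export
read_cq_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  cq_table(df)
}

#' @rdname read_cq_table
#' @param df Data frame with the columns above.
#' @export
cq_table <- function(df) {
  need <- c("sample_id", "group", "gene", "rep", "cq")
  if (!all(need %in% names(df)))
    stopf("Cq table needs columns: %s", paste(need, collapse = ", "))
  if (any(df$cq <= 0)) stopf("Cq values must be positive")
  class(df) <- c("cq_table", "data.frame")
  df
}

#' Normalized relative expression by the 2^-ddCq method
#'
#' Technical replicates are averaged per (sample, gene); per sample,
#' `dCq = Cq(target) - Cq(reference)`; `ddCq = dCq - mean(dCq)` over the
#' calibrator-group samples; `NREQ = 2^-ddCq`. Calibrating on the
#' arithmetic mean of the calibrator dCq makes the \emph{geometric} mean of
#' calibrator-group NREQ exactly 1; `calibration = "mean_nreq"` instead
#' divides by the calibrator arithmetic-mean NREQ.
#'
#' @param table A `cq_table`.
#' @param target_gene,reference_gene Gene names in the table.
#' @param calibrator_group Group whose mean expression defines NREQ = 1
#'   (default `"0B"`).
#' @param calibration `"mean_dcq"` (default) or `"mean_nreq"`.
#' @return Data frame with one row per sample: `sample_id`, `group`,
#'   `cq_target`, `cq_ref`, `dcq`, `ddcq`, `nreq`.
#' @export
nreq_ddcq <- function(table, target_gene, reference_gene,
                      calibrator_group = "0B",
                      calibration = c("mean_dcq", "mean_nreq")) {
  calibration <- match.arg(calibration)
  t_rows <- table[table$gene == target_gene, , drop = FALSE]
  r_rows <- table[table$gene == reference_gene, , drop = FALSE]
  samples <- unique(table$sample_id)
  agg <- function(rows, sm) {
    v <- rows$cq[rows$sample_id == sm]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  cq_t <- vapply(samples, agg, numeric(1), rows = t_rows)
  cq_r <- vapply(samples, agg, numeric(1), rows = r_rows)
  if (any(is.na(cq_r)))
    stopf("sample '%s' is missing the reference gene",
          samples[which(is.na(cq_r))[1]])
  if (any(is.na(cq_t)))
    stopf("sample '%s' is missing the target gene",
          samples[which(is.na(cq_t))[1]])
  grp <- table$group[match(samples, table$sample_id)]
  if (!any(grp == calibrator_group)) stopf("calibrator group is empty")
  dcq <- cq_t - cq_r
  ddcq <- dcq - mean(dcq[grp == calibrator_group])
  nreq <- 2^(-ddcq)
  if (calibration == "mean_nreq")
    nreq <- nreq / mean(nreq[grp == calibrator_group])
  data.frame(sample_id = samples, group = grp, cq_target = cq_t,
             cq_ref = cq_r, dcq = dcq, ddcq = ddcq, nreq = nreq,
             row.names = NULL)
}

#' Fold change between groups
#'
#' `FC = mean NREQ(0B) / mean NREQ(1B)` on arithmetic group means; the
#' log-scale alternative `2^(mean ddCq(1B) - mean ddCq(0B))` is reported
#' alongside since the two coincide only without inter-sample variance.
#'
#' @param nreq Output of [nreq_ddcq()].
#' @param num_group,den_group Numerator and denominator groups.
#' @return List with `fc` (arithmetic, the default definition) and
#'   `fc_log_scale`.
#' @export
fold_change <- function(nreq, num_group = "0B", den_group = "1B") {
  v0 <- nreq$nreq[nreq$group == num_group]
  v1 <- nreq$nreq[nreq$group == den_group]
  if (length(v0) == 0L || length(v1) == 0L) stopf("both groups must be non-empty")
  d0 <- nreq$ddcq[nreq$group == num_group]
  d1 <- nreq$ddcq[nreq$group == den_group]
  list(fc = mean(v0) / mean(v1),
       fc_log_scale = 2^(mean(d1) - mean(d0)))
}

#' Two-group effect size with BCa bootstrap confidence interval
#'
#' The estimation-statistics companion of a Gardner-Altman plot: the effect
#' is `mean(values_1b) - mean(values_0b)`; the confidence interval comes
#' from a bias-corrected-and-accelerated (BCa) bootstrap of the mean
#' difference, resampling within groups, with the acceleration constant
#' from a leave-one-out jackknife over all observations. Degenerate
#' resamples (zero bootstrap variance) collapse the interval onto the
#' observed effect. Fully reproducible given `seed`.
#'
#' @param values_0b,values_1b Numeric vectors (n >= 2 each).
#' @param n_boot Bootstrap resamples (default 5000).
#' @param seed RNG seed.
#' @param conf Confidence level (default 0.95).
#' @return A `gardner_altman` list: `effect`, `ci` (lower, upper),
#'   `boot_dist`, group summaries, `n_boot`, `seed`.
#' @export
gardner_altman <- function(values_0b, values_1b, n_boot = 5000L, seed = 1L,
                           conf = 0.95) {
  if (length(values_0b) < 2L || length(values_1b) < 2L)
    stopf("need at least 2 observations per group")
  if (n_boot < 1000L) stopf("n_boot must be >= 1000")
  n0 <- length(values_0b); n1 <- length(values_1b)
  effect <- mean(values_1b) - mean(values_0b)
  set.seed(seed)
  i0 <- matrix(sample.int(n0, n0 * n_boot, replace = TRUE), nrow = n_boot)
  i1 <- matrix(sample.int(n1, n1 * n_boot, replace = TRUE), nrow = n_boot)
  boot <- rowMeans(matrix(values_1b[i1], nrow = n_boot)) -
          rowMeans(matrix(values_0b[i0], nrow = n_boot))
  alpha <- (1 - conf) / 2
  if (stats::var(boot) == 0) {
    ci <- c(effect, effect)
  } else {
    # bias correction
    z0 <- qnorm((sum(boot < effect) + 0.5 * sum(boot == effect)) / n_boot)
    # acceleration from a delete-one jackknife over all observations
    jack <- c(
      vapply(seq_len(n0), function(k) mean(values_1b) - mean(values_0b[-k]),
             numeric(1)),
      vapply(seq_len(n1), function(k) mean(values_1b[-k]) - mean(values_0b),
             numeric(1)))
    jm <- mean(jack)
    denom <- sum((jm - jack)^2)^1.5
    a <- if (denom == 0) 0 else sum((jm - jack)^3) / (6 * denom)
    adj <- function(al) {
      z <- z0 + qnorm(al)
      pnorm(z0 + z / (1 - a * z))
    }
    ci <- unname(quantile(boot, probs = c(adj(alpha), adj(1 - alpha)),
                          type = 7))
  }
  structure(list(effect = effect, ci = ci, conf = conf,
                 boot_dist = boot, n_boot = as.integer(n_boot),
                 seed = as.integer(seed),
                 group_means = c(`0B` = mean(values_0b), `1B` = mean(values_1b)),
                 values_0b = values_0b, values_1b = values_1b),
            class = "gardner_altman")
}

#' @export
print.gardner_altman <- function(x, ...) {
  cat(sprintf("<gardner_altman> mean difference (1B - 0B) = %.4f, %d%% CI [%.4f, %.4f] (BCa, %d resamples)\n",
              x$effect, round(100 * x$conf), x$ci[1], x$ci[2], x$n_boot))
  invisible(x)
}

#' Gardner-Altman estimation plot
#'
#' Two-axis layout: raw per-sample values of both groups on the left axis;
#' the bootstrap distribution of the mean difference on a floating right
#' axis, with the observed difference as a black dot and the confidence
#' interval as the ends of the vertical bar.
#'
#' @param x A `gardner_altman` object.
#' @param ylab Left-axis label.
#' @param ... Ignored.
#' @export
plot.gardner_altman <- function(x, ylab = "NREQ", ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  g <- c(rep(1, length(x$values_0b)), rep(2, length(x$values_1b)))
  v <- c(x$values_0b, x$values_1b)
  graphics::plot(jitter(g, amount = 0.05), v, xlim = c(0.5, 2.5),
                 xaxt = "n", xlab = "", ylab = ylab, pch = 19,
                 col = c("#4477AA", "#EE6677")[g])
  graphics::axis(1, at = 1:2, labels = c("0B", "1B"))
  graphics::segments(0.8, x$group_means[1], 1.2, x$group_means[1])
  graphics::segments(1.8, x$group_means[2], 2.2, x$group_means[2])
  d <- stats::density(x$boot_dist)
  graphics::plot(d$y, d$x, type = "l", xlab = "bootstrap density",
                 ylab = "mean difference (1B - 0B)")
  graphics::abline(h = 0, lty = 3)
  graphics::points(max(d$y) * 0.05, x$effect, pch = 19)
  graphics::segments(max(d$y) * 0.05, x$ci[1], max(d$y) * 0.05, x$ci[2])
  invisible(x)
}

#' RT-qPCR relative-expression analysis
#'
#' Convenience wrapper chaining [nreq_ddcq()], [fold_change()] and
#' [gardner_altman()] into one classed result.
#'
#' @inheritParams nreq_ddcq
#' @inheritParams gardner_altman
#' @return An `nreq_fit` object with `per_sample`, `fc`, `fc_log_scale`,
#'   `effect` (a `gardner_altman`).
#' @export
rtqpcr_analysis <- function(table, target_gene, reference_gene,
                            calibrator_group = "0B", n_boot = 5000L,
                            seed = 1L,
                            calibration = c("mean_dcq", "mean_nreq")) {
  per_sample <- nreq_ddcq(table, target_gene, reference_gene,
                          calibrator_group, calibration)
  fc <- fold_change(per_sample)
  ga <- gardner_altman(per_sample$nreq[per_sample$group == "0B"],
                       per_sample$nreq[per_sample$group == "1B"],
                       n_boot = n_boot, seed = seed)
  structure(list(per_sample = per_sample, fc = fc$fc,
                 fc_log_scale = fc$fc_log_scale, effect = ga,
                 target_gene = target_gene, reference_gene = reference_gene),
            class = "nreq_fit")
}

#' @export
print.nreq_fit <- function(x, ...) {
  cat(sprintf("<nreq_fit> %s (reference %s)\n", x$target_gene, x$reference_gene))
  cat(sprintf("  fold change 0B/1B: %.2f (log-scale %.2f)\n",
              x$fc, x$fc_log_scale))
  print(x$effect)
  invisible(x)
}

#' @export
summary.nreq_fit <- function(object, ...) {
  print(object)
  cat("\nPer-sample NREQ:\n")
  print(object$per_sample, row.names = FALSE)
  invisible(object)
}

#' @export
plot.nreq_fit <- function(x, ...) plot(x$effect, ...)
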