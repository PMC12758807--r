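#' Coverage contrast plot
#'
#' Per-library normalized depth over the spliced gene, 0B libraries in
#' blue and 1B in red, with called amplified regions shaded — the layout
#' conventionally used to show a truncated pseudogene's high-coverage B
#' region.
#'
#' @param group0,group1 Lists of normalized `coverage_profile`s.
#' @param calls Optional `amplified_region_calls` to shade.
#' @param main Plot title.
#' @export
plot_coverage <- function(group0, group1, calls = NULL, main = "") {
  L <- length(group0[[1]]$depth)
  ymax <- max(vapply(c(group0, group1),
                     function(p) max(normalized_depth(p)), numeric(1)))
  graphics::plot(NULL, xlim = c(0, L), ylim = c(0, ymax * 1.05),
                 xlab = "spliced position (bp)", ylab = "normalized depth",
                 main = main)
  if (!is.null(calls) && nrow(calls) > 0L) {
    for (k in seq_len(nrow(calls)))
      graphics::rect(calls$start[k], 0, calls$end[k], ymax * 1.05,
                     col = "#FFEECC", border = NA)
  }
  for (p in group0)
    graphics::lines(seq_len(L) - 1L, normalized_depth(p), col = "#4477AA")
  for (p in group1)
    graphics::lines(seq_len(L) - 1L, normalized_depth(p), col = "#EE6677")
  graphics::legend("topleft", legend = c("0B", "1B"), bty = "n",
                   col = c("#4477AA", "#EE6677"), lty = 1)
  invisible(NULL)
}
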