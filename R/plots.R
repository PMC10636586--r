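# Simple base-graphics reports: a genetic-correlation heatmap and a
# per-instrument forest plot. Deliberately plain; the numeric tables the
# pipeline writes are the primary record.

#' Heatmap of genetic correlations with FDR significance marks
#'
#' @param report a `correlation_report` from [correlation_report()].
#' @param file optional path to write a PNG instead of drawing on the
#'   active device.
#' @param fdr_threshold correlations with FDR-adjusted p below this get
#'   an asterisk.
#' @return Invisibly, the correlation matrix drawn.
#' @export
plot_rg_heatmap <- function(report, file = NULL, fdr_threshold = 0.05) {
  rg <- report$rg
  k <- ncol(rg)
  if (!is.null(file)) {
    grDevices::png(file, width = 720, height = 680)
    on.exit(grDevices::dev.off())
  }
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  op <- graphics::par(mar = c(6, 6, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::image(seq_len(k), seq_len(k), t(rg[k:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(k), labels = colnames(rg), las = 2)
  graphics::axis(2, at = seq_len(k), labels = rev(rownames(rg)), las = 1)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    lab <- sprintf("%.2f", rg[i, j])
    if (i != j && !is.na(report$p_fdr[i, j]) &&
        report$p_fdr[i, j] < fdr_threshold)
      lab <- paste0(lab, "*")
    graphics::text(j, k + 1 - i, lab, cex = 0.7)
  }
  invisible(rg)
}

#' Forest plot of per-instrument Wald ratios for one MR direction
#'
#' @param bmr a `bidirectional_mr` result.
#' @param direction `"forward"` or `"reverse"`.
#' @param file optional PNG path.
#' @return Invisibly, the forest data frame drawn.
#' @export
plot_mr_forest <- function(bmr, direction = c("forward", "reverse"),
                           file = NULL) {
  direction <- match.arg(direction)
  dirres <- bmr[[direction]]
  if (is.null(dirres$methods)) stop("direction was not estimable")
  is <- dirres$instruments
  ratio <- is$beta_out / is$beta_exp
  se <- sqrt(is$se_out^2 / is$beta_exp^2 +
               is$beta_out^2 * is$se_exp^2 / is$beta_exp^4)
  ord <- order(ratio)
  ratio <- ratio[ord]; se <- se[ord]; snp <- is$snp[ord]
  n <- length(ratio)
  ivw <- dirres$methods$ivw
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 120 + 22 * n)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mar = c(4, 8, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  xlim <- range(c(ratio - 2 * se, ratio + 2 * se, 0, ivw$beta))
  graphics::plot(ratio, seq_len(n), xlim = xlim, ylim = c(0, n + 1),
                 pch = 15, axes = FALSE, xlab = "causal estimate (Wald ratio)",
                 ylab = "")
  graphics::segments(ratio - 1.96 * se, seq_len(n),
                     ratio + 1.96 * se, seq_len(n))
  graphics::axis(1)
  graphics::axis(2, at = seq_len(n), labels = snp, las = 1, cex.axis = 0.7)
  graphics::abline(v = 0, lty = 3)
  graphics::abline(v = ivw$beta, col = "#B2182B")
  graphics::mtext(sprintf("IVW %.3f (SE %.3f)", ivw$beta, ivw$se), cex = 0.8)
  invisible(data.frame(snp = snp, ratio = ratio, se = se))
}
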