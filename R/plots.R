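#' Manhattan plot of a dAF scan
#'
#' Plots each window's -log10 empirical p-value along the genome, scaffolds
#' laid end to end in order of appearance, with horizontal lines at the
#' p-values corresponding to the null percentile thresholds.
#'
#' @param scan A `daf_scan` from [lineage_scan()].
#' @return A ggplot object.
#' @export
plot_manhattan <- function(scan) {
  stopifnot(inherits(scan, "daf_scan"))
  w <- scan$windows
  if (nrow(w) == 0L) abort("scan has no windows to plot")
  scafs <- unique(w$scaffold)
  span <- vapply(scafs, function(s) max(w$end[w$scaffold == s]), numeric(1))
  offset <- setNames(cumsum(c(0, head(span, -1))), scafs)
  w$x <- offset[w$scaffold] + (w$start + w$end) / 2
  w$parity <- factor(match(w$scaffold, scafs) %% 2L)
  thr_p <- vapply(names(scan$null$thresholds), function(k) {
    n_ge <- sum(scan$null$values >= scan$null$thresholds[[k]])
    (1 + n_ge) / (1 + length(scan$null$values))
  }, numeric(1))
  ggplot2::ggplot(w, ggplot2::aes(x = .data$x, y = -log10(.data$p),
                                  colour = .data$parity)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(thr_p), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c("grey35", "grey65")) +
    ggplot2::labs(x = "genome position (scaffolds in order)",
                  y = expression(-log[10](p)),
                  title = paste0("dAF scan",
                                 if (!is.null(scan$lineage))
                                   paste0(" - ", scan$lineage))) +
    ggplot2::theme_minimal()
}

#' Histogram of the permutation null with thresholds
#'
#' @param object A `daf_null` from [build_null()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.daf_null <- function(object, ...) {
  df <- tibble(stat = object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 100, fill = "grey70") +
    ggplot2::geom_vline(xintercept = unname(object$thresholds),
                        linetype = "dashed") +
    ggplot2::labs(x = "window statistic (null)", y = "count",
                  title = paste0("Permutation null (",
                                 object$n_perm, " permutations)")) +
    ggplot2::theme_minimal()
}

#' Cross-lineage convergence heat map
#'
#' Tiles of mean standardized dAF for the target lineage's outlier windows
#' (rows) in every lineage (columns); excluded cells (fewer SNPs than the
#' minimum) are blank.
#'
#' @param object A `convergence_tbl` from [convergence_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.convergence_tbl <- function(object, ...) {
  if (nrow(object) == 0L) abort("empty convergence matrix")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$lineage,
                               y = factor(.data$window_id),
                               fill = .data$mean_z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(x = "lineage", y = "outlier window",
                  fill = "mean z",
                  title = paste0("Convergence heat map (target: ",
                                 attr(object, "target") %||% "?", ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
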