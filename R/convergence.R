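#' Cross-lineage dAF heat-map matrix
#'
#' For each 99.9th-percentile outlier window of the target lineage, computes
#' the mean standardized dAF (`mean_z`) of every lineage's SNPs falling in
#' the same genomic span. A cell is excluded (NA) when that lineage has
#' fewer than `min_snps` SNPs in the span. The target lineage's own column
#' reproduces the scan's window statistics.
#'
#' @param scan A `daf_scan` for the target lineage (see [lineage_scan()]).
#' @param dafs Named list of per-lineage per-SNP statistic tibbles from
#'   [snp_daf()] (`scaffold`, `pos`, `mean_z`), on shared reference
#'   coordinates. May include the target lineage.
#' @param percentile Which outlier set of the scan to use (default `99.9`).
#' @param min_snps Minimum SNPs per cell (default 2; cells below are
#'   excluded).
#' @return A tibble of class `convergence_tbl`, long format: `window_id`,
#'   `scaffold`, `start`, `end`, `lineage`, `n_snps`, `mean_z`, `excluded`.
#' @export
convergence_matrix <- function(scan, dafs, percentile = 99.9, min_snps = 2L) {
  stopifnot(inherits(scan, "daf_scan"), is.list(dafs), !is.null(names(dafs)))
  key <- pct_key(percentile)
  wins <- scan$outliers[[key]]
  if (is.null(wins) || nrow(wins) == 0L) {
    warn(paste0("target lineage has no ", key, "th-percentile outlier windows"))
    out <- tibble(window_id = integer(), scaffold = character(),
                  start = integer(), end = integer(), lineage = character(),
                  n_snps = integer(), mean_z = double(), excluded = logical())
    class(out) <- c("convergence_tbl", class(out))
    return(out)
  }
  rows <- lapply(names(dafs), function(lin) {
    d <- dafs[[lin]]
    cells <- span_mean_z(wins, d)
    tibble(window_id = seq_len(nrow(wins)), scaffold = wins$scaffold,
           start = wins$start, end = wins$end, lineage = lin,
           n_snps = cells$n,
           mean_z = ifelse(cells$n >= min_snps, cells$mean_z, NA_real_),
           excluded = cells$n < min_snps)
  })
  out <- bind_rows(rows)
  attr(out, "target") <- scan$lineage
  attr(out, "percentile") <- percentile
  class(out) <- c("convergence_tbl", class(out))
  out
}

# mean of mean_z over SNPs of `daf` inside each window span
span_mean_z <- function(wins, daf) {
  daf <- arrange(daf, .data$scaffold, .data$pos)
  n <- integer(nrow(wins))
  mz <- rep(NA_real_, nrow(wins))
  for (sc in unique(wins$scaffold)) {
    wr <- which(wins$scaffold == sc)
    dr <- which(daf$scaffold == sc)
    if (!length(dr)) next
    pos <- daf$pos[dr]
    cs <- cumsum(c(0, daf$mean_z[dr]))
    lo <- findInterval(wins$start[wr] - 1L, pos) + 1L
    hi <- findInterval(wins$end[wr], pos)
    cnt <- pmax(hi - lo + 1L, 0L)
    n[wr] <- cnt
    ok <- cnt > 0L
    mz[wr[ok]] <- (cs[hi[ok] + 1L] - cs[lo[ok]]) / cnt[ok]
  }
  list(n = n, mean_z = mz)
}

#' Export a convergence matrix as TSV
#'
#' Wide format: one row per window, one column per lineage; excluded cells
#' (fewer than the minimum SNPs) are written as `NA:lt2snps`.
#'
#' @param cm A `convergence_tbl` from [convergence_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_convergence_matrix <- function(cm, path) {
  wide <- tidyr::pivot_wider(
    mutate(cm, cell = ifelse(.data$excluded, "NA:lt2snps",
                             format(.data$mean_z, trim = TRUE))),
    id_cols = c("window_id", "scaffold", "start", "end"),
    names_from = "lineage", values_from = "cell"
  )
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Shared nonsynonymous-site convergence test
#'
#' Finds sites that are nonsynonymous in both lineages (matched by scaffold
#' and position; effect tables carry no allele phase, so alleles are not
#' compared) and asks, for each, whether its per-site standardized dAF
#' (`mean_z`) reaches the nearest-rank `percentile` of `mean_z` over *all*
#' nonsynonymous sites within each lineage. The headline count is the number
#' of shared sites in the top tail of both lineages.
#'
#' @param daf_a,daf_b Per-site statistic tibbles from [snp_daf()] for the
#'   two lineages.
#' @param effects_a,effects_b Effect tables (`scaffold`, `pos`, `effect`).
#' @param percentile Tail percentile (default 95).
#' @param units Optional length-2 names for the lineages.
#' @return Object of class `shared_nonsyn`: list with `sites` (tibble of
#'   shared nonsynonymous sites with per-lineage z and top-tail flags),
#'   `thresholds`, `n_shared`, `n_top_both`, `percentile`.
#' @export
shared_nonsyn_test <- function(daf_a, effects_a, daf_b, effects_b,
                               percentile = 95, units = c("A", "B")) {
  za <- nonsyn_z(daf_a, effects_a, units[1])
  zb <- nonsyn_z(daf_b, effects_b, units[2])
  thr_a <- nearest_rank(za$mean_z, percentile)
  thr_b <- nearest_rank(zb$mean_z, percentile)
  shared <- inner_join(
    rename(za, z_a = "mean_z"), rename(zb, z_b = "mean_z"),
    by = c("scaffold", "pos")
  )
  shared$top_a <- shared$z_a >= thr_a
  shared$top_b <- shared$z_b >= thr_b
  shared$top_both <- shared$top_a & shared$top_b
  structure(
    list(sites = shared,
         thresholds = setNames(c(thr_a, thr_b), units),
         n_shared = nrow(shared),
         n_top_both = sum(shared$top_both),
         percentile = percentile, units = units),
    class = "shared_nonsyn"
  )
}

nonsyn_z <- function(daf, effects, unit) {
  if (is.null(effects) || nrow(effects) == 0L) {
    abort(paste0("empty effect table for lineage '", unit, "'"))
  }
  ns <- effects[effects$effect == "nonsynonymous", c("scaffold", "pos")]
  out <- inner_join(ns, daf, by = c("scaffold", "pos"))
  if (nrow(out) == 0L) {
    abort(paste0("no nonsynonymous SNPs for lineage '", unit, "'"))
  }
  out[, c("scaffold", "pos", "mean_z")]
}

#' @export
print.shared_nonsyn <- function(x, ...) {
  cat("Shared nonsynonymous-site test (", x$units[1], " vs ", x$units[2],
      ")\n", sep = "")
  cat("  shared nonsynonymous sites:", x$n_shared, "\n")
  cat(sprintf("  at or above the %gth percentile in both lineages: %d\n",
              x$percentile, x$n_top_both))
  invisible(x)
}

#' @rdname tidy.daf_scan
#' @export
tidy.shared_nonsyn <- function(x, ...) x$sites

#' @rdname tidy.daf_scan
#' @export
glance.shared_nonsyn <- function(x, ...) {
  tibble(unit_a = x$units[1], unit_b = x$units[2],
         percentile = x$percentile, n_shared = x$n_shared,
         n_top_both = x$n_top_both,
         threshold_a = unname(x$thresholds[1]),
         threshold_b = unname(x$thresholds[2]))
}

#' Write the shared nonsynonymous-site report to TSV
#' @param x A `shared_nonsyn` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shared_nonsyn <- function(x, path) {
  readr::write_tsv(x$sites, path)
  invisible(path)
}
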