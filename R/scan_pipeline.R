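#' Per-SNP standardized dAF statistic
#'
#' Convenience wrapper: [pair_daf()] followed by [standardize_daf()],
#' returning the per-SNP `mean_z` track used by the window scan and the
#' cross-lineage convergence analyses.
#'
#' @inheritParams pair_daf
#' @inheritParams standardize_daf
#' @return Tibble `scaffold`, `pos`, `mean_z`.
#' @export
snp_daf <- function(snps, anad = NULL, fresh = NULL, pooled = FALSE) {
  z <- standardize_daf(pair_daf(snps, anad = anad, fresh = fresh),
                       pooled = pooled)
  tibble(scaffold = z$scaffold, pos = z$pos, mean_z = z$mean_z)
}

#' Full dAF outlier scan for one lineage
#'
#' Runs the whole genome scan: per-SNP standardized dAF averaged over all
#' anadromous x freshwater pool pairs, sliding 20-SNP/10-step windows on the
#' longest scaffolds, a label-permutation null with random window offsets,
#' empirical p-values, percentile outlier calls, and merging of outlier
#' windows into genomic outlier regions (with optional gene annotation).
#'
#' @inheritParams build_null
#' @param snps SNP table from [call_snps()].
#' @param merge_gap Merge distance for outlier windows in bases
#'   (default 20000).
#' @param genes Optional gene tibble for region annotation.
#' @param gene_flank Gene-annotation flank in bases (default 20000).
#' @return An object of class `daf_scan`: list with elements `daf` (per-SNP
#'   statistic), `windows` (with `p` and `outlier_<pct>` flags), `null`,
#'   `outliers` and `regions` (named lists keyed by percentile), `lineage`,
#'   and `params`.
#' @export
lineage_scan <- function(snps, n_perm = 1000L, seed = 1L, window = 20L,
                         step = 10L, top_scaffolds = 1000L,
                         scaffold_lengths = NULL, percentiles = c(99, 99.9),
                         merge_gap = 20000L, genes = NULL,
                         gene_flank = 20000L, pooled = FALSE) {
  daf <- snp_daf(snps, pooled = pooled)
  windows <- window_scan(daf, window = window, step = step, offset = 1L,
                         top_scaffolds = top_scaffolds,
                         scaffold_lengths = scaffold_lengths)
  null <- build_null(snps, n_perm = n_perm, seed = seed, window = window,
                     step = step, top_scaffolds = top_scaffolds,
                     scaffold_lengths = scaffold_lengths,
                     percentiles = percentiles, pooled = pooled)
  windows <- window_pvalues(windows, null)
  keys <- pct_key(percentiles)
  outliers <- list()
  regions <- list()
  for (i in seq_along(percentiles)) {
    windows[[paste0("outlier_", keys[i])]] <-
      windows$stat >= null$thresholds[[keys[i]]]
    out_i <- call_outliers(windows, null, percentiles[i])
    reg_i <- merge_regions(out_i, gap = merge_gap)
    if (!is.null(genes)) reg_i <- annotate_genes(reg_i, genes, flank = gene_flank)
    outliers[[keys[i]]] <- out_i
    regions[[keys[i]]] <- reg_i
  }
  structure(
    list(daf = daf, windows = windows, null = null, outliers = outliers,
         regions = regions, lineage = attr(snps, "lineage"),
         params = list(n_perm = n_perm, seed = seed, window = window,
                       step = step, top_scaffolds = top_scaffolds,
                       percentiles = percentiles, merge_gap = merge_gap,
                       gene_flank = gene_flank, pooled = pooled)),
    class = "daf_scan"
  )
}

#' Outlier scan for a single freshwater population
#'
#' Reruns the full scan using only the pool pairs that involve one chosen
#' freshwater population (against all the lineage's anadromous pools); used
#' to measure parallelism between freshwater populations within a lineage.
#'
#' @inheritParams lineage_scan
#' @param fresh_pool Name of the freshwater pool to scan.
#' @return A `daf_scan` object (see [lineage_scan()]).
#' @export
population_scan <- function(snps, fresh_pool, ...) {
  pools <- snp_pools(snps)
  if (!fresh_pool %in% pools$pool[pools$life_history == "freshwater"]) {
    abort(paste0("'", fresh_pool, "' is not a freshwater pool of this lineage"))
  }
  keep <- pools$life_history == "anadromous" | pools$pool == fresh_pool
  sub <- snp_attrs(snps, pools[keep, , drop = FALSE],
                   attr(snps, "lineage"), attr(snps, "mean_cov")[keep])
  res <- lineage_scan(sub, ...)
  res$fresh_pool <- fresh_pool
  res
}

#' @export
print.daf_scan <- function(x, ...) {
  cat("dAF genome scan", if (!is.null(x$lineage)) paste0("(", x$lineage, ")"),
      "\n")
  cat("  SNPs:", nrow(x$daf), " windows:", nrow(x$windows), "\n")
  for (k in names(x$outliers)) {
    cat(sprintf("  %sth pct: %d outlier windows -> %d regions\n",
                k, nrow(x$outliers[[k]]), nrow(x$regions[[k]])))
  }
  invisible(x)
}

#' Tidy and summarise scan objects
#'
#' `tidy()` on a `daf_scan` returns the window table (one row per window,
#' with p-values and outlier flags); on a `daf_null` it returns the
#' percentile thresholds. `glance()` returns a one-row summary.
#'
#' @param x A `daf_scan` or `daf_null` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.daf_scan <- function(x, ...) x$windows

#' @rdname tidy.daf_scan
#' @export
glance.daf_scan <- function(x, ...) {
  keys <- names(x$outliers)
  out <- tibble(lineage = x$lineage %||% NA_character_,
                n_snps = nrow(x$daf), n_windows = nrow(x$windows),
                n_perm = x$null$n_perm, seed = x$params$seed)
  for (k in keys) {
    out[[paste0("threshold_", k)]] <- x$null$thresholds[[k]]
    out[[paste0("n_outliers_", k)]] <- nrow(x$outliers[[k]])
    out[[paste0("n_regions_", k)]] <- nrow(x$regions[[k]])
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
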