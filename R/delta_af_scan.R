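#' Per-SNP allele-frequency differences for all anadromous x freshwater pairs
#'
#' For every SNP and every (anadromous, freshwater) pool pair within the
#' lineage, computes the raw absolute allele-frequency difference
#' `|freq_fresh - freq_anad|`. The absolute value is used because allele
#' labels are arbitrary across populations; the statistic is one-sided on
#' magnitude.
#'
#' @param snps SNP table from [call_snps()].
#' @param anad,fresh Optional character vectors of pool names overriding the
#'   life-history grouping in the attached manifest.
#' @return Tibble `scaffold`, `pos`, then one column per pair named
#'   `d_<anad>..<fresh>`. Attribute `pairs` is a tibble (`anad`, `fresh`,
#'   `name`) describing the columns.
#' @export
pair_daf <- function(snps, anad = NULL, fresh = NULL) {
  pools <- snp_pools(snps)
  if (is.null(anad)) anad <- pools$pool[pools$life_history == "anadromous"]
  if (is.null(fresh)) fresh <- pools$pool[pools$life_history == "freshwater"]
  if (length(anad) == 0L) abort("no anadromous pools in group")
  if (length(fresh) == 0L) abort("no freshwater pools in group")
  f <- freq_matrix(snps)
  pairs <- tidyr::expand_grid(anad = anad, fresh = fresh)
  pairs$name <- paste0("d_", pairs$anad, "..", pairs$fresh)
  out <- tibble(scaffold = snps$scaffold, pos = snps$pos)
  for (k in seq_len(nrow(pairs))) {
    out[[pairs$name[k]]] <- abs(f[, pairs$fresh[k]] - f[, pairs$anad[k]])
  }
  attr(out, "pairs") <- pairs
  out
}

daf_pairs <- function(daf) {
  p <- attr(daf, "pairs")
  if (is.null(p)) abort("not a pair_daf() result: no `pairs` attribute")
  p
}

#' Standardize per-pair dAF genome-wide and average over pairs
#'
#' Each pair's raw differences are centred on their genome-wide mean and
#' divided by their genome-wide standard deviation (population form,
#' divide-by-n), computed over all SNPs of the lineage. The per-pair z-scores
#' are then averaged across pairs into `mean_z`, the per-SNP scan statistic.
#' Per-pair scaling removes pair-specific drift baselines; set
#' `pooled = TRUE` to instead standardize against the mean/sd of all pairs'
#' values pooled.
#'
#' @param daf Result of [pair_daf()].
#' @param pooled Standardize against the pooled distribution over all pairs
#'   rather than per pair (default `FALSE`).
#' @return `daf` with per-pair `z_` columns and a `mean_z` column added.
#' @export
standardize_daf <- function(daf, pooled = FALSE) {
  pairs <- daf_pairs(daf)
  d <- as.matrix(daf[, pairs$name, drop = FALSE])
  z <- standardize_core(d, pairs$name, pooled = pooled)
  out <- daf
  zn <- sub("^d_", "z_", pairs$name)
  for (k in seq_along(zn)) out[[zn[k]]] <- z[, k]
  out$mean_z <- rowMeans(z)
  attr(out, "pairs") <- pairs
  out
}

# d: sites x pairs raw |dAF|; returns z matrix. Population (divide-by-n) sd.
standardize_core <- function(d, pair_names, pooled = FALSE) {
  if (nrow(d) < 2L) abort("standardization needs at least 2 SNPs")
  if (pooled) {
    m <- mean(d)
    s <- sqrt(mean((d - m)^2))
    if (s == 0) abort("dAF values are constant across all pairs; sd is zero")
    return((d - m) / s)
  }
  z <- d
  for (k in seq_len(ncol(d))) {
    m <- mean(d[, k])
    s <- sqrt(mean((d[, k] - m)^2))
    if (s == 0) {
      abort(paste0("pair '", pair_names[k],
                   "' has constant dAF; standard deviation is zero"))
    }
    z[, k] <- (d[, k] - m) / s
  }
  z
}

# mean_z straight from the frequency matrix; the permutation hot path.
daf_mean_z_core <- function(f, anad_idx, fresh_idx, pooled = FALSE) {
  n <- nrow(f)
  if (pooled) {
    np <- length(anad_idx) * length(fresh_idx)
    d <- matrix(0, n, np)
    k <- 0L
    for (i in anad_idx) for (j in fresh_idx) {
      k <- k + 1L
      d[, k] <- abs(f[, j] - f[, i])
    }
    m <- mean(d)
    s <- sqrt(mean((d - m)^2))
    if (s == 0) abort("dAF values are constant; standard deviation is zero")
    return(rowMeans((d - m) / s))
  }
  acc <- numeric(n)
  for (i in anad_idx) for (j in fresh_idx) {
    d <- abs(f[, j] - f[, i])
    m <- sum(d) / n
    s <- sqrt(sum((d - m)^2) / n)
    if (s == 0) {
      abort(paste0("pair '", colnames(f)[i], "'..'", colnames(f)[j],
                   "' has constant dAF; standard deviation is zero"))
    }
    acc <- acc + (d - m) / s
  }
  acc / (length(anad_idx) * length(fresh_idx))
}

#' Select the scaffolds to scan
#'
#' Keeps the `top_scaffolds` longest scaffolds; smaller scaffolds are
#' typically enriched in repeats and are excluded from windowing. Ties are
#' broken by scaffold name for determinism.
#'
#' @param scaffold_lengths Named numeric vector of scaffold lengths in bp.
#' @param top_scaffolds How many scaffolds to keep (default 1000).
#' @return Character vector of retained scaffold names.
#' @export
top_scaffold_names <- function(scaffold_lengths, top_scaffolds = 1000L) {
  o <- order(-scaffold_lengths, names(scaffold_lengths))
  names(scaffold_lengths)[o][seq_len(min(top_scaffolds, length(scaffold_lengths)))]
}

#' Sliding-window scan statistic
#'
#' Aggregates the per-SNP `mean_z` statistic into windows of `window`
#' consecutive SNPs, advancing by `step` SNPs, separately along each
#' scaffold. Only full windows are emitted; windows start at SNP indices
#' `offset, offset + step, ...` within each scaffold. When
#' `scaffold_lengths` is supplied, only the `top_scaffolds` longest
#' scaffolds are scanned.
#'
#' @param daf Tibble with columns `scaffold`, `pos`, `mean_z`, sorted by
#'   (scaffold, pos) — e.g. the output of [standardize_daf()].
#' @param window SNPs per window (default 20).
#' @param step SNPs between window starts (default 10).
#' @param offset 1-based SNP index of the first window on each scaffold
#'   (default 1).
#' @param top_scaffolds Number of longest scaffolds scanned when
#'   `scaffold_lengths` is given (default 1000).
#' @param scaffold_lengths Optional named vector of scaffold lengths; `NULL`
#'   scans every scaffold present.
#' @return Tibble with `scaffold`, `snp_start_index`, `start`, `end`,
#'   `n_snps`, `stat` (window mean of `mean_z`).
#' @export
window_scan <- function(daf, window = 20L, step = 10L, offset = 1L,
                        top_scaffolds = 1000L, scaffold_lengths = NULL) {
  stopifnot(window >= 1L, step >= 1L, offset >= 1L, offset <= window)
  if (!is.null(scaffold_lengths)) {
    keep <- top_scaffold_names(scaffold_lengths, top_scaffolds)
    daf <- daf[daf$scaffold %in% keep, , drop = FALSE]
  }
  if (nrow(daf) == 0L) {
    return(tibble(scaffold = character(), snp_start_index = integer(),
                  start = integer(), end = integer(), n_snps = integer(),
                  stat = double()))
  }
  runs <- rle(daf$scaffold)
  ends <- cumsum(runs$lengths)
  begins <- ends - runs$lengths + 1L
  res <- vector("list", length(runs$values))
  for (r in seq_along(runs$values)) {
    n <- runs$lengths[r]
    if (n - window + 1L < offset) next
    starts_local <- seq.int(offset, n - window + 1L, by = step)
    abs_start <- begins[r] + starts_local - 1L
    cs <- cumsum(c(0, daf$mean_z[begins[r]:ends[r]]))
    stat <- (cs[starts_local + window] - cs[starts_local]) / window
    res[[r]] <- tibble(
      scaffold = runs$values[r],
      snp_start_index = starts_local,
      start = daf$pos[abs_start],
      end = daf$pos[abs_start + window - 1L],
      n_snps = as.integer(window),
      stat = stat
    )
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(tibble(scaffold = character(), snp_start_index = integer(),
                  start = integer(), end = integer(), n_snps = integer(),
                  stat = double()))
  }
  bind_rows(res)
}

# Window stat values only (no spans): used inside the permutation loop.
# scaffold_runs: rle() of the (already subset, sorted) scaffold column.
window_values_core <- function(mean_z, scaffold_runs, window, step, offset) {
  ends <- cumsum(scaffold_runs$lengths)
  begins <- ends - scaffold_runs$lengths + 1L
  out <- vector("list", length(scaffold_runs$values))
  for (r in seq_along(scaffold_runs$values)) {
    n <- scaffold_runs$lengths[r]
    if (n - window + 1L < offset) next
    starts_local <- seq.int(offset, n - window + 1L, by = step)
    cs <- cumsum(c(0, mean_z[begins[r]:ends[r]]))
    out[[r]] <- (cs[starts_local + window] - cs[starts_local]) / window
  }
  unlist(out, use.names = FALSE)
}

#' Write a window track to TSV
#' @param windows Window tibble from [window_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_track <- function(windows, path) {
  readr::write_tsv(windows, path)
  invisible(path)
}
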