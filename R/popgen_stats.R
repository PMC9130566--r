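#' Per-site nucleotide diversity from read counts
#'
#' Pool-seq estimator of site heterozygosity with the small-sample read
#' correction: `pi = C/(C-1) * (1 - sum(p_i^2))` where `p_i` are the read
#' frequencies of the alleles and `C` is the read depth over those alleles.
#' Undefined (NA) when `C < 2`.
#'
#' @param counts Numeric vector of per-allele read counts for one site, or a
#'   matrix with one site per row.
#' @return Numeric scalar (or vector for matrix input); `NA` where coverage
#'   is below 2.
#' @examples
#' site_pi(c(A = 5, T = 5)) # 10/9 * 0.5
#' @export
site_pi <- function(counts) {
  if (is.matrix(counts)) {
    C <- rowSums(counts)
    het <- 1 - rowSums((counts / ifelse(C > 0, C, 1))^2)
    out <- ifelse(C >= 2, C / (C - 1) * het, NA_real_)
    return(out)
  }
  C <- sum(counts)
  if (C < 2) return(NA_real_)
  C / (C - 1) * (1 - sum((counts / C)^2))
}

# biallelic fast path from minor-allele frequency + allele read depth
site_pi_biallelic <- function(freq, reads) {
  het <- 1 - freq^2 - (1 - freq)^2
  ifelse(reads >= 2, reads / (reads - 1) * het, NA_real_)
}

#' Per-site absolute divergence between two populations
#'
#' `dxy = p1 (1 - p2) + p2 (1 - p1)`, the probability that one allele drawn
#' from each population differs, with both frequencies referring to the same
#' allele. Symmetric, and maximal (1) at fixed differences.
#'
#' @param p1,p2 Allele frequencies in `[0, 1]` (vectorised).
#' @return Numeric vector of dxy values.
#' @examples
#' site_dxy(0.2, 0.7) # 0.62
#' @export
site_dxy <- function(p1, p2) {
  p1 * (1 - p2) + p2 * (1 - p1)
}

#' Constants of Tajima's D for sample size n
#'
#' The standard coefficients: `a1 = sum(1/i)`, `a2 = sum(1/i^2)` for
#' `i in 1..n-1`, `b1 = (n+1)/(3(n-1))`, `b2 = 2(n^2+n+3)/(9n(n-1))`,
#' `c1 = b1 - 1/a1`, `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`,
#' `e2 = c2/(a1^2 + a2)`.
#'
#' @param n Sample size (number of sequences), `n >= 2`.
#' @return Named list of the constants.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D from window summaries
#'
#' `D = (theta_pi - theta_W) / sqrt(e1 S + e2 S (S - 1))` with
#' `theta_W = S / a1`. Undefined (NA) when there are no segregating sites or
#' the effective sample size is below 4.
#'
#' @param S Number of segregating sites in the window.
#' @param theta_pi Sum of per-site pairwise diversity over the window.
#' @param n Effective sample size (sequences).
#' @return Tajima's D, or `NA` when undefined.
#' @export
tajima_d <- function(S, theta_pi, n) {
  if (is.na(S) || is.na(n) || S < 1 || n < 4) return(NA_real_)
  k <- tajima_constants(n)
  theta_w <- S / k$a1
  v <- k$e1 * S + k$e2 * S * (S - 1)
  (theta_pi - theta_w) / sqrt(v)
}

#' Windowed pool-seq population-genetic statistics
#'
#' Computes, over the same windows as the dAF scan, per-pool nucleotide
#' diversity (pi), Watterson's theta and Tajima's D, and per
#' anadromous x freshwater pair dxy. Statistics are averages over the
#' variant sites inside each window span (per-SNP-window, not per-bp; the
#' windows hold SNPs only). The effective sample size per site is
#' `min(coverage, haploid pool size)` — reads cannot sample more
#' chromosomes than the pool contains — and the window value is the floor of
#' the per-site mean.
#'
#' @param snps SNP table from [call_snps()].
#' @param windows Window tibble (spans define the windows; typically from
#'   [window_scan()]).
#' @return Tibble with one row per window x unit: `scaffold`, `start`,
#'   `end`, `unit` (pool name or `anad..fresh` pair), `type` (`"pool"` or
#'   `"pair"`), `n_sites`, `pi`, `theta_w`, `tajima_d`, `dxy`, `n_eff`.
#'   Undefined values are `NA`, never silently zero.
#' @export
popgen_windows <- function(snps, windows) {
  pools <- snp_pools(snps)
  f <- freq_matrix(snps)
  reads <- as.matrix(snps[, paste0("reads_", pools$pool), drop = FALSE])
  cov <- cov_matrix(snps)
  n_eff_site <- pmin(cov, matrix(rep(pools$haploid_size, each = nrow(snps)),
                                 nrow = nrow(snps)))
  anad <- pools$pool[pools$life_history == "anadromous"]
  fresh <- pools$pool[pools$life_history == "freshwater"]

  idx <- window_site_index(snps, windows)
  out <- vector("list", nrow(pools) + length(anad) * length(fresh))
  k <- 0L
  for (j in seq_len(nrow(pools))) {
    pj <- site_pi_biallelic(f[, j], reads[, j])
    seg <- as.numeric(f[, j] > 0 & f[, j] < 1)
    k <- k + 1L
    out[[k]] <- window_pool_stats(windows, idx, pj, seg, n_eff_site[, j],
                                  pools$pool[j])
  }
  for (a in anad) for (b in fresh) {
    dxy <- site_dxy(f[, a], f[, b])
    k <- k + 1L
    out[[k]] <- window_pair_stats(windows, idx, dxy, paste0(a, "..", b))
  }
  bind_rows(out)
}

# first/last SNP-row index per window (NA when the span holds no SNP)
window_site_index <- function(snps, windows) {
  i1 <- integer(nrow(windows))
  i2 <- integer(nrow(windows))
  for (sc in unique(windows$scaffold)) {
    wr <- which(windows$scaffold == sc)
    sr <- which(snps$scaffold == sc)
    pos <- snps$pos[sr]
    lo <- findInterval(windows$start[wr] - 1L, pos) + 1L
    hi <- findInterval(windows$end[wr], pos)
    i1[wr] <- ifelse(lo <= hi & length(sr) > 0L, sr[pmin(lo, length(sr))], NA)
    i2[wr] <- ifelse(lo <= hi & length(sr) > 0L, sr[pmax(hi, 1L)], NA)
  }
  list(i1 = i1, i2 = i2, n = ifelse(is.na(i1), 0L, i2 - i1 + 1L))
}

window_sum <- function(x, idx) {
  cs <- cumsum(c(0, ifelse(is.na(x), 0, x)))
  ifelse(is.na(idx$i1), NA_real_, cs[idx$i2 + 1L] - cs[idx$i1])
}

window_pool_stats <- function(windows, idx, pi_site, seg, n_eff_site, unit) {
  n <- idx$n
  pi_sum <- window_sum(pi_site, idx)
  S <- window_sum(seg, idx)
  ne <- floor(window_sum(n_eff_site, idx) / pmax(n, 1L))
  D <- vapply(seq_len(nrow(windows)), function(w) {
    if (is.na(S[w])) return(NA_real_)
    tajima_d(S[w], pi_sum[w], ne[w])
  }, numeric(1))
  theta_w <- vapply(seq_len(nrow(windows)), function(w) {
    if (is.na(S[w]) || S[w] < 1 || ne[w] < 2) return(NA_real_)
    (S[w] / tajima_constants(ne[w])$a1) / n[w]
  }, numeric(1))
  tibble(scaffold = windows$scaffold, start = windows$start,
         end = windows$end, unit = unit, type = "pool",
         n_sites = n, pi = pi_sum / pmax(n, 1L), theta_w = theta_w,
         tajima_d = D, dxy = NA_real_, n_eff = ne)
}

window_pair_stats <- function(windows, idx, dxy_site, unit) {
  n <- idx$n
  tibble(scaffold = windows$scaffold, start = windows$start,
         end = windows$end, unit = unit, type = "pair",
         n_sites = n, pi = NA_real_, theta_w = NA_real_,
         tajima_d = NA_real_, dxy = window_sum(dxy_site, idx) / pmax(n, 1L),
         n_eff = NA_real_)
}

#' Contrast a population-genetic statistic in outlier vs non-outlier windows
#'
#' Partitions the track's windows into those whose span intersects an
#' outlier region and the rest, then compares the chosen statistic between
#' the two groups per unit with a two-sided Mann-Whitney U test.
#'
#' @param track Tibble from [popgen_windows()].
#' @param regions Outlier-region tibble (e.g. `scan$regions[["99.9"]]`).
#' @param stat Which column to contrast: `"dxy"`, `"tajima_d"`, `"pi"` or
#'   `"theta_w"`.
#' @return Tibble with one row per unit: group sizes, group means, the U
#'   statistic and the two-sided p-value (`NA`, with a warning, when either
#'   partition is empty).
#' @export
contrast_outliers <- function(track, regions,
                              stat = c("dxy", "tajima_d", "pi", "theta_w")) {
  stat <- match.arg(stat)
  if (nrow(regions) == 0L) {
    warn("no outlier regions; contrast is undefined")
  }
  is_out <- rep(FALSE, nrow(track))
  if (nrow(regions) > 0L && nrow(track) > 0L) {
    hit <- suppressWarnings(
      GenomicRanges::findOverlaps(regions_gr(track), regions_gr(regions)))
    is_out[unique(S4Vectors::queryHits(hit))] <- TRUE
  }
  units <- unique(track$unit[!is.na(track[[stat]])])
  rows <- lapply(units, function(u) {
    sel <- track$unit == u & !is.na(track[[stat]])
    x <- track[[stat]][sel & is_out]
    y <- track[[stat]][sel & !is_out]
    if (length(x) == 0L || length(y) == 0L) {
      warn(paste0("unit '", u, "': one partition is empty; p undefined"))
      return(tibble(unit = u, statistic = stat,
                    n_outlier = length(x), n_background = length(y),
                    mean_outlier = if (length(x)) mean(x) else NA_real_,
                    mean_background = if (length(y)) mean(y) else NA_real_,
                    U = NA_real_, p = NA_real_))
    }
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    tibble(unit = u, statistic = stat,
           n_outlier = length(x), n_background = length(y),
           mean_outlier = mean(x), mean_background = mean(y),
           U = unname(wt$statistic), p = wt$p.value)
  })
  bind_rows(rows)
}

#' Write a population-genetics track to TSV
#'
#' The header records that pi and dxy are per-variant-site averages over
#' SNP windows, not per-bp.
#'
#' @param track Tibble from [popgen_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_popgen_track <- function(track, path) {
  writeLines(paste0("# pi/theta_w/dxy are averages over variant sites in ",
                    "each SNP window (per variant site, not per bp)"), path)
  readr::write_tsv(track, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
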