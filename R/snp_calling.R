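#' Call biallelic SNPs for one lineage from pool counts
#'
#' Applies count-level filters to per-pool nucleotide counts and returns
#' per-pool frequencies of the lineage-wide minor allele. A site is retained
#' iff, with counts summed over the lineage's pools, exactly two of A/C/G/T
#' are observed (biallelic); the summed minor-allele count is at least
#' `min_minor_count`; and every pool's coverage (all six sync fields,
#' including N and del) lies in `[min_cov, max_cov_factor x that pool's
#' genome-wide mean coverage]`. Genome-wide mean coverage per pool is taken
#' over *all* input sites, before any filtering.
#'
#' N and del counts contribute to coverage but never to allele calls, and the
#' per-pool frequency denominator is `minor + major` reads only.
#'
#' @param counts Long counts tibble from [read_sync()] (or
#'   [simulate_poolseq()]).
#' @param manifest Pool manifest; only pools belonging to `lineage` are used.
#' @param lineage Lineage to call SNPs for; defaults to the single lineage
#'   present in `manifest`.
#' @param min_minor_count Minimum lineage-wide minor-allele read count
#'   (default 4).
#' @param min_cov Minimum per-pool coverage (default 10).
#' @param max_cov_factor Maximum per-pool coverage as a multiple of that
#'   pool's genome-wide mean (default 2).
#' @return A tibble sorted by (scaffold, pos) with columns `scaffold`, `pos`,
#'   `ref`, `major`, `minor`, then `freq_<pool>` (minor-allele frequency),
#'   `cov_<pool>` (all six sync fields) and `reads_<pool>` (major + minor
#'   allele reads) for each pool. Attributes: `pools` (the manifest rows
#'   used), `lineage`, `mean_cov` (named per-pool genome-wide means).
#' @export
call_snps <- function(counts, manifest, lineage = NULL,
                      min_minor_count = 4L, min_cov = 10L,
                      max_cov_factor = 2) {
  validate_manifest(manifest)
  if (is.null(lineage)) {
    lin <- unique(manifest$lineage)
    if (length(lin) != 1L) {
      abort("manifest holds several lineages; supply `lineage`")
    }
    lineage <- lin
  }
  pools <- manifest[manifest$lineage == lineage, , drop = FALSE]
  if (nrow(pools) == 0L) {
    abort(paste0("no pools in manifest for lineage '", lineage, "'"))
  }
  counts <- counts[counts$pool %in% pools$pool, , drop = FALSE]
  if (nrow(counts) == 0L) {
    return(empty_snp_table(pools, lineage))
  }
  counts <- counts[order(counts$scaffold, counts$pos,
                         match(counts$pool, pools$pool)), , drop = FALSE]
  n_pools <- nrow(pools)
  if (nrow(counts) %% n_pools != 0L) {
    abort("counts do not cover every pool at every site")
  }
  n_sites <- nrow(counts) / n_pools
  bases <- c("A", "C", "G", "T")
  # sites x pools matrix per base; rows are sorted sites
  base_m <- lapply(c(bases, "N", "del"), function(b) {
    matrix(counts[[b]], ncol = n_pools, byrow = TRUE)
  })
  names(base_m) <- c(bases, "N", "del")
  cov <- Reduce(`+`, base_m)                       # sites x pools
  mean_cov <- colMeans(cov)
  names(mean_cov) <- pools$pool

  tot <- vapply(bases, function(b) rowSums(base_m[[b]]), numeric(n_sites))
  if (n_sites == 1L) tot <- matrix(tot, nrow = 1L, dimnames = list(NULL, bases))
  nonzero <- tot > 0L
  biallelic <- rowSums(nonzero) == 2L

  # major/minor among the two observed alleles; ties broken by base order
  ord <- matrix(0L, n_sites, 2L)
  idx2 <- which(biallelic)
  if (length(idx2)) {
    nz <- nonzero[idx2, , drop = FALSE]
    first <- max.col(nz, ties.method = "first")
    last <- max.col(nz, ties.method = "last")
    c_first <- tot[cbind(idx2, first)]
    c_last <- tot[cbind(idx2, last)]
    swap <- c_last > c_first
    maj <- ifelse(swap, last, first)
    mnr <- ifelse(swap, first, last)
    ord[idx2, 1L] <- maj
    ord[idx2, 2L] <- mnr
  }
  minor_total <- rep(0, n_sites)
  minor_total[idx2] <- tot[cbind(idx2, ord[idx2, 2L])]

  cov_ok <- rowSums(cov < min_cov) == 0L &
    rowSums(sweep(cov, 2L, max_cov_factor * mean_cov, `>`)) == 0L
  keep <- biallelic & minor_total >= min_minor_count & cov_ok
  site_rows <- seq(1L, nrow(counts), by = n_pools)
  out_idx <- which(keep)
  if (!length(out_idx)) {
    return(snp_attrs(empty_snp_table(pools, lineage), pools, lineage, mean_cov))
  }

  arr <- array(unlist(base_m[bases], use.names = FALSE),
               dim = c(n_sites, n_pools, 4L))
  maj_i <- ord[out_idx, 1L]
  mnr_i <- ord[out_idx, 2L]
  nk <- length(out_idx)
  site_rep <- rep(out_idx, times = n_pools)
  pool_rep <- rep(seq_len(n_pools), each = nk)
  maj_cnt <- matrix(arr[cbind(site_rep, pool_rep, rep(maj_i, n_pools))], ncol = n_pools)
  mnr_cnt <- matrix(arr[cbind(site_rep, pool_rep, rep(mnr_i, n_pools))], ncol = n_pools)
  freq <- mnr_cnt / (mnr_cnt + maj_cnt)

  out <- tibble(
    scaffold = counts$scaffold[site_rows][out_idx],
    pos = counts$pos[site_rows][out_idx],
    ref = counts$ref[site_rows][out_idx],
    major = bases[maj_i],
    minor = bases[mnr_i]
  )
  for (j in seq_len(n_pools)) out[[paste0("freq_", pools$pool[j])]] <- freq[, j]
  for (j in seq_len(n_pools)) out[[paste0("cov_", pools$pool[j])]] <- cov[out_idx, j]
  # allele reads (major + minor) back the pi / dxy estimators, where N/del
  # reads must not count
  for (j in seq_len(n_pools)) {
    out[[paste0("reads_", pools$pool[j])]] <- mnr_cnt[, j] + maj_cnt[, j]
  }
  snp_attrs(out, pools, lineage, mean_cov)
}

empty_snp_table <- function(pools, lineage) {
  out <- tibble(scaffold = character(), pos = integer(), ref = character(),
                major = character(), minor = character())
  for (p in pools$pool) out[[paste0("freq_", p)]] <- double()
  for (p in pools$pool) out[[paste0("cov_", p)]] <- integer()
  for (p in pools$pool) out[[paste0("reads_", p)]] <- integer()
  snp_attrs(out, pools, lineage, setNames(rep(NA_real_, nrow(pools)), pools$pool))
}

snp_attrs <- function(x, pools, lineage, mean_cov) {
  attr(x, "pools") <- pools
  attr(x, "lineage") <- lineage
  attr(x, "mean_cov") <- mean_cov
  x
}

restore_snp_attrs <- function(new, old) {
  snp_attrs(new, attr(old, "pools"), attr(old, "lineage"),
            attr(old, "mean_cov"))
}

#' Pools attached to a SNP table
#' @param snps SNP table from [call_snps()].
#' @return The manifest rows the table was built with.
#' @export
snp_pools <- function(snps) {
  p <- attr(snps, "pools")
  if (is.null(p)) abort("SNP table has no pool manifest attached")
  p
}

#' Minor-allele frequency matrix of a SNP table
#' @param snps SNP table from [call_snps()].
#' @return Numeric matrix, sites x pools, pool names as columns.
#' @export
freq_matrix <- function(snps) {
  pools <- snp_pools(snps)
  m <- as.matrix(snps[, paste0("freq_", pools$pool), drop = FALSE])
  colnames(m) <- pools$pool
  m
}

#' Coverage matrix of a SNP table
#' @param snps SNP table from [call_snps()].
#' @return Integer matrix, sites x pools.
#' @export
cov_matrix <- function(snps) {
  pools <- snp_pools(snps)
  m <- as.matrix(snps[, paste0("cov_", pools$pool), drop = FALSE])
  colnames(m) <- pools$pool
  m
}

#' Remove SNPs near insertions or deletions
#'
#' Drops SNPs within `distance` bp of an indel position on the same scaffold
#' (inclusive: `|snp - indel| <= distance` removes the SNP).
#'
#' @param snps SNP table from [call_snps()].
#' @param indels Tibble with columns `scaffold`, `pos` (1-based indel
#'   positions).
#' @param distance Exclusion radius in bp (default 10).
#' @return The SNP table with offending sites removed.
#' @export
filter_near_indels <- function(snps, indels, distance = 10L) {
  if (is.null(indels) || nrow(indels) == 0L) return(snps)
  keep <- rep(TRUE, nrow(snps))
  for (sc in unique(indels$scaffold)) {
    iv <- sort(indels$pos[indels$scaffold == sc])
    rows <- which(snps$scaffold == sc)
    if (!length(rows)) next
    p <- snps$pos[rows]
    i <- findInterval(p, iv)
    left_ok <- i >= 1L
    d_left <- rep(Inf, length(p))
    d_left[left_ok] <- p[left_ok] - iv[pmax(i[left_ok], 1L)]
    right_ok <- i < length(iv)
    d_right <- rep(Inf, length(p))
    d_right[right_ok] <- iv[pmin(i[right_ok] + 1L, length(iv))] - p[right_ok]
    keep[rows] <- pmin(d_left, d_right) > distance
  }
  restore_snp_attrs(snps[keep, , drop = FALSE], snps)
}

#' Polymorphic sites of a lineage
#'
#' A site is polymorphic if at least one pool segregates (frequency strictly
#' between 0 and 1) or at least one pool is fixed for an allele that differs
#' from the reference base. Sites where every pool is fixed for the reference
#' allele are excluded.
#'
#' @param snps SNP table from [call_snps()] (carries `ref`, `major`, `minor`).
#' @return Tibble of the polymorphic sites (`scaffold`, `pos`).
#' @export
polymorphic_sites <- function(snps) {
  if (nrow(snps) == 0L) return(tibble(scaffold = character(), pos = integer()))
  f <- freq_matrix(snps)
  segregating <- rowSums(f > 0 & f < 1, na.rm = TRUE) > 0L
  fixed_minor <- rowSums(f == 1, na.rm = TRUE) > 0L & snps$minor != snps$ref
  fixed_major <- rowSums(f == 0, na.rm = TRUE) > 0L & snps$major != snps$ref
  keep <- segregating | fixed_minor | fixed_major
  tibble(scaffold = snps$scaffold[keep], pos = snps$pos[keep])
}

#' Write a SNP table to TSV
#' @param snps SNP table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(snps, path) {
  readr::write_tsv(snps, path)
  invisible(path)
}
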