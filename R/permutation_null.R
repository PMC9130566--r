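#' Nearest-rank percentile
#'
#' The smallest element of `x` such that at least `p` percent of `x` is less
#' than or equal to it: `sort(x)[ceiling(p/100 * n)]`.
#'
#' @param x Numeric vector.
#' @param p Percentile in (0, 100].
#' @return The nearest-rank percentile value.
#' @examples
#' nearest_rank(1:1000, 99) # 990
#' @export
nearest_rank <- function(x, p) {
  stopifnot(length(x) >= 1L, p > 0, p <= 100)
  s <- sort(x)
  # tiny tolerance so exact ranks (e.g. 99.9% of 1000 = 999) are not pushed
  # up by floating-point error in p/100 * n
  s[max(1L, ceiling(p / 100 * length(s) - 1e-9))]
}

# One L'Ecuyer-CMRG stream per permutation index: the pooled null is
# invariant to the order (or parallelisation) in which permutations run.
make_streams <- function(seed, n) {
  state <- preserve_rng()
  on.exit(restore_rng(state))
  suppressWarnings(set.seed(seed, kind = "L'Ecuyer-CMRG"))
  s <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

preserve_rng <- function() {
  list(
    seed = get0(".Random.seed", envir = globalenv()),
    kind = RNGkind()
  )
}

restore_rng <- function(state) {
  # the active RNG kind must be reset too: .Random.seed removal alone leaves
  # the session on whatever kind was last set
  suppressWarnings(RNGkind(state$kind[1], state$kind[2], state$kind[3]))
  if (is.null(state$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state$seed, envir = globalenv())
  }
  invisible(NULL)
}

# Shared preparation for scans and permutations: frequency matrix restricted
# to the scanned scaffolds, scaffold run lengths, and group indices.
scan_prep <- function(snps, scaffold_lengths = NULL, top_scaffolds = 1000L) {
  pools <- snp_pools(snps)
  keep <- rep(TRUE, nrow(snps))
  if (!is.null(scaffold_lengths)) {
    keep <- snps$scaffold %in% top_scaffold_names(scaffold_lengths, top_scaffolds)
  }
  f <- freq_matrix(snps)[keep, , drop = FALSE]
  list(
    f = f,
    scaffold = snps$scaffold[keep],
    pos = snps$pos[keep],
    runs = rle(snps$scaffold[keep]),
    anad_idx = which(pools$life_history == "anadromous"),
    fresh_idx = which(pools$life_history == "freshwater"),
    pools = pools
  )
}

#' One permutation of the dAF scan
#'
#' Randomly reassigns the lineage's pools to the anadromous/freshwater
#' labels (preserving group sizes), reruns the full dAF pipeline
#' (pair differences, genome-wide standardization, window aggregation), and
#' draws the window start offset uniformly from `1:window` so that all
#' possible 20-SNP window phasings are sampled across permutations.
#'
#' @inheritParams window_scan
#' @param snps SNP table from [call_snps()] with at least two pools.
#' @param seed Integer seed for this permutation.
#' @param pooled Passed to the standardization (see [standardize_daf()]).
#' @return Window tibble as from [window_scan()], for the permuted labels.
#' @export
permute_scan <- function(snps, seed, window = 20L, step = 10L,
                         top_scaffolds = 1000L, scaffold_lengths = NULL,
                         pooled = FALSE) {
  prep <- scan_prep(snps, scaffold_lengths, top_scaffolds)
  check_permutable(prep)
  state <- preserve_rng()
  on.exit(restore_rng(state))
  set.seed(seed)
  draw <- draw_permutation(prep)
  mean_z <- daf_mean_z_core(prep$f, draw$anad_idx, draw$fresh_idx, pooled)
  daf <- tibble(scaffold = prep$scaffold, pos = prep$pos, mean_z = mean_z)
  window_scan(daf, window = window, step = step, offset = draw$offset,
              top_scaffolds = top_scaffolds, scaffold_lengths = NULL)
}

check_permutable <- function(prep) {
  n_pools <- length(prep$anad_idx) + length(prep$fresh_idx)
  if (n_pools < 2L) {
    abort("permutation needs at least two pools in the lineage")
  }
  if (length(prep$anad_idx) == 0L || length(prep$fresh_idx) == 0L) {
    abort("lineage must have at least one anadromous and one freshwater pool")
  }
}

# uses the current RNG state; group sizes are preserved
draw_permutation <- function(prep, window = 20L) {
  all_idx <- c(prep$anad_idx, prep$fresh_idx)
  shuffled <- sample(all_idx)
  list(
    anad_idx = shuffled[seq_along(prep$anad_idx)],
    fresh_idx = shuffled[-seq_along(prep$anad_idx)],
    offset = sample.int(window, 1L)
  )
}

#' Build the permutation null distribution of window statistics
#'
#' Runs `n_perm` label permutations of the scan (see [permute_scan()]) and
#' pools every permutation's window statistics into one empirical null
#' distribution per lineage, from which genome-wide nearest-rank percentile
#' thresholds are taken. Group sizes are preserved in each permutation and
#' the identity assignment may be drawn; the random window offset supplies
#' additional null variation.
#'
#' @inheritParams permute_scan
#' @param n_perm Number of permutations (default 1000).
#' @param percentiles Percentile thresholds to compute (default 99 and 99.9).
#' @return An object of class `daf_null`: list with `values` (pooled null
#'   stats), `n_perm`, `thresholds` (named numeric), `percentiles`, `seed`,
#'   `window`, `step`.
#' @export
build_null <- function(snps, n_perm = 1000L, seed = 1L, window = 20L,
                       step = 10L, top_scaffolds = 1000L,
                       scaffold_lengths = NULL, percentiles = c(99, 99.9),
                       pooled = FALSE) {
  stopifnot(n_perm >= 1L)
  prep <- scan_prep(snps, scaffold_lengths, top_scaffolds)
  check_permutable(prep)
  streams <- make_streams(seed, n_perm)
  state <- preserve_rng()
  on.exit(restore_rng(state))
  vals <- vector("list", n_perm)
  for (i in seq_len(n_perm)) {
    assign(".Random.seed", streams[[i]], envir = globalenv())
    draw <- draw_permutation(prep, window)
    mean_z <- daf_mean_z_core(prep$f, draw$anad_idx, draw$fresh_idx, pooled)
    vals[[i]] <- window_values_core(mean_z, prep$runs, window, step, draw$offset)
  }
  values <- unlist(vals, use.names = FALSE)
  if (length(values) == 0L) {
    warn("no full windows in any permutation; null distribution is empty")
    thresholds <- setNames(rep(NA_real_, length(percentiles)),
                           pct_key(percentiles))
  } else {
    thresholds <- vapply(percentiles, function(p) nearest_rank(values, p),
                         numeric(1))
    names(thresholds) <- pct_key(percentiles)
  }
  structure(
    list(values = values, n_perm = as.integer(n_perm),
         thresholds = thresholds, percentiles = percentiles,
         seed = as.integer(seed), window = as.integer(window),
         step = as.integer(step)),
    class = "daf_null"
  )
}

#' @export
print.daf_null <- function(x, ...) {
  cat("Permutation null of dAF window statistics\n")
  cat("  permutations:", x$n_perm, " pooled window stats:",
      length(x$values), "\n")
  for (i in seq_along(x$thresholds)) {
    cat(sprintf("  %sth percentile threshold: %.4f\n",
                names(x$thresholds)[i], x$thresholds[i]))
  }
  invisible(x)
}

#' Empirical window p-values against a permutation null
#'
#' Add-one empirical p-values: `p = (1 + #(null >= stat)) / (1 + #null)`,
#' always in (0, 1].
#'
#' @param windows Window tibble from [window_scan()].
#' @param null A `daf_null` from [build_null()].
#' @return `windows` with a `p` column added.
#' @export
window_pvalues <- function(windows, null) {
  stopifnot(inherits(null, "daf_null"))
  nv <- length(null$values)
  if (nv == 0L) abort("null distribution is empty")
  s <- sort(null$values)
  n_less <- findInterval(windows$stat, s, left.open = TRUE)
  windows$p <- (1 + (nv - n_less)) / (1 + nv)
  windows
}

#' Flag outlier windows at a percentile threshold
#'
#' A window is an outlier when its statistic is greater than or equal to the
#' null's nearest-rank threshold at the requested percentile; ties at the
#' threshold are included. The 99.9th-percentile set is always a subset of
#' the 99th-percentile set.
#'
#' @param windows Window tibble.
#' @param null A `daf_null` with the requested percentile computed.
#' @param percentile One of the percentiles stored in `null` (default 99).
#' @return The subset of `windows` with `stat >= threshold`.
#' @export
call_outliers <- function(windows, null, percentile = 99) {
  stopifnot(inherits(null, "daf_null"))
  key <- pct_key(percentile)
  if (!key %in% names(null$thresholds)) {
    abort(paste0("percentile ", key, " not present in null thresholds"))
  }
  thr <- null$thresholds[[key]]
  if (is.na(thr)) abort("null threshold is undefined (empty null)")
  windows[windows$stat >= thr, , drop = FALSE]
}

#' @rdname tidy.daf_scan
#' @export
tidy.daf_null <- function(x, ...) {
  tibble(percentile = x$percentiles, threshold = unname(x$thresholds))
}

#' @rdname tidy.daf_scan
#' @export
glance.daf_null <- function(x, ...) {
  tibble(n_perm = x$n_perm, n_values = length(x$values), seed = x$seed,
         window = x$window, step = x$step)
}

#' Write a null-distribution summary to TSV
#' @param null A `daf_null`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_null_summary <- function(null, path) {
  readr::write_tsv(
    tibble(n_perm = null$n_perm, percentile = null$percentiles,
           threshold = unname(null$thresholds), seed = null$seed),
    path
  )
  invisible(path)
}
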