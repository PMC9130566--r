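# Shared fixtures: tiny hand-built count tables and a cached small
# simulation used across test files.

two_pool_manifest <- function(lineage = "L1") {
  pool_manifest(
    pool = c("sea1", "lake1"),
    lineage = lineage,
    life_history = c("anadromous", "freshwater"),
    n_individuals = 25L
  )
}

four_pool_manifest <- function(lineage = "L1") {
  pool_manifest(
    pool = c("sea1", "sea2", "lake1", "lake2"),
    lineage = lineage,
    life_history = c("anadromous", "anadromous", "freshwater", "freshwater"),
    n_individuals = 25L
  )
}

# one site x pools long counts tibble from a list of 6-count vectors
make_counts <- function(scaffold, pos, ref, pool_counts, manifest) {
  stopifnot(length(pool_counts) == nrow(manifest))
  rows <- lapply(seq_along(pool_counts), function(j) {
    cc <- pool_counts[[j]]
    tibble::tibble(scaffold = scaffold, pos = as.integer(pos), ref = ref,
                   pool = manifest$pool[j],
                   A = cc[1], T = cc[2], C = cc[3], G = cc[4],
                   N = cc[5], del = cc[6])
  })
  dplyr::bind_rows(rows)
}

# a clean biallelic site passing all filters, frequencies chosen per pool
make_site <- function(scaffold, pos, manifest, minor_freq, depth = 30L,
                      ref = "A", major = "A", minor = "T") {
  stopifnot(length(minor_freq) == nrow(manifest))
  pool_counts <- lapply(minor_freq, function(f) {
    mnr <- round(depth * f)
    counts <- c(A = 0L, T = 0L, C = 0L, G = 0L, N = 0L, del = 0L)
    counts[major] <- depth - mnr
    counts[minor] <- mnr
    counts
  })
  make_counts(scaffold, pos, ref, pool_counts, manifest)
}

# many clean sites along one or more scaffolds; freq matrix sites x pools
make_sites <- function(manifest, freq, scaffold = "scaf1",
                       pos = NULL, depth = 30L) {
  n <- nrow(freq)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  scaffold <- rep(scaffold, length.out = n)
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_site(scaffold[i], pos[i], manifest, freq[i, ], depth = depth)
  }))
}

# cached small simulation shared by read-only tests
.sim_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    cfg <- sim_config(
      n_lineages = 2, n_scaffolds = 5, scaffold_length = 2e5,
      n_snps = 4000, seed = 99,
      planted_regions = tibble::tibble(scaffold = "scaf001",
                                       start = 50000L, end = 62000L,
                                       delta = 0.7),
      min_snps_per_region = 45L, n_indels = 30L,
      force_planted_nonsyn = TRUE
    )
    .sim_cache$sim <- suppressWarnings(simulate_poolseq(cfg))
  }
  .sim_cache$sim
}

small_snps <- function(lineage = "L1") {
  key <- paste0("snps_", lineage)
  if (is.null(.sim_cache[[key]])) {
    sim <- small_sim()
    .sim_cache[[key]] <- call_snps(sim$counts[[lineage]], sim$manifest,
                                   lineage)
  }
  .sim_cache[[key]]
}
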