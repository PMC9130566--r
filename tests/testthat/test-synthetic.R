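test_that("the generator is deterministic and leaves the session RNG alone", {
  cfg <- sim_config(n_scaffolds = 3, scaffold_length = 5e4, n_snps = 500,
                    seed = 5)
  s1 <- simulate_poolseq(cfg)
  set.seed(777)
  expected <- runif(2)
  set.seed(777)
  s2 <- simulate_poolseq(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth$freqs, s2$truth$freqs)
  expect_identical(runif(2), expected)

  # a different seed gives different data
  s3 <- simulate_poolseq(sim_config(n_scaffolds = 3, scaffold_length = 5e4,
                                    n_snps = 500, seed = 6))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("simulated structure matches the configuration", {
  cfg <- sim_config(n_lineages = 2, pools_per_lineage = list(c(2L, 3L)),
                    n_scaffolds = 4, scaffold_length = 1e5, n_snps = 800,
                    shared_fraction = 0.5, coverage_mean = 32, seed = 2)
  sim <- simulate_poolseq(cfg)
  expect_setequal(names(sim$counts), c("L1", "L2"))
  expect_equal(nrow(sim$manifest), 10L)
  expect_equal(sum(sim$manifest$life_history == "freshwater"), 6L)
  expect_equal(sim$manifest$haploid_size[1], 58L)
  # scaffold lengths taper from full to half
  expect_equal(unname(sim$scaffold_lengths[1]), 1e5)
  expect_equal(unname(sim$scaffold_lengths[4]), 5e4)

  for (l in c("L1", "L2")) {
    cts <- sim$counts[[l]]
    n_pools <- sum(sim$manifest$lineage == l)
    expect_equal(nrow(cts), 800 * n_pools)
    # positions are unique per lineage and within scaffold bounds
    sites <- dplyr::distinct(cts, scaffold, pos)
    expect_equal(nrow(sites), 800L)
    expect_true(all(sites$pos >= 1 &
                      sites$pos <= sim$scaffold_lengths[sites$scaffold]))
  }
  # shared fraction: exactly round(0.5 * 800) positions in common
  k1 <- dplyr::distinct(sim$counts$L1, scaffold, pos)
  k2 <- dplyr::distinct(sim$counts$L2, scaffold, pos)
  shared <- nrow(dplyr::inner_join(k1, k2, by = c("scaffold", "pos")))
  expect_equal(shared, 400L)
  # coverage is near the Poisson mean
  cov <- sim$counts$L1$A + sim$counts$L1$T + sim$counts$L1$C +
    sim$counts$L1$G + sim$counts$L1$N + sim$counts$L1$del
  expect_equal(mean(cov), 32, tolerance = 0.05)
})

test_that("planted regions shift freshwater frequencies by delta", {
  sim <- small_sim()
  tf <- sim$truth$freqs$L1
  pr <- sim$config$planted_regions
  inside <- tf$scaffold == pr$scaffold & tf$pos >= pr$start & tf$pos <= pr$end
  expect_gte(sum(inside), 45L)     # min_snps_per_region honoured
  daf_in <- abs(tf$freq_L1_fresh1[inside] - tf$freq_L1_anad1[inside])
  daf_out <- abs(tf$freq_L1_fresh1[!inside] - tf$freq_L1_anad1[!inside])
  # expected |dAF| near delta inside, near zero outside (drift noise aside)
  expect_gt(mean(daf_in), mean(daf_out) + 0.3)
  # regions are planted in both lineages by default
  expect_setequal(unique(sim$truth$regions$lineage), c("L1", "L2"))
  # forced nonsynonymous labelling inside the region
  eff <- sim$truth$effects
  eff_in <- eff$effect[eff$scaffold == pr$scaffold &
                         eff$pos >= pr$start & eff$pos <= pr$end]
  expect_true(all(eff_in == "nonsynonymous"))
})

test_that("planting can be restricted to chosen lineages and pools", {
  pr <- tibble::tibble(scaffold = "scaf001", start = 1000L, end = 20000L,
                       delta = 0.8)
  cfg <- sim_config(n_scaffolds = 2, scaffold_length = 1e5, n_snps = 600,
                    planted_regions = pr, planted_lineages = "L1",
                    planted_fresh_pools = "L1_fresh1",
                    min_snps_per_region = 30L, seed = 8)
  sim <- suppressWarnings(simulate_poolseq(cfg))
  expect_equal(unique(sim$truth$regions$lineage), "L1")
  f1 <- sim$truth$freqs$L1
  inside <- f1$scaffold == "scaf001" & f1$pos >= 1000 & f1$pos <= 20000
  d_f1 <- abs(f1$freq_L1_fresh1[inside] - f1$freq_L1_anad1[inside])
  d_f2 <- abs(f1$freq_L1_fresh2[inside] - f1$freq_L1_anad1[inside])
  expect_gt(mean(d_f1), mean(d_f2) + 0.3)
  # L2 untouched
  f2 <- sim$truth$freqs$L2
  in2 <- f2$scaffold == "scaf001" & f2$pos >= 1000 & f2$pos <= 20000
  if (sum(in2) >= 5) {
    d2 <- abs(f2$freq_L2_fresh1[in2] - f2$freq_L2_anad1[in2])
    expect_lt(mean(d2), 0.35)
  }
})

test_that("null_dataset refuses planted configs", {
  pr <- tibble::tibble(scaffold = "scaf001", start = 1L, end = 10L,
                       delta = 0.5)
  expect_error(null_dataset(sim_config(planted_regions = pr)), "planted")
  nd <- null_dataset(sim_config(n_scaffolds = 2, scaffold_length = 2e4,
                                n_snps = 100, seed = 3))
  expect_equal(nrow(nd$truth$regions), 0L)
})

test_that("write_sim emits readable text files that round trip", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  paths <- write_sim(sim, dir)
  expect_true(all(file.exists(paths)))
  m <- read_pool_manifest(paths[["manifest"]])
  expect_equal(m$pool, sim$manifest$pool)
  back <- read_sync(paths[["sync_L1"]], m[m$lineage == "L1", ])
  expect_equal(nrow(back), nrow(sim$counts$L1))
  expect_equal(back$A, sim$counts$L1$A)
  # truth BED is 0-based half-open
  bed <- readLines(paths[["truth_regions"]])
  expect_match(bed[1], "^scaf001\t49999\t62000\t")
  genes <- read_gene_models(paths[["genes"]])
  expect_true("gene_region_1" %in% genes$gene_id)
})

test_that("simulated data survive the full SNP-calling front end", {
  snps <- small_snps("L1")
  expect_gt(nrow(snps), 1000)
  f <- freq_matrix(snps)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(snps$major != snps$minor))
  # minor is the rarer allele lineage-wide: mean minor freq below 0.5
  expect_lt(mean(f), 0.5)
})
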