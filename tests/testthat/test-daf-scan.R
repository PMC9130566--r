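test_that("pair dAF is the absolute frequency difference for every pair", {
  m <- four_pool_manifest()
  freq <- rbind(c(0.1, 0.2, 0.8, 0.9),
                c(0.5, 0.5, 0.5, 0.5),
                c(0.9, 0.1, 0.2, 0.3))
  snps <- call_snps(make_sites(m, freq, depth = 100L), m)
  daf <- pair_daf(snps)
  pairs <- attr(daf, "pairs")
  expect_equal(nrow(pairs), 4L)   # 2 anadromous x 2 freshwater
  expect_equal(daf$d_sea1..lake1, abs(freq[, 3] - freq[, 1]), tolerance = 0.03)
  expect_equal(daf$d_sea2..lake2, abs(freq[, 4] - freq[, 2]), tolerance = 0.03)
})

test_that("standardization matches the closed-form z-scores", {
  # DERIVED: d = {0, 0.2, 0.4}; mean 0.2, population sd sqrt(mean of squared
  # deviations) = sqrt((0.04 + 0 + 0.04)/3) = 0.1632993; z = -1.224745, 0,
  # +1.224745
  d <- matrix(c(0, 0.2, 0.4), ncol = 1)
  z <- poolscan:::standardize_core(d, "p")
  expect_equal(as.vector(z), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)

  # constant pair is a fatal error naming the pair
  d2 <- cbind(c(0, 0.2, 0.4), c(0.3, 0.3, 0.3))
  expect_error(poolscan:::standardize_core(d2, c("pA", "pB")), "pB")

  # pooled mode standardizes against all values together
  zp <- poolscan:::standardize_core(d2[, 1, drop = FALSE], "p", pooled = TRUE)
  expect_equal(mean(zp), 0)
  expect_equal(sqrt(mean(zp^2)), 1)
})

test_that("mean_z averages the per-pair z-scores", {
  m <- four_pool_manifest()
  set.seed(42)
  freq <- matrix(runif(40 * 4, 0.1, 0.9), ncol = 4)
  snps <- call_snps(make_sites(m, freq, depth = 200L), m)
  z <- standardize_daf(pair_daf(snps))
  zc <- as.matrix(z[, grep("^z_", names(z))])
  expect_equal(z$mean_z, rowMeans(zc))
  # each z column has genome-wide mean 0 and population sd 1
  expect_equal(colMeans(zc), rep(0, 4), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(apply(zc, 2, function(v) sqrt(mean(v^2))), rep(1, 4),
               ignore_attr = TRUE, tolerance = 1e-12)

  # fast core used in permutations agrees with the tibble pipeline
  pools <- snp_pools(snps)
  core <- poolscan:::daf_mean_z_core(freq_matrix(snps),
                                     which(pools$life_history == "anadromous"),
                                     which(pools$life_history == "freshwater"))
  expect_equal(core, z$mean_z, tolerance = 1e-12)
})

test_that("window scan emits only full windows with the right spans", {
  # DERIVED: 35 SNPs, window 20, step 10 -> starts 1 and 11 only (21 would
  # need SNP 40)
  daf <- tibble::tibble(scaffold = "s", pos = seq_len(35) * 10L,
                        mean_z = as.numeric(1:35))
  w <- window_scan(daf, window = 20, step = 10)
  expect_equal(nrow(w), 2L)
  expect_equal(w$snp_start_index, c(1L, 11L))
  expect_equal(w$start, c(10L, 110L))
  expect_equal(w$end, c(200L, 300L))
  expect_equal(w$stat, c(mean(1:20), mean(11:30)))

  # offset shifts the first window
  w2 <- window_scan(daf, window = 20, step = 10, offset = 5)
  expect_equal(w2$snp_start_index, c(5L, 15L))

  # fewer SNPs than a window -> no windows
  expect_equal(nrow(window_scan(daf[1:19, ], window = 20, step = 10)), 0L)

  # windows never span scaffolds
  daf2 <- dplyr::bind_rows(daf, dplyr::mutate(daf, scaffold = "t"))
  w3 <- window_scan(daf2, window = 20, step = 10)
  expect_equal(nrow(w3), 4L)
  expect_equal(sort(unique(w3$scaffold)), c("s", "t"))
})

test_that("window scan agrees with a brute-force oracle", {
  set.seed(7)
  daf <- tibble::tibble(
    scaffold = rep(c("a", "b", "c"), c(53, 20, 8)),
    pos = c(sort(sample.int(1e5, 53)), sort(sample.int(1e5, 20)),
            sort(sample.int(1e5, 8))),
    mean_z = rnorm(81)
  )
  w <- window_scan(daf, window = 20, step = 10, offset = 3)
  oracle <- list()
  for (sc in c("a", "b", "c")) {
    d <- daf[daf$scaffold == sc, ]
    n <- nrow(d)
    s <- 3
    while (s + 19 <= n) {
      oracle[[length(oracle) + 1]] <- tibble::tibble(
        scaffold = sc, snp_start_index = s, start = d$pos[s],
        end = d$pos[s + 19], n_snps = 20L, stat = mean(d$mean_z[s:(s + 19)]))
      s <- s + 10
    }
  }
  oracle <- dplyr::bind_rows(oracle)
  expect_equal(as.data.frame(w), as.data.frame(oracle), tolerance = 1e-12)
})

test_that("scaffold selection keeps the longest with deterministic ties", {
  sl <- c(b = 100, a = 100, c = 500, d = 50)
  expect_equal(top_scaffold_names(sl, 2), c("c", "a"))
  expect_equal(top_scaffold_names(sl, 10), c("c", "a", "b", "d"))
  daf <- tibble::tibble(scaffold = rep(c("c", "d"), each = 25),
                        pos = rep(seq_len(25) * 10L, 2),
                        mean_z = rnorm(50))
  w <- window_scan(daf, window = 20, step = 10, top_scaffolds = 1,
                   scaffold_lengths = sl)
  expect_equal(unique(w$scaffold), "c")
})
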