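test_that("convergence cells are span means with the <2-SNP exclusion", {
  # hand-built scan object: two outlier windows, two lineages
  wins <- tibble::tibble(scaffold = "s", snp_start_index = c(1L, 1L),
                         start = c(100L, 5000L), end = c(1000L, 6000L),
                         n_snps = 20L, stat = c(2, 3))
  scan <- structure(list(outliers = list("99.9" = wins), lineage = "L1"),
                    class = "daf_scan")
  dafs <- list(
    L1 = tibble::tibble(scaffold = "s",
                        pos = c(100L, 500L, 1000L, 5500L, 6000L),
                        mean_z = c(1, 2, 3, 4, 6)),
    # L2 has a single SNP in window 1 (excluded) and two in window 2
    L2 = tibble::tibble(scaffold = "s", pos = c(500L, 5000L, 5999L),
                        mean_z = c(9, 1, 3))
  )
  cm <- convergence_matrix(scan, dafs, percentile = 99.9, min_snps = 2)
  expect_s3_class(cm, "convergence_tbl")
  l1 <- cm[cm$lineage == "L1", ]
  expect_equal(l1$mean_z, c(mean(c(1, 2, 3)), mean(c(4, 6))))
  expect_equal(l1$n_snps, c(3L, 2L))
  l2 <- cm[cm$lineage == "L2", ]
  expect_true(l2$excluded[1])
  expect_true(is.na(l2$mean_z[1]))
  expect_equal(l2$mean_z[2], mean(c(1, 3)))

  # brute-force oracle over a random layout
  set.seed(14)
  wins2 <- tibble::tibble(scaffold = rep(c("a", "b"), each = 4),
                          snp_start_index = 1L,
                          start = rep(seq(1L, 3001L, by = 1000L), 2),
                          end = rep(seq(900L, 3901L, by = 1000L), 2),
                          n_snps = 20L, stat = rnorm(8))
  scan2 <- structure(list(outliers = list("99.9" = wins2), lineage = "LX"),
                     class = "daf_scan")
  d <- tibble::tibble(scaffold = sample(c("a", "b"), 40, TRUE),
                      pos = sample.int(4000L, 40), mean_z = rnorm(40))
  cm2 <- convergence_matrix(scan2, list(LX = d), min_snps = 2)
  for (i in seq_len(nrow(wins2))) {
    inside <- d$scaffold == wins2$scaffold[i] &
      d$pos >= wins2$start[i] & d$pos <= wins2$end[i]
    row <- cm2[cm2$window_id == i, ]
    expect_equal(row$n_snps, sum(inside))
    if (sum(inside) >= 2) {
      expect_equal(row$mean_z, mean(d$mean_z[inside]))
    } else {
      expect_true(row$excluded)
    }
  }

  # no outlier windows -> empty matrix with a warning
  scan0 <- structure(list(outliers = list("99.9" = wins[0, ]), lineage = "L1"),
                     class = "daf_scan")
  expect_warning(cm0 <- convergence_matrix(scan0, dafs), "no")
  expect_equal(nrow(cm0), 0L)
})

test_that("convergence matrix exports excluded cells explicitly", {
  wins <- tibble::tibble(scaffold = "s", snp_start_index = 1L,
                         start = 100L, end = 1000L, n_snps = 20L, stat = 2)
  scan <- structure(list(outliers = list("99.9" = wins), lineage = "L1"),
                    class = "daf_scan")
  dafs <- list(L1 = tibble::tibble(scaffold = "s", pos = c(100L, 200L),
                                   mean_z = c(1, 3)),
               L2 = tibble::tibble(scaffold = "s", pos = 150L, mean_z = 9))
  cm <- convergence_matrix(scan, dafs)
  f <- withr::local_tempfile()
  write_convergence_matrix(cm, f)
  wide <- readr::read_tsv(f, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  expect_equal(wide$L2, "NA:lt2snps")
  expect_equal(as.numeric(wide$L1), 2)
})

test_that("shared nonsynonymous test thresholds and counts are exact", {
  mk <- function(n, z) tibble::tibble(scaffold = "s", pos = seq_len(n),
                                      mean_z = z)
  eff <- tibble::tibble(scaffold = "s", pos = 1:40,
                        effect = rep(c("nonsynonymous", "intronic"),
                                     times = c(20, 20)))
  za <- c(seq(0, 1.8, length.out = 19), 5)   # site 20 is the extreme one
  zb <- c(seq(0, 1.8, length.out = 19), 7)
  daf_a <- mk(40, c(za, rnorm(20)))
  daf_b <- mk(40, c(zb, rnorm(20)))
  res <- shared_nonsyn_test(daf_a, eff, daf_b, eff, percentile = 95,
                            units = c("A", "B"))
  # nearest rank: sort(z)[ceiling(0.95*20)] = 19th value
  expect_equal(unname(res$thresholds["A"]), sort(za)[19])
  expect_equal(unname(res$thresholds["B"]), sort(zb)[19])
  expect_equal(res$n_shared, 20L)
  # sites 19 and 20 reach the 19th value in both lineages
  expect_equal(res$n_top_both, 2L)
  expect_setequal(res$sites$pos[res$sites$top_both], c(19L, 20L))

  # empty / missing nonsynonymous sites are fatal
  eff_none <- dplyr::mutate(eff, effect = "intronic")
  expect_error(shared_nonsyn_test(daf_a, eff_none, daf_b, eff), "nonsynonymous")
  expect_error(shared_nonsyn_test(daf_a, eff[0, ], daf_b, eff), "empty")
})
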