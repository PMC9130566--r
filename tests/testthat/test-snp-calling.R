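test_that("biallelic filter works on lineage-wide summed counts", {
  m <- two_pool_manifest()
  counts <- dplyr::bind_rows(
    # biallelic only when summed: pool1 all-A, pool2 all-T
    make_counts("s", 100, "A", list(c(20, 0, 0, 0, 0, 0),
                                    c(0, 20, 0, 0, 0, 0)), m),
    # triallelic summed -> dropped
    make_counts("s", 200, "A", list(c(10, 10, 0, 0, 0, 0),
                                    c(10, 0, 10, 0, 0, 0)), m),
    # monomorphic -> dropped
    make_counts("s", 300, "A", list(c(20, 0, 0, 0, 0, 0),
                                    c(20, 0, 0, 0, 0, 0)), m),
    # clean biallelic in both
    make_counts("s", 400, "A", list(c(15, 5, 0, 0, 0, 0),
                                    c(12, 8, 0, 0, 0, 0)), m)
  )
  snps <- call_snps(counts, m)
  expect_equal(snps$pos, c(100L, 400L))
  # pos 100: major is the more frequent allele lineage-wide (tie -> base order)
  expect_equal(snps$major[2], "A")
  expect_equal(snps$minor[2], "T")
  expect_equal(snps$freq_sea1[2], 5 / 20)
  expect_equal(snps$freq_lake1[2], 8 / 20)
})

test_that("minor count and coverage bounds filter sites", {
  m <- two_pool_manifest()
  # mean coverage per pool is computed over all sites pre-filtering
  counts <- dplyr::bind_rows(
    # minor count 3 (< 4) -> dropped
    make_counts("s", 100, "A", list(c(18, 2, 0, 0, 0, 0),
                                    c(19, 1, 0, 0, 0, 0)), m),
    # coverage 9 in pool 2 (< 10) -> dropped
    make_counts("s", 200, "A", list(c(15, 5, 0, 0, 0, 0),
                                    c(5, 4, 0, 0, 0, 0)), m),
    # clean
    make_counts("s", 300, "A", list(c(15, 5, 0, 0, 0, 0),
                                    c(12, 8, 0, 0, 0, 0)), m),
    # clean
    make_counts("s", 400, "A", list(c(10, 10, 0, 0, 0, 0),
                                    c(16, 4, 0, 0, 0, 0)), m)
  )
  snps <- call_snps(counts, m)
  expect_equal(snps$pos, c(300L, 400L))
  # N/del count toward coverage: mean_cov attribute uses all six fields
  mc <- attr(snps, "mean_cov")
  expect_equal(unname(mc["sea1"]), mean(c(20, 20, 20, 20)))

  # upper bound: a site at > 2x the pool's genome-wide mean is dropped
  counts2 <- dplyr::bind_rows(
    make_counts("s", 100, "A", list(c(15, 5, 0, 0, 0, 0),
                                    c(15, 5, 0, 0, 0, 0)), m),
    make_counts("s", 200, "A", list(c(15, 5, 0, 0, 0, 0),
                                    c(15, 5, 0, 0, 0, 0)), m),
    make_counts("s", 300, "A", list(c(80, 20, 0, 0, 0, 0),
                                    c(15, 5, 0, 0, 0, 0)), m)
  )
  # sea1 mean = (20+20+100)/3 = 46.67; 100 > 2*46.67 -> site 300 dropped
  snps2 <- call_snps(counts2, m)
  expect_equal(snps2$pos, c(100L, 200L))
})

test_that("N and del reads count for coverage but not for alleles", {
  m <- two_pool_manifest()
  counts <- make_counts("s", 100, "A",
                        list(c(10, 5, 0, 0, 3, 2),
                             c(12, 8, 0, 0, 0, 0)), m)
  # add a second site so sd isn't an issue downstream
  counts <- dplyr::bind_rows(
    counts,
    make_counts("s", 200, "A", list(c(14, 6, 0, 0, 0, 0),
                                    c(10, 10, 0, 0, 0, 0)), m))
  snps <- call_snps(counts, m)
  expect_equal(snps$cov_sea1[1], 20L)       # 10+5+3+2
  expect_equal(snps$reads_sea1[1], 15L)     # allele reads only
  expect_equal(snps$freq_sea1[1], 5 / 15)   # denominator excludes N/del
})

test_that("indel proximity filter is inclusive at the boundary", {
  m <- two_pool_manifest()
  freq <- matrix(rep(c(0.2, 0.4), 5), ncol = 2, byrow = TRUE)
  counts <- make_sites(m, freq, pos = c(100L, 111L, 200L, 500L, 511L))
  snps <- call_snps(counts, m)
  indels <- tibble::tibble(scaffold = "scaf1", pos = c(110L, 490L))
  kept <- filter_near_indels(snps, indels, distance = 10L)
  # 100 (|100-110|=10 <= 10) dropped, 111 (1) dropped, 200 (90) kept,
  # 500 (10) dropped, 511 (21) kept
  expect_equal(kept$pos, c(200L, 511L))
  # attributes survive subsetting
  expect_equal(snp_pools(kept)$pool, m$pool)
  # no indels on a scaffold leaves it untouched
  expect_equal(filter_near_indels(snps,
    tibble::tibble(scaffold = "other", pos = 100L))$pos, snps$pos)
})

test_that("polymorphic sites include fixed non-reference differences", {
  m <- two_pool_manifest()
  counts <- dplyr::bind_rows(
    # segregating in pool 1
    make_counts("s", 100, "A", list(c(15, 5, 0, 0, 0, 0),
                                    c(20, 0, 0, 0, 0, 0)), m),
    # fixed difference, minor allele T absent from ref A: both pools fixed
    make_counts("s", 200, "A", list(c(20, 0, 0, 0, 0, 0),
                                    c(0, 20, 0, 0, 0, 0)), m),
    # ref is C but site is A/T: fixed for non-reference in every pool
    make_counts("s", 300, "C", list(c(20, 0, 0, 0, 0, 0),
                                    c(0, 20, 0, 0, 0, 0)), m)
  )
  snps <- call_snps(counts, m)
  poly <- polymorphic_sites(snps)
  expect_true(all(c(100L, 200L, 300L) %in% poly$pos))
})

test_that("multi-lineage manifests require an explicit lineage", {
  m <- dplyr::bind_rows(two_pool_manifest("L1"),
                        pool_manifest(c("sea2", "lake2"), "L2",
                                      c("anadromous", "freshwater"), 25L))
  counts <- make_sites(two_pool_manifest("L1"),
                       matrix(c(0.2, 0.4, 0.3, 0.5), ncol = 2, byrow = TRUE))
  expect_error(call_snps(counts, m), "several lineages")
  snps <- call_snps(counts, m, lineage = "L1")
  expect_equal(attr(snps, "lineage"), "L1")
  expect_equal(snp_pools(snps)$pool, c("sea1", "lake1"))
  expect_error(call_snps(counts, m, lineage = "L9"), "no pools")
})
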