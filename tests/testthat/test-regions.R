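mk_windows <- function(scaffold, start, end, stat = 1) {
  tibble::tibble(scaffold = scaffold, start = as.integer(start),
                 end = as.integer(end), stat = rep_len(stat, length(start)))
}

test_that("window merging respects the 20 kb gap boundary exactly", {
  # DERIVED: gap 20000 is inclusive on next.start - prev.end - 1, so a
  # window starting at end + 20001 merges and one at end + 20002 does not
  w <- mk_windows("s",
                  start = c(1000, 2000 + 20001, 60000 + 20002),
                  end = c(2000, 2000 + 20001 + 1000, 60000 + 20002 + 500),
                  stat = c(3, 5, 4))
  r <- merge_regions(w, gap = 20000)
  expect_equal(nrow(r), 2L)
  expect_equal(r$start[1], 1000L)
  expect_equal(r$end[1], 23001L)
  expect_equal(r$n_windows, c(2L, 1L))
  expect_equal(r$peak_stat, c(5, 4))
  expect_equal(nrow(r$windows[[1]]), 2L)

  # different scaffolds never merge
  w2 <- mk_windows(c("s", "t"), c(100, 100), c(200, 200))
  expect_equal(nrow(merge_regions(w2, gap = 20000)), 2L)

  # empty input gives an empty typed tibble
  expect_equal(nrow(merge_regions(w[0, ])), 0L)
})

test_that("gene annotation attaches genes within 20 kb, inclusive", {
  # region is [50000, 60000]; separation = intervening bases, so a gene
  # ending at 29999 sits exactly 20000 bases away (positions 30000..49999)
  regions <- merge_regions(mk_windows("s", 50000, 60000, 2.5), gap = 20000)
  genes <- tibble::tibble(
    scaffold = "s",
    start = c(29000L, 25000L, 80002L, 50500L, 80001L),
    end = c(29999L, 29998L, 81000L, 50900L, 80900L),
    strand = "+",
    gene_id = c("at_20000", "at_20001", "right_at_20001", "inside",
                "right_at_20000"),
    description = ""
  )
  ann <- annotate_genes(regions, genes, flank = 20000)
  ids <- strsplit(ann$gene_ids, ",")[[1]]
  expect_true("inside" %in% ids)
  expect_true("at_20000" %in% ids)            # 20000 bases away: attached
  expect_false("at_20001" %in% ids)           # 20001 bases away: not
  expect_true("right_at_20000" %in% ids)      # symmetric on the right
  expect_false("right_at_20001" %in% ids)
  expect_equal(ann$n_genes, length(ids))

  # no genes -> zero counts, not an error
  ann3 <- annotate_genes(regions, genes[0, ])
  expect_equal(ann3$n_genes, 0L)
})

test_that("shared region percentage is the mean of directional fractions", {
  # DERIVED: A has 2 regions (1 shared), B has 4 (1 shared):
  # 100 * mean(1/2, 1/4) = 37.5
  a <- mk_windows("s", c(100, 5000), c(200, 5100))
  b <- mk_windows("s", c(150, 9000, 12000, 20000),
                  c(250, 9100, 12100, 20100))
  res <- shared_regions(a, b, units = c("x", "y"))
  expect_equal(res$pct_shared, 37.5)
  expect_equal(res$n_shared_a, 1L)
  expect_equal(res$n_shared_b, 1L)
  # symmetric
  expect_equal(shared_regions(b, a)$pct_shared, 37.5)
  # empty set warns and reports 0
  expect_warning(z <- shared_regions(a[0, ], b), "empty")
  expect_equal(z$pct_shared, 0)
})

test_that("shared_across returns loci present in every set", {
  a <- mk_windows("s", 100, 500)
  b <- mk_windows("s", 300, 800)
  c3 <- mk_windows("s", 400, 450)
  res <- shared_across(list(a, b, c3))
  expect_equal(nrow(res), 1L)
  expect_equal(res$start, 400L)
  expect_equal(res$end, 450L)
  expect_equal(nrow(shared_across(list(a, mk_windows("t", 100, 200)))), 0L)
  expect_equal(nrow(shared_across(list(a, b[0, ]))), 0L)
})

test_that("shared polymorphism matches sites by scaffold and position", {
  a <- tibble::tibble(scaffold = "s", pos = c(1L, 2L, 3L, 4L))
  b <- tibble::tibble(scaffold = c("s", "s", "t"), pos = c(2L, 4L, 2L))
  res <- shared_polymorphism(a, b, units = c("A", "B"))
  expect_equal(res$n_shared, 2L)
  # 100 * mean(2/4, 2/3)
  expect_equal(res$pct_shared, 100 * mean(c(0.5, 2 / 3)))
  expect_error(shared_polymorphism(a[0, ], b), "non-empty")
})

test_that("pairwise parallelism covers every unordered pair", {
  sets <- list(A = mk_windows("s", 100, 200),
               B = mk_windows("s", 150, 250),
               C = mk_windows("s", 1000, 1100))
  sites <- list(A = tibble::tibble(scaffold = "s", pos = 1:10),
                B = tibble::tibble(scaffold = "s", pos = 6:15),
                C = tibble::tibble(scaffold = "s", pos = 11:20))
  tab <- pairwise_parallelism(sets, sites)
  expect_equal(nrow(tab), 3L)
  ab <- tab[tab$unit_a == "A" & tab$unit_b == "B", ]
  expect_equal(ab$pct_shared_regions, 100)
  expect_equal(ab$pct_shared_polymorphism, 50)  # 5/10 both directions
  ac <- tab[tab$unit_a == "A" & tab$unit_b == "C", ]
  expect_equal(ac$pct_shared_regions, 0)
})
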