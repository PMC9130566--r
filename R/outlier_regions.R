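regions_gr <- function(tbl, flank = 0L) {
  start <- pmax(1L, tbl$start - flank)
  GenomicRanges::GRanges(tbl$scaffold, IRanges::IRanges(start, tbl$end + flank))
}

#' Merge outlier windows into genomic outlier regions
#'
#' Outlier windows on the same scaffold that overlap or whose spans are
#' separated by at most `gap` bases (`next.start - prev.end - 1 <= gap`) are
#' merged transitively; each merged region spans the union hull of its
#' windows. Neighbouring extreme windows often reflect selection on a single
#' locus, so merging gives a more conservative count of candidate loci.
#'
#' @param outlier_windows Window tibble (e.g. from [call_outliers()]).
#' @param gap Maximum separation in bases for merging (default 20000,
#'   inclusive).
#' @return Tibble with `scaffold`, `start`, `end`, `n_windows`, `peak_stat`,
#'   and a `windows` list-column holding each region's constituent windows.
#' @export
merge_regions <- function(outlier_windows, gap = 20000L) {
  if (nrow(outlier_windows) == 0L) {
    return(tibble(scaffold = character(), start = integer(), end = integer(),
                  n_windows = integer(), peak_stat = double(),
                  windows = list()))
  }
  w <- arrange(outlier_windows, .data$scaffold, .data$start)
  gr <- regions_gr(w)
  red <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1L)
  hit <- GenomicRanges::findOverlaps(gr, red)
  grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  out <- tibble(
    scaffold = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red),
    end = GenomicRanges::end(red),
    n_windows = as.integer(tabulate(grp, nbins = length(red))),
    peak_stat = unname(vapply(split(w$stat, grp), max, numeric(1))[
      as.character(seq_along(red))]),
    windows = unname(split(w, grp))[order(unique(grp))]
  )
  arrange(out, .data$scaffold, .data$start)
}

#' Annotate genes near outlier regions
#'
#' A gene is attached to a region when it overlaps the region or is separated
#' from it by at most `flank` intervening bases (the same distance convention
#' as [merge_regions()]); genes within 20 kb of an outlier region are
#' considered possible targets of selection.
#'
#' @param regions Region tibble from [merge_regions()].
#' @param genes Gene tibble from [read_gene_models()].
#' @param flank Maximum separation in bases (default 20000, inclusive).
#' @return `regions` with `genes` (list-column of gene rows), `n_genes`, and
#'   `gene_ids` (comma-separated) added.
#' @export
annotate_genes <- function(regions, genes, flank = 20000L) {
  if (nrow(regions) == 0L) {
    regions$genes <- list()
    regions$n_genes <- integer()
    regions$gene_ids <- character()
    return(regions)
  }
  if (is.null(genes) || nrow(genes) == 0L) {
    regions$genes <- rep(list(genes %||% tibble()), nrow(regions))
    regions$n_genes <- 0L
    regions$gene_ids <- ""
    return(regions)
  }
  # extending by flank + 1 makes "separated by exactly `flank` bases" touch,
  # matching the inclusive intervening-bases rule used by merge_regions()
  rg <- regions_gr(regions, flank = flank + 1L)
  gg <- regions_gr(genes)
  hit <- suppressWarnings(GenomicRanges::findOverlaps(rg, gg))
  q <- S4Vectors::queryHits(hit)
  s <- S4Vectors::subjectHits(hit)
  glist <- rep(list(genes[0, , drop = FALSE]), nrow(regions))
  for (i in unique(q)) glist[[i]] <- genes[s[q == i], , drop = FALSE]
  regions$genes <- glist
  regions$n_genes <- vapply(glist, nrow, integer(1))
  regions$gene_ids <- vapply(glist, function(g) {
    paste(g$gene_id, collapse = ",")
  }, character(1))
  regions
}

#' Percentage of outlier regions shared by two region sets
#'
#' A region of one set is shared when it overlaps (by at least 1 bp) any
#' region of the other set; the reported percentage is the mean of the two
#' directional fractions, `100 * mean(shared_A/|A|, shared_B/|B|)`, which is
#' symmetric in the arguments.
#'
#' @param a,b Region tibbles on the same reference coordinates.
#' @param units Optional length-2 character vector naming the two sets.
#' @return One-row tibble: `unit_a`, `unit_b`, `n_a`, `n_b`, `n_shared_a`,
#'   `n_shared_b`, `pct_shared`.
#' @export
shared_regions <- function(a, b, units = c("A", "B")) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    warn("one region set is empty; shared percentage is 0")
    return(tibble(unit_a = units[1], unit_b = units[2],
                  n_a = nrow(a), n_b = nrow(b),
                  n_shared_a = 0L, n_shared_b = 0L, pct_shared = 0))
  }
  ga <- regions_gr(a)
  gb <- regions_gr(b)
  # sets whose scaffolds only partly coincide are valid input, not a
  # seqlevel mismatch worth a GenomicRanges warning
  sa <- sum(suppressWarnings(GenomicRanges::countOverlaps(ga, gb)) > 0L)
  sb <- sum(suppressWarnings(GenomicRanges::countOverlaps(gb, ga)) > 0L)
  tibble(unit_a = units[1], unit_b = units[2],
         n_a = nrow(a), n_b = nrow(b),
         n_shared_a = as.integer(sa), n_shared_b = as.integer(sb),
         pct_shared = 100 * mean(c(sa / nrow(a), sb / nrow(b))))
}

#' Loci where every region set overlaps (complete parallelism)
#'
#' Returns the maximal genomic intervals covered by at least one region in
#' *every* input set — candidate loci under selection in all the populations
#' or lineages compared.
#'
#' @param sets A list of two or more region tibbles.
#' @return Tibble `scaffold`, `start`, `end` of the shared loci (empty if
#'   any set is empty).
#' @export
shared_across <- function(sets) {
  stopifnot(length(sets) >= 2L)
  if (any(vapply(sets, nrow, integer(1)) == 0L)) {
    return(tibble(scaffold = character(), start = integer(), end = integer()))
  }
  grs <- lapply(sets, function(s) GenomicRanges::reduce(regions_gr(s)))
  inter <- Reduce(function(x, y) {
    # sets on disjoint scaffolds are a valid (empty) intersection, not a
    # condition worth a GenomicRanges warning
    suppressWarnings(GenomicRanges::intersect(x, y, ignore.strand = TRUE))
  }, grs)
  tibble(scaffold = as.character(GenomicRanges::seqnames(inter)),
         start = GenomicRanges::start(inter),
         end = GenomicRanges::end(inter))
}

#' Percentage of polymorphism shared by two lineages
#'
#' Sites are matched by (scaffold, position). Because lineages differ in
#' their total SNP counts, the percentage is the mean of the two directional
#' fractions: `100 * mean(|A n B|/|A|, |A n B|/|B|)`.
#'
#' @param a,b Site tibbles with columns `scaffold`, `pos` (e.g. from
#'   [polymorphic_sites()]).
#' @param units Optional names for the two lineages.
#' @return One-row tibble: `unit_a`, `unit_b`, `n_a`, `n_b`, `n_shared`,
#'   `pct_shared`.
#' @export
shared_polymorphism <- function(a, b, units = c("A", "B")) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    abort("shared_polymorphism: site sets must be non-empty")
  }
  ka <- paste(a$scaffold, a$pos)
  kb <- paste(b$scaffold, b$pos)
  ns <- length(intersect(ka, kb))
  tibble(unit_a = units[1], unit_b = units[2],
         n_a = length(unique(ka)), n_b = length(unique(kb)),
         n_shared = ns,
         pct_shared = 100 * mean(c(ns / length(unique(ka)),
                                   ns / length(unique(kb)))))
}

#' Pairwise parallelism matrix
#'
#' For every pair of units, reports the percentage of outlier regions shared
#' and (when site sets are given) the percentage of polymorphism shared.
#'
#' @param region_sets Named list of region tibbles, one per unit.
#' @param site_sets Optional named list of polymorphic-site tibbles matching
#'   `region_sets` names.
#' @return Tibble with one row per unordered pair.
#' @export
pairwise_parallelism <- function(region_sets, site_sets = NULL) {
  nm <- names(region_sets)
  stopifnot(!is.null(nm), length(nm) >= 2L)
  pairs <- utils::combn(nm, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    u <- pairs[1, k]; v <- pairs[2, k]
    r <- shared_regions(region_sets[[u]], region_sets[[v]], units = c(u, v))
    r$pct_shared_regions <- r$pct_shared
    r$pct_shared <- NULL
    if (!is.null(site_sets)) {
      sp <- shared_polymorphism(site_sets[[u]], site_sets[[v]], units = c(u, v))
      r$pct_shared_polymorphism <- sp$pct_shared
      r$n_shared_sites <- sp$n_shared
    }
    r
  })
  bind_rows(rows)
}

#' Write a parallelism table to TSV
#' @param parallelism Tibble from [pairwise_parallelism()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parallelism <- function(parallelism, path) {
  readr::write_tsv(parallelism, path)
  invisible(path)
}
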