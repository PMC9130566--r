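#' Pool manifest
#'
#' Describes the sequenced pools: one row per pool with its lineage, life
#' history (anadromous or freshwater), and the number of diploid individuals
#' pooled. The haploid pool size used by downstream estimators is twice the
#' number of individuals, the usual convention for diploid pools.
#'
#' @param pool Character vector of pool names (unique).
#' @param lineage Character vector, the lineage each pool belongs to.
#' @param life_history `"anadromous"` or `"freshwater"` per pool.
#' @param n_individuals Positive integer, diploid individuals per pool.
#' @return A tibble with columns `pool`, `lineage`, `life_history`,
#'   `n_individuals`, `haploid_size`.
#' @examples
#' pool_manifest(
#'   pool = c("sea1", "lake1"), lineage = "L1",
#'   life_history = c("anadromous", "freshwater"), n_individuals = 29
#' )
#' @export
pool_manifest <- function(pool, lineage, life_history, n_individuals) {
  m <- tibble(
    pool = as.character(pool),
    lineage = as.character(lineage),
    life_history = as.character(life_history),
    n_individuals = as.integer(n_individuals)
  )
  m$haploid_size <- 2L * m$n_individuals
  validate_manifest(m)
  m
}

validate_manifest <- function(m) {
  req <- c("pool", "lineage", "life_history", "n_individuals")
  missing_cols <- setdiff(req, names(m))
  if (length(missing_cols)) {
    abort(paste0("pool manifest lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(m$pool)) abort("pool names must be unique")
  bad <- !m$life_history %in% c("anadromous", "freshwater")
  if (any(bad)) {
    abort(paste0("life_history must be 'anadromous' or 'freshwater'; got: ",
                 paste(unique(m$life_history[bad]), collapse = ", ")))
  }
  if (any(is.na(m$n_individuals)) || any(m$n_individuals < 1L)) {
    abort("n_individuals must be a positive integer")
  }
  invisible(m)
}

#' Read a pool manifest from a TSV file
#'
#' Expects a header line with columns `pool`, `lineage`, `life_history`,
#' `n_individuals`. A `haploid_size` column is recomputed as
#' `2 * n_individuals` regardless of input.
#'
#' @param path Path to a tab-separated manifest.
#' @return A validated manifest tibble (see [pool_manifest()]).
#' @export
read_pool_manifest <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  m$n_individuals <- as.integer(m$n_individuals)
  pool_manifest(m$pool, m$lineage, m$life_history, m$n_individuals)
}

#' Write a pool manifest to TSV
#' @param manifest A manifest tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pool_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  readr::write_tsv(manifest, path)
  invisible(path)
}

sync_count_cols <- c("A", "T", "C", "G", "N", "del")

#' Read a Popoolation2 sync file
#'
#' The sync format is tab-separated: scaffold, 1-based position, reference
#' base, then one column per pool holding colon-separated counts in the order
#' `A:T:C:G:N:del`. The number of pool columns must match the manifest; pools
#' are matched to manifest rows by column order.
#'
#' @param path Path to a sync file.
#' @param manifest Pool manifest; its rows name the pool columns in order.
#' @return A long tibble with one row per site x pool: columns `scaffold`,
#'   `pos`, `ref`, `pool`, `A`, `T`, `C`, `G`, `N`, `del`. Rows are in file
#'   order (site-major, pools in manifest order).
#' @export
read_sync <- function(path, manifest) {
  validate_manifest(manifest)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n_pools <- nrow(manifest)
  if (length(lines) == 0L) {
    warn(paste0("sync file is empty: ", path))
    return(empty_counts(manifest))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  len <- lengths(fields)
  want <- 3L + n_pools
  if (any(len != want)) {
    bad <- which(len != want)[1L]
    abort(paste0(
      "sync line ", bad, " has ", len[bad], " columns; expected ", want,
      " (3 + ", n_pools, " pools)"
    ))
  }
  mat <- matrix(unlist(fields, use.names = FALSE), ncol = want, byrow = TRUE)
  pos <- suppressWarnings(as.integer(mat[, 2L]))
  if (anyNA(pos)) {
    abort(paste0("non-integer position at sync line ",
                 which(is.na(pos))[1L]))
  }
  n_sites <- nrow(mat)
  # one block of count columns per pool, then interleave site-major
  count_list <- vector("list", n_pools)
  for (j in seq_len(n_pools)) {
    toks <- strsplit(mat[, 3L + j], ":", fixed = TRUE)
    if (any(lengths(toks) != 6L)) {
      bad <- which(lengths(toks) != 6L)[1L]
      abort(paste0("sync line ", bad, ", pool '", manifest$pool[j],
                   "': expected 6 colon-separated counts"))
    }
    cm <- matrix(suppressWarnings(as.integer(unlist(toks, use.names = FALSE))),
                 ncol = 6L, byrow = TRUE)
    if (anyNA(cm)) {
      bad <- which(rowSums(is.na(cm)) > 0L)[1L]
      abort(paste0("non-integer count at sync line ", bad, ", pool '",
                   manifest$pool[j], "'"))
    }
    count_list[[j]] <- cm
  }
  big <- matrix(0L, nrow = n_sites * n_pools, ncol = 6L)
  idx <- rep(seq_len(n_sites), each = n_pools)
  for (j in seq_len(n_pools)) {
    big[seq(j, by = n_pools, length.out = n_sites), ] <- count_list[[j]]
  }
  out <- tibble(
    scaffold = mat[idx, 1L],
    pos = pos[idx],
    ref = mat[idx, 3L],
    pool = rep(manifest$pool, times = n_sites)
  )
  for (k in seq_along(sync_count_cols)) out[[sync_count_cols[k]]] <- big[, k]
  out
}

empty_counts <- function(manifest) {
  out <- tibble(scaffold = character(), pos = integer(), ref = character(),
                pool = character())
  for (k in sync_count_cols) out[[k]] <- integer()
  out
}

#' Write site counts to a sync file
#'
#' Inverse of [read_sync()]: a canonical sync file survives a
#' read/write round trip byte-identically.
#'
#' @param counts Long counts tibble as returned by [read_sync()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(counts, path) {
  pools <- unique(counts$pool)
  n_pools <- length(pools)
  if (nrow(counts) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  stopifnot(nrow(counts) %% n_pools == 0L)
  n_sites <- nrow(counts) / n_pools
  cm <- as.matrix(counts[, sync_count_cols])
  tok <- paste(cm[, 1], cm[, 2], cm[, 3], cm[, 4], cm[, 5], cm[, 6], sep = ":")
  tokm <- matrix(tok, nrow = n_pools)          # site-major rows -> pools x sites
  site_rows <- seq(1L, nrow(counts), by = n_pools)
  lines <- paste(counts$scaffold[site_rows], counts$pos[site_rows],
                 counts$ref[site_rows], sep = "\t")
  pool_part <- apply(tokm, 2L, paste, collapse = "\t")
  writeLines(paste(lines, pool_part, sep = "\t"), path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Only records of type `gene` are retained; coordinates stay 1-based
#' inclusive as in the file. Records with `start > end` are dropped with a
#' warning.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with columns `scaffold`, `start`, `end`, `strand`,
#'   `gene_id`, `description`.
#' @export
read_gene_models <- function(path) {
  empty <- tibble(scaffold = character(), start = integer(), end = integer(),
                  strand = character(), gene_id = character(),
                  description = character())
  raw <- tryCatch(
    as.data.frame(rtracklayer::readGFF(path)),
    error = function(e) NULL
  )
  if (is.null(raw) || nrow(raw) == 0L) return(empty)
  raw <- raw[raw$type == "gene", , drop = FALSE]
  if (nrow(raw) == 0L) return(empty)
  bad <- raw$start > raw$end
  if (any(bad)) {
    warn(paste0("dropping ", sum(bad), " gene record(s) with start > end"))
    raw <- raw[!bad, , drop = FALSE]
  }
  desc <- if ("description" %in% names(raw)) as.character(raw$description)
          else rep(NA_character_, nrow(raw))
  tibble(
    scaffold = as.character(raw$seqid),
    start = as.integer(raw$start),
    end = as.integer(raw$end),
    strand = as.character(raw$strand),
    gene_id = as.character(raw$ID %||% raw$gene_id),
    description = desc
  )
}

#' Write gene models as GFF3
#' @param genes Gene tibble as from [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  header <- "##gff-version 3"
  if (nrow(genes) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  attrs <- paste0("ID=", genes$gene_id,
                  ifelse(is.na(genes$description) | genes$description == "",
                         "", paste0(";description=", genes$description)))
  lines <- paste(genes$scaffold, "poolscan", "gene", genes$start, genes$end,
                 ".", genes$strand, ".", attrs, sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write outlier regions as BED6
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' `bed_start = start - 1` and `bed_end = end`. The score column carries the
#' region's peak window statistic.
#'
#' @param regions Region tibble (see [merge_regions()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  regions <- arrange(regions, .data$scaffold, .data$start)
  lines <- paste(regions$scaffold,
                 regions$start - 1L,
                 regions$end,
                 paste0("region_", seq_len(nrow(regions))),
                 format(regions$peak_stat, trim = TRUE),
                 ".",
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of regions back to 1-based inclusive coordinates
#' @param path Path to a BED file written by [write_regions_bed()].
#' @return Tibble with `scaffold`, `start`, `end`, `name`, `peak_stat`.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(scaffold = character(), start = integer(), end = integer(),
                  name = character(), peak_stat = double()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  m <- matrix(unlist(f, use.names = FALSE), ncol = length(f[[1L]]), byrow = TRUE)
  tibble(
    scaffold = m[, 1L],
    start = as.integer(m[, 2L]) + 1L,
    end = as.integer(m[, 3L]),
    name = if (ncol(m) >= 4L) m[, 4L] else NA_character_,
    peak_stat = if (ncol(m) >= 5L) as.numeric(m[, 5L]) else NA_real_
  )
}

#' Variant-effect classes recognised in effect tables
#' @return Character vector of the seven effect classes.
#' @export
effect_classes <- function() {
  c("nonsynonymous", "synonymous", "UTR", "upstream", "downstream",
    "intronic", "intergenic")
}

#' Read a variant-effect table
#'
#' Tab-separated with header columns `scaffold`, `pos`, `effect`; the effect
#' must be one of [effect_classes()].
#'
#' @param path Path to a TSV effect table.
#' @return Tibble `scaffold`, `pos`, `effect`.
#' @export
read_effects <- function(path) {
  e <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         scaffold = "c", pos = "i", effect = "c"))
  bad <- !e$effect %in% effect_classes()
  if (any(bad)) {
    abort(paste0("unknown effect class(es): ",
                 paste(unique(e$effect[bad]), collapse = ", ")))
  }
  e
}

#' Write a variant-effect table
#' @param effects Tibble `scaffold`, `pos`, `effect`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_effects <- function(effects, path) {
  readr::write_tsv(effects[, c("scaffold", "pos", "effect")], path)
  invisible(path)
}

#' Read indel positions (TSV with header `scaffold`, `pos`)
#' @param path Path to a TSV file.
#' @return Tibble `scaffold`, `pos`.
#' @export
read_indels <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(scaffold = "c", pos = "i"))
}
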