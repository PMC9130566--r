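#' Configuration for the synthetic pool-seq generator
#'
#' Defines a multi-lineage pooled-sequencing experiment with known truth:
#' scaffolded genome, SNPs shared between lineages at a controlled rate,
#' neutral drift between pools on the logit scale, planted
#' freshwater-selected regions with a target allele-frequency shift, and
#' binomial read sampling at Poisson coverage. Defaults mirror a typical
#' pooled resequencing design: pools of 29 diploid individuals sequenced to
#' a mean 32x coverage, two anadromous and two freshwater pools per lineage.
#'
#' @param n_lineages Number of lineages (default 2).
#' @param pools_per_lineage List of length-2 integer vectors
#'   `c(anadromous, freshwater)` per lineage, recycled (default `c(2, 2)`).
#' @param n_scaffolds,scaffold_length Genome shape; scaffold lengths taper
#'   linearly from `scaffold_length` down to half of it.
#' @param n_snps SNPs per lineage (default 50000).
#' @param ancestral_shape1,ancestral_shape2 Beta parameters of the ancestral
#'   (alternative-allele) frequency distribution (default 0.8, 0.8).
#' @param drift_sd Per-pool logit-scale drift standard deviation
#'   (default 0.5).
#' @param planted_regions Tibble `scaffold`, `start`, `end`, `delta`
#'   (target |dAF| shift, in `[0, 1]`) of freshwater-selected regions, or
#'   `NULL` for none. Regions are planted in every lineage (complete
#'   parallelism) unless `planted_lineages` narrows them.
#' @param planted_lineages Optional character vector of lineages carrying
#'   the planted regions (`NULL` = all).
#' @param planted_fresh_pools Optional character vector restricting the
#'   shift to certain freshwater pools, for partial-parallelism scenarios
#'   (`NULL` = all freshwater pools).
#' @param min_snps_per_region Guarantee at least this many SNP positions
#'   inside every planted region (default 0 = purely uniform placement).
#' @param coverage_mean Poisson mean read depth per pool; scalar or one
#'   value per pool of a lineage (default 32).
#' @param shared_fraction Fraction of SNP positions shared between lineages
#'   (default 0.5).
#' @param pool_n_individuals Diploid individuals per pool (default 29).
#' @param effect_rates Named probabilities over [effect_classes()] used to
#'   label SNPs in the effect table.
#' @param force_planted_nonsyn Label every SNP inside a planted region
#'   nonsynonymous (default `FALSE`).
#' @param n_indels Random indel positions to emit for the indel-proximity
#'   filter (default 0).
#' @param genes_per_scaffold Background toy genes per scaffold (default 2).
#' @param seed Integer master seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_lineages = 2L,
                       pools_per_lineage = list(c(2L, 2L)),
                       n_scaffolds = 20L,
                       scaffold_length = 1e6,
                       n_snps = 50000L,
                       ancestral_shape1 = 0.8,
                       ancestral_shape2 = 0.8,
                       drift_sd = 0.5,
                       planted_regions = NULL,
                       planted_lineages = NULL,
                       planted_fresh_pools = NULL,
                       min_snps_per_region = 0L,
                       coverage_mean = 32,
                       shared_fraction = 0.5,
                       pool_n_individuals = 29L,
                       effect_rates = c(nonsynonymous = 0.02,
                                        synonymous = 0.04, UTR = 0.03,
                                        upstream = 0.03, downstream = 0.03,
                                        intronic = 0.35, intergenic = 0.50),
                       force_planted_nonsyn = FALSE,
                       n_indels = 0L,
                       genes_per_scaffold = 2L,
                       seed = 1L) {
  stopifnot(shared_fraction >= 0, shared_fraction <= 1,
            n_snps >= 1L, n_scaffolds >= 1L, drift_sd >= 0)
  if (!is.null(planted_regions)) {
    stopifnot(all(c("scaffold", "start", "end", "delta") %in%
                    names(planted_regions)))
    stopifnot(all(planted_regions$delta >= 0),
              all(planted_regions$delta <= 1))
  }
  if (length(pools_per_lineage) < n_lineages) {
    pools_per_lineage <- rep(pools_per_lineage,
                             length.out = n_lineages)
  }
  stopifnot(all(names(effect_rates) %in% effect_classes()))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a multi-lineage pool-seq dataset with known truth
#'
#' Draws SNP positions per lineage with the configured cross-lineage
#' sharing, an ancestral alternative-allele frequency per position from a
#' Beta distribution, per-pool frequencies as ancestral plus Normal logit
#' drift, and read counts as Poisson coverage with binomial allele
#' sampling. Freshwater pools inside planted regions have their base
#' frequency shifted so the expected |dAF| against anadromous pools equals
#' the region's `delta` (the shift direction is chosen to stay in `[0, 1]`;
#' infeasible shifts are clipped with a warning). Fully deterministic given
#' the config seed.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `poolseq_sim`: list with `counts` (named list of
#'   long sync-shaped count tibbles per lineage), `manifest`,
#'   `scaffold_lengths`, `truth` (planted regions per lineage, true per-pool
#'   frequencies, effect table, toy genes, indel positions), and `config`.
#' @export
simulate_poolseq <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, simulate_poolseq_impl(cfg),
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

simulate_poolseq_impl <- function(cfg) {
  n_scaf <- cfg$n_scaffolds
  scaf_names <- sprintf("scaf%03d", seq_len(n_scaf))
  taper <- if (n_scaf == 1L) 1 else 1 - 0.5 * (seq_len(n_scaf) - 1) / (n_scaf - 1)
  lengths <- setNames(round(cfg$scaffold_length * taper), scaf_names)

  lineages <- sprintf("L%d", seq_len(cfg$n_lineages))
  manifest <- build_sim_manifest(cfg, lineages)

  pr <- cfg$planted_regions
  planted_lineages <- cfg$planted_lineages %||% lineages

  # --- SNP positions ----------------------------------------------------
  n_forced <- 0L
  forced <- NULL
  if (!is.null(pr) && cfg$min_snps_per_region > 0L) {
    forced <- bind_rows(lapply(seq_len(nrow(pr)), function(r) {
      span <- pr$start[r]:pr$end[r]
      k <- min(cfg$min_snps_per_region, length(span))
      tibble(scaffold = pr$scaffold[r], pos = sort(sample(span, k)))
    }))
    forced <- distinct(forced, .data$scaffold, .data$pos)
    n_forced <- nrow(forced)
  }
  n_shared <- round(cfg$shared_fraction * cfg$n_snps)
  n_shared <- max(n_shared, n_forced)   # forced positions live in every lineage
  shared <- sample_positions(n_shared - n_forced, lengths,
                             exclude = forced)
  shared <- bind_rows(forced, shared)
  pos_by_lineage <- lapply(lineages, function(l) {
    priv <- sample_positions(cfg$n_snps - nrow(shared), lengths,
                             exclude = shared)
    arrange(bind_rows(shared, priv), .data$scaffold, .data$pos)
  })
  names(pos_by_lineage) <- lineages

  # --- global allele map ------------------------------------------------
  all_pos <- distinct(bind_rows(pos_by_lineage), .data$scaffold, .data$pos)
  all_pos <- arrange(all_pos, .data$scaffold, .data$pos)
  bases <- c("A", "C", "G", "T")
  ref_i <- sample.int(4L, nrow(all_pos), replace = TRUE)
  alt_i <- ((ref_i - 1L + sample.int(3L, nrow(all_pos), replace = TRUE)) %% 4L) + 1L
  all_pos$ref <- bases[ref_i]
  all_pos$alt <- bases[alt_i]
  all_pos$anc_freq <- rbeta(nrow(all_pos), cfg$ancestral_shape1,
                            cfg$ancestral_shape2)
  key_all <- paste(all_pos$scaffold, all_pos$pos)

  in_region <- function(scaffold, pos) {
    hit <- rep(FALSE, length(pos))
    if (is.null(pr)) return(hit)
    for (r in seq_len(nrow(pr))) {
      hit <- hit | (scaffold == pr$scaffold[r] &
                      pos >= pr$start[r] & pos <= pr$end[r])
    }
    hit
  }

  clipped_any <- FALSE
  counts <- vector("list", length(lineages))
  true_freqs <- vector("list", length(lineages))
  names(counts) <- names(true_freqs) <- lineages

  for (l in lineages) {
    sites <- pos_by_lineage[[l]]
    m <- match(paste(sites$scaffold, sites$pos), key_all)
    sites$ref <- all_pos$ref[m]
    sites$alt <- all_pos$alt[m]
    p0 <- all_pos$anc_freq[m]
    pools <- manifest[manifest$lineage == l, , drop = FALSE]
    n_pools <- nrow(pools)
    n_sites <- nrow(sites)
    covm <- rep(cfg$coverage_mean, length.out = n_pools)

    planted_here <- l %in% planted_lineages & !is.null(pr)
    reg_hit <- if (planted_here) in_region(sites$scaffold, sites$pos)
               else rep(FALSE, n_sites)
    delta_site <- rep(0, n_sites)
    if (planted_here && any(reg_hit)) {
      for (r in seq_len(nrow(pr))) {
        sel <- sites$scaffold == pr$scaffold[r] &
          sites$pos >= pr$start[r] & sites$pos <= pr$end[r]
        delta_site[sel] <- pr$delta[r]
      }
    }
    shift_up <- p0 + delta_site <= 1
    target <- ifelse(shift_up, p0 + delta_site, p0 - delta_site)
    if (any(target < 0 | target > 1)) {
      clipped_any <- TRUE
      target <- pmin(pmax(target, 0), 1)
    }

    eps <- 1e-6
    freq <- matrix(0, n_sites, n_pools)
    shifted_fresh <- pools$life_history == "freshwater" &
      (is.null(cfg$planted_fresh_pools) |
         pools$pool %in% (cfg$planted_fresh_pools %||% character()))
    for (j in seq_len(n_pools)) {
      base <- if (shifted_fresh[j]) ifelse(delta_site > 0, target, p0) else p0
      lg <- qlogis(pmin(pmax(base, eps), 1 - eps))
      freq[, j] <- plogis(lg + rnorm(n_sites, 0, cfg$drift_sd))
    }

    cov <- matrix(rpois(n_sites * n_pools, rep(covm, each = n_sites)),
                  n_sites, n_pools)
    alt_reads <- matrix(rbinom(n_sites * n_pools, as.vector(cov),
                               as.vector(freq)), n_sites, n_pools)
    ref_reads <- cov - alt_reads

    counts[[l]] <- assemble_counts(sites, pools, alt_reads, ref_reads)
    tf <- sites[, c("scaffold", "pos", "ref", "alt")]
    for (j in seq_len(n_pools)) tf[[paste0("freq_", pools$pool[j])]] <- freq[, j]
    true_freqs[[l]] <- tf
  }
  if (clipped_any) {
    warn("some planted shifts pushed frequencies outside [0, 1]; clipped")
  }

  # --- effect table, genes, indels -------------------------------------
  eff <- all_pos[, c("scaffold", "pos")]
  pr_hit <- in_region(eff$scaffold, eff$pos)
  classes <- names(cfg$effect_rates)
  eff$effect <- sample(classes, nrow(eff), replace = TRUE,
                       prob = cfg$effect_rates)
  if (isTRUE(cfg$force_planted_nonsyn)) eff$effect[pr_hit] <- "nonsynonymous"

  genes <- sim_genes(pr, lengths, cfg$genes_per_scaffold)
  indels <- if (cfg$n_indels > 0L) {
    sample_positions(cfg$n_indels, lengths, exclude = NULL)
  } else tibble(scaffold = character(), pos = integer())

  truth_regions <- if (is.null(pr)) {
    tibble(lineage = character(), scaffold = character(), start = integer(),
           end = integer(), delta = double())
  } else {
    tidyr::expand_grid(lineage = planted_lineages, pr)
  }

  structure(
    list(counts = counts, manifest = manifest, scaffold_lengths = lengths,
         truth = list(regions = truth_regions, freqs = true_freqs,
                      effects = eff, genes = genes, indels = indels),
         config = cfg),
    class = "poolseq_sim"
  )
}

build_sim_manifest <- function(cfg, lineages) {
  rows <- lapply(seq_along(lineages), function(i) {
    np <- cfg$pools_per_lineage[[i]]
    tibble(
      pool = c(sprintf("%s_anad%d", lineages[i], seq_len(np[1])),
               sprintf("%s_fresh%d", lineages[i], seq_len(np[2]))),
      lineage = lineages[i],
      life_history = rep(c("anadromous", "freshwater"), times = np),
      n_individuals = as.integer(cfg$pool_n_individuals)
    )
  })
  m <- bind_rows(rows)
  m$haploid_size <- 2L * m$n_individuals
  validate_manifest(m)
  m
}

# k distinct positions uniform over the genome, avoiding `exclude`
sample_positions <- function(k, lengths, exclude = NULL) {
  out <- tibble(scaffold = character(), pos = integer())
  if (k <= 0L) return(out)
  excl_keys <- if (is.null(exclude) || nrow(exclude) == 0L) character()
               else paste(exclude$scaffold, exclude$pos)
  total <- sum(lengths)
  brk <- cumsum(lengths)
  deficit <- k
  guard <- 0L
  while (deficit > 0L && guard < 50L) {
    guard <- guard + 1L
    u <- ceiling(stats::runif(deficit) * total)
    si <- findInterval(u - 1L, c(0, brk), rightmost.closed = TRUE)
    pos <- as.integer(u - c(0, brk)[si])
    cand <- tibble(scaffold = names(lengths)[si], pos = pos)
    cand <- distinct(cand, .data$scaffold, .data$pos)
    cand <- cand[!paste(cand$scaffold, cand$pos) %in%
                   c(excl_keys, paste(out$scaffold, out$pos)), , drop = FALSE]
    if (nrow(cand) > deficit) cand <- cand[seq_len(deficit), , drop = FALSE]
    out <- bind_rows(out, cand)
    deficit <- k - nrow(out)
  }
  if (deficit > 0L) abort("could not place the requested number of SNPs")
  out
}

assemble_counts <- function(sites, pools, alt_reads, ref_reads) {
  n_sites <- nrow(sites)
  n_pools <- nrow(pools)
  idx <- rep(seq_len(n_sites), each = n_pools)
  out <- tibble(
    scaffold = sites$scaffold[idx],
    pos = sites$pos[idx],
    ref = sites$ref[idx],
    pool = rep(pools$pool, times = n_sites)
  )
  base_cols <- c("A", "T", "C", "G", "N", "del")
  cm <- matrix(0L, n_sites * n_pools, 6L)
  ref_col <- match(sites$ref[idx], base_cols)
  alt_col <- match(sites$alt[idx], base_cols)
  pool_j <- rep(seq_len(n_pools), times = n_sites)
  flat <- cbind(seq_len(n_sites * n_pools), ref_col)
  cm[flat] <- as.integer(ref_reads[cbind(idx, pool_j)])
  cm[cbind(seq_len(n_sites * n_pools), alt_col)] <-
    as.integer(alt_reads[cbind(idx, pool_j)])
  for (b in seq_along(base_cols)) out[[base_cols[b]]] <- cm[, b]
  out
}

sim_genes <- function(pr, lengths, genes_per_scaffold) {
  rows <- list()
  if (!is.null(pr) && nrow(pr) > 0L) {
    rows[[1]] <- tibble(
      scaffold = pr$scaffold,
      start = as.integer(pr$start), end = as.integer(pr$end),
      strand = "+",
      gene_id = sprintf("gene_region_%d", seq_len(nrow(pr))),
      description = "synthetic gene spanning a planted region"
    )
  }
  bg <- lapply(names(lengths), function(sc) {
    if (genes_per_scaffold < 1L) return(NULL)
    st <- sort(sample.int(max(lengths[[sc]] - 2000L, 1L), genes_per_scaffold))
    tibble(scaffold = sc, start = st, end = st + 1999L, strand = "+",
           gene_id = sprintf("gene_%s_%d", sc, seq_len(genes_per_scaffold)),
           description = "synthetic background gene")
  })
  bind_rows(c(rows, bg))
}

#' Simulate a pure-drift dataset (no planted selection)
#'
#' Convenience wrapper over [simulate_poolseq()] that insists the config has
#' no planted regions; used for type-I-error calibration of the scan.
#'
#' @param cfg A [sim_config()] with `planted_regions = NULL`.
#' @return A `poolseq_sim` (see [simulate_poolseq()]).
#' @export
null_dataset <- function(cfg) {
  if (!is.null(cfg$planted_regions) && nrow(cfg$planted_regions) > 0L) {
    abort("null_dataset requires a config without planted regions")
  }
  simulate_poolseq(cfg)
}

#' @export
print.poolseq_sim <- function(x, ...) {
  cat("Synthetic pool-seq dataset\n")
  cat("  lineages:", paste(names(x$counts), collapse = ", "), "\n")
  cat("  pools:", nrow(x$manifest), " SNPs per lineage:",
      x$config$n_snps, "\n")
  cat("  planted regions:",
      nrow(x$truth$regions %||% tibble()), "\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits one sync file per lineage plus the manifest, truth regions (BED,
#' 0-based half-open), toy gene models (GFF3), effect table and indel list.
#'
#' @param sim A `poolseq_sim`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (l in names(sim$counts)) {
    p <- file.path(dir, paste0("counts_", l, ".sync"))
    write_sync(sim$counts[[l]], p)
    paths[paste0("sync_", l)] <- p
  }
  paths["manifest"] <- write_pool_manifest(sim$manifest,
                                           file.path(dir, "manifest.tsv"))
  tr <- sim$truth$regions
  bed <- file.path(dir, "truth_regions.bed")
  if (nrow(tr) > 0L) {
    writeLines(paste(tr$scaffold, tr$start - 1L, tr$end,
                     paste0(tr$lineage, "_delta", tr$delta), sep = "\t"), bed)
  } else writeLines(character(), bed)
  paths["truth_regions"] <- bed
  paths["genes"] <- write_gene_models(sim$truth$genes,
                                      file.path(dir, "genes.gff3"))
  paths["effects"] <- write_effects(sim$truth$effects,
                                    file.path(dir, "effects.tsv"))
  readr::write_tsv(sim$truth$indels, file.path(dir, "indels.tsv"))
  paths["indels"] <- file.path(dir, "indels.tsv")
  readr::write_tsv(tibble(scaffold = names(sim$scaffold_lengths),
                          length = unname(sim$scaffold_lengths)),
                   file.path(dir, "scaffolds.tsv"))
  paths["scaffolds"] <- file.path(dir, "scaffolds.tsv")
  invisible(paths)
}
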