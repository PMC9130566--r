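#' Default run configuration
#'
#' Returns the full nested parameter list used by [run_pipeline()], with the
#' standard defaults: minor-allele count 4, coverage in `[10, 2x mean]`,
#' 10 bp indel exclusion, 20-SNP/10-step windows on the 1000 longest
#' scaffolds, 1000 permutations with 99/99.9 percentile thresholds, 20 kb
#' region merging and gene flank, 2-SNP minimum per convergence cell and the
#' 95th-percentile shared-nonsynonymous test. Every value can be overridden
#' through the config passed to [run_pipeline()].
#'
#' @return Nested named list of parameters.
#' @export
default_run_config <- function() {
  list(
    params = list(
      filter = list(min_minor_count = 4L, min_cov = 10L, max_cov_factor = 2,
                    indel_distance = 10L),
      scan = list(window = 20L, step = 10L, top_scaffolds = 1000L,
                  pooled = FALSE),
      perm = list(n_perm = 1000L, percentiles = c(99, 99.9), seed = 1L),
      regions = list(merge_gap = 20000L, gene_flank = 20000L),
      convergence = list(min_snps_per_cell = 2L, nonsyn_percentile = 95)
    ),
    simulate = NULL,
    inputs = NULL,
    parallelism = list(population_scans = FALSE)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

# deterministic per-stage seed derived from the master seed and a label
derive_seed <- function(seed, label) {
  v <- utf8ToInt(label)
  h <- sum(v * seq_along(v)) %% 104729
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483646 + 1)
}

pipeline_log <- function(...) message("[poolscan] ", ...)

#' Run the full genome-scan pipeline
#'
#' Orchestrates every stage — simulate (or read inputs), SNP calling, dAF
#' scan with permutation null, outlier regions, population genetics,
#' cross-lineage parallelism and convergence — writing each stage's tables
#' under `out_dir` plus a machine-readable `run_manifest.json` (parameters,
#' seed, package version, md5 checksums of outputs). Identical inputs,
#' config and seed give identical outputs. Logs go to stderr; results only
#' to files.
#'
#' @param config A nested list overriding [default_run_config()], or a path
#'   to a YAML file holding one. Supply either `simulate` (arguments for
#'   [sim_config()]) or `inputs` (paths: `manifest`, named `sync` list per
#'   lineage, `scaffolds` TSV with `scaffold`/`length` columns, optional
#'   `genes`, `effects`, `indels`).
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run, or `"all"`. Stages:
#'   `snps`, `scan`, `popgen`, `parallelism`, `convergence`.
#' @return Invisibly, a list with the computed objects (`snps`, `scans`,
#'   `popgen`, `parallelism`, `convergence`, `paths`).
#' @export
run_pipeline <- function(config = list(), out_dir, stages = "all") {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_run_config(), config)
  all_stages <- c("snps", "scan", "popgen", "parallelism", "convergence")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()

  # --- inputs -----------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    pipeline_log("simulating dataset")
    sc <- do.call(sim_config, cfg$simulate)
    sim <- simulate_poolseq(sc)
    manifest <- sim$manifest
    counts <- sim$counts
    scaffold_lengths <- sim$scaffold_lengths
    genes <- sim$truth$genes
    effects <- sim$truth$effects
    indels <- sim$truth$indels
  } else if (!is.null(cfg$inputs)) {
    ins <- cfg$inputs
    for (p in c(ins$manifest, unlist(ins$sync), ins$scaffolds)) {
      if (!file.exists(p)) abort(paste0("missing input file: ", p))
    }
    manifest <- read_pool_manifest(ins$manifest)
    # each sync file holds one lineage's pools; the list is named by lineage
    counts <- lapply(names(ins$sync), function(l) {
      read_sync(ins$sync[[l]],
                manifest = manifest[manifest$lineage == l, , drop = FALSE])
    })
    names(counts) <- names(ins$sync)
    sl <- readr::read_tsv(ins$scaffolds, show_col_types = FALSE)
    scaffold_lengths <- setNames(sl$length, sl$scaffold)
    genes <- if (!is.null(ins$genes)) read_gene_models(ins$genes) else NULL
    effects <- if (!is.null(ins$effects)) read_effects(ins$effects) else NULL
    indels <- if (!is.null(ins$indels)) read_indels(ins$indels) else NULL
  } else {
    abort("config must provide either `simulate` or `inputs`")
  }
  lineages <- names(counts)
  p <- cfg$params
  seed <- p$perm$seed

  # --- SNP calling ------------------------------------------------------
  pipeline_log("calling SNPs for ", length(lineages), " lineage(s)")
  snps <- lapply(lineages, function(l) {
    s <- call_snps(counts[[l]], manifest, lineage = l,
                   min_minor_count = p$filter$min_minor_count,
                   min_cov = p$filter$min_cov,
                   max_cov_factor = p$filter$max_cov_factor)
    if (!is.null(indels) && nrow(indels) > 0L) {
      s <- filter_near_indels(s, indels, distance = p$filter$indel_distance)
    }
    s
  })
  names(snps) <- lineages
  if ("snps" %in% stages) {
    for (l in lineages) {
      f <- file.path(out_dir, paste0("snps_", l, ".tsv"))
      write_snp_table(snps[[l]], f)
      paths[paste0("snps_", l)] <- f
    }
  }

  scans <- NULL
  popgen <- NULL
  par_tbl <- NULL
  conv <- NULL

  if (any(c("scan", "popgen", "parallelism", "convergence") %in% stages)) {
    pipeline_log("running dAF scans (", p$perm$n_perm, " permutations)")
    scans <- lapply(lineages, function(l) {
      lineage_scan(snps[[l]], n_perm = p$perm$n_perm,
                   seed = derive_seed(seed, paste0("scan_", l)),
                   window = p$scan$window, step = p$scan$step,
                   top_scaffolds = p$scan$top_scaffolds,
                   scaffold_lengths = scaffold_lengths,
                   percentiles = p$perm$percentiles,
                   merge_gap = p$regions$merge_gap, genes = genes,
                   gene_flank = p$regions$gene_flank,
                   pooled = p$scan$pooled)
    })
    names(scans) <- lineages
    if ("scan" %in% stages) {
      for (l in lineages) {
        wf <- file.path(out_dir, paste0("windows_", l, ".tsv"))
        write_window_track(scans[[l]]$windows, wf)
        paths[paste0("windows_", l)] <- wf
        nf <- file.path(out_dir, paste0("null_", l, ".tsv"))
        write_null_summary(scans[[l]]$null, nf)
        paths[paste0("null_", l)] <- nf
        for (k in names(scans[[l]]$regions)) {
          bf <- file.path(out_dir, paste0("regions_", l, "_p", k, ".bed"))
          write_regions_bed(scans[[l]]$regions[[k]], bf)
          paths[paste0("regions_", l, "_", k)] <- bf
          reg <- scans[[l]]$regions[[k]]
          tf <- file.path(out_dir, paste0("regions_", l, "_p", k, ".tsv"))
          flat <- reg[, setdiff(names(reg), c("windows", "genes"))]
          readr::write_tsv(flat, tf)
          paths[paste0("regions_tsv_", l, "_", k)] <- tf
        }
      }
    }
  }

  if ("popgen" %in% stages) {
    pipeline_log("windowed population genetics")
    popgen <- lapply(lineages, function(l) {
      tr <- popgen_windows(snps[[l]], scans[[l]]$windows)
      f <- file.path(out_dir, paste0("popgen_", l, ".tsv"))
      write_popgen_track(tr, f)
      paths[paste0("popgen_", l)] <<- f
      key <- utils::tail(names(scans[[l]]$regions), 1)
      ct <- bind_rows(
        contrast_outliers(tr, scans[[l]]$regions[[key]], "dxy"),
        contrast_outliers(tr, scans[[l]]$regions[[key]], "tajima_d")
      )
      cf <- file.path(out_dir, paste0("contrasts_", l, ".tsv"))
      readr::write_tsv(ct, cf)
      paths[paste0("contrasts_", l)] <<- cf
      list(track = tr, contrasts = ct)
    })
    names(popgen) <- lineages
  }

  if ("parallelism" %in% stages && length(lineages) >= 2L) {
    pipeline_log("cross-lineage parallelism")
    first_pct <- pct_key(p$perm$percentiles[1])
    region_sets <- lapply(scans, function(s) s$regions[[first_pct]])
    site_sets <- lapply(snps, polymorphic_sites)
    par_tbl <- pairwise_parallelism(region_sets, site_sets)
    f <- file.path(out_dir, "parallelism.tsv")
    write_parallelism(par_tbl, f)
    paths["parallelism"] <- f
    sa <- shared_across(region_sets)
    f2 <- file.path(out_dir, "shared_across.tsv")
    readr::write_tsv(sa, f2)
    paths["shared_across"] <- f2
  }

  if ("convergence" %in% stages && length(lineages) >= 2L) {
    pipeline_log("convergence analyses")
    dafs <- lapply(scans, function(s) s$daf)
    conv <- list()
    last_pct <- utils::tail(p$perm$percentiles, 1)
    for (l in lineages) {
      cm <- withCallingHandlers(
        convergence_matrix(scans[[l]], dafs, percentile = last_pct,
                           min_snps = p$convergence$min_snps_per_cell),
        warning = function(w) invokeRestart("muffleWarning")
      )
      f <- file.path(out_dir, paste0("convergence_", l, ".tsv"))
      write_convergence_matrix(cm, f)
      paths[paste0("convergence_", l)] <- f
      conv[[l]] <- cm
    }
    if (!is.null(effects)) {
      ab <- lineages[1:2]
      sn <- shared_nonsyn_test(dafs[[ab[1]]], effects, dafs[[ab[2]]], effects,
                               percentile = p$convergence$nonsyn_percentile,
                               units = ab)
      f <- file.path(out_dir, "shared_nonsyn.tsv")
      write_shared_nonsyn(sn, f)
      paths["shared_nonsyn"] <- f
      conv$shared_nonsyn <- sn
    }
  }

  manifest_path <- file.path(out_dir, "run_manifest.json")
  run_manifest <- list(
    package = "poolscan",
    version = as.character(utils::packageVersion("poolscan")),
    seed = seed,
    params = p,
    stages = stages,
    outputs = as.list(setNames(unname(tools::md5sum(unname(paths))),
                               basename(unname(paths))))
  )
  jsonlite::write_json(run_manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  paths["run_manifest"] <- manifest_path
  pipeline_log("done; outputs in ", out_dir)
  invisible(list(snps = snps, scans = scans, popgen = popgen,
                 parallelism = par_tbl, convergence = conv, paths = paths))
}
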