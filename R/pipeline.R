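# One-config orchestration of the full analysis: simulate (or load) a
# cohort, then run whichever stage blocks the config contains, in
# dependency order, writing TSV/BED outputs plus a machine-readable
# summary. Reruns with the same config and seed are byte-identical.

#' Build a run configuration
#'
#' Exactly one of `scenario` or `vcf`+`manifest` must be supplied.
#'
#' @param scenario a [scenario_config()] (simulated input).
#' @param vcf,manifest paths to a VCF and manifest TSV (real input).
#' @param out_dir output directory.
#' @param seed integer seed for the run (defaults to the scenario's seed).
#' @param windows list(size, step, min_snps) for the sweep-scan window
#'   frame (default 40 kb / 20 kb / 20).
#' @param het_scan optional list(window, z_contigs, test): heterozygosity
#'   scan and Z-vs-autosome contrast (window default 500 kb).
#' @param sweep optional list(target, reference, quantile, z_contigs).
#' @param dstat optional list(p1, p2, p3, outgroup, block_size).
#' @param isochore optional list(fasta = path or NULL to use a simulated
#'   reference, window = bp or "auto", variant_class).
#' @param afd optional list(groupA, groupB, hi, lo, p_max).
#' @param ld optional list(pop, max_dist, bin_width, maf_min).
#' @return list of class `run_config`.
#' @export
run_config <- function(scenario = NULL, vcf = NULL, manifest = NULL,
                       out_dir, seed = NULL,
                       windows = list(size = 4e4, step = 2e4, min_snps = 20),
                       het_scan = NULL, sweep = NULL, dstat = NULL,
                       isochore = NULL, afd = NULL, ld = NULL) {
  has_scenario <- !is.null(scenario)
  has_vcf <- !is.null(vcf) || !is.null(manifest)
  if (has_scenario == has_vcf)
    stop("supply exactly one of 'scenario' or 'vcf' + 'manifest'")
  if (has_vcf && (is.null(vcf) || is.null(manifest)))
    stop("vcf input needs both 'vcf' and 'manifest' paths")
  seed <- seed %||% (if (has_scenario) scenario$seed else
    stop("seed required for vcf input"))
  structure(list(scenario = scenario, vcf = vcf, manifest = manifest,
                 out_dir = out_dir, seed = as.integer(seed),
                 windows = windows, het_scan = het_scan, sweep = sweep,
                 dstat = dstat, isochore = isochore, afd = afd, ld = ld),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors the arguments of [run_config()]; a `scenario` block is
#' passed to [scenario_config()] (its `contigs` entry as a list of
#' name/length/n_sites records).
#'
#' @param path YAML path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml_fix_keys(yaml::read_yaml(path))
  if (!is.null(y$scenario)) {
    sc <- y$scenario
    sc$contigs <- do.call(rbind, lapply(sc$contigs, as.data.frame))
    y$scenario <- do.call(scenario_config, sc)
  }
  do.call(run_config, y)
}

# YAML 1.1 resolves bare y/n keys to booleans; restore the `n` key that the
# scenario pops blocks use.
#' @noRd
yaml_fix_keys <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x))) names(x)[names(x) == "FALSE"] <- "n"
    x <- lapply(x, yaml_fix_keys)
  }
  x
}

#' Run the full pipeline from one configuration
#'
#' Executes, in order: input acquisition (simulation or VCF load), the
#' window frame, diversity statistics, and then each configured stage
#' (heterozygosity Z-contrast, sweep scan, D-statistic, isochores, AFD
#' screen, LD decay). Every output file and a summary of headline numbers
#' land in `config$out_dir`; `summary.json` and `run_metadata.json` make
#' the run self-describing.
#'
#' @param config a [run_config()].
#' @return list with `summary` (headline counts and statistics) and
#'   `files` (paths written), invisibly also written to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  summary <- list(seed = config$seed)
  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$scenario)) {
      cohort <- simulate_cohort(config$scenario)
      gm <- cohort$geno; manifest <- cohort$manifest
      files <- c(files, write_cohort(cohort, file.path(config$out_dir,
                                                       "cohort")))
    } else {
      cohort <- NULL
      inp <- read_variants(config$vcf, config$manifest)
      gm <- inp$geno; manifest <- inp$manifest
    }
    summary$n_sites <- n_sites(gm)
    summary$n_samples <- n_samples(gm)

    stage <- "windows"
    wcfg <- config$windows
    spec <- window_spec(wcfg$size %||% 4e4, wcfg$step %||% 2e4,
                        wcfg$min_snps %||% 20)
    win <- make_windows(gm$contigs, spec)
    summary$n_windows <- nrow(win)
    tables <- list()

    if (!is.null(config$het_scan)) {
      stage <- "het_scan"
      hc <- config$het_scan
      hw <- make_windows(gm$contigs,
                         window_spec(hc$window %||% 5e5,
                                     min_snps = hc$min_snps %||% 0))
      het <- window_diversity(gm, manifest, hc$pop %||%
                                setdiff(unique(manifest$population),
                                        "outgroup")[1],
                              hw, "het_count")
      het$het_per_bp <- het$het_count / (het$end - het$start)
      tables$het_windows <- het
      if (!is.null(hc$z_contigs)) {
        cmp <- compare_chromosome_groups(het, hc$z_contigs, "het_per_bp",
                                         hc$test %||% "t_two_tailed")
        tables$z_contrast <- cmp
        summary$z_vs_autosomes_p <- cmp$p[cmp$autosome == "all_autosomes"]
      }
    }

    if (!is.null(config$sweep)) {
      stage <- "sweep"
      sc <- config$sweep
      fst <- weir_cockerham_fst(gm, manifest, sc$target, sc$reference, win)
      pi_t <- window_diversity(gm, manifest, sc$target, win, "theta_pi")
      pi_r <- window_diversity(gm, manifest, sc$reference, win, "theta_pi")
      ratio <- log2_pi_ratio(pi_r, pi_t)
      d_t <- window_diversity(gm, manifest, sc$target, win, "tajimas_d")
      d_r <- window_diversity(gm, manifest, sc$reference, win, "tajimas_d")
      regions <- call_sweep_regions(fst$windows, ratio, d_t, d_r,
                                    quantile = sc$quantile %||% 0.95,
                                    z_contigs = sc$z_contigs %||% character())
      tables$fst_windows <- attr(regions, "windows")
      tables$sweep_regions <- regions
      summary$fst_genome <- fst$fst_genome
      summary$n_sweep_regions <- nrow(regions)
      summary$sweep_total_bp <- sum(regions$end - regions$start)
      if (nrow(regions)) {
        bc <- background_contrast(regions)
        tables$sweep_background_contrast <- bc
        summary$sweep_contrast_p_zfst <- bc$p[bc$statistic == "zfst"]
      }
    }

    if (!is.null(config$dstat)) {
      stage <- "dstat"
      dc <- config$dstat
      ds <- d_statistic_pops(gm, manifest, dc$p1, dc$p2, dc$p3,
                             dc$outgroup %||% "outgroup",
                             block_size = dc$block_size %||% 1e6)
      tables$dstat <- data.frame(p1 = dc$p1, p2 = dc$p2, p3 = dc$p3,
                                 D = ds$D, se = ds$se, z = ds$z,
                                 n_sites = ds$n_sites,
                                 n_blocks = ds$n_blocks)
      summary$D <- ds$D
      summary$D_z <- ds$z
    }

    if (!is.null(config$isochore)) {
      stage <- "isochore"
      ic <- config$isochore
      ref <- read_reference(ic$fasta)
      wsz <- ic$window %||% "auto"
      if (identical(wsz, "auto"))
        wsz <- choose_gc_window(ref)$chosen
      segs <- segment_isochores(ref, wsz)
      corr <- variant_gc_correlation(segs, gm,
                                     ic$variant_class %||% "snp")
      tables$isochore_segments <- corr$segments
      summary$isochore_window <- wsz
      summary$n_isochore_segments <- nrow(segs)
      summary$gc_variant_r <- corr$pearson_r
    }

    if (!is.null(config$afd)) {
      stage <- "afd"
      ac <- config$afd
      hits <- screen_differential(gm, manifest, ac$groupA, ac$groupB,
                                  hi = ac$hi %||% 0.8, lo = ac$lo %||% 0.2,
                                  p_max = ac$p_max %||% 0.001)
      tables$afd_hits <- hits
      summary$n_afd_hits <- nrow(hits)
    }

    if (!is.null(config$ld)) {
      stage <- "ld"
      lc <- config$ld
      src <- if (!is.null(cohort)) cohort else gm
      pr <- pairwise_r2(src, manifest, lc$pop, lc$max_dist %||% 4e4,
                        lc$maf_min %||% 0.05)
      curve <- decay_curve(pr, lc$bin_width %||% 1e3,
                           max_dist = lc$max_dist %||% 4e4)
      tables$ld_curve <- curve
      summary$n_ld_pairs <- nrow(pr)
      summary$ld_first_bin_r2 <- curve$mean_r2[1]
    }

    stage <- "write"
    files <- c(files, write_tables(tables, config$out_dir))
    meta <- list(seed = config$seed,
                 windows = list(size = spec$size, step = spec$step,
                                min_snps = spec$min_snps),
                 stages = names(tables))
    jsonlite::write_json(meta, file.path(config$out_dir,
                                         "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    files <- c(files, file.path(config$out_dir,
                                c("run_metadata.json", "summary.json")))
    list(summary = summary, files = files)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  res
}
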