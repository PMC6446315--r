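# Cohort simulator with known truth. Population allele frequencies follow
# the Balding-Nichols model: given an ancestral frequency p and a divergence
# parameter F in (0,1), each population's frequency is drawn
# Beta(p(1-F)/F, (1-p)(1-F)/F), so E[freq] = p, Var = F p(1-p), and the
# expected Weir-Cockerham FST between two such populations is ~ F. This gives
# the scan statistics closed-form expectations without a coalescent engine.

#' Build a simulation scenario configuration
#'
#' @param pops named list; each element a list with `n` (diploids) and `F`
#'   (Balding-Nichols divergence in (0,1)).
#' @param contigs data.frame with columns `name`, `length` (bp) and
#'   `n_sites` (segregating sites to place on the contig).
#' @param outgroup_n diploid outgroup samples, emitted fixed for the
#'   ancestral (reference) allele at every site; population label
#'   `"outgroup"`.
#' @param sfs `"uniform"` draws ancestral frequencies Uniform(0.05, 0.95);
#'   `"neutral"` draws a derived count i with probability proportional to 1/i
#'   over a notional panel of `panel_size` chromosomes and uses p = i /
#'   `panel_size`, giving sample data a neutral site-frequency spectrum.
#' @param panel_size notional panel size for the neutral SFS (default 200).
#' @param founder_haps if `NULL` (default) haplotypes are drawn i.i.d.
#'   Bernoulli per site (no linkage, exact Balding-Nichols sampling); an
#'   integer K builds each haplotype as a recombining mosaic of K founder
#'   haplotypes, which creates distance-decaying LD for the r2 analyses.
#' @param rho per-bp founder switch rate of the mosaic model (default 1e-6).
#' @param sweeps list of sweep specs: `list(contig, start, end, pop,
#'   fixation_prob)` with 0-based half-open intervals (see
#'   [implant_sweep()]).
#' @param introgressions list of introgression specs: `list(donor,
#'   recipient, f, tract_length, tracts_per_hap)` (see
#'   [implant_introgression()]).
#' @param indel_fraction fraction of sites flagged as 1-bp indels rather
#'   than SNPs (default 0); used by the isochore variant-class analyses.
#' @param z_contig optional contig name treated as the low-diversity sex
#'   chromosome: its site count is scaled by `z_theta_scale`.
#' @param z_theta_scale diversity scale factor for `z_contig` (default 0.5).
#' @param seed integer seed; mandatory, recorded in the truth record.
#'
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(pops,
                            contigs,
                            outgroup_n = 2L,
                            sfs = c("uniform", "neutral"),
                            panel_size = 200L,
                            founder_haps = NULL,
                            rho = 1e-6,
                            sweeps = list(),
                            introgressions = list(),
                            indel_fraction = 0,
                            z_contig = NULL,
                            z_theta_scale = 0.5,
                            seed) {
  sfs <- match.arg(sfs)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  contigs <- as.data.frame(contigs)
  stopifnot(all(c("name", "length", "n_sites") %in% names(contigs)))
  for (p in pops) {
    if (p$F <= 0 || p$F >= 1)
      stop("Balding-Nichols F must lie strictly in (0,1)")
  }
  for (sw in sweeps) {
    len <- contigs$length[contigs$name == sw$contig]
    if (!length(len) || sw$start < 0 || sw$end > len || sw$start >= sw$end)
      stop("sweep interval outside contig bounds")
    if (sw$fixation_prob < 0 || sw$fixation_prob > 1)
      stop("fixation_prob must lie in [0,1]")
  }
  for (ig in introgressions) {
    if (ig$f < 0 || ig$f > 1) stop("introgression fraction f must lie in [0,1]")
    if (identical(ig$donor, ig$recipient)) stop("donor must differ from recipient")
  }
  structure(list(pops = pops, contigs = contigs, outgroup_n = outgroup_n,
                 sfs = sfs, panel_size = panel_size,
                 founder_haps = founder_haps, rho = rho, sweeps = sweeps,
                 introgressions = introgressions,
                 indel_fraction = indel_fraction,
                 z_contig = z_contig, z_theta_scale = z_theta_scale,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate a diploid cohort with known truth
#'
#' Draws ancestral allele frequencies per site, per-population frequencies
#' via the Balding-Nichols model, builds phased haplotypes (i.i.d. or founder
#' mosaics), pairs them into diploids, adds a fixed-ancestral outgroup, and
#' applies any configured sweeps and introgression pulses. The ancestral
#' allele is always the reference allele, so outgroup dosages are all 0 and
#' the alternate allele is the derived allele.
#'
#' @param config a [scenario_config()].
#' @return list of class `sim_cohort` with elements `geno`
#'   ([genotype_matrix()]), `haplotypes` (0/1 matrix, sites x haplotypes,
#'   columns `<sample>_1`, `<sample>_2`; outgroup excluded — it is fixed
#'   ancestral), `manifest`, and `truth` (ancestral and per-population
#'   frequencies, sweep intervals, introgression tracts, seed).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  ctg <- config$contigs
  eff_sites <- ctg$n_sites
  if (!is.null(config$z_contig)) {
    zi <- ctg$name == config$z_contig
    eff_sites[zi] <- round(eff_sites[zi] * config$z_theta_scale)
  }
  sites <- do.call(rbind, lapply(seq_len(nrow(ctg)), function(i) {
    pos <- sort(sample.int(ctg$length[i], eff_sites[i]))
    data.frame(contig = ctg$name[i], pos = pos, stringsAsFactors = FALSE)
  }))
  S <- nrow(sites)
  ref <- sample(c("A", "C", "G", "T"), S, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                character(1))
  is_indel <- stats::runif(S) < config$indel_fraction
  alt[is_indel] <- paste0(ref[is_indel], "A")   # 1-bp insertion
  sites$ref <- ref; sites$alt <- alt; sites$is_indel <- is_indel

  p_anc <- switch(config$sfs,
    uniform = stats::runif(S, 0.05, 0.95),
    neutral = {
      i <- sample.int(config$panel_size - 1L, S, replace = TRUE,
                      prob = 1 / seq_len(config$panel_size - 1L))
      i / config$panel_size
    })

  pop_names <- names(config$pops)
  pop_freq <- matrix(NA_real_, S, length(pop_names),
                     dimnames = list(NULL, pop_names))
  haps <- NULL; hap_names <- character(); sample_ids <- character()
  pop_of_sample <- character()
  for (pn in pop_names) {
    pp <- config$pops[[pn]]
    Fst <- pp$F
    shape_scale <- (1 - Fst) / Fst
    pf <- stats::rbeta(S, p_anc * shape_scale, (1 - p_anc) * shape_scale)
    pop_freq[, pn] <- pf
    nh <- 2L * pp$n
    h <- draw_haplotypes(pf, nh, sites, config)
    haps <- cbind(haps, h)
    ids <- sprintf("%s_%02d", pn, seq_len(pp$n))
    sample_ids <- c(sample_ids, ids)
    pop_of_sample <- c(pop_of_sample, rep(pn, pp$n))
    hap_names <- c(hap_names, paste0(rep(ids, each = 2L), c("_1", "_2")))
  }
  colnames(haps) <- hap_names

  out_ids <- character(); out_pop <- character()
  if (config$outgroup_n > 0L) {
    out_ids <- sprintf("outgroup_%02d", seq_len(config$outgroup_n))
    out_pop <- rep("outgroup", config$outgroup_n)
  }
  manifest <- data.frame(sample_id = c(sample_ids, out_ids),
                         population = c(pop_of_sample, out_pop),
                         stringsAsFactors = FALSE)
  class(manifest) <- c("pop_manifest", "data.frame")

  cohort <- structure(list(haplotypes = haps, sites = sites,
                           contigs = ctg[, c("name", "length")],
                           manifest = manifest, sample_ids = sample_ids,
                           outgroup_ids = out_ids,
                           truth = list(seed = config$seed,
                                        ancestral_freq = p_anc,
                                        pop_freq = pop_freq,
                                        sweeps = list(),
                                        introgression_tracts = NULL),
                           config = config),
                      class = "sim_cohort")
  for (sw in config$sweeps) cohort <- implant_sweep(cohort, sw)
  for (ig in config$introgressions) cohort <- implant_introgression(cohort, ig)
  cohort$geno <- cohort_genotypes(cohort)
  cohort
}

# Haplotype drawing: exact Bernoulli sampling, or a founder-mosaic copy model
# in which each haplotype follows one of K founders and switches founders
# between consecutive sites with probability 1 - exp(-rho * distance).
#' @noRd
draw_haplotypes <- function(freq, n_hap, sites, config) {
  S <- length(freq)
  if (is.null(config$founder_haps)) {
    matrix(stats::rbinom(S * n_hap, 1L, freq), nrow = S, ncol = n_hap)
  } else {
    K <- config$founder_haps
    founders <- matrix(stats::rbinom(S * K, 1L, freq), nrow = S, ncol = K)
    h <- matrix(0L, S, n_hap)
    for (cn in unique(sites$contig)) {
      idx <- which(sites$contig == cn)
      d <- diff(sites$pos[idx])
      p_switch <- 1 - exp(-config$rho * d)
      for (j in seq_len(n_hap)) {
        f <- integer(length(idx))
        f[1] <- sample.int(K, 1L)
        if (length(idx) > 1L) {
          sw <- stats::runif(length(d)) < p_switch
          for (s in seq_along(d)) f[s + 1L] <- if (sw[s]) sample.int(K, 1L) else f[s]
        }
        h[idx, j] <- founders[cbind(idx, f)]
      }
    }
    h
  }
}

#' @noRd
cohort_genotypes <- function(cohort) {
  H <- cohort$haplotypes
  n <- length(cohort$sample_ids)
  dos <- H[, 2L * seq_len(n) - 1L, drop = FALSE] +
    H[, 2L * seq_len(n), drop = FALSE]
  colnames(dos) <- cohort$sample_ids
  if (length(cohort$outgroup_ids)) {
    og <- matrix(0L, nrow(dos), length(cohort$outgroup_ids),
                 dimnames = list(NULL, cohort$outgroup_ids))
    dos <- cbind(dos, og)
  }
  genotype_matrix(cohort$contigs, cohort$sites, dos,
                  c(cohort$sample_ids, cohort$outgroup_ids))
}

#' Implant a selective sweep into a simulated cohort
#'
#' Within the interval, in the target population only, every segregating site
#' is driven to fixation (all haplotypes set to the locally major allele)
#' with probability `fixation_prob`, depressing local diversity and raising
#' local differentiation — the footprint the sweep scan looks for.
#'
#' @param cohort a `sim_cohort`.
#' @param spec list with `contig`, `start`, `end` (0-based half-open), `pop`,
#'   `fixation_prob`.
#' @return the modified cohort; the interval is appended to
#'   `truth$sweeps`.
#' @export
implant_sweep <- function(cohort, spec) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!spec$pop %in% cohort$manifest$population)
    stop(sprintf("sweep target population '%s' not in manifest", spec$pop))
  ids <- pop_samples(cohort$manifest, spec$pop)
  hcols <- which(sub("_[12]$", "", colnames(cohort$haplotypes)) %in% ids)
  in_iv <- cohort$sites$contig == spec$contig &
    cohort$sites$pos > spec$start & cohort$sites$pos <= spec$end
  H <- cohort$haplotypes
  for (s in which(in_iv)) {
    f <- mean(H[s, hcols])
    if (f > 0 && f < 1 && stats::runif(1) < spec$fixation_prob)
      H[s, hcols] <- as.integer(f >= 0.5)
  }
  cohort$haplotypes <- H
  cohort$truth$sweeps <- c(cohort$truth$sweeps,
                           list(list(contig = spec$contig, start = spec$start,
                                     end = spec$end, pop = spec$pop,
                                     fixation_prob = spec$fixation_prob)))
  if (!is.null(cohort$geno)) cohort$geno <- cohort_genotypes(cohort)
  cohort
}

#' Implant haplotype-tract introgression into a simulated cohort
#'
#' A fraction `f` of the recipient population's haplotypes receive tracts
#' copied from randomly chosen donor haplotypes; tract lengths are geometric
#' with mean `tract_length`. This produces the asymmetric derived-allele
#' sharing that the ABBA-BABA D-statistic detects.
#'
#' @param cohort a `sim_cohort`.
#' @param spec list with `donor`, `recipient` (population labels), `f`
#'   (fraction of recipient haplotypes carrying tracts), `tract_length`
#'   (mean, bp), optional `tracts_per_hap` per contig (default 1).
#' @return the modified cohort; tract coordinates appended to
#'   `truth$introgression_tracts`.
#' @export
implant_introgression <- function(cohort, spec) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (spec$f < 0 || spec$f > 1) stop("f must lie in [0,1]")
  if (identical(spec$donor, spec$recipient)) stop("donor must differ from recipient")
  tracts_per_hap <- spec$tracts_per_hap %||% 1L
  don_ids <- pop_samples(cohort$manifest, spec$donor)
  rec_ids <- pop_samples(cohort$manifest, spec$recipient)
  hap_pop <- sub("_[12]$", "", colnames(cohort$haplotypes))
  don_cols <- which(hap_pop %in% don_ids)
  rec_cols <- which(hap_pop %in% rec_ids)
  n_carry <- round(spec$f * length(rec_cols))
  if (n_carry == 0L) return(cohort)
  carriers <- sample(rec_cols, n_carry)
  H <- cohort$haplotypes
  tracts <- list()
  for (hc in carriers) {
    for (ci in seq_len(nrow(cohort$contigs))) {
      cn <- cohort$contigs$name[ci]; clen <- cohort$contigs$length[ci]
      for (t in seq_len(tracts_per_hap)) {
        start <- floor(stats::runif(1, 0, clen))
        len <- stats::rgeom(1, 1 / spec$tract_length) + 1
        end <- min(start + len, clen)
        donor_hap <- if (length(don_cols) == 1L) don_cols else sample(don_cols, 1L)
        idx <- cohort$sites$contig == cn &
          cohort$sites$pos > start & cohort$sites$pos <= end
        H[idx, hc] <- H[idx, donor_hap]
        tracts[[length(tracts) + 1L]] <-
          data.frame(haplotype = colnames(H)[hc], donor_haplotype =
                       colnames(H)[donor_hap], contig = cn,
                     start = start, end = end, stringsAsFactors = FALSE)
      }
    }
  }
  cohort$haplotypes <- H
  cohort$truth$introgression_tracts <-
    rbind(cohort$truth$introgression_tracts, do.call(rbind, tracts))
  if (!is.null(cohort$geno)) cohort$geno <- cohort_genotypes(cohort)
  cohort
}

#' Simulate a reference genome with block-structured GC content
#'
#' Each block's bases are drawn i.i.d. with the block's GC probability
#' (G and C equiprobable, likewise A and T), giving a reference whose
#' isochore segmentation is known by construction.
#'
#' @param gc_block_plan data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open) and `gc` in `[0,1]`. Blocks must tile each contig
#'   without gaps or overlaps.
#' @param seed integer seed.
#' @return a `Biostrings::DNAStringSet`.
#' @export
simulate_reference <- function(gc_block_plan, seed) {
  set.seed(seed)
  plan <- as.data.frame(gc_block_plan)
  stopifnot(all(c("contig", "start", "end", "gc") %in% names(plan)))
  seqs <- lapply(split(plan, plan$contig), function(bl) {
    bl <- bl[order(bl$start), ]
    if (bl$start[1] != 0 || any(bl$start[-1] != bl$end[-nrow(bl)]))
      stop("blocks must tile the contig without gaps or overlaps")
    paste(vapply(seq_len(nrow(bl)), function(i) {
      n <- bl$end[i] - bl$start[i]
      g <- bl$gc[i]
      paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
                   prob = c(g / 2, g / 2, (1 - g) / 2, (1 - g) / 2)),
            collapse = "")
    }, character(1)), collapse = "")
  })
  Biostrings::DNAStringSet(unlist(seqs))
}

#' Write a simulated cohort to disk
#'
#' Emits `cohort.vcf`, `manifest.tsv` and `truth.json` into `dir`.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return character vector of paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, "cohort.vcf")
  man <- file.path(dir, "manifest.tsv")
  tru <- file.path(dir, "truth.json")
  write_variants(cohort$geno, vcf)
  write_manifest(cohort$manifest, man)
  truth <- cohort$truth
  truth$pop_freq <- as.data.frame(truth$pop_freq)
  jsonlite::write_json(truth, tru, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(vcf, man, tru))
}
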