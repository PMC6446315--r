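test_that("cohort simulation is deterministic and outgroup is fixed ancestral", {
  cfg <- scenario_config(
    pops = list(A = list(n = 5, F = 0.1)),
    contigs = data.frame(name = "chr1", length = 1e5, n_sites = 300),
    outgroup_n = 2, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$geno$dosages, b$geno$dosages)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$truth$pop_freq, b$truth$pop_freq)
  # outgroup carries only the ancestral (= reference) allele
  expect_true(all(a$geno$dosages[, a$outgroup_ids] == 0L))
  # diploid dosages are the haplotype pair sums
  expect_identical(unname(a$geno$dosages[, "A_01"]),
                   unname(a$haplotypes[, "A_01_1"] + a$haplotypes[, "A_01_2"]))
})

test_that("degenerate Balding-Nichols parameters are rejected", {
  ctg <- data.frame(name = "chr1", length = 1e4, n_sites = 10)
  expect_error(scenario_config(pops = list(A = list(n = 2, F = 0)),
                               contigs = ctg, seed = 1), "strictly in")
  expect_error(scenario_config(pops = list(A = list(n = 2, F = 1)),
                               contigs = ctg, seed = 1), "strictly in")
  expect_error(scenario_config(pops = list(A = list(n = 2, F = 0.1)),
                               contigs = ctg), "seed")
})

test_that("Balding-Nichols cohorts recover F from truth and sample frequencies", {
  cfg <- scenario_config(
    pops = list(A = list(n = 50, F = 0.1), B = list(n = 50, F = 0.1)),
    contigs = data.frame(name = "chr1", length = 4e6, n_sites = 20000),
    outgroup_n = 0, seed = 202)
  co <- simulate_cohort(cfg)
  # brute-force frequency-based estimator over the stored truth frequencies
  f_truth <- oracle_fst_from_freqs(co$truth$pop_freq[, "A"],
                                   co$truth$pop_freq[, "B"])
  expect_lt(abs(f_truth - 0.10), 0.02)
  # the Weir-Cockerham estimate from the sampled genotypes agrees
  fst <- weir_cockerham_fst(co$geno, co$manifest, "A", "B")
  expect_lt(abs(fst$fst_genome - 0.10), 0.02)
})

test_that("sample frequencies are unbiased for truth and tighten with n", {
  dev_for_n <- function(n, seed) {
    cfg <- scenario_config(
      pops = list(A = list(n = n, F = 0.1)),
      contigs = data.frame(name = "chr1", length = 1e6, n_sites = 4000),
      outgroup_n = 0, seed = seed)
    co <- simulate_cohort(cfg)
    st <- popgenscan:::site_stats(co$geno,
                                  seq_along(co$sample_ids))
    mean(abs(st$p - co$truth$pop_freq[, "A"]))
  }
  d_small <- mean(vapply(1:3, function(s) dev_for_n(8, s), numeric(1)))
  d_large <- mean(vapply(1:3, function(s) dev_for_n(64, s), numeric(1)))
  expect_lt(d_large, d_small)
  # binomial sampling theory: MAD ~ 1/sqrt(2n); 8 -> 64 should shrink ~2.8x
  expect_lt(d_large, d_small / 2)
})

test_that("implanted sweeps fix local variation in the target population only", {
  base_cfg <- function(seed, fixation_prob) scenario_config(
    pops = list(target = list(n = 10, F = 0.05),
                reference = list(n = 10, F = 0.05)),
    contigs = data.frame(name = "chr1", length = 1e6, n_sites = 3000),
    outgroup_n = 0,
    sweeps = list(list(contig = "chr1", start = 4e5, end = 6e5,
                       pop = "target", fixation_prob = fixation_prob)),
    seed = seed)

  # fixation probability 1: all target variation inside the interval is gone
  co <- simulate_cohort(base_cfg(31, 1))
  tcols <- grepl("^target", colnames(co$haplotypes))
  inside <- co$sites$pos > 4e5 & co$sites$pos <= 6e5
  f_in <- rowMeans(co$haplotypes[inside, tcols])
  expect_true(all(f_in %in% c(0, 1)))
  hap_in <- co$haplotypes[inside, tcols]
  expect_equal(oracle_pi(hap_in), 0)

  # fixation probability 0: nothing changes
  cfg0 <- base_cfg(32, 0)
  co0 <- simulate_cohort(cfg0)
  cfg_null <- cfg0; cfg_null$sweeps <- list()
  co_null <- simulate_cohort(cfg_null)
  expect_identical(co0$haplotypes, co_null$haplotypes)

  # fixation probability 0.9 over 200 kb: interval diversity collapses
  # relative to the flanks (direct pairwise-difference oracle, per bp)
  ratios <- vapply(1:20, function(s) {
    cs <- simulate_cohort(base_cfg(300 + s, 0.9))
    tc <- grepl("^target", colnames(cs$haplotypes))
    ins <- cs$sites$pos > 4e5 & cs$sites$pos <= 6e5
    pi_in <- oracle_pi(cs$haplotypes[ins, tc]) / 2e5
    pi_out <- oracle_pi(cs$haplotypes[!ins, tc]) / 8e5
    pi_in / pi_out
  }, numeric(1))
  expect_lt(mean(ratios), 0.25)
})

test_that("introgression copies donor tracts and respects f = 0", {
  cfg <- scenario_config(
    pops = list(P2 = list(n = 6, F = 0.1), P3 = list(n = 6, F = 0.1)),
    contigs = data.frame(name = "chr1", length = 1e6, n_sites = 2000),
    outgroup_n = 0,
    introgressions = list(list(donor = "P3", recipient = "P2", f = 0.5,
                               tract_length = 3e5)),
    seed = 41)
  co <- simulate_cohort(cfg)
  tr <- co$truth$introgression_tracts
  expect_gt(nrow(tr), 0)
  for (i in seq_len(nrow(tr))) {
    idx <- co$sites$pos > tr$start[i] & co$sites$pos <= tr$end[i]
    expect_identical(co$haplotypes[idx, tr$haplotype[i]],
                     unname(co$haplotypes[idx, tr$donor_haplotype[i]]))
  }
  # f = 0 leaves the cohort untouched
  cfg0 <- cfg; cfg0$introgressions[[1]]$f <- 0
  co0 <- simulate_cohort(cfg0)
  cfg_null <- cfg; cfg_null$introgressions <- list()
  expect_identical(co0$haplotypes, simulate_cohort(cfg_null)$haplotypes)
  expect_error(scenario_config(
    pops = cfg$pops, contigs = cfg$contigs, seed = 1,
    introgressions = list(list(donor = "P3", recipient = "P2", f = 1.2,
                               tract_length = 1e5))), "f must lie")
})

test_that("simulated references hit their block GC targets", {
  plan <- data.frame(contig = "cI", start = 0, end = 3e5, gc = 0.5)
  ref <- simulate_reference(plan, seed = 7)
  expect_lt(abs(gc_fraction(ref) - 0.5), 0.005)   # binomial SD ~ 0.0009
  ref0 <- simulate_reference(data.frame(contig = "c", start = 0, end = 1e4,
                                        gc = 0), seed = 7)
  expect_false(grepl("[GC]", as.character(ref0[[1]])))
  expect_error(simulate_reference(
    data.frame(contig = "c", start = c(0, 5e3), end = c(6e3, 1e4),
               gc = 0.4), seed = 1), "tile")
})

test_that("the Z contig carries reduced diversity", {
  cfg <- scenario_config(
    pops = list(A = list(n = 10, F = 0.1)),
    contigs = data.frame(name = c("chr1", "chrZ"), length = c(5e5, 5e5),
                         n_sites = c(2000, 2000)),
    outgroup_n = 0, z_contig = "chrZ", z_theta_scale = 0.5, seed = 13)
  co <- simulate_cohort(cfg)
  n_auto <- sum(co$sites$contig == "chr1")
  n_z <- sum(co$sites$contig == "chrZ")
  expect_equal(n_z, 1000L)
  expect_equal(n_auto, 2000L)
})
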