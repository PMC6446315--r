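test_that("window tiling follows the half-open sliding convention", {
  ctg <- data.frame(name = "chr1", length = 1e5)
  w <- make_windows(ctg, window_spec(4e4, 2e4))
  expect_equal(w$start, c(0, 2e4, 4e4, 6e4, 8e4))
  expect_equal(w$end, c(4e4, 6e4, 8e4, 1e5, 1e5))
  expect_equal(w$truncated, c(FALSE, FALSE, FALSE, FALSE, TRUE))

  w2 <- make_windows(ctg, window_spec(4e4))       # step = size tiling
  expect_equal(w2$start, c(0, 4e4, 8e4))
  expect_true(all(diff(w2$start) == 4e4))

  w3 <- make_windows(data.frame(name = "c", length = 1e4),
                     window_spec(4e4, 2e4))
  expect_equal(nrow(w3), 1L)                      # contig shorter than size
  expect_true(w3$truncated)
  expect_error(window_spec(4e4, 8e4), "step <= size")
})

test_that("theta_pi and Tajima's D match the hand-worked 4-chromosome case", {
  # 2 diploids = 4 chromosomes; derived counts {1, 1, 2} across 3 sites
  man <- toy_manifest(c(A = 2))
  gm <- toy_gm(rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L)),
               pos = c(100L, 200L, 300L), contig_len = 1000L,
               sample_ids = man$sample_id)
  w <- make_windows(gm$contigs, window_spec(1000L, min_snps = 1L))
  pi_tab <- window_diversity(gm, man, "A", w, "theta_pi")
  expect_equal(pi_tab$theta_pi, 5 / 3, tolerance = 1e-12)
  # independent enumeration oracle over explicit haplotype phasings with the
  # same allele counts (pi depends only on counts)
  haps <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(oracle_pi(haps), 5 / 3)

  d_tab <- window_diversity(gm, man, "A", w, "tajimas_d")
  expect_equal(d_tab$tajimas_d, oracle_tajima(3, 5 / 3, 4), tolerance = 1e-6)
  expect_equal(d_tab$tajimas_d, 0.1676558, tolerance = 1e-6)

  # monomorphic windows have zero diversity
  gm0 <- toy_gm(rbind(c(2L, 2L), c(0L, 0L)), pos = c(10L, 20L),
                contig_len = 1000L, sample_ids = man$sample_id)
  pi0 <- window_diversity(gm0, man, "A",
                          make_windows(gm0$contigs,
                                       window_spec(1000L, min_snps = 0L)),
                          "theta_pi")
  expect_equal(pi0$theta_pi, 0)
})

test_that("heterozygote counts pool correctly across samples", {
  man <- toy_manifest(c(A = 3))
  d <- rbind(c(1L, 0L, 1L),
             c(1L, 1L, 0L),
             c(1L, 2L, 2L),
             c(1L, 1L, 1L),
             c(1L, 0L, NA))
  gm <- toy_gm(d, pos = c(10L, 20L, 30L, 40L, 50L), contig_len = 100L,
               sample_ids = man$sample_id)
  w <- make_windows(gm$contigs, window_spec(100L, min_snps = 0L))
  het <- window_diversity(gm, man, "A", w, "het_count", per_sample = TRUE)
  expect_equal(het$het_count, 9)                  # one sample 0/1 at 5 sites
  expect_equal(het$het_A_01, 5)
  per_sample <- het$het_A_01 + het$het_A_02 + het$het_A_03
  expect_equal(het$het_count, per_sample)         # pooled = sum of per-sample
})

test_that("windows below the SNP threshold are flagged and blanked", {
  man <- toy_manifest(c(A = 2))
  gm <- toy_gm(matrix(1L, 5, 2), pos = c(1:5) * 10L, contig_len = 2000L,
               sample_ids = man$sample_id)
  w <- make_windows(gm$contigs, window_spec(1000L, min_snps = 20L))
  pi_tab <- window_diversity(gm, man, "A", w, "theta_pi")
  expect_true(all(pi_tab$low_snps))
  expect_true(all(is.na(pi_tab$theta_pi)))
  expect_equal(pi_tab$n_snps[1], 5L)              # counts survive the flag
})

test_that("Z-vs-autosome contrasts behave at ties, power and contracts", {
  wt <- data.frame(contig = rep(c("chrZ", "chr1", "chr2"), each = 10),
                   start = 0, end = 1, value = 1)
  cmp <- compare_chromosome_groups(wt, "chrZ", "value", "mann_whitney")
  expect_equal(cmp$p, rep(1, 3))                  # identical values -> p = 1

  expect_error(compare_chromosome_groups(wt, "chrX", "value"), "absent")
  wt_empty <- wt[wt$contig == "chrZ", ]
  expect_error(compare_chromosome_groups(wt_empty, "chrZ", "value"),
               "autosom")

  # simulated Z at half diversity separates from autosomes
  detected <- vapply(1:20, function(s) {
    cfg <- scenario_config(
      pops = list(A = list(n = 10, F = 0.1)),
      contigs = data.frame(name = c("chr1", "chrZ"),
                           length = c(2.5e6, 2.5e6), n_sites = c(5000, 5000)),
      outgroup_n = 0, z_contig = "chrZ", seed = 500 + s)
    co <- simulate_cohort(cfg)
    w <- make_windows(co$geno$contigs, window_spec(2.5e4, min_snps = 0L))
    het <- window_diversity(co$geno, co$manifest, "A", w, "het_count")
    het$het_per_bp <- het$het_count / (het$end - het$start)
    cmp <- compare_chromosome_groups(het, "chrZ", "het_per_bp",
                                     "t_two_tailed")
    cmp$p[cmp$autosome == "all_autosomes"] < 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.9)
})

test_that("window-size selection saturates as constructed and breaks ties small", {
  mk <- function(spacing, len = 4e5) {
    pos <- seq(spacing, len, by = spacing)
    toy_gm(matrix(1L, length(pos), 4), pos = as.integer(pos),
           contig_len = len)
  }
  # 3 SNPs/kb: both 10 kb (30 SNPs) and 40 kb (120) saturate -> tie -> 10 kb
  dense <- select_window_size(mk(333), c(1e4, 4e4))
  expect_equal(dense$table$prop_saturated, c(1, 1))
  expect_equal(dense$chosen, 1e4)
  # 0.5 SNPs/kb: 10-kb windows hold 5 (< 20) but 40-kb hold exactly 20
  sparse <- select_window_size(mk(2000), c(1e4, 4e4))
  expect_equal(sparse$chosen, 4e4)
  expect_equal(sparse$table$prop_saturated[sparse$table$size == 1e4], 0)
  # single candidate comes straight back
  expect_equal(select_window_size(mk(1000), 25000)$chosen, 25000)
  expect_error(select_window_size(mk(1000), numeric()), "empty")
})

test_that("per-bp diversity respects its theoretical per-site bound", {
  cfg <- scenario_config(
    pops = list(A = list(n = 6, F = 0.2)),
    contigs = data.frame(name = "chr1", length = 2e5, n_sites = 1000),
    outgroup_n = 0, seed = 9)
  co <- simulate_cohort(cfg)
  w <- make_windows(co$geno$contigs, window_spec(2e4, min_snps = 0L))
  pi_tab <- window_diversity(co$geno, co$manifest, "A", w, "theta_pi")
  expect_true(all(pi_tab$theta_pi >= 0, na.rm = TRUE))
  n <- 12  # chromosomes
  per_site_max <- 0.5 * n / (n - 1)
  expect_true(all(pi_tab$theta_pi <= per_site_max * pi_tab$n_snps + 1e-9,
                  na.rm = TRUE))
})
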