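test_that("Weir-Cockerham components match the independent scalar oracle", {
  man <- toy_manifest(c(A = 10, B = 10))
  set.seed(77)
  d <- matrix(sample(c(0:2, NA), 50 * 20, replace = TRUE,
                     prob = c(0.4, 0.3, 0.25, 0.05)), nrow = 50)
  gm <- toy_gm(d, pos = (1:50) * 100L, contig_len = 10000L,
               sample_ids = man$sample_id)
  fst <- weir_cockerham_fst(gm, man, "A", "B")
  for (i in c(1, 7, 19, 33, 50)) {
    o <- oracle_wc_site(d[i, 1:10], d[i, 11:20])
    if (all(!is.na(o))) {
      pbar <- mean(c(d[i, 1:10], d[i, 11:20]), na.rm = TRUE) / 2
      if (pbar > 0 && pbar < 1) {
        expect_equal(fst$per_site$a[i], unname(o["a"]), tolerance = 1e-12)
        expect_equal(fst$per_site$abc[i], unname(sum(o)), tolerance = 1e-12)
      }
    }
  }
  # genome estimate is the ratio of sums, not the mean of ratios
  expect_equal(fst$fst_genome,
               sum(fst$per_site$a, na.rm = TRUE) /
                 sum(fst$per_site$abc, na.rm = TRUE))
})

test_that("FST hits its textbook fixed points", {
  man <- toy_manifest(c(A = 5, B = 5))
  # fixed difference, no within-population variation -> theta = 1
  gm1 <- toy_gm(matrix(c(rep(0L, 5), rep(2L, 5)), nrow = 1),
                sample_ids = man$sample_id)
  f1 <- weir_cockerham_fst(gm1, man, "A", "B")
  expect_equal(f1$per_site$theta, 1)
  # identical allele counts in both populations -> theta <= 0
  gm2 <- toy_gm(matrix(rep(c(0L, 0L, 1L, 1L, 2L), 2), nrow = 1),
                sample_ids = man$sample_id)
  f2 <- weir_cockerham_fst(gm2, man, "A", "B")
  expect_lte(f2$per_site$theta, 0)
  expect_error(weir_cockerham_fst(gm1, man, "A", man$sample_id[1:5]),
               "disjoint")
})

test_that("zFST standardizes with the n-1 convention and rejects degeneracy", {
  z <- zfst_transform(c(0.1, 0.3))
  expect_equal(z, c(-0.7071068, 0.7071068), tolerance = 1e-6)
  expect_error(zfst_transform(c(0.2, 0.2, 0.2)), "constant")
  set.seed(4)
  x <- c(runif(50), NA)
  zx <- zfst_transform(x)
  expect_equal(mean(zx, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(zx, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_true(is.na(zx[51]))                      # missing in, missing out
})

test_that("log2 diversity ratio handles the documented edge cases", {
  frame <- data.frame(contig = "c", start = c(0, 100, 200, 300),
                      end = c(100, 200, 300, 400), n_snps = 5L)
  ref <- frame; ref$theta_pi <- c(2, 8, 2, NA)
  tgt <- frame; tgt$theta_pi <- c(2, 2, 0, 1)
  r <- log2_pi_ratio(ref, tgt)
  expect_equal(r$log2_pi_ratio[1], 0)             # equal diversity
  expect_equal(r$log2_pi_ratio[2], 2)             # 4x -> log2 = 2
  expect_true(is.na(r$log2_pi_ratio[3]))
  expect_equal(r$ratio_reason[3], "zero_target_pi")
  expect_equal(r$ratio_reason[4], "missing_pi")
  bad <- frame[c(2, 1, 3, 4), ]
  bad$theta_pi <- 1
  expect_error(log2_pi_ratio(ref, bad), "frames")
})

test_that("outlier windows merge by overlap/abutment and stay below the tail budget", {
  mk_tabs <- function(fst, ratio, step = 2e4, size = 4e4) {
    n <- length(fst)
    frame <- data.frame(contig = "chr1", start = (seq_len(n) - 1L) * step,
                        truncated = FALSE)
    frame$end <- frame$start + size
    f <- frame; f$fst <- fst; f$n_snps <- 30L
    r <- frame; r$log2_pi_ratio <- ratio; r$n_snps <- 30L
    list(fst = f, ratio = r)
  }
  set.seed(12)
  base_f <- runif(100, 0, 0.2); base_r <- rnorm(100, 0, 0.3)
  base_f[40:41] <- 0.9; base_r[40:41] <- 4     # two adjacent outliers
  tt <- mk_tabs(base_f, base_r)
  reg <- call_sweep_regions(tt$fst, tt$ratio)
  hit <- reg[reg$start <= 39 * 2e4 & reg$end >= 40 * 2e4 + 4e4, ]
  expect_equal(nrow(hit), 1L)                     # merged into one region
  expect_equal(hit$end - hit$start, 6e4)          # 2 windows sharing 20 kb
  w <- attr(reg, "windows")
  expect_lte(mean(w$fst >= attr(reg, "thresholds")["fst"]), 0.05)
  expect_lte(mean(w$log2_pi_ratio >=
                    attr(reg, "thresholds")["log2_pi_ratio"]), 0.05)
  expect_lte(sum(w$flagged), 0.05 * nrow(w))
  expect_error(call_sweep_regions(tt$fst, tt$ratio, quantile = 0.4),
               "quantile")
  small <- mk_tabs(runif(10), rnorm(10))
  expect_error(call_sweep_regions(small$fst, small$ratio), "20")
})

test_that("region calling is reproducible and respects Z exclusion", {
  set.seed(5)
  n <- 60
  frame <- data.frame(contig = rep(c("chr1", "chrZ"), c(40, 20)),
                      start = c((0:39) * 2e4, (0:19) * 2e4), truncated = FALSE)
  frame$end <- frame$start + 4e4
  f <- frame; f$fst <- runif(n); f$n_snps <- 30L
  r <- frame; r$log2_pi_ratio <- rnorm(n); r$n_snps <- 30L
  f$fst[41:60] <- 0.99; r$log2_pi_ratio[41:60] <- 9  # extreme Z windows
  reg <- call_sweep_regions(f, r, z_contigs = "chrZ")
  expect_false(any(reg$contig == "chrZ"))         # Z never called
  reg2 <- call_sweep_regions(f, r, z_contigs = "chrZ")
  expect_identical(as.data.frame(reg), as.data.frame(reg2))
})

test_that("background contrast separates regions and degrades to p = 1", {
  set.seed(8)
  n <- 200
  frame <- data.frame(contig = "chr1", start = (seq_len(n) - 1L) * 2e4,
                      truncated = FALSE)
  frame$end <- frame$start + 4e4
  f <- frame; f$fst <- c(runif(n - 10, 0, 0.2), runif(10, 0.7, 0.9))
  f$n_snps <- 30L
  r <- frame; r$log2_pi_ratio <- c(rnorm(n - 10), rnorm(10, 5)); r$n_snps <- 30L
  reg <- call_sweep_regions(f, r)
  bc <- background_contrast(reg)
  expect_true(all(bc$p < 0.05))
  # regions covering every window: indistinguishable from background
  all_reg <- data.frame(contig = "chr1", start = 0, end = max(frame$end))
  w <- attr(reg, "windows")
  bc_all <- background_contrast(all_reg, w)
  expect_equal(bc_all$p, c(1, 1))
  # a single-window region still yields a valid p
  one <- reg[1, , drop = FALSE]
  expect_true(is.finite(background_contrast(one, w)$p[1]))
  expect_error(background_contrast(reg[0, ]), "empty")
})

test_that("gene annotation respects half-open overlap and shared tallies", {
  reg <- data.frame(contig = "chr1", start = 1e5, end = 2e5)
  genes <- data.frame(contig = "chr1",
                      start = c(1.2e5, 2e5, 0.9e5),
                      end = c(1.4e5, 2.4e5, 1.0e5),
                      gene = c("inside", "abutting_end", "abutting_start"))
  ann <- annotate_regions(reg, genes)
  expect_equal(ann$genes, "inside")               # abutting genes excluded
  expect_equal(ann$n_genes, 1L)
  sets <- list(
    p1 = data.frame(genes = "g1,g2"), p2 = data.frame(genes = "g1"),
    p3 = data.frame(genes = "g1,g3"), p4 = data.frame(genes = ""))
  counts <- shared_gene_counts(sets)
  expect_equal(counts$n_populations[counts$gene == "g1"], 3L)
  expect_equal(counts$n_populations[counts$gene == "g2"], 1L)
  expect_error(annotate_regions(reg, data.frame(contig = "chr1", start = 10,
                                                end = 5, gene = "x")),
               "malformed")
})
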