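# Fixture builders and independent oracles used across the suite. Oracles
# are deliberately naive (scalar loops, direct formulas) so they share no
# code with the implementation they check.

toy_manifest <- function(pops) {
  # pops: named integer vector, population -> n diploids
  ids <- unlist(lapply(names(pops), function(p)
    sprintf("%s_%02d", p, seq_len(pops[[p]]))))
  m <- data.frame(sample_id = ids,
                  population = rep(names(pops), unname(pops)),
                  stringsAsFactors = FALSE)
  class(m) <- c("pop_manifest", "data.frame")
  m
}

toy_gm <- function(dosages, pos = NULL, contig = "chr1", contig_len = NULL,
                   sample_ids = NULL, is_indel = FALSE) {
  dosages <- as.matrix(dosages)
  S <- nrow(dosages)
  pos <- pos %||% (seq_len(S) * 100L)
  contig_len <- contig_len %||% (max(pos) + 100L)
  sample_ids <- sample_ids %||% sprintf("s%02d", seq_len(ncol(dosages)))
  genotype_matrix(
    data.frame(name = contig, length = contig_len),
    data.frame(contig = contig, pos = pos,
               ref = "A", alt = "T",
               is_indel = rep(is_indel, length.out = S)),
    dosages, sample_ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent Weir-Cockerham (1984) two-population variance components for
# one site, written as direct scalar formulas from the published paper.
oracle_wc_site <- function(gA, gB) {
  gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
  n <- c(length(gA), length(gB))
  p <- c(sum(gA) / (2 * n[1]), sum(gB) / (2 * n[2]))
  h <- c(mean(gA == 1), mean(gB == 1))
  r <- 2
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Independent nucleotide diversity: mean pairwise difference summed over
# sites, by explicit enumeration of chromosome pairs.
oracle_pi <- function(hap_mat) {
  # hap_mat: sites x chromosomes, 0/1
  n <- ncol(hap_mat)
  total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    total <- total + sum(hap_mat[, i] != hap_mat[, j])
  total / choose(n, 2)
}

# Independent Tajima's D from first principles (textbook constants).
oracle_tajima <- function(S, pi_sum, n) {
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi_sum - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# Hudson-style frequency-based FST from true population frequencies:
# ratio of averages of (p1-p2)^2 over p1(1-p2)+p2(1-p1).
oracle_fst_from_freqs <- function(p1, p2) {
  mean((p1 - p2)^2) / mean(p1 * (1 - p2) + p2 * (1 - p1))
}

# Exhaustive two-locus r2 from a haplotype count table.
oracle_r2_counts <- function(n_AB, n_Ab, n_aB, n_ab) {
  n <- n_AB + n_Ab + n_aB + n_ab
  pA <- (n_AB + n_Ab) / n
  pB <- (n_AB + n_aB) / n
  pAB <- n_AB / n
  (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}
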