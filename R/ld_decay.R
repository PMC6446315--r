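# Pairwise linkage disequilibrium within a distance cap and the averaged
# decay curve. On phased haplotypes,
#   r2 = (p_AB - p_A p_B)^2 / (p_A (1 - p_A) p_B (1 - p_B));
# on unphased genotypes the squared Pearson correlation of alternate-allele
# dosages is the documented surrogate, flagged in the output metadata.

#' Pairwise r2 within a distance cap
#'
#' @param x a `sim_cohort` (phased path, uses its haplotypes) or a
#'   [genotype_matrix()] (unphased dosage-correlation path).
#' @param manifest a `pop_manifest` (taken from the cohort when `x` is one).
#' @param pop population label (or sample id vector).
#' @param max_dist maximum pair distance, bp (default 40 kb).
#' @param maf_min minor-allele-frequency filter applied before pairing
#'   (default 0.05).
#' @return data.frame with `contig`, `pos1`, `pos2`, `dist`, `r2`;
#'   attribute `"phased"` records which path produced it.
#' @export
pairwise_r2 <- function(x, manifest = NULL, pop, max_dist = 4e4,
                        maf_min = 0.05) {
  if (inherits(x, "sim_cohort")) {
    manifest <- manifest %||% x$manifest
    ids <- if (length(pop) == 1L && pop %in% manifest$population)
      pop_samples(manifest, pop) else pop
    cols <- which(sub("_[12]$", "", colnames(x$haplotypes)) %in% ids)
    if (length(cols) < 4L) stop("phased path needs at least 4 haplotypes")
    H <- x$haplotypes[, cols, drop = FALSE]
    sites <- x$sites
    pairs <- r2_scan(H, sites, max_dist, maf_min, phased = TRUE)
  } else if (inherits(x, "genotype_matrix")) {
    if (is.null(manifest)) stop("manifest required for genotype input")
    idx <- resolve_samples(x, manifest, pop)
    if (length(idx) < 5L) stop("unphased path needs at least 5 diploids")
    D <- x$dosages[, idx, drop = FALSE]
    keep <- rowSums(is.na(D)) == 0L          # complete cases per site
    pairs <- r2_scan(D[keep, , drop = FALSE], x$sites[keep, , drop = FALSE],
                     max_dist, maf_min, phased = FALSE)
  } else stop("x must be a sim_cohort or genotype_matrix")
  pairs
}

# Shared scan: rows of M are sites (haplotype alleles when phased, dosages
# when not); computes r2 for all same-contig pairs within max_dist.
#' @noRd
r2_scan <- function(M, sites, max_dist, maf_min, phased) {
  ncol_m <- ncol(M)
  f <- rowMeans(M) / (if (phased) 1 else 2)
  keep <- f >= maf_min & f <= 1 - maf_min
  M <- M[keep, , drop = FALSE]
  sites <- sites[keep, , drop = FALSE]
  res <- list()
  for (cn in unique(sites$contig)) {
    si <- which(sites$contig == cn)
    pos <- sites$pos[si]
    Mc <- M[si, , drop = FALSE]
    if (length(si) < 2L) next
    hi_all <- findInterval(pos + max_dist, pos)
    for (k in seq_along(si)) {
      hi <- hi_all[k]
      if (hi <= k) next
      jj <- (k + 1L):hi
      if (phased) {
        pa <- mean(Mc[k, ]); pb <- rowMeans(Mc[jj, , drop = FALSE])
        pab <- as.vector(Mc[jj, , drop = FALSE] %*% Mc[k, ]) / ncol_m
        r2 <- (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
      } else {
        r2 <- suppressWarnings(
          as.vector(stats::cor(Mc[k, ], t(Mc[jj, , drop = FALSE])))^2)
      }
      res[[length(res) + 1L]] <- data.frame(
        contig = cn, pos1 = pos[k], pos2 = pos[jj],
        dist = pos[jj] - pos[k], r2 = r2, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res)
  else data.frame(contig = character(), pos1 = integer(), pos2 = integer(),
                  dist = integer(), r2 = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "phased") <- phased
  out
}

#' Average r2 into a distance-binned decay curve
#'
#' @param pair_table output of [pairwise_r2()].
#' @param bin_width distance bin width, bp (default 1 kb).
#' @param max_dist upper distance bound for emitted bins (default: the
#'   largest observed pair distance). Bins with no pairs are emitted with a
#'   missing mean, not zero.
#' @return data.frame of class `ld_curve`: `bin_start`, `bin_end`,
#'   `n_pairs`, `mean_r2`.
#' @export
decay_curve <- function(pair_table, bin_width = 1e3, max_dist = NULL) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (!nrow(pair_table)) stop("pair table is empty")
  max_dist <- max_dist %||% max(pair_table$dist)
  n_bins <- ceiling(max_dist / bin_width)
  bin <- pmin(ceiling(pair_table$dist / bin_width), n_bins)
  sums <- tapply(pair_table$r2, factor(bin, levels = seq_len(n_bins)), sum)
  cnts <- tapply(pair_table$r2, factor(bin, levels = seq_len(n_bins)), length)
  cnts[is.na(cnts)] <- 0L
  out <- data.frame(bin_start = (seq_len(n_bins) - 1L) * bin_width,
                    bin_end = seq_len(n_bins) * bin_width,
                    n_pairs = as.integer(cnts),
                    mean_r2 = ifelse(cnts > 0, sums / cnts, NA_real_))
  rownames(out) <- NULL
  attr(out, "phased") <- attr(pair_table, "phased")
  class(out) <- c("ld_curve", "data.frame")
  out
}
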