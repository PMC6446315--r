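# Frequency-based ABBA-BABA D-statistic. With derived-allele frequencies
# p1, p2, p3 in three populations (polarized against a fixed outgroup P4):
#
#   D = sum[(1 - p1) p2 p3 - p1 (1 - p2) p3] /
#       sum[(1 - p1) p2 p3 + p1 (1 - p2) p3]
#
# The outgroup enters only through polarization, so p4 does not appear.
# D > 0 indicates excess ABBA sharing (gene flow between P3 and P2). The
# standard error is a delete-one block jackknife over contiguous genomic
# blocks, which is robust to linkage among nearby sites.

#' Polarize alleles against an outgroup
#'
#' Keeps sites where the outgroup is fixed (derived frequency 0 or 1 among
#' its non-missing chromosomes); the derived allele is the one absent from
#' the outgroup. Sites with a polymorphic or fully missing outgroup are
#' dropped and counted.
#'
#' @param gm a [genotype_matrix()].
#' @param manifest a `pop_manifest`.
#' @param outgroup outgroup population label (or sample ids).
#' @param pops character vector of population labels to emit frequencies
#'   for.
#' @param snps_only drop indel sites (default TRUE).
#' @return list with `sites` (kept site rows), `freq` (matrix sites x
#'   pops of derived-allele frequencies), and `dropped`
#'   (`outgroup_polymorphic`, `outgroup_missing` counts).
#' @export
polarize_alleles <- function(gm, manifest, outgroup, pops, snps_only = TRUE) {
  io <- resolve_samples(gm, manifest, outgroup)
  if (!length(io)) stop("outgroup is empty")
  use <- if (snps_only) !gm$sites$is_indel else rep(TRUE, n_sites(gm))
  og <- site_stats(gm, io)
  all_missing <- og$n == 0
  fixed <- !all_missing & (og$p == 0 | og$p == 1)
  keep <- which(use & fixed)
  flip <- og$p[keep] == 1       # outgroup carries the alt allele -> derived = ref
  freq <- sapply(pops, function(pn) {
    st <- site_stats(gm, resolve_samples(gm, manifest, pn))
    f <- st$p[keep]
    ifelse(flip, 1 - f, f)
  })
  freq <- matrix(freq, ncol = length(pops), dimnames = list(NULL, pops))
  list(sites = gm$sites[keep, c("contig", "pos"), drop = FALSE],
       freq = freq,
       dropped = c(outgroup_polymorphic = sum(use & !fixed & !all_missing),
                   outgroup_missing = sum(use & all_missing)))
}

#' ABBA-BABA D-statistic with block-jackknife standard error
#'
#' @param p1,p2,p3 aligned derived-allele frequency vectors for the two
#'   sister populations (P1, P2) and the candidate donor (P3).
#' @param contig,pos optional site coordinates; required for the jackknife.
#' @param block_size jackknife block length in bp (default 1 Mb).
#' @return list of class `dstat_result`: `D`, `abba` and `baba` weight sums,
#'   `n_sites` (informative), `se`, `z`, `n_blocks`, `se_unreliable`
#'   (TRUE when fewer than 5 non-empty blocks).
#' @export
d_statistic <- function(p1, p2, p3, contig = NULL, pos = NULL,
                        block_size = 1e6) {
  stopifnot(length(p1) == length(p2), length(p2) == length(p3))
  if (block_size <= 0) stop("block_size must be positive")
  ok <- !(is.na(p1) | is.na(p2) | is.na(p3))
  p1 <- p1[ok]; p2 <- p2[ok]; p3 <- p3[ok]
  abba <- (1 - p1) * p2 * p3
  baba <- p1 * (1 - p2) * p3
  num <- sum(abba - baba)
  den <- sum(abba + baba)
  if (den == 0) stop("no informative sites: ABBA + BABA weights sum to zero")
  D <- num / den
  se <- NA_real_; z <- NA_real_; n_blocks <- 0L; unreliable <- TRUE
  if (!is.null(contig) && !is.null(pos)) {
    contig <- contig[ok]; pos <- pos[ok]
    blk <- paste(contig, (pos - 1) %/% block_size, sep = ":")
    informative <- abba + baba > 0
    blocks <- unique(blk[informative])
    n_blocks <- length(blocks)
    if (n_blocks >= 2L) {
      num_b <- vapply(split(abba - baba, blk)[blocks], sum, numeric(1))
      den_b <- vapply(split(abba + baba, blk)[blocks], sum, numeric(1))
      d_loo <- (num - num_b) / (den - den_b)
      se <- sqrt((n_blocks - 1) / n_blocks *
                   sum((d_loo - mean(d_loo))^2))
      z <- if (se > 0) D / se else NA_real_
      unreliable <- n_blocks < 5L
    }
  }
  structure(list(D = D, abba = sum(abba), baba = sum(baba),
                 n_sites = sum(abba + baba > 0), se = se, z = z,
                 n_blocks = n_blocks, se_unreliable = unreliable),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("D = %.4f  (ABBA = %.1f, BABA = %.1f, %d informative sites)\n",
              x$D, x$abba, x$baba, x$n_sites))
  if (!is.na(x$se))
    cat(sprintf("block jackknife: SE = %.4f, Z = %.2f over %d blocks%s\n",
                x$se, x$z, x$n_blocks,
                if (x$se_unreliable) " [<5 blocks: SE unreliable]" else ""))
  invisible(x)
}

#' D-statistic straight from a cohort
#'
#' Convenience wrapper: polarizes against the outgroup and computes
#' [d_statistic()] for the (P1, P2, P3, outgroup) configuration.
#'
#' @inheritParams polarize_alleles
#' @param p1,p2,p3 population labels.
#' @param block_size jackknife block length in bp.
#' @return a `dstat_result`.
#' @export
d_statistic_pops <- function(gm, manifest, p1, p2, p3, outgroup,
                             block_size = 1e6) {
  pol <- polarize_alleles(gm, manifest, outgroup, c(p1, p2, p3))
  d_statistic(pol$freq[, p1], pol$freq[, p2], pol$freq[, p3],
              contig = pol$sites$contig, pos = pol$sites$pos,
              block_size = block_size)
}

#' Read an IBD tract table
#'
#' Accepts a TSV with header columns `sample1`, `sample2`, `contig`,
#' `start`, `end` (and optional `score`), or a headerless BEAGLE-style
#' table in that column order.
#'
#' @param path TSV path.
#' @return data.frame of tracts.
#' @export
read_ibd_tracts <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("^sample1\t", first)
  df <- utils::read.table(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!header) {
    nm <- c("sample1", "sample2", "contig", "start", "end", "score")
    names(df) <- nm[seq_len(ncol(df))]
  }
  df
}

#' Summarize IBD tracts per population pair
#'
#' @param tracts data.frame from [read_ibd_tracts()] (columns `sample1`,
#'   `sample2`, `contig`, `start`, `end`).
#' @param manifest a `pop_manifest`.
#' @param recipient_pop optional population label: for pairs involving it,
#'   `ibd_per_recipient` divides the tract count by the number of manifest
#'   samples of that population (the "average number of IBDs" convention).
#' @return data.frame with one row per unordered population pair: `pop1`,
#'   `pop2`, `n_tracts`, `total_length`, `mean_length`, and
#'   `ibd_per_recipient` when `recipient_pop` is given. Empty input yields
#'   zero rows without error.
#' @export
ibd_summary <- function(tracts, manifest, recipient_pop = NULL) {
  cols <- c("pop1", "pop2", "n_tracts", "total_length", "mean_length")
  if (is.null(tracts) || !nrow(tracts)) {
    out <- data.frame(pop1 = character(), pop2 = character(),
                      n_tracts = integer(), total_length = numeric(),
                      mean_length = numeric(), stringsAsFactors = FALSE)
    return(out)
  }
  if (any(tracts$end <= tracts$start)) stop("tract with end <= start")
  popof <- stats::setNames(manifest$population, manifest$sample_id)
  miss <- setdiff(c(tracts$sample1, tracts$sample2), names(popof))
  if (length(miss))
    stop(sprintf("tract samples absent from manifest: %s",
                 paste(unique(miss), collapse = ", ")))
  pa <- popof[tracts$sample1]; pb <- popof[tracts$sample2]
  pair <- ifelse(pa <= pb, paste(pa, pb, sep = "|"), paste(pb, pa, sep = "|"))
  len <- tracts$end - tracts$start
  out <- do.call(rbind, lapply(split(seq_along(pair), pair), function(ii) {
    ps <- strsplit(pair[ii[1]], "|", fixed = TRUE)[[1]]
    data.frame(pop1 = ps[1], pop2 = ps[2], n_tracts = length(ii),
               total_length = sum(len[ii]), mean_length = mean(len[ii]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(recipient_pop)) {
    n_rec <- sum(manifest$population == recipient_pop)
    out$ibd_per_recipient <- ifelse(
      (out$pop1 == recipient_pop | out$pop2 == recipient_pop) & n_rec > 0,
      out$n_tracts / n_rec, NA_real_)
  }
  out
}
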