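# Sliding/tiling-window diversity statistics.
#
# Per-site quantities use the local number of non-missing chromosomes n:
#   theta_pi (unbiased per-site heterozygosity) = 2 p q n / (n - 1)
# summed over sites in a window. Tajima's D uses the textbook a1, a2, b1,
# b2, c1, c2, e1, e2 constants with S = segregating sites in the window and
# the window-median n for the constants (per-site n varies with
# missingness; the median is the documented default).

#' Window specification
#'
#' @param size window size, bp.
#' @param step step between window starts, bp (default `size`, i.e.
#'   non-overlapping tiling). Must satisfy `step <= size`.
#' @param min_snps windows with fewer SNPs than this are flagged and their
#'   statistic values set to `NA` (default 20).
#' @return list of class `window_spec`.
#' @export
window_spec <- function(size, step = size, min_snps = 20L) {
  if (size <= 0 || step <= 0 || step > size)
    stop("need 0 < step <= size")
  structure(list(size = as.integer(size), step = as.integer(step),
                 min_snps = as.integer(min_snps)), class = "window_spec")
}

#' Tile windows across contigs
#'
#' Half-open windows `[start, start + size)` are placed every `step` bp from
#' 0; the final window is clipped at the contig end and flagged `truncated`.
#'
#' @param contigs data.frame with `name`, `length`, or a [genotype_matrix()].
#' @param spec a [window_spec()].
#' @return data.frame with `contig`, `start`, `end`, `truncated`, sorted by
#'   contig then start.
#' @export
make_windows <- function(contigs, spec) {
  if (inherits(contigs, "genotype_matrix")) contigs <- contigs$contigs
  stopifnot(inherits(spec, "window_spec"))
  out <- lapply(seq_len(nrow(contigs)), function(i) {
    len <- contigs$length[i]
    starts <- seq.int(0L, max(0L, len - 1L), by = spec$step)
    ends <- pmin(starts + spec$size, len)
    data.frame(contig = contigs$name[i], start = starts, end = ends,
               truncated = ends - starts < spec$size,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "window_spec") <- spec
  res
}

# Per-site frequency summaries for a sample subset: non-missing chromosome
# count n, alternate-allele count, frequency, per-site unbiased pi, and
# heterozygote count.
#' @noRd
site_stats <- function(gm, sample_idx) {
  d <- gm$dosages[, sample_idx, drop = FALSE]
  nn <- 2L * rowSums(!is.na(d))
  ac <- rowSums(d, na.rm = TRUE)
  p <- ifelse(nn > 0, ac / nn, NA_real_)
  pi_site <- ifelse(nn >= 2, 2 * p * (1 - p) * nn / (nn - 1), NA_real_)
  list(n = nn, ac = ac, p = p, pi = pi_site,
       het = rowSums(d == 1L, na.rm = TRUE))
}

#' Tajima's D from window summaries
#'
#' Standard normalization of the difference between the pairwise-difference
#' estimate of theta (`pi_sum`) and Watterson's `S / a1`.
#'
#' @param S number of segregating sites.
#' @param pi_sum sum of per-site pairwise differences (the window theta_pi
#'   sum).
#' @param n number of chromosomes used for the constants.
#' @return Tajima's D (`NA` if `S == 0` or `n < 4`).
#' @export
tajimas_d_from_counts <- function(S, pi_sum, n) {
  if (is.na(S) || S == 0L || is.na(n) || n < 4) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  denom <- sqrt(e1 * S + e2 * S * (S - 1))
  if (denom == 0) return(NA_real_)
  (pi_sum - S / a1) / denom
}

#' Windowed diversity statistics for one population
#'
#' @param gm a [genotype_matrix()].
#' @param manifest a `pop_manifest` (see [read_manifest()]).
#' @param pop population label (or explicit character vector of sample ids).
#' @param windows window frame from [make_windows()].
#' @param stat one of `"theta_pi"`, `"tajimas_d"`, `"het_count"`,
#'   `"snp_count"`.
#' @param min_snps overrides the window spec's `min_snps` if given; windows
#'   below it keep their `n_snps` but get `NA` statistics and
#'   `low_snps = TRUE`.
#' @param per_sample for `het_count`, also return one column per sample
#'   (requires a non-overlapping tiling). Pooled `het_count` always equals
#'   the row sum of the per-sample columns.
#' @param snps_only drop indel sites before computing (default TRUE).
#'
#' @return the window frame with `n_snps`, `low_snps`, and statistic
#'   column(s): `theta_pi` (window sum) and `theta_pi_bp`; `tajimas_d`;
#'   `het_count` (and `het_<sample>` when `per_sample`); `snp_count`.
#' @export
window_diversity <- function(gm, manifest, pop, windows,
                             stat = c("theta_pi", "tajimas_d", "het_count",
                                      "snp_count"),
                             min_snps = NULL, per_sample = FALSE,
                             snps_only = TRUE) {
  stat <- match.arg(stat)
  idx <- resolve_samples(gm, manifest, pop)
  if (length(idx) == 0L) stop("population is empty")
  if (stat == "theta_pi" && length(idx) < 2L)
    stop("theta_pi needs at least 2 samples")
  spec <- attr(windows, "window_spec")
  if (is.null(min_snps)) min_snps <- if (!is.null(spec)) spec$min_snps else 20L

  use <- if (snps_only) !gm$sites$is_indel else rep(TRUE, n_sites(gm))
  st <- site_stats(gm, idx)
  res <- windows
  res$n_snps <- 0L
  val_cols <- switch(stat,
    theta_pi = c("theta_pi", "theta_pi_bp"),
    tajimas_d = "tajimas_d",
    het_count = "het_count",
    snp_count = "snp_count")
  for (vc in val_cols) res[[vc]] <- NA_real_
  if (per_sample && stat == "het_count") {
    if (!is.null(spec) && spec$step < spec$size)
      stop("per-sample het counts require a non-overlapping tiling")
    for (sid in gm$sample_ids[idx]) res[[paste0("het_", sid)]] <- NA_real_
  }

  for (cn in unique(windows$contig)) {
    si <- which(gm$sites$contig == cn & use)
    wi <- which(windows$contig == cn)
    if (!length(wi)) next
    pos <- gm$sites$pos[si]
    rg <- window_site_ranges(pos, windows$start[wi], windows$end[wi])
    cnt <- pmax(rg[, "hi"] - rg[, "lo"] + 1L, 0L)
    res$n_snps[wi] <- cnt
    if (stat == "snp_count") {
      res$snp_count[wi] <- cnt
    } else if (stat == "theta_pi") {
      s <- window_sums(st$pi[si], rg)
      res$theta_pi[wi] <- s
      res$theta_pi_bp[wi] <- s / (windows$end[wi] - windows$start[wi])
    } else if (stat == "het_count") {
      res$het_count[wi] <- window_sums(st$het[si], rg)
      if (per_sample) {
        d <- gm$dosages[si, idx, drop = FALSE]
        for (k in seq_along(idx)) {
          res[wi, paste0("het_", gm$sample_ids[idx[k]])] <-
            window_sums(as.numeric(d[, k] == 1L), rg)
        }
      }
    } else if (stat == "tajimas_d") {
      seg <- st$p[si] > 0 & st$p[si] < 1 & st$n[si] >= 2
      seg[is.na(seg)] <- FALSE
      for (w in seq_along(wi)) {
        lo <- rg[w, "lo"]; hi <- rg[w, "hi"]
        if (hi < lo) next
        ii <- si[lo:hi][seg[lo:hi]]
        S <- length(ii)
        if (S == 0L) { res$tajimas_d[wi[w]] <- NA_real_; next }
        nmed <- stats::median(st$n[ii])
        res$tajimas_d[wi[w]] <-
          tajimas_d_from_counts(S, sum(st$pi[ii]), nmed)
      }
    }
  }
  res$low_snps <- res$n_snps < min_snps
  if (stat != "snp_count")
    for (vc in val_cols) res[[vc]][res$low_snps] <- NA_real_
  res
}

#' Compare Z-chromosome windows against autosomes
#'
#' Tests a per-window value (e.g. heterozygous SNPs per window) on the Z
#' chromosome against each autosome separately and against all autosomes
#' pooled, with a two-tailed t-test (default) or Mann-Whitney U.
#'
#' @param win_table window table with a value column.
#' @param z_contigs contig name(s) forming the Z group.
#' @param value_col name of the value column to compare.
#' @param test `"t_two_tailed"` or `"mann_whitney"`.
#' @return data.frame with one row per autosome plus a `"all_autosomes"`
#'   row: group medians, statistic, two-sided p.
#' @export
compare_chromosome_groups <- function(win_table, z_contigs, value_col,
                                      test = c("t_two_tailed", "mann_whitney")) {
  test <- match.arg(test)
  if (!any(win_table$contig %in% z_contigs))
    stop("z_contigs absent from window table")
  v <- win_table[[value_col]]
  zv <- v[win_table$contig %in% z_contigs]
  zv <- zv[!is.na(zv)]
  autosomes <- setdiff(unique(win_table$contig), z_contigs)
  if (!length(autosomes)) stop("no autosomal windows")
  one <- function(av, label) {
    av <- av[!is.na(av)]
    if (length(av) < 2L || length(zv) < 2L)
      stop("need at least 2 windows per group")
    p <- two_group_p(zv, av, test)
    data.frame(autosome = label, n_z = length(zv), n_auto = length(av),
               median_z = stats::median(zv), median_auto = stats::median(av),
               p = p, stringsAsFactors = FALSE)
  }
  rows <- lapply(autosomes, function(a)
    one(v[win_table$contig == a], a))
  rows <- c(rows, list(one(v[win_table$contig %in% autosomes],
                           "all_autosomes")))
  out <- do.call(rbind, rows)
  attr(out, "test") <- test
  out
}

# Two-sided two-sample p-value with degenerate-data conventions: if all
# values in both groups are identical the groups are indistinguishable and
# p = 1.
#' @noRd
two_group_p <- function(x, y, test) {
  if (length(unique(c(x, y))) == 1L) return(1)
  if (test == "t_two_tailed") {
    stats::t.test(x, y)$p.value
  } else {
    n <- length(x) + length(y)
    exact <- n <= 20 && !anyDuplicated(c(x, y))
    suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                        correct = FALSE)$p.value)
  }
}

#' Choose a window size by SNP saturation
#'
#' For each candidate size, tiles non-overlapping windows and computes the
#' proportion with at least `min_snps` SNPs (truncated terminal windows
#' excluded). The chosen size maximizes that proportion; ties break toward
#' the smaller size, which retains more power to detect short sweeps.
#'
#' @param gm a [genotype_matrix()].
#' @param candidate_sizes numeric vector of window sizes (bp).
#' @param min_snps saturation threshold (default 20).
#' @return list with `chosen` (bp) and `table` (size, n_windows,
#'   prop_saturated).
#' @export
select_window_size <- function(gm, candidate_sizes, min_snps = 20L) {
  if (!length(candidate_sizes)) stop("candidate_sizes is empty")
  if (n_sites(gm) == 0L) stop("genotype matrix has no sites")
  tab <- do.call(rbind, lapply(sort(candidate_sizes), function(sz) {
    w <- make_windows(gm$contigs, window_spec(sz, sz, min_snps))
    w <- w[!w$truncated, , drop = FALSE]
    if (!nrow(w))
      return(data.frame(size = sz, n_windows = 0L, prop_saturated = NA_real_))
    cnt <- integer(nrow(w))
    for (cn in unique(w$contig)) {
      si <- which(gm$sites$contig == cn & !gm$sites$is_indel)
      wi <- which(w$contig == cn)
      rg <- window_site_ranges(gm$sites$pos[si], w$start[wi], w$end[wi])
      cnt[wi] <- pmax(rg[, "hi"] - rg[, "lo"] + 1L, 0L)
    }
    data.frame(size = sz, n_windows = nrow(w),
               prop_saturated = mean(cnt >= min_snps))
  }))
  ok <- !is.na(tab$prop_saturated)
  if (!any(ok)) stop("no candidate size yields complete windows")
  best <- tab$size[ok][which.max(tab$prop_saturated[ok])]  # ties -> smallest
  list(chosen = best, table = tab)
}
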