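# Selective-sweep caller: Weir-Cockerham FST per window, z-transformed FST,
# log2 diversity ratio, and intersection of the top-quantile tails of both
# distributions followed by merging of overlapping/abutting outlier windows.

#' Weir-Cockerham FST between two populations
#'
#' Computes the per-site variance components a (among populations),
#' b (among individuals within populations) and c (within individuals) of
#' Weir & Cockerham's theta for diploid data, with per-site sample sizes
#' taken from the non-missing genotypes. The window (and genome-wide)
#' estimate is the ratio of sums `sum(a) / sum(a + b + c)` — not the mean of
#' per-site ratios — which is the standard, low-diversity-stable choice.
#' Negative per-site components are retained so sums stay unbiased.
#'
#' @param gm a [genotype_matrix()].
#' @param manifest a `pop_manifest`.
#' @param popA,popB disjoint population labels (or sample id vectors), each
#'   with at least 2 diploids.
#' @param windows optional window frame from [make_windows()]; if supplied
#'   the return gains a per-window table.
#' @param snps_only drop indel sites (default TRUE).
#' @return list with `per_site` (contig, pos, a, abc, theta), `fst_genome`
#'   (ratio of sums over all sites) and, when `windows` is given, `windows`
#'   (the frame plus `n_snps`, `fst`; windows with no polymorphic site get
#'   `NA`).
#' @export
weir_cockerham_fst <- function(gm, manifest, popA, popB, windows = NULL,
                               snps_only = TRUE) {
  ia <- resolve_samples(gm, manifest, popA)
  ib <- resolve_samples(gm, manifest, popB)
  if (length(intersect(ia, ib))) stop("popA and popB must be disjoint")
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each population needs at least 2 diploids")
  use <- if (snps_only) !gm$sites$is_indel else rep(TRUE, n_sites(gm))

  comp <- wc_components(gm$dosages[, ia, drop = FALSE],
                        gm$dosages[, ib, drop = FALSE])
  per_site <- data.frame(contig = gm$sites$contig, pos = gm$sites$pos,
                         a = comp$a, abc = comp$abc, theta = comp$theta,
                         stringsAsFactors = FALSE)[use, , drop = FALSE]
  out <- list(per_site = per_site,
              fst_genome = sum(per_site$a, na.rm = TRUE) /
                sum(per_site$abc, na.rm = TRUE))
  if (!is.null(windows)) {
    wt <- windows
    wt$n_snps <- 0L
    wt$fst <- NA_real_
    for (cn in unique(windows$contig)) {
      si <- which(per_site$contig == cn)
      wi <- which(windows$contig == cn)
      if (!length(wi)) next
      rg <- window_site_ranges(per_site$pos[si], windows$start[wi],
                               windows$end[wi])
      a_sum <- window_sums(per_site$a[si], rg)
      abc_sum <- window_sums(per_site$abc[si], rg)
      wt$n_snps[wi] <- pmax(rg[, "hi"] - rg[, "lo"] + 1L, 0L)
      ok <- abc_sum > 0
      wt$fst[wi[ok]] <- a_sum[ok] / abc_sum[ok]
    }
    out$windows <- wt
  }
  out
}

# Weir-Cockerham (1984) variance components for r = 2 populations of
# diploids, vectorized over sites. Sites monomorphic across both
# populations contribute a = abc = 0 and theta = NA.
#' @noRd
wc_components <- function(dA, dB) {
  n1 <- rowSums(!is.na(dA)); n2 <- rowSums(!is.na(dB))
  p1 <- rowSums(dA, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(dB, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(dA == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(dB == 1L, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  mono <- pbar <= 0 | pbar >= 1
  a[mono] <- 0; b[mono] <- 0; cc[mono] <- 0
  bad <- n1 < 2 | n2 < 2
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  abc <- a + b + cc
  theta <- ifelse(!is.na(abc) & abc > 0, a / abc, NA_real_)
  list(a = a, b = b, c = cc, abc = abc, theta = theta)
}

#' Z-transform window FST values
#'
#' `z = (x - mean(x)) / sd(x)` with the sample (n-1) standard deviation,
#' computed over non-missing values; missing in, missing out. Intended for
#' autosomal windows only — sex chromosomes have different effective
#' population sizes and should be excluded before calling.
#'
#' @param x numeric vector of window FST values.
#' @return numeric vector of the same length.
#' @export
zfst_transform <- function(x) {
  v <- x[!is.na(x)]
  if (length(v) < 2L) stop("need at least 2 non-missing FST values")
  s <- stats::sd(v)
  if (s == 0) stop("FST values are constant; z-transform undefined")
  (x - mean(v)) / s
}

#' Log2 diversity ratio between matched window tables
#'
#' `log2(theta_pi[reference] / theta_pi[target])` per window: large values
#' mark windows where the target population lost diversity relative to the
#' reference — the sweep direction.
#'
#' @param pi_reference,pi_target window tables from [window_diversity()]
#'   (`stat = "theta_pi"`) on the identical window frame.
#' @param pseudo_floor optional small value added to both diversities before
#'   the ratio (off by default; zero-diversity target windows then become
#'   missing with a reason code instead).
#' @return the window frame plus `log2_pi_ratio` and `ratio_reason`
#'   (`"ok"`, `"zero_target_pi"`, `"zero_reference_pi"`, `"missing_pi"`).
#' @export
log2_pi_ratio <- function(pi_reference, pi_target, pseudo_floor = 0) {
  same_frame(pi_reference, pi_target)
  pr <- pi_reference$theta_pi + pseudo_floor
  pt <- pi_target$theta_pi + pseudo_floor
  out <- pi_reference[, c("contig", "start", "end",
                          intersect("truncated", names(pi_reference)))]
  out$n_snps <- pmax(pi_reference$n_snps, pi_target$n_snps)
  ratio <- rep(NA_real_, length(pr))
  reason <- rep("ok", length(pr))
  reason[is.na(pr) | is.na(pt)] <- "missing_pi"
  zt <- !is.na(pt) & pt == 0 & !is.na(pr)
  zr <- !is.na(pr) & pr == 0 & !is.na(pt) & pt > 0
  reason[zt] <- "zero_target_pi"
  reason[zr] <- "zero_reference_pi"
  ok <- reason == "ok"
  ratio[ok] <- log2(pr[ok] / pt[ok])
  out$log2_pi_ratio <- ratio
  out$ratio_reason <- reason
  out
}

#' @noRd
same_frame <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !all(a$contig == b$contig & a$start == b$start & a$end == b$end))
    stop("window frames do not match")
  invisible(TRUE)
}

#' Call selective-sweep regions from joint FST / diversity-ratio outliers
#'
#' Windows in the top `quantile` tail of both the window-FST distribution and
#' the log2 diversity-ratio distribution (empirical quantiles over
#' non-missing, non-truncated autosomal windows, "higher" interpolation so
#' the flagged fraction per criterion never exceeds `1 - quantile`) are
#' flagged and merged when they overlap or abut. zFST is computed over the
#' same eligible windows and summarized per region; a Tajima's D difference
#' (`|D_target - D_reference|`), when given, is attached as annotation only —
#' it is not a calling criterion.
#'
#' @param fst_table window table with an `fst` column (from
#'   [weir_cockerham_fst()]).
#' @param ratio_table matched table from [log2_pi_ratio()].
#' @param d_target,d_reference optional matched Tajima's D tables from
#'   [window_diversity()].
#' @param quantile outlier quantile in (0.5, 1), default 0.95 (top 5%).
#' @param z_contigs contig names excluded from quantile computation and
#'   calling (sex chromosomes).
#' @return data.frame of class `sweep_regions`: `contig`, `start`, `end`,
#'   `n_windows`, `mean_fst`, `max_fst`, `max_zfst`, `mean_log2_ratio`,
#'   optionally `mean_abs_delta_d`. The window table used (with `flagged`
#'   and `zfst` columns) is attached as attribute `"windows"`.
#' @export
call_sweep_regions <- function(fst_table, ratio_table, d_target = NULL,
                               d_reference = NULL, quantile = 0.95,
                               z_contigs = character()) {
  if (quantile <= 0.5 || quantile >= 1) stop("quantile must lie in (0.5, 1)")
  same_frame(fst_table, ratio_table)
  w <- fst_table[, c("contig", "start", "end")]
  w$truncated <- fst_table$truncated %||% rep(FALSE, nrow(w))
  w$fst <- fst_table$fst
  w$log2_pi_ratio <- ratio_table$log2_pi_ratio
  if (!is.null(d_target) && !is.null(d_reference)) {
    same_frame(fst_table, d_target); same_frame(fst_table, d_reference)
    w$abs_delta_d <- abs(d_target$tajimas_d - d_reference$tajimas_d)
  }
  eligible <- !w$truncated & !(w$contig %in% z_contigs) &
    !is.na(w$fst) & !is.na(w$log2_pi_ratio)
  if (sum(eligible) < 20L)
    stop("fewer than 20 usable windows; quantile thresholds unstable")
  thr_fst <- quantile_higher(w$fst[eligible], quantile)
  thr_ratio <- quantile_higher(w$log2_pi_ratio[eligible], quantile)
  w$zfst <- NA_real_
  w$zfst[eligible] <- zfst_transform(w$fst[eligible])
  w$flagged <- eligible & w$fst >= thr_fst & w$log2_pi_ratio >= thr_ratio

  regions <- merge_flagged_windows(w)
  attr(regions, "windows") <- w
  attr(regions, "thresholds") <- c(fst = thr_fst, log2_pi_ratio = thr_ratio)
  class(regions) <- c("sweep_regions", "data.frame")
  regions
}

#' @noRd
merge_flagged_windows <- function(w) {
  fl <- w[w$flagged %in% TRUE, , drop = FALSE]
  cols <- c("contig", "start", "end", "n_windows", "mean_fst", "max_fst",
            "max_zfst", "mean_log2_ratio",
            if ("abs_delta_d" %in% names(w)) "mean_abs_delta_d")
  if (!nrow(fl)) {
    out <- as.data.frame(stats::setNames(
      lapply(cols, function(x) vector(if (x == "contig") "character" else "numeric", 0L)),
      cols))
    return(out)
  }
  fl <- fl[order(match(fl$contig, unique(w$contig)), fl$start), ]
  grp <- integer(nrow(fl)); g <- 1L; grp[1] <- g
  cur_end <- fl$end[1]
  if (nrow(fl) > 1L) {
    for (i in 2:nrow(fl)) {
      if (fl$contig[i] == fl$contig[i - 1L] && fl$start[i] <= cur_end) {
        grp[i] <- g
        cur_end <- max(cur_end, fl$end[i])
      } else {
        g <- g + 1L; grp[i] <- g; cur_end <- fl$end[i]
      }
    }
  }
  out <- do.call(rbind, lapply(split(fl, grp), function(b) {
    r <- data.frame(contig = b$contig[1], start = min(b$start),
                    end = max(b$end), n_windows = nrow(b),
                    mean_fst = mean(b$fst), max_fst = max(b$fst),
                    max_zfst = max(b$zfst), mean_log2_ratio =
                      mean(b$log2_pi_ratio), stringsAsFactors = FALSE)
    if ("abs_delta_d" %in% names(b))
      r$mean_abs_delta_d <- mean(b$abs_delta_d, na.rm = TRUE)
    r
  }))
  rownames(out) <- NULL
  out
}

#' Contrast sweep regions against the genomic background
#'
#' Two-sided Mann-Whitney U tests of in-region window values against all
#' window values, separately for zFST and the log2 diversity ratio — the
#' violin-plot contrast between selected regions and the whole genome.
#'
#' @param regions a `sweep_regions` frame from [call_sweep_regions()].
#' @param window_table the window table attached to the regions (default),
#'   or any table with `contig`, `start`, `end`, `zfst`, `log2_pi_ratio`.
#' @return data.frame with one row per statistic: n in-region windows,
#'   n background windows, medians, two-sided p.
#' @export
background_contrast <- function(regions,
                                window_table = attr(regions, "windows")) {
  if (!nrow(regions)) stop("region set is empty")
  w <- window_table
  in_region <- rep(FALSE, nrow(w))
  for (i in seq_len(nrow(regions))) {
    in_region <- in_region | (w$contig == regions$contig[i] &
                                w$start < regions$end[i] &
                                w$end > regions$start[i])
  }
  one <- function(col) {
    x <- w[[col]][in_region]; y <- w[[col]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    data.frame(statistic = col, n_region = length(x), n_background = length(y),
               median_region = stats::median(x),
               median_background = stats::median(y),
               p = two_group_p(x, y, "mann_whitney"),
               stringsAsFactors = FALSE)
  }
  rbind(one("zfst"), one("log2_pi_ratio"))
}

#' Annotate sweep regions with overlapping genes
#'
#' Genes overlapping a region by at least 1 bp (half-open coordinates on
#' both sides: a gene abutting a region end is not joined) are attached as a
#' comma-separated list.
#'
#' @param regions a `sweep_regions` frame (or any frame with `contig`,
#'   `start`, `end`).
#' @param gene_intervals data.frame from [read_gene_intervals()].
#' @return `regions` with added columns `genes` and `n_genes`.
#' @export
annotate_regions <- function(regions, gene_intervals) {
  g <- as.data.frame(gene_intervals)
  if (any(g$end <= g$start)) stop("malformed intervals: end <= start")
  regions$genes <- ""
  regions$n_genes <- 0L
  for (cn in unique(regions$contig)) {
    ri <- which(regions$contig == cn)
    gi <- which(g$contig == cn)
    if (!length(gi)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = regions$start[ri] + 1L, end = regions$end[ri]),
      IRanges::IRanges(start = g$start[gi] + 1L, end = g$end[gi]),
      minoverlap = 1L)
    if (!length(hits)) next
    by_region <- split(g$gene[gi][S4Vectors::subjectHits(hits)],
                       S4Vectors::queryHits(hits))
    for (k in names(by_region)) {
      i <- ri[as.integer(k)]
      genes <- unique(by_region[[k]])
      regions$genes[i] <- paste(genes, collapse = ",")
      regions$n_genes[i] <- length(genes)
    }
  }
  regions
}

#' Tally genes shared across population scans
#'
#' Counts, for each gene, how many region sets (one per population scan)
#' contain it — the "shared selected gene" tally.
#'
#' @param annotated_region_sets named list of annotated region frames (from
#'   [annotate_regions()]).
#' @return data.frame with `gene`, `n_populations`, sorted decreasing.
#' @export
shared_gene_counts <- function(annotated_region_sets) {
  per_set <- lapply(annotated_region_sets, function(r) {
    unique(unlist(strsplit(r$genes[r$genes != ""], ",", fixed = TRUE)))
  })
  tab <- table(unlist(per_set))
  out <- data.frame(gene = names(tab), n_populations = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$n_populations, out$gene), , drop = FALSE]
}
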