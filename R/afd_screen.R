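# Allele-frequency-differential screen: flag sites near fixation for
# opposite alleles in two groups (alternate-allele frequency strictly above
# `hi` in one group and strictly below `lo` in the other), and test each
# flagged site with Pearson's chi-squared on the 2x2 allele-count table
# (allele counts, not genotype counts; no continuity correction by
# default). A Benjamini-Hochberg q is reported alongside, but the default
# filter is the raw p-value.

#' Screen for extreme allele-frequency differences between two groups
#'
#' @param gm a [genotype_matrix()].
#' @param manifest a `pop_manifest`.
#' @param groupA,groupB disjoint population labels (or sample id vectors),
#'   each with at least 5 diploids.
#' @param hi,lo frequency thresholds (defaults 0.8 / 0.2, strict
#'   inequalities); a site qualifies when one group exceeds `hi` while the
#'   other is below `lo`.
#' @param p_max raw chi-squared p-value cutoff for a hit (default 0.001).
#' @param yates apply the Yates continuity correction (default FALSE).
#' @param snps_only drop indel sites (default TRUE).
#' @return data.frame of hits: site coordinates and alleles, `freq_a`,
#'   `freq_b`, the allele-count table columns (`alt_a`, `ref_a`, `alt_b`,
#'   `ref_b`), `chisq`, `p`, `q` (BH over all tested sites), and
#'   `direction` (`"A_high"` / `"B_high"`). The full per-site test table is
#'   attached as attribute `"tested"`.
#' @export
screen_differential <- function(gm, manifest, groupA, groupB,
                                hi = 0.8, lo = 0.2, p_max = 0.001,
                                yates = FALSE, snps_only = TRUE) {
  if (hi <= lo) stop("hi must exceed lo")
  ia <- resolve_samples(gm, manifest, groupA)
  ib <- resolve_samples(gm, manifest, groupB)
  if (!length(ia) || !length(ib)) stop("empty group")
  if (length(intersect(ia, ib))) stop("groups must be disjoint")
  if (length(ia) < 5L || length(ib) < 5L)
    stop("each group needs at least 5 diploids")
  use <- if (snps_only) !gm$sites$is_indel else rep(TRUE, n_sites(gm))
  sa <- site_stats(gm, ia); sb <- site_stats(gm, ib)
  alt_a <- sa$ac; ref_a <- sa$n - sa$ac
  alt_b <- sb$ac; ref_b <- sb$n - sb$ac
  n_tot <- sa$n + sb$n
  alt_tot <- alt_a + alt_b
  # Pearson chi-squared on [[alt_a, ref_a], [alt_b, ref_b]]
  det <- alt_a * ref_b - ref_a * alt_b
  adj <- if (yates) pmax(abs(det) - n_tot / 2, 0) else abs(det)
  denom <- as.numeric(sa$n) * sb$n * alt_tot * (n_tot - alt_tot)
  chisq <- ifelse(denom > 0, n_tot * adj^2 / denom, NA_real_)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  tested <- use & sa$n > 0 & sb$n > 0 & !is.na(p)
  q <- rep(NA_real_, length(p))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  fa <- sa$p; fb <- sb$p
  pass <- tested &
    ((fa > hi & fb < lo) | (fa < lo & fb > hi)) &
    p < p_max
  pass[is.na(pass)] <- FALSE
  out <- data.frame(gm$sites[pass, c("contig", "pos", "ref", "alt")],
                    freq_a = fa[pass], freq_b = fb[pass],
                    alt_a = alt_a[pass], ref_a = ref_a[pass],
                    alt_b = alt_b[pass], ref_b = ref_b[pass],
                    chisq = chisq[pass], p = p[pass], q = q[pass],
                    direction = ifelse(fa[pass] > hi, "A_high", "B_high"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "tested") <- data.frame(
    gm$sites[tested, c("contig", "pos")], chisq = chisq[tested],
    p = p[tested], q = q[tested], stringsAsFactors = FALSE)
  out
}

#' Join consequence annotations onto screen hits
#'
#' @param hits data.frame from [screen_differential()].
#' @param annotation_table data.frame keyed by (`contig`, `pos`, `alt`) with
#'   a `consequence` column (e.g. synonymous / missense / nonsense /
#'   noncoding). Duplicate keys with conflicting classes are an error.
#' @param keep_classes consequence classes to retain; empty (default) keeps
#'   every hit, labelled. Unannotated hits are labelled `"unannotated"` and
#'   are dropped only when `keep_classes` is non-empty; the excluded counts
#'   are attached as attribute `"excluded"`.
#' @return filtered hits with a `consequence` column.
#' @export
join_consequences <- function(hits, annotation_table,
                              keep_classes = character()) {
  ann <- as.data.frame(annotation_table)
  stopifnot(all(c("contig", "pos", "alt", "consequence") %in% names(ann)))
  key <- function(df) paste(df$contig, df$pos, df$alt, sep = "|")
  ak <- key(ann)
  if (anyDuplicated(ak)) {
    cls_per_key <- tapply(ann$consequence, ak, function(x) length(unique(x)))
    if (any(cls_per_key > 1L))
      stop("duplicate annotation keys with conflicting consequence classes")
    ann <- ann[!duplicated(ak), , drop = FALSE]
    ak <- key(ann)
  }
  m <- match(key(hits), ak)
  hits$consequence <- ifelse(is.na(m), "unannotated", ann$consequence[m])
  if (length(keep_classes)) {
    excluded <- table(hits$consequence[!hits$consequence %in% keep_classes])
    hits <- hits[hits$consequence %in% keep_classes, , drop = FALSE]
    attr(hits, "excluded") <- excluded
  }
  hits
}
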