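# Isochore segmentation: classify fixed GC windows into the five canonical
# families, merge consecutive windows of the same family, and correlate
# variant density with segment GC. Family boundaries follow the isochore
# literature (left-closed bins on GC fraction):
#   L1 < 0.37 <= L2 < 0.41 <= H1 < 0.46 <= H2 < 0.53 <= H3
# and are overridable. Windows that are >= 50% N become unclassified "gap"
# segments so that segments always tile the contig.

#' @noRd
default_gc_thresholds <- c(L2 = 0.37, H1 = 0.41, H2 = 0.46, H3 = 0.53)

#' @noRd
gc_family <- function(gc, thresholds = default_gc_thresholds) {
  fam <- c("L1", "L2", "H1", "H2", "H3")[
    findInterval(gc, thresholds) + 1L]
  fam[is.na(gc)] <- "gap"
  fam
}

# Fixed tiling windows with GC over non-N bases and the N fraction.
#' @noRd
gc_window_table <- function(ref, window_size) {
  out <- lapply(seq_along(ref), function(i) {
    len <- Biostrings::width(ref)[i]
    starts <- seq.int(0L, max(0L, len - 1L), by = window_size)
    ends <- pmin(starts + window_size, len)
    v <- Biostrings::Views(ref[[i]], start = starts + 1L, end = ends)
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    inf <- rowSums(freq)
    gc <- ifelse(inf > 0, rowSums(freq[, c("C", "G"), drop = FALSE]) / inf,
                 NA_real_)
    data.frame(contig = names(ref)[i], start = starts, end = ends,
               gc = gc, n_frac = 1 - inf / (ends - starts),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Segment a reference into isochores
#'
#' Classifies fixed windows of `window_size` by GC family, merges
#' consecutive windows of the same family, and assigns each segment the
#' length-weighted (by informative bases) mean GC. Windows at least half N
#' are emitted as unclassified `"gap"` segments; segments tile each contig
#' exactly.
#'
#' @param ref a `DNAStringSet` from [read_reference()].
#' @param window_size classification window, bp (>= 10 kb recommended; see
#'   [choose_gc_window()]).
#' @param thresholds named numeric vector of lower GC bounds for families
#'   L2, H1, H2, H3 (L1 is everything below).
#' @param max_n_frac windows with a larger N fraction become gaps
#'   (default 0.5).
#' @return data.frame of class `isochore_segments`: `contig`, `start`,
#'   `end` (0-based half-open), `gc`, `family`, `n_windows`.
#' @export
segment_isochores <- function(ref, window_size,
                              thresholds = default_gc_thresholds,
                              max_n_frac = 0.5) {
  if (!length(ref)) stop("empty reference")
  w <- gc_window_table(ref, window_size)
  w$family <- gc_family(w$gc, thresholds)
  w$family[w$n_frac >= max_n_frac] <- "gap"
  segs <- do.call(rbind, lapply(split(w, w$contig), function(wc) {
    wc <- wc[order(wc$start), ]
    r <- rle(wc$family)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    inf_bp <- (wc$end - wc$start) * (1 - wc$n_frac)
    data.frame(
      contig = wc$contig[1],
      start = wc$start[idx_start],
      end = wc$end[idx_end],
      gc = vapply(seq_along(r$values), function(k) {
        ii <- idx_start[k]:idx_end[k]
        wsum <- sum(inf_bp[ii])
        if (r$values[k] == "gap" || wsum == 0) NA_real_
        else sum(wc$gc[ii] * inf_bp[ii], na.rm = TRUE) / wsum
      }, numeric(1)),
      family = r$values,
      n_windows = r$lengths,
      stringsAsFactors = FALSE)
  }))
  rownames(segs) <- NULL
  segs <- segs[order(match(segs$contig, names(ref)), segs$start), ]
  class(segs) <- c("isochore_segments", "data.frame")
  segs
}

#' Choose the GC classification window size
#'
#' For each candidate size, computes the standard deviation of per-window GC
#' over windows belonging to segments of at least `min_segment_windows`
#' windows, then walks the sizes in increasing order and picks the smallest
#' size at which the relative SD decrease to the next size falls below
#' `tol` — the start of the plateau.
#'
#' @param ref a `DNAStringSet`.
#' @param sizes candidate window sizes, bp (default 10 kb to 750 kb).
#' @param tol relative-decrease tolerance defining the plateau
#'   (default 0.05).
#' @param min_segment_windows segments shorter than this many windows are
#'   excluded from the SD (default 4).
#' @return list with `chosen` (bp) and `table` (size, n_windows_used, sd).
#' @export
choose_gc_window <- function(ref,
                             sizes = c(1e4, 2e4, 4e4, 1e5, 2e5, 5e5, 7.5e5),
                             tol = 0.05, min_segment_windows = 4L) {
  sizes <- sort(sizes)
  if (any(Biostrings::width(ref) < sizes[1]))
    stop("a contig is shorter than the smallest candidate window")
  if (length(sizes) == 1L)
    return(list(chosen = sizes, table = data.frame(size = sizes,
                                                   n_windows_used = NA,
                                                   sd = NA)))
  tab <- do.call(rbind, lapply(sizes, function(sz) {
    w <- gc_window_table(ref, sz)
    w$family <- gc_family(w$gc)
    w$family[w$n_frac >= 0.5] <- "gap"
    keep <- unlist(lapply(split(seq_len(nrow(w)), w$contig), function(ii) {
      ii <- ii[order(w$start[ii])]
      r <- rle(w$family[ii])
      ii[rep(r$lengths >= min_segment_windows & r$values != "gap",
             r$lengths)]
    }))
    data.frame(size = sz, n_windows_used = length(keep),
               sd = if (length(keep) >= 2L) stats::sd(w$gc[keep]) else NA_real_)
  }))
  chosen <- tab$size[nrow(tab)]
  for (i in seq_len(nrow(tab) - 1L)) {
    if (is.na(tab$sd[i]) || is.na(tab$sd[i + 1L])) next
    rel_drop <- (tab$sd[i] - tab$sd[i + 1L]) / tab$sd[i]
    if (rel_drop < tol) { chosen <- tab$size[i]; break }
  }
  list(chosen = chosen, table = tab)
}

#' Correlate variant density with isochore GC
#'
#' Counts variants of the requested class per segment, converts to counts
#' per Mb, and reports the Pearson correlation between segment GC and
#' density, plus the per-family share of classified variants.
#'
#' @param segments an `isochore_segments` frame.
#' @param gm a [genotype_matrix()].
#' @param variant_class `"snp"` or `"indel"`.
#' @return list with `segments` (input plus `n_variants`, `per_mb`),
#'   `pearson_r`, `p`, `n_segments`, and `family_share` (percentage of
#'   classified variants per family; sums to 100 when any variant is
#'   classified).
#' @export
variant_gc_correlation <- function(segments, gm,
                                   variant_class = c("snp", "indel")) {
  variant_class <- match.arg(variant_class)
  segs <- as.data.frame(segments)
  if (nrow(segs) < 3L) stop("need at least 3 segments")
  want_indel <- variant_class == "indel"
  vs <- gm$sites[gm$sites$is_indel == want_indel, , drop = FALSE]
  segs$n_variants <- 0L
  for (cn in unique(segs$contig)) {
    si <- which(segs$contig == cn)
    pos <- vs$pos[vs$contig == cn]
    if (!length(pos)) next
    rg <- window_site_ranges(sort(pos), segs$start[si], segs$end[si])
    segs$n_variants[si] <- pmax(rg[, "hi"] - rg[, "lo"] + 1L, 0L)
  }
  segs$per_mb <- segs$n_variants / (segs$end - segs$start) * 1e6
  cl <- !is.na(segs$gc)
  if (sum(cl) < 3L) stop("need at least 3 classified (non-gap) segments")
  ct <- stats::cor.test(segs$gc[cl], segs$per_mb[cl], method = "pearson")
  fam_tot <- tapply(segs$n_variants[cl], segs$family[cl], sum)
  total <- sum(fam_tot)
  share <- if (total > 0) 100 * fam_tot / total else fam_tot * NA_real_
  list(segments = segs, pearson_r = unname(ct$estimate), p = ct$p.value,
       n_segments = sum(cl),
       family_share = share)
}
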