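# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Empirical quantile with "higher" interpolation: returns the sorted value at
# 1-based index ceiling((n-1)*q) + 1, so that the fraction of values strictly
# above the threshold never exceeds 1-q (ties can only shrink the flagged set
# when flagging with >=, which is why callers that need the <= (1-q) guarantee
# flag with >= against this threshold on distinct values).
#' @noRd
quantile_higher <- function(x, q) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) stop("no non-missing values for quantile")
  x[min(n, ceiling((n - 1) * q) + 1L)]
}

# Locate, for each half-open window [start, end) on one contig, the run of
# sites (1-based positions, sorted ascending) it contains. A site at VCF
# position p occupies 0-based coordinate p-1, so p is inside iff
# start < p <= end. Returns a two-column matrix of [lo, hi] index bounds into
# `pos`; lo > hi means an empty window.
#' @noRd
window_site_ranges <- function(pos, starts, ends) {
  lo <- findInterval(starts, pos) + 1L      # first pos >  start
  hi <- findInterval(ends, pos)             # last  pos <= end
  cbind(lo = lo, hi = hi)
}

# Sum a per-site vector over window index ranges in O(sites + windows).
#' @noRd
window_sums <- function(values, ranges) {
  cs <- c(0, cumsum(ifelse(is.na(values), 0, values)))
  lo <- ranges[, "lo"]; hi <- ranges[, "hi"]
  out <- cs[hi + 1L] - cs[lo]
  out[hi < lo] <- 0
  out
}

#' @noRd
assert_pop_in_manifest <- function(manifest, pop) {
  if (!pop %in% manifest$population)
    stop(sprintf("population '%s' not present in manifest", pop))
}

#' @noRd
pop_samples <- function(manifest, pop) {
  manifest$sample_id[manifest$population == pop]
}

# Resolve a population label or an explicit character vector of sample ids to
# column indices of the dosage matrix.
#' @noRd
resolve_samples <- function(gm, manifest, who) {
  ids <- if (length(who) == 1L && who %in% manifest$population)
    pop_samples(manifest, who) else who
  idx <- match(ids, gm$sample_ids)
  if (anyNA(idx))
    stop(sprintf("samples not in genotype matrix: %s",
                 paste(ids[is.na(idx)], collapse = ", ")))
  idx
}

#' @noRd
write_tsv_file <- function(df, path, comment_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cl in comment_lines) writeLines(paste0("# ", cl), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
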