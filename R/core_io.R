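# Shared data model and readers/writers for the standard formats the
# pipeline touches (VCF, FASTA, TSV manifests, TSV/BED outputs).
#
# Coordinate conventions, stated once and used everywhere:
#   * variant sites are 1-based inclusive, as in VCF;
#   * windows, regions and BED output are 0-based half-open.

#' Construct a genotype matrix
#'
#' The central container of the package: biallelic sites by samples, with
#' diploid alternate-allele dosages 0/1/2 (`NA` for a missing genotype), plus
#' contig and site metadata. Indels and SNPs share the matrix and are told
#' apart by the per-site `is_indel` flag.
#'
#' @param contigs data.frame with columns `name`, `length` (bp).
#' @param sites data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`, and logical `is_indel`. Positions must be strictly increasing
#'   within each contig and contigs must appear in `contigs$name` order.
#' @param dosages integer matrix, `nrow(sites)` x `length(sample_ids)`,
#'   values in `{0, 1, 2, NA}`.
#' @param sample_ids character vector of sample names (column order).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(contigs, sites, dosages, sample_ids) {
  contigs <- as.data.frame(contigs)
  sites <- as.data.frame(sites)
  stopifnot(all(c("name", "length") %in% names(contigs)),
            all(c("contig", "pos", "ref", "alt") %in% names(sites)))
  if (is.null(sites$is_indel)) sites$is_indel <- nchar(sites$ref) != 1L | nchar(sites$alt) != 1L
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (nrow(dosages) != nrow(sites) || ncol(dosages) != length(sample_ids))
    stop("dosage matrix dimensions must match sites x samples")
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (!all(sites$contig %in% contigs$name))
    stop("site contig not declared in contigs")
  for (cn in unique(sites$contig)) {
    p <- sites$pos[sites$contig == cn]
    if (is.unsorted(p, strictly = TRUE))
      stop(sprintf("positions not strictly increasing on contig '%s'", cn))
  }
  colnames(dosages) <- sample_ids
  structure(list(contigs = contigs, sites = sites, dosages = dosages,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites (%d indels) x %d samples on %d contig(s)\n",
              nrow(x$sites), sum(x$sites$is_indel), length(x$sample_ids),
              nrow(x$contigs)))
  invisible(x)
}

#' Number of sites / samples in a genotype matrix
#' @param gm a [genotype_matrix()].
#' @return integer count.
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' @rdname n_sites
#' @export
n_samples <- function(gm) length(gm$sample_ids)

#' Read a sample-to-population manifest
#'
#' A manifest is a TSV with header columns `sample_id`, `population`, and any
#' number of optional role columns (e.g. `role_dstat` with values
#' P1/P2/P3/outgroup, `role_sweep` with target/reference, `role_afd` with
#' groupA/groupB, `sex` for Z-chromosome work). Role columns are carried
#' through untouched; operations address populations or roles by label.
#'
#' @param path TSV path.
#' @return data.frame of class `pop_manifest`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("sample_id", "population") %in% names(df)))
    stop("manifest must have columns sample_id and population")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in manifest")
  class(df) <- c("pop_manifest", "data.frame")
  df
}

#' Read variant calls and a population manifest
#'
#' Loads a sorted VCF 4.x with GT fields into a [genotype_matrix()]. Dosage is
#' the count of alternate alleles per diploid genotype; `./.` becomes `NA`.
#' Multi-allelic records are dropped by default (the analyses here are defined
#' on biallelic SNPs and indels); set `drop_multiallelic = FALSE` to split
#' them into one record per alternate allele instead (dosage counts that
#' allele only).
#'
#' @param vcf_path path to a (plain or bgzipped) VCF.
#' @param manifest_path path to the manifest TSV; every sample named there
#'   must be present in the VCF, otherwise a hard error lists the missing
#'   names.
#' @param drop_multiallelic drop (default) or split multi-allelic records.
#' @param max_site_missing per-site missing-genotype fraction above which the
#'   site is removed (default 0.2). Set to 1 to keep everything.
#' @return list with elements `geno` ([genotype_matrix()]) and `manifest`.
#' @export
read_variants <- function(vcf_path, manifest_path, drop_multiallelic = TRUE,
                          max_site_missing = 0.2) {
  manifest <- read_manifest(manifest_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  vcf_samples <- colnames(gt)
  missing <- setdiff(manifest$sample_id, vcf_samples)
  if (length(missing))
    stop(sprintf("manifest samples absent from VCF: %s",
                 paste(missing, collapse = ", ")))
  pos <- as.integer(fix$POS)
  for (cn in unique(fix$CHROM)) {
    p <- pos[fix$CHROM == cn]
    if (is.unsorted(p))
      stop(sprintf("VCF not sorted: contig '%s' has decreasing positions", cn))
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  keep <- rep(TRUE, nrow(fix))
  split_rows <- NULL
  if (drop_multiallelic) {
    keep <- !multi
  } else if (any(multi)) {
    split_rows <- which(multi)
  }
  chrom <- fix$CHROM[keep]; pos_k <- pos[keep]
  ref <- fix$REF[keep]; alt <- fix$ALT[keep]
  gt_k <- gt[keep, , drop = FALSE]
  dos <- gt_to_dosage(gt_k, allele = 1L)
  sites <- data.frame(contig = chrom, pos = pos_k, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  if (!is.null(split_rows)) {
    extra <- lapply(split_rows, function(i) {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      lapply(seq_along(alts), function(a) {
        list(site = data.frame(contig = fix$CHROM[i], pos = pos[i],
                               ref = fix$REF[i], alt = alts[a],
                               stringsAsFactors = FALSE),
             dos = gt_to_dosage(gt[i, , drop = FALSE], allele = a))
      })
    })
    extra <- unlist(extra, recursive = FALSE)
    sites <- rbind(sites, do.call(rbind, lapply(extra, `[[`, "site")))
    dos <- rbind(dos, do.call(rbind, lapply(extra, `[[`, "dos")))
    o <- order(match(sites$contig, unique(fix$CHROM)), sites$pos)
    sites <- sites[o, , drop = FALSE]
    dos <- dos[o, , drop = FALSE]
  }
  # collapse duplicate positions (split records at one pos violate the
  # strictly-increasing invariant); keep the first
  dup <- duplicated(paste(sites$contig, sites$pos))
  if (any(dup)) { sites <- sites[!dup, ]; dos <- dos[!dup, , drop = FALSE] }
  miss_frac <- rowMeans(is.na(dos))
  ok <- miss_frac <= max_site_missing
  sites <- sites[ok, , drop = FALSE]
  dos <- dos[ok, , drop = FALSE]
  rownames(sites) <- NULL
  contigs <- contig_table_from_vcf(v, sites)
  gm <- genotype_matrix(contigs, sites,
                        dos[, manifest$sample_id, drop = FALSE],
                        manifest$sample_id)
  list(geno = gm, manifest = manifest)
}

# GT strings -> dosage of one alternate allele. Accepts / or | separators.
#' @noRd
gt_to_dosage <- function(gt, allele = 1L) {
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  d <- (a1 == as.character(allele)) + (a2 == as.character(allele))
  d[a1 == "." | a2 == "." | is.na(gt)] <- NA
  m <- matrix(as.integer(d), nrow = nrow(gt), dimnames = dimnames(gt))
  m
}

#' @noRd
contig_table_from_vcf <- function(v, sites) {
  meta <- v@meta
  ctg <- grep("^##contig=", meta, value = TRUE)
  if (length(ctg)) {
    nm <- sub('.*ID=([^,>]+).*', "\\1", ctg)
    ln <- suppressWarnings(as.integer(sub('.*length=([0-9]+).*', "\\1", ctg)))
    tab <- data.frame(name = nm, length = ln, stringsAsFactors = FALSE)
    tab <- tab[tab$name %in% unique(sites$contig) | !anyNA(tab$length), ]
    if (!anyNA(tab$length) && all(unique(sites$contig) %in% tab$name))
      return(tab[tab$name %in% unique(sites$contig), , drop = FALSE])
  }
  # fall back to observed extent
  data.frame(name = unique(sites$contig),
             length = vapply(unique(sites$contig), function(cn)
               max(sites$pos[sites$contig == cn]), integer(1)),
             stringsAsFactors = FALSE)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCF 4.2 with GT-only genotypes; round-trips through
#' [read_variants()] preserving contigs, positions, alleles and dosages.
#' Dosage 1 is written as the unphased heterozygote `0/1`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_variants <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", gm$contigs$name,
                       gm$contigs$length),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$sample_ids), collapse = "\t")),
             con)
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = n_sites(gm), ncol = n_samples(gm))
  ok <- !is.na(gm$dosages)
  gt[ok] <- gt_code[gm$dosages[ok] + 1L]
  lines <- paste(gm$sites$contig, gm$sites$pos, ".", gm$sites$ref,
                 gm$sites$alt, ".", "PASS", ".", "GT",
                 apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write a population manifest TSV
#' @param manifest a `pop_manifest` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write_tsv_file(as.data.frame(manifest), path)
}

#' Read a reference genome
#'
#' @param fasta_path FASTA path. Contig names must be unique; sequences are
#'   uppercased and N's retained.
#' @return a `Biostrings::DNAStringSet` (named by contig, in file order).
#' @export
read_reference <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate contig names in FASTA")
  Biostrings::DNAStringSet(toupper(seqs))
}

#' GC fraction of sequences over non-N bases
#'
#' @param seqs a `DNAStringSet` or single character string.
#' @return numeric vector; `NA` where a sequence has no informative (non-N)
#'   bases.
#' @export
gc_fraction <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  informative <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- rowSums(freq[, c("C", "G"), drop = FALSE])
  ifelse(informative > 0, gc / informative, NA_real_)
}

#' Contig name/length table for a reference
#' @param seqs a `DNAStringSet` as from [read_reference()].
#' @return data.frame with `name`, `length`.
#' @export
contig_table <- function(seqs) {
  data.frame(name = names(seqs), length = Biostrings::width(seqs),
             stringsAsFactors = FALSE)
}

#' Write pipeline tables to a directory
#'
#' Window tables and hit lists are written as TSV with a header comment
#' stating the coordinate convention; region tables are additionally written
#' as BED (0-based half-open).
#'
#' @param objects named list of data.frames. Elements whose name ends in
#'   `regions` (or that carry class `sweep_regions`) also produce a `.bed`.
#' @param out_dir output directory, created if needed.
#' @return character vector of files written, invisibly.
#' @export
write_tables <- function(objects, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  for (nm in names(objects)) {
    obj <- as.data.frame(objects[[nm]])
    tsv <- file.path(out_dir, paste0(nm, ".tsv"))
    conv <- if (all(c("start", "end") %in% names(obj)))
      "coordinates: 0-based half-open [start, end)"
    else if ("pos" %in% names(obj)) "coordinates: pos is 1-based (VCF)"
    else character()
    write_tsv_file(obj, tsv, comment_lines = conv)
    written <- c(written, tsv)
    is_region <- inherits(objects[[nm]], "sweep_regions") ||
      grepl("regions$|segments$", nm)
    if (is_region && all(c("contig", "start", "end") %in% names(obj))) {
      bed <- file.path(out_dir, paste0(nm, ".bed"))
      name_col <- if ("genes" %in% names(obj)) obj$genes
      else if ("family" %in% names(obj)) obj$family
      else "."
      name_col[is.na(name_col) | name_col == ""] <- "."
      writeLines(paste(obj$contig, obj$start, obj$end, name_col, sep = "\t"),
                 bed)
      written <- c(written, bed)
    }
  }
  invisible(written)
}

#' Read gene/annotation intervals (BED or TSV)
#'
#' @param path BED (3+ columns, 4th used as the gene identifier) or a TSV
#'   with header columns `contig`, `start`, `end`, `gene`. Coordinates are
#'   0-based half-open in both cases.
#' @return data.frame with `contig`, `start`, `end`, `gene`.
#' @export
read_gene_intervals <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^contig\t", first)) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    names(df)[1:3] <- c("contig", "start", "end")
    names(df)[4] <- if (ncol(df) >= 4L) "gene" else NULL
    if (ncol(df) < 4L) df$gene <- paste0("feature_", seq_len(nrow(df)))
  }
  if (any(df$end <= df$start)) stop("malformed intervals: end <= start")
  df[, c("contig", "start", "end", "gene")]
}
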