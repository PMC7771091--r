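#' Count aligned reads overlapping genomic regions
#'
#' Counts, for one SAM/BAM file, the reads whose aligned span overlaps each
#' region by at least 1 bp. A read overlapping several (possibly overlapping)
#' regions is counted in each of them. Unmapped, secondary and supplementary
#' alignments are always excluded; reads with mapping quality below
#' `min_mapq` are excluded; reads flagged as PCR/optical duplicates are
#' excluded only when `exclude_duplicates = TRUE`. Counting is strand-agnostic
#' and each mapped segment of a pair counts once.
#'
#' @param alignment_path Path to a BAM file, or a SAM file (converted on the
#'   fly).
#' @param regions Tibble of 0-based half-open intervals with columns `chrom`,
#'   `start`, `end` plus any key columns (e.g. `gene_id`, `tss`).
#' @param min_mapq Minimum mapping quality (default 0: keep all mapped reads).
#' @param exclude_duplicates Drop reads with the duplicate flag set.
#' @return The `regions` tibble with an added integer `count` column.
#' @export
count_reads <- function(alignment_path, regions, min_mapq = 0,
                        exclude_duplicates = FALSE) {
  if (!file.exists(alignment_path)) {
    abort(sprintf("alignment file not found: %s", alignment_path))
  }
  bam <- alignment_path
  if (grepl("\\.sam$", alignment_path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(alignment_path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (exclude_duplicates) FALSE else NA
  )
  param <- Rsamtools::ScanBamParam(flag = flags, mapqFilter = min_mapq)
  reads <- GenomicRanges::granges(
    GenomicAlignments::readGAlignments(bam, param = param)
  )

  known <- GenomeInfoDb::seqlevels(reads)
  missing_chrom <- setdiff(unique(regions$chrom), known)
  if (length(missing_chrom) > 0) {
    warn(sprintf("chromosome(s) %s absent from alignment header; their regions get zero counts",
                 paste(missing_chrom, collapse = ", ")))
  }

  counts <- integer(nrow(regions))
  present <- regions$chrom %in% known
  if (any(present)) {
    gr <- intervals_granges(regions[present, , drop = FALSE])
    GenomeInfoDb::seqlevels(gr) <- known
    counts[present] <- GenomicRanges::countOverlaps(
      gr, reads, minoverlap = 1L, ignore.strand = TRUE
    )
  }
  dplyr::mutate(regions, count = counts)
}

#' Count reads in regions for a set of samples
#'
#' Applies [count_reads()] to one alignment file per sample and assembles a
#' region-by-sample count table.
#'
#' @param paths Named character vector of SAM/BAM paths; names are sample ids.
#' @param regions Region tibble (see [count_reads()]); its key columns
#'   (`gene_id`, and `tss` for promoter windows) are kept.
#' @inheritParams count_reads
#' @return Tibble of region keys plus one count column per sample.
#' @export
count_reads_samples <- function(paths, regions, min_mapq = 0,
                                exclude_duplicates = FALSE) {
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    abort("paths must be a named vector (names are sample ids)")
  }
  keys <- intersect(c("gene_id", "tss"), names(regions))
  out <- regions[keys]
  for (s in names(paths)) {
    out[[s]] <- count_reads(paths[[s]], regions, min_mapq = min_mapq,
                            exclude_duplicates = exclude_duplicates)$count
  }
  out
}

#' Read a precomputed region count table
#'
#' Lets users (and tests) bypass alignment files: a TSV whose key columns are
#' `gene_id` (gene bodies) or `gene_id` and `tss` (promoter windows), followed
#' by one column of counts per sample. Counts must be non-negative integers
#' and region keys unique.
#'
#' @param path Path to the TSV.
#' @return A validated tibble of region keys plus per-sample count columns.
#' @export
read_region_counts <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_region_counts(tbl, source = path)
}

validate_region_counts <- function(tbl, source = "region count table") {
  if (!"gene_id" %in% names(tbl)) {
    abort(sprintf("%s must have a gene_id column", source))
  }
  keys <- intersect(c("gene_id", "tss"), names(tbl))
  samples <- setdiff(names(tbl), keys)
  if (nrow(tbl) == 0) abort(sprintf("%s is empty (no regions)", source))
  if (length(samples) == 0) abort(sprintf("%s has no sample columns", source))
  if (anyDuplicated(tbl[keys])) {
    abort(sprintf("%s has duplicated region keys", source))
  }
  m <- as.matrix(tbl[samples])
  if (!is.numeric(m) || anyNA(m) || any(m < 0) || any(m != floor(m))) {
    abort(sprintf("%s must contain non-negative integer counts", source))
  }
  tbl
}
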