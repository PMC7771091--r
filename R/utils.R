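# Internal helpers shared across modules.

# Columns of a counts/signal tibble that hold per-sample values, i.e.
# everything except the region-key columns.
key_cols <- c("gene_id", "tss", "chrom", "start", "end", "strand")

sample_cols <- function(tbl) setdiff(names(tbl), key_cols)

# counts tibble (gene_id + one numeric column per sample) -> numeric matrix
counts_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), "gene_id" %in% names(counts))
  samples <- sample_cols(counts)
  if (length(samples) == 0L) abort("no sample columns found")
  m <- as.matrix(counts[samples])
  if (!is.numeric(m)) abort("sample columns must be numeric")
  rownames(m) <- counts$gene_id
  m
}

matrix_counts <- function(m) {
  dplyr::bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
}

# Round half away from zero (R's round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# 0-based half-open interval tibble -> GRanges (1-based closed internally)
intervals_granges <- function(tbl) {
  GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end)
  )
}

assert_two_conditions <- function(design) {
  if (!all(c("sample_id", "condition") %in% names(design))) {
    abort("design must have columns sample_id and condition")
  }
  conds <- unique(design$condition)
  if (length(conds) != 2L) {
    abort(sprintf("design must have exactly two conditions, found %d", length(conds)))
  }
  invisible(conds)
}
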