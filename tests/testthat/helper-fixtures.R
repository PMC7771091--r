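# Programmatic fixtures shared across test files.

# Write a GTF from (chrom, start, end, strand, gene, tx) rows.
write_test_gtf <- function(rows, path = tempfile(fileext = ".gtf")) {
  lines <- vapply(rows, function(r) {
    sprintf('%s\ttest\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            r[[1]], as.integer(r[[2]]), as.integer(r[[3]]), r[[4]], r[[5]], r[[6]])
  }, character(1))
  writeLines(lines, path)
  path
}

# Write a minimal SAM file from 1-based alignment positions.
write_test_sam <- function(pos, width = 50, chrom = "chr1", chrom_len = 1e6,
                           mapq = 60, flag = 0,
                           path = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, as.integer(chrom_len)))
  if (length(flag) == 1) flag <- rep(flag, length(pos))
  if (length(mapq) == 1) mapq <- rep(mapq, length(pos))
  if (length(width) == 1) width <- rep(width, length(pos))
  records <- sprintf("r%03d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                     seq_along(pos), flag, chrom, pos, mapq, width)
  writeLines(c(header, records), path)
  path
}

# Write a kallisto-style abundance TSV.
write_test_abundance <- function(target_id, est_counts,
                                 length = rep(1000, base::length(target_id)),
                                 path = tempfile(fileext = ".tsv")) {
  tbl <- data.frame(target_id = target_id, length = length,
                    eff_length = pmax(length - 150, 10),
                    est_counts = est_counts,
                    tpm = est_counts / sum(est_counts) * 1e6)
  readr::write_tsv(tbl, path, progress = FALSE)
  path
}

# Small two-condition design (two replicates each).
test_design <- function(samples = c("a1", "a2", "b1", "b2")) {
  tibble::tibble(sample_id = samples,
                 condition = rep(c("A", "B"), each = length(samples) / 2))
}

# Random Z-score style table with k objective columns.
random_ztable <- function(n, k, scale = 3) {
  marks <- paste0("m", seq_len(k))
  zt <- tibble::tibble(gene_id = sprintf("g%04d", seq_len(n)))
  for (m in marks) zt[[m]] <- round(stats::rnorm(n, sd = scale), 2)
  zt
}

# Independent median-of-ratios oracle: explicit loops, manual median.
oracle_size_factors <- function(m) {
  keep <- apply(m, 1, function(x) all(x > 0))
  ref <- apply(m[keep, , drop = FALSE], 1, function(x) prod(x)^(1 / length(x)))
  vapply(seq_len(ncol(m)), function(s) {
    ratios <- sort(m[keep, s] / ref)
    n <- length(ratios)
    if (n %% 2 == 1) ratios[(n + 1) / 2] else
      (ratios[n / 2] + ratios[n / 2 + 1]) / 2
  }, numeric(1))
}

all_activating <- function(zt) {
  marks <- setdiff(names(zt), c("gene_id", "front"))
  stats::setNames(rep("activating", length(marks)), marks)
}
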