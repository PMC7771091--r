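#' Load gene models from a GTF annotation
#'
#' Parses a GTF file into one gene model per `gene_id`: the gene's chromosome,
#' strand, genomic span (1-based, inclusive), the deduplicated set of
#' transcription start sites (TSSs) of its transcripts, and its transcript
#' ids. The TSS of a transcript is its start coordinate on the `+` strand and
#' its end coordinate on the `-` strand. The gene body spans the minimum start
#' to the maximum end over all of the gene's records.
#'
#' @param gtf_path Path to a GTF file (9 tab-separated columns with
#'   `gene_id`/`transcript_id` attributes).
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `start`, `end` (1-based inclusive gene span), and list-columns
#'   `tss` (sorted unique TSS positions) and `transcript_ids`.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "src", "transcript", 1001, 2000, ".", "+", ".",
#'                  'gene_id "g1"; transcript_id "t1";', sep = "\t"), gtf)
#' load_annotation(gtf)
#' @export
load_annotation <- function(gtf_path) {
  if (!file.exists(gtf_path)) abort(sprintf("GTF file not found: %s", gtf_path))
  validate_gtf_lines(gtf_path)

  gr <- rtracklayer::import(gtf_path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  if (!"gene_id" %in% names(df)) abort("GTF has no gene_id attributes")
  if (!"transcript_id" %in% names(df)) abort("GTF has no transcript_id attributes")

  tx <- df |>
    dplyr::filter(!is.na(.data$transcript_id)) |>
    dplyr::mutate(strand = as.character(.data$strand),
                  chrom = as.character(.data$seqnames))
  if (any(is.na(tx$gene_id))) {
    bad <- unique(tx$transcript_id[is.na(tx$gene_id)])
    abort(sprintf("transcript(s) without gene_id: %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  if (!all(tx$strand %in% c("+", "-"))) {
    abort("every transcript must be on strand '+' or '-'")
  }

  # one record per transcript (a transcript's exons share its span extremes)
  tx <- tx |>
    dplyr::group_by(.data$gene_id, .data$transcript_id) |>
    dplyr::summarise(chrom = dplyr::first(.data$chrom),
                     strand = dplyr::first(.data$strand),
                     start = min(.data$start), end = max(.data$end),
                     .groups = "drop") |>
    dplyr::mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end))

  tx |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      strand = dplyr::first(.data$strand),
      start = min(.data$start),
      end = max(.data$end),
      tss = list(sort(unique(.data$tss))),
      transcript_ids = list(sort(unique(.data$transcript_id))),
      .groups = "drop"
    )
}

# Cheap structural validation so parse failures carry a line number.
validate_gtf_lines <- function(gtf_path) {
  lines <- readLines(gtf_path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    lineno <- which(body)[which(nfield != 9L)[1]]
    abort(sprintf("malformed GTF line %d: expected 9 tab-separated fields, found %d",
                  lineno, nfield[which(nfield != 9L)[1]]))
  }
  invisible(TRUE)
}

#' Derive promoter windows around every transcription start site
#'
#' Each distinct TSS of each gene gets a fixed-width window with the TSS at
#' its center (default 5 kb). For a 1-based TSS `t` the window is
#' `[t - 1 - promoter_size/2, t - 1 + promoter_size/2)` in 0-based half-open
#' coordinates, clipped at position 0. Overlapping windows of the same gene
#' are kept separate so that per-promoter matching strategies can see them
#' individually.
#'
#' @param genes Gene models from [load_annotation()].
#' @param promoter_size Window width in bp; must be even and positive.
#' @return A tibble with one row per (gene, TSS): `gene_id`, `tss`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`.
#' @export
derive_promoters <- function(genes, promoter_size = 5000) {
  if (length(promoter_size) != 1L || is.na(promoter_size) ||
      promoter_size <= 0 || promoter_size %% 2 != 0) {
    abort("promoter_size must be a positive even number of base pairs")
  }
  half <- promoter_size / 2
  genes |>
    dplyr::select("gene_id", "chrom", "strand", "tss") |>
    tidyr::unnest_longer("tss") |>
    dplyr::mutate(start = pmax(0, .data$tss - 1 - half),
                  end = .data$tss - 1 + half) |>
    dplyr::select("gene_id", "tss", "chrom", "start", "end", "strand")
}

#' Gene-body intervals
#'
#' Converts each gene's annotated span (start to end, not the exon union) to
#' a 0-based half-open interval. This is the counting region for marks that
#' cover transcribed regions, such as H3K36me3.
#'
#' @param genes Gene models from [load_annotation()].
#' @return A tibble `gene_id`, `chrom`, `start`, `end` (0-based half-open),
#'   `strand`; empty input yields an empty tibble.
#' @export
gene_bodies <- function(genes) {
  genes |>
    dplyr::transmute(gene_id = .data$gene_id, chrom = .data$chrom,
                     start = .data$start - 1, end = .data$end,
                     strand = .data$strand)
}

#' Export promoter windows as BED6
#'
#' Writes the promoter windows (already 0-based half-open, as BED requires)
#' for inspection in a genome browser. Score is 0; the name field is
#' `gene_id:tss`.
#'
#' @param promoters Output of [derive_promoters()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_promoters_bed <- function(promoters, path) {
  bed <- promoters |>
    dplyr::transmute(.data$chrom, .data$start, .data$end,
                     name = paste0(.data$gene_id, ":", .data$tss),
                     score = 0L, .data$strand)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
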