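#' Read a transcript-level abundance file
#'
#' Reads one sample's transcript quantification in the kallisto output layout:
#' a tab-separated file with header columns `target_id`, `length`,
#' `eff_length`, `est_counts`, `tpm`. Only `target_id` and `est_counts` are
#' required; `tpm` is carried through when present. Estimated counts are kept
#' as reals — rounding happens only after gene-level aggregation.
#'
#' @param path Path to the abundance TSV.
#' @param sample_id Sample label attached to every row.
#' @return A tibble `sample_id`, `target_id`, `est_counts` and, if present,
#'   `tpm`.
#' @export
read_abundance <- function(path, sample_id) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("target_id", "est_counts")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("abundance file %s is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  if (any(tbl$est_counts < 0, na.rm = TRUE)) {
    abort(sprintf("abundance file %s contains negative est_counts", path))
  }
  if (anyDuplicated(tbl$target_id)) {
    abort(sprintf("abundance file %s has duplicated target_id values", path))
  }
  out <- tibble(sample_id = sample_id,
                target_id = as.character(tbl$target_id),
                est_counts = as.numeric(tbl$est_counts))
  if ("tpm" %in% names(tbl)) out$tpm <- as.numeric(tbl$tpm)
  out
}

#' Aggregate transcript abundances to gene-level counts
#'
#' Sums estimated counts over each gene's transcripts per sample, then rounds
#' half away from zero so downstream count models receive integers.
#' Transcripts absent from the transcript-to-gene map are dropped (their
#' number is reported via a message).
#'
#' @param abundances One tibble, or a list of tibbles, as returned by
#'   [read_abundance()]; samples are identified by their `sample_id` column.
#' @param tx2gene Tibble with columns `transcript_id` and `gene_id` (see
#'   [read_tx2gene()] and [tx2gene_from_annotation()]).
#' @return A gene count tibble: `gene_id` plus one integer column per sample.
#' @export
aggregate_to_genes <- function(abundances, tx2gene) {
  if (is.data.frame(abundances)) abundances <- list(abundances)
  ab <- dplyr::bind_rows(abundances)
  if (!all(c("transcript_id", "gene_id") %in% names(tx2gene))) {
    abort("tx2gene must have columns transcript_id and gene_id")
  }
  mapped <- dplyr::inner_join(ab, tx2gene, by = c(target_id = "transcript_id"))
  if (nrow(mapped) == 0) {
    abort("no transcript in the abundance files matches tx2gene")
  }
  n_dropped <- length(setdiff(unique(ab$target_id), tx2gene$transcript_id))
  if (n_dropped > 0) {
    inform(sprintf("aggregate_to_genes: dropped %d transcript(s) absent from tx2gene",
                   n_dropped))
  }
  mapped |>
    dplyr::group_by(.data$gene_id, .data$sample_id) |>
    dplyr::summarise(count = round_half_away(sum(.data$est_counts)),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                       values_fill = 0) |>
    dplyr::arrange(.data$gene_id)
}

#' Read a transcript-to-gene map
#'
#' @param path Two-column TSV (transcript id, gene id), with or without a
#'   header line named `transcript_id`/`gene_id`.
#' @return Tibble with columns `transcript_id`, `gene_id`.
#' @export
read_tx2gene <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("transcript_id", first, fixed = TRUE)
  tbl <- readr::read_tsv(path, col_names = has_header,
                         show_col_types = FALSE, progress = FALSE)
  if (!has_header) names(tbl) <- c("transcript_id", "gene_id")
  if (ncol(tbl) < 2) abort("tx2gene file must have two columns")
  tibble(transcript_id = as.character(tbl$transcript_id),
         gene_id = as.character(tbl$gene_id))
}

#' Derive the transcript-to-gene map from gene models
#'
#' @param genes Gene models from [load_annotation()].
#' @return Tibble with columns `transcript_id`, `gene_id`.
#' @export
tx2gene_from_annotation <- function(genes) {
  genes |>
    dplyr::select("gene_id", "transcript_ids") |>
    tidyr::unnest_longer("transcript_ids") |>
    dplyr::transmute(transcript_id = .data$transcript_ids,
                     gene_id = .data$gene_id)
}
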