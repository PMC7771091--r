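#' Match promoter signal to genes: highest-abundance promoter
#'
#' Collapses a promoter-by-sample count table to one row per gene by picking,
#' per gene, the single promoter with the largest mean count across all
#' samples, and copying that promoter's full per-sample count vector. One
#' consistent promoter is chosen per gene (not a per-sample argmax), so a
#' between-condition fold change on the matched signal reflects abundance
#' change at one promoter rather than promoter switching. Ties are broken by
#' the smallest TSS coordinate.
#'
#' @param promoter_counts Tibble with key columns `gene_id`, `tss` and one
#'   count column per sample (see [count_reads_samples()] /
#'   [read_region_counts()]).
#' @param genes Optional character vector of expected gene ids; genes with no
#'   promoter rows are reported with a warning and excluded.
#' @return A matched-signal tibble: `gene_id` plus one column per sample, with
#'   attributes `strategy = "highest"`.
#' @export
match_highest <- function(promoter_counts, genes = NULL) {
  pc <- check_promoter_counts(promoter_counts, genes)
  samples <- setdiff(names(pc), c("gene_id", "tss"))
  pc$.abundance <- rowMeans(as.matrix(pc[samples]))
  out <- pc |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(dplyr::desc(.data$.abundance), .data$tss, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", dplyr::all_of(samples)) |>
    dplyr::arrange(.data$gene_id)
  structure(out, strategy = "highest", class = class(out))
}

#' Match promoter signal to genes: abundance-weighted mean
#'
#' Collapses promoter counts to one row per gene as the abundance-weighted
#' mean over the gene's promoters: promoter `p` gets weight `w_p` equal to its
#' mean count across all samples, and the gene's value in sample `s` is
#' `sum_p w_p x_ps / sum_p w_p`. If every promoter of a gene has weight 0 the
#' unweighted mean is used (all-zero promoters therefore yield 0).
#'
#' @inheritParams match_highest
#' @return A matched-signal tibble: `gene_id` plus one column per sample, with
#'   attribute `strategy = "weighted.mean"`.
#' @export
match_weighted_mean <- function(promoter_counts, genes = NULL) {
  pc <- check_promoter_counts(promoter_counts, genes)
  samples <- setdiff(names(pc), c("gene_id", "tss"))
  pc$.w <- rowMeans(as.matrix(pc[samples]))
  out <- pc |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(d, key) {
      m <- as.matrix(d[samples])
      v <- if (sum(d$.w) > 0) colSums(d$.w * m) / sum(d$.w) else colMeans(m)
      as_tibble(as.list(v))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gene_id)
  structure(out, strategy = "weighted.mean", class = class(out))
}

check_promoter_counts <- function(promoter_counts, genes) {
  if (!all(c("gene_id", "tss") %in% names(promoter_counts))) {
    abort("promoter counts must have gene_id and tss columns")
  }
  if (nrow(promoter_counts) == 0) abort("promoter counts table is empty")
  if (!is.null(genes)) {
    missing <- setdiff(genes, promoter_counts$gene_id)
    if (length(missing) > 0) {
      warn(sprintf("%d gene(s) have no promoter counts and are excluded: %s",
                   length(missing),
                   paste(head(missing, 5), collapse = ", ")))
    }
  }
  promoter_counts
}

#' Spearman correlation matrix across RNA and matched ChIP samples
#'
#' Computes the sample-by-sample Spearman rank correlation over the genes
#' shared by the RNA count table and every matched ChIP signal, on
#' log2(x + 1)-transformed values. Columns are labelled `<layer>.<sample>`
#' (layer = `RNA` or the mark name). A constant column yields `NA`
#' correlations (undefined, deliberately not coerced to 0); the diagonal is 1.
#'
#' @param rna Gene count tibble (`gene_id` + sample columns).
#' @param matched Named list of matched-signal tibbles, one per mark; names
#'   are mark names.
#' @return A symmetric correlation matrix of class `mark_cor`.
#' @export
correlation_matrix <- function(rna, matched) {
  if (is.data.frame(matched)) matched <- list(ChIP = matched)
  if (is.null(names(matched)) || any(!nzchar(names(matched)))) {
    abort("matched must be a named list (names are mark names)")
  }
  layers <- c(list(RNA = rna), matched)
  shared <- Reduce(intersect, lapply(layers, function(x) x$gene_id))
  if (length(shared) < 3) {
    abort(sprintf("only %d gene(s) shared across layers; need at least 3",
                  length(shared)))
  }
  cols <- lapply(names(layers), function(layer) {
    tbl <- layers[[layer]]
    tbl <- tbl[match(shared, tbl$gene_id), ]
    m <- as.matrix(tbl[setdiff(names(tbl), "gene_id")])
    colnames(m) <- paste(layer, colnames(m), sep = ".")
    m
  })
  m <- log2(do.call(cbind, cols) + 1)
  cm <- suppressWarnings(cor(m, method = "spearman"))
  diag(cm) <- 1
  structure(cm, class = c("mark_cor", "matrix", "array"))
}

#' Heatmap of a sample correlation matrix
#'
#' @param object A correlation matrix from [correlation_matrix()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mark_cor <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("sample_a", "sample_b", "rho")
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_a, .data$sample_b,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b",
                                  name = "Spearman rho") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
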