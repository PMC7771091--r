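#' Gene-set enrichment score of a gene list
#'
#' The fraction of a gene set `G` annotated with a term:
#' `f = |G intersect GO_term| / |G|`. A plain fraction in `[0, 1]` — no
#' background model or significance test.
#'
#' @param genes Character vector of gene ids (non-empty; deduplicated
#'   internally).
#' @param gene_sets Tibble with columns `term` and `gene_id` (see
#'   [read_gene_sets()]).
#' @param term A term present in `gene_sets`.
#' @return A single number in `[0, 1]`.
#' @export
enrichment_score <- function(genes, gene_sets, term) {
  genes <- unique(genes)
  if (length(genes) == 0) abort("gene list is empty")
  if (!all(c("term", "gene_id") %in% names(gene_sets))) {
    abort("gene_sets must have columns term and gene_id")
  }
  if (!term %in% gene_sets$term) {
    abort(sprintf("term %s not present in the annotation", term))
  }
  members <- gene_sets$gene_id[gene_sets$term == term]
  length(intersect(genes, members)) / length(genes)
}

#' Cumulative enrichment scores over Pareto fronts
#'
#' For each front `i`, takes the union `G` of all genes in fronts `1..i` and
#' reports `|G|` together with the enrichment score of `G` for the term.
#' Mirrors the cumulative curves used to compare prioritization methods: the
#' first point is the top front(s), later points add one front at a time.
#'
#' @param ranking A `pareto_ranking` from [assign_fronts()].
#' @param gene_sets Tibble with columns `term`, `gene_id`.
#' @param term Term to score.
#' @return Tibble `front`, `n_genes` (strictly increasing), `score`.
#' @export
cumulative_front_scores <- function(ranking, gene_sets, term) {
  if (nrow(ranking) == 0) abort("ranking is empty")
  fronts <- sort(unique(ranking$front))
  purrr::map_dfr(fronts, function(f) {
    g <- ranking$gene_id[ranking$front <= f]
    tibble(front = f, n_genes = length(unique(g)),
           score = enrichment_score(g, gene_sets, term))
  })
}

#' Read a term-to-gene annotation table
#'
#' @param path Two-column TSV (term, gene id), with or without a
#'   `term`/`gene_id` header.
#' @return Tibble with columns `term`, `gene_id`.
#' @export
read_gene_sets <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("term", first, fixed = TRUE)
  tbl <- readr::read_tsv(path, col_names = has_header,
                         show_col_types = FALSE, progress = FALSE)
  if (!has_header) names(tbl) <- c("term", "gene_id")
  tibble(term = as.character(tbl$term), gene_id = as.character(tbl$gene_id))
}

#' Cumulative enrichment curve plot
#'
#' @param scores Output of [cumulative_front_scores()], or several bound
#'   together with a `method` column for comparison.
#' @return A ggplot object.
#' @export
plot_cumulative_enrichment <- function(scores) {
  aes <- if ("method" %in% names(scores)) {
    ggplot2::aes(.data$n_genes, .data$score, color = .data$method)
  } else {
    ggplot2::aes(.data$n_genes, .data$score)
  }
  ggplot2::ggplot(scores, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "genes in first fronts", y = "enrichment score") +
    ggplot2::theme_minimal()
}
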