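#' Pareto dominance between two objective vectors
#'
#' `a` dominates `b` when `a` is at least as good in every objective and
#' strictly better in at least one, with every objective maximized.
#'
#' @param a,b Numeric vectors of equal length.
#' @return `TRUE` or `FALSE`.
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) abort("objective vectors must have equal length")
  all(a >= b) && any(a > b)
}

#' Rank genes into Pareto fronts over signed Z scores
#'
#' Orients each mark's Z column so that larger is always better — Z scores of
#' repressive marks are negated (`alpha = -1`), activating marks kept
#' (`alpha = +1`) — then performs non-dominated sorting: front 1 is the set
#' of genes not dominated by any other gene, front 2 the non-dominated set
#' after removing front 1, and so on. Genes with identical objective vectors
#' share a front. Output is ordered by ascending front, then gene id; the
#' reported Z columns are the raw (unsigned) Z scores.
#'
#' Internally the fronts are found by a dominance-count peeling sort: all
#' pairwise dominance relations are established once with vectorized
#' comparisons, then fronts are peeled by repeatedly collecting the genes
#' whose count of dominators has dropped to zero.
#'
#' @param zt A `zscore_table` from [z_scores()], or a plain tibble
#'   (`gene_id` + one numeric column per mark) combined with `directions`.
#' @param directions Named `"activating"`/`"repressive"` vector per mark;
#'   taken from the `zscore_table` attribute when omitted.
#' @return A `pareto_ranking`: tibble `gene_id`, the Z columns, and `front`
#'   (positive integer, fronts contiguous from 1).
#' @export
assign_fronts <- function(zt, directions = attr(zt, "directions")) {
  prep <- signed_objectives(zt, directions)
  v <- prep$v
  zt <- prep$zt
  n <- nrow(v)

  # dominance counts: dom[i,j] TRUE when point i dominates point j
  ge <- matrix(TRUE, n, n)
  gt <- matrix(FALSE, n, n)
  for (j in seq_len(ncol(v))) {
    d <- outer(v[, j], v[, j], ">=")
    ge <- ge & d
    gt <- gt | outer(v[, j], v[, j], ">")
  }
  dom <- ge & gt
  n_dominators <- colSums(dom)

  front <- integer(n)
  current <- which(n_dominators == 0)
  f <- 1L
  while (length(current) > 0) {
    front[current] <- f
    n_dominators[current] <- NA_integer_
    if (length(current) == 1L) {
      n_dominators <- n_dominators - dom[current, ]
    } else {
      n_dominators <- n_dominators - colSums(dom[current, , drop = FALSE])
    }
    current <- which(!is.na(n_dominators) & n_dominators == 0)
    f <- f + 1L
  }
  finish_ranking(zt, directions, front)
}

#' Brute-force Pareto front oracle
#'
#' Reference implementation by literal peeling: at every round, each
#' surviving gene is tested for dominance against all other survivors
#' directly from the definition, the non-dominated ones form the next front
#' and are removed. Quadratic in the number of genes; used to cross-check
#' [assign_fronts()].
#'
#' @inheritParams assign_fronts
#' @return A `pareto_ranking` identical in contract to [assign_fronts()].
#' @export
brute_force_fronts <- function(zt, directions = attr(zt, "directions")) {
  prep <- signed_objectives(zt, directions)
  v <- prep$v
  zt <- prep$zt
  n <- nrow(v)
  front <- integer(n)
  alive <- seq_len(n)
  f <- 1L
  while (length(alive) > 0) {
    va <- v[alive, , drop = FALSE]
    tva <- t(va)
    k <- ncol(va)
    nondom <- vapply(seq_along(alive), function(i) {
      # a point never dominates itself (no strict component), so no exclusion
      ge_all <- colSums(tva >= va[i, ]) == k
      gt_any <- colSums(tva > va[i, ]) > 0
      !any(ge_all & gt_any)
    }, logical(1))
    front[alive[nondom]] <- f
    alive <- alive[!nondom]
    f <- f + 1L
  }
  finish_ranking(zt, directions, front)
}

# zscore table -> filtered table + matrix of objectives, all maximized
# (repressive-mark columns negated)
signed_objectives <- function(zt, directions) {
  marks <- setdiff(names(zt), c("gene_id", "front"))
  if (nrow(zt) == 0) abort("cannot rank an empty Z-score table")
  if (is.null(directions)) abort("mark directions are required")
  check_directions(directions, marks)
  v <- as.matrix(zt[marks])
  bad <- rowSums(!is.finite(v)) > 0
  if (any(bad)) {
    inform(sprintf("excluding %d gene(s) with missing or non-finite Z scores",
                   sum(bad)))
    if (all(bad)) abort("no gene has a complete Z-score vector")
    zt <- zt[!bad, , drop = FALSE]
    v <- v[!bad, , drop = FALSE]
  }
  alpha <- ifelse(directions[marks] == "activating", 1, -1)
  list(zt = zt, v = sweep(v, 2, alpha, "*"))
}

finish_ranking <- function(zt, directions, front) {
  out <- as_tibble(zt)
  out$front <- front
  out <- dplyr::arrange(out, .data$front, .data$gene_id)
  structure(out, directions = directions,
            class = c("pareto_ranking", class(as_tibble(out))))
}

#' @exportS3Method generics::tidy
tidy.pareto_ranking <- function(x, ...) {
  marks <- setdiff(names(x), c("gene_id", "front"))
  as_tibble(x) |>
    tidyr::pivot_longer(dplyr::all_of(marks), names_to = "mark",
                        values_to = "z") |>
    dplyr::select("gene_id", "front", "mark", "z")
}

#' @exportS3Method generics::glance
glance.pareto_ranking <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_marks = length(setdiff(names(x), c("gene_id", "front"))),
         n_fronts = max(x$front),
         front1_size = sum(x$front == 1L))
}

#' Scatter plot of the first Pareto fronts
#'
#' Plots the signed objectives for two marks, coloring genes by front and
#' graying out genes beyond `max_front`.
#'
#' @param object A `pareto_ranking`.
#' @param marks Two mark names (defaults to the first two Z columns).
#' @param max_front Highest front drawn in color.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pareto_ranking <- function(object, marks = NULL, max_front = 5, ...) {
  zcols <- setdiff(names(object), c("gene_id", "front"))
  if (is.null(marks)) marks <- zcols[seq_len(min(2, length(zcols)))]
  if (length(marks) != 2) abort("autoplot needs exactly two marks")
  df <- as_tibble(object)
  df$front_band <- ifelse(df$front <= max_front,
                          as.character(df$front), paste0(">", max_front))
  ggplot2::ggplot(df, ggplot2::aes(.data[[marks[1]]], .data[[marks[2]]],
                                   color = .data$front_band)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = paste("Z", marks[1]), y = paste("Z", marks[2]),
                  color = "front") +
    ggplot2::theme_minimal()
}
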