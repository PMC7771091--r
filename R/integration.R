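#' Median-of-ratios size factors
#'
#' Per-sample normalization constants for sequencing depth and composition:
#' each gene's geometric mean across samples serves as a pseudo-reference
#' (genes with a zero in any sample are excluded), and a sample's size factor
#' is the median over genes of the ratio of its count to that reference.
#'
#' @param counts Count tibble: `gene_id` plus one numeric column per sample.
#' @param pseudo_reference If no gene is strictly positive in every sample,
#'   `size_factors()` errors unless this is `TRUE`, in which case the
#'   reference is built from the positive counts of each gene and the median
#'   is taken over each sample's positive ratios.
#' @return Tibble `sample_id`, `size_factor` (all positive).
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  m <- counts_matrix(counts)
  if (!pseudo_reference) {
    keep <- rowSums(m > 0) == ncol(m)
    if (!any(keep)) {
      abort(paste("no gene has strictly positive counts in every sample;",
                  "rerun with pseudo_reference = TRUE"))
    }
    mk <- m[keep, , drop = FALSE]
    ref <- exp(rowMeans(log(mk)))
    sf <- apply(mk, 2, function(cnt) median(cnt / ref))
  } else {
    logref <- apply(m, 1, function(x) mean(log(x[x > 0])))
    sf <- vapply(seq_len(ncol(m)), function(j) {
      ok <- m[, j] > 0 & is.finite(logref)
      median(m[ok, j] / exp(logref[ok]))
    }, numeric(1))
    names(sf) <- colnames(m)
  }
  tibble(sample_id = names(sf), size_factor = unname(sf))
}

#' Per-gene log2 fold change and standard error between two conditions
#'
#' Normalizes counts by median-of-ratios size factors, then for each gene
#' computes `logfc = log2((mean_B + pc) / (mean_A + pc))` on normalized
#' counts, condition B over condition A, with pseudocount `pc`. Genes that
#' are all-zero in both conditions are excluded. Two standard-error
#' estimators are offered, both floored at `se_min` so downstream Z scores
#' stay finite:
#'
#' * `"model"` (default): a delta-method negative-binomial standard error,
#'   `se = (1/ln 2) * sqrt(sum_c (1/(mu_c + pc) + alpha) / n_c)` over the two
#'   conditions, with one dispersion `alpha` pooled across all genes (median
#'   method-of-moments estimate, floored at 0). Because it depends on the
#'   data only through the condition means and a global dispersion, it is
#'   stable at few replicates — the same property that makes model-based
#'   Wald standard errors the norm for count data. With one replicate per
#'   condition `alpha` is not estimable and 0 (Poisson) is used, with a
#'   message.
#' * `"welch"`: the empirical Welch form `sqrt(var_A/n_A + var_B/n_B)` of the
#'   per-condition variances of `log2(n + pc)`. With one (or zero) replicates
#'   in either condition no variance is estimable and every gene gets
#'   `se = se_min` (reported prominently). With two replicates this estimate
#'   is itself very noisy, which propagates into the Z scores.
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param design Tibble `sample_id`, `condition` covering the count columns.
#' @param condition_a,condition_b The two condition labels; the fold change is
#'   B over A.
#' @param pseudocount Added to normalized means (and inside the log2 for the
#'   variance); default 0.5, the usual half-count continuity correction.
#' @param se_min Lower floor on the standard error (default 0.05).
#' @param se_method `"model"` or `"welch"` (see above).
#' @param size_factors Optional precomputed size factors (as returned by
#'   [size_factors()]); computed from `counts` when `NULL`.
#' @return Tibble `gene_id`, `base_mean` (mean normalized count), `logfc`,
#'   `se`.
#' @export
logfc_se <- function(counts, design, condition_a, condition_b,
                     pseudocount = 0.5, se_min = 0.05,
                     se_method = c("model", "welch"), size_factors = NULL) {
  se_method <- match.arg(se_method)
  assert_two_conditions(design)
  if (!all(c(condition_a, condition_b) %in% design$condition)) {
    abort(sprintf("unknown condition label(s): %s",
                  paste(setdiff(c(condition_a, condition_b),
                                design$condition), collapse = ", ")))
  }
  m <- counts_matrix(counts)
  cond <- setNames(design$condition, design$sample_id)[colnames(m)]
  if (anyNA(cond)) abort("every sample column must appear in the design")
  a_cols <- which(cond == condition_a)
  b_cols <- which(cond == condition_b)
  if (length(a_cols) == 0 || length(b_cols) == 0) {
    abort("each condition needs at least one sample")
  }

  if (is.null(size_factors)) size_factors <- size_factors(counts)
  sf <- setNames(size_factors$size_factor, size_factors$sample_id)[colnames(m)]
  n <- sweep(m, 2, sf, "/")

  keep <- rowSums(m[, c(a_cols, b_cols), drop = FALSE]) > 0
  n <- n[keep, , drop = FALSE]

  mean_a <- rowMeans(n[, a_cols, drop = FALSE])
  mean_b <- rowMeans(n[, b_cols, drop = FALSE])
  logfc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))

  few_reps <- length(a_cols) < 2 || length(b_cols) < 2
  if (se_method == "model") {
    alpha <- if (few_reps) {
      inform("logfc_se: a condition has <= 1 replicate; dispersion not estimable, using alpha = 0 (Poisson)")
      0
    } else {
      pooled_dispersion(n, list(a_cols, b_cols))
    }
    se <- (1 / log(2)) *
      sqrt((1 / (mean_a + pseudocount) + alpha) / length(a_cols) +
             (1 / (mean_b + pseudocount) + alpha) / length(b_cols))
    se <- pmax(se, se_min)
  } else if (few_reps) {
    inform(paste("logfc_se: a condition has <= 1 replicate;",
                 sprintf("every standard error set to the floor se_min = %g", se_min)))
    se <- rep(se_min, nrow(n))
  } else {
    la <- log2(n[, a_cols, drop = FALSE] + pseudocount)
    lb <- log2(n[, b_cols, drop = FALSE] + pseudocount)
    va <- apply(la, 1, var)
    vb <- apply(lb, 1, var)
    se <- pmax(sqrt(va / length(a_cols) + vb / length(b_cols)), se_min)
  }

  tibble(gene_id = rownames(n), base_mean = rowMeans(n),
         logfc = unname(logfc), se = unname(se))
}

# global NB dispersion: median over genes/conditions of the method-of-moments
# estimate (s^2 - mu)/mu^2 on normalized counts, floored at 0
pooled_dispersion <- function(n, cond_cols) {
  est <- unlist(lapply(cond_cols, function(cols) {
    mu <- rowMeans(n[, cols, drop = FALSE])
    s2 <- apply(n[, cols, drop = FALSE], 1, var)
    ifelse(mu > 0, (s2 - mu) / mu^2, NA_real_)
  }))
  max(0, median(est, na.rm = TRUE))
}

#' Shrink log fold changes toward zero
#'
#' Empirical multiplicative shrinkage: with prior variance `tau^2`, each
#' gene's fold change becomes `logfc * tau^2 / (tau^2 + se^2)`, so precise
#' estimates (small `se`) are nearly untouched while noisy ones are pulled
#' toward zero. With `prior_scale = "auto"`, `tau^2` is the method-of-moments
#' estimate `max(0, var(logfc) - mean(se^2))`; if that is 0 the data carry no
#' signal beyond noise and every fold change is shrunk to 0 (with a warning).
#' Shrinkage never changes a fold change's sign and never increases its
#' magnitude.
#'
#' @param diff Tibble from [logfc_se()] (`gene_id`, `logfc`, `se`, ...).
#' @param prior_scale `"auto"` or a positive number taken as `tau`.
#' @return `diff` with `logfc` replaced by its shrunken value; `se` unchanged.
#' @export
shrink_logfc <- function(diff, prior_scale = "auto") {
  if (any(diff$se <= 0)) abort("shrink_logfc requires se > 0 for every gene")
  if (identical(prior_scale, "auto")) {
    tau2 <- max(0, var(diff$logfc) - mean(diff$se^2))
  } else {
    if (!is.numeric(prior_scale) || prior_scale <= 0) {
      abort("prior_scale must be \"auto\" or a positive number")
    }
    tau2 <- prior_scale^2
  }
  if (tau2 == 0) {
    warn("estimated prior variance is 0; all log fold changes shrunk to 0")
  }
  dplyr::mutate(diff, logfc = .data$logfc * tau2 / (tau2 + .data$se^2))
}

#' Combine RNA and ChIP fold changes into per-gene per-mark Z scores
#'
#' For gene `g` and mark `h`, `Z_{g,h}` is the product of the standardized
#' log2 fold changes of the two layers:
#' `(logfc_RNA / se_RNA) * (logfc_ChIP / se_ChIP)`. Z is large and positive
#' when expression and the mark change strongly in the same direction between
#' conditions, and negative when they move in opposite directions. Genes
#' absent from any layer are dropped (reported via a message).
#'
#' @param rna Differential result for the RNA layer ([logfc_se()] output).
#' @param chips Named list of differential results, one per mark.
#' @param directions Named character vector over the same marks, each
#'   `"activating"` or `"repressive"`; stored on the result for
#'   [assign_fronts()].
#' @return A `zscore_table`: tibble `gene_id` plus one Z column per mark, with
#'   attribute `directions`.
#' @export
z_scores <- function(rna, chips, directions) {
  if (is.null(names(chips)) || any(!nzchar(names(chips)))) {
    abort("chips must be a named list (names are mark names)")
  }
  check_directions(directions, names(chips))
  layers <- c(list(rna), chips)
  shared <- Reduce(intersect, lapply(layers, function(x) x$gene_id))
  if (length(shared) == 0) abort("no gene is present in every layer")
  n_all <- length(unique(unlist(lapply(layers, function(x) x$gene_id))))
  if (n_all > length(shared)) {
    inform(sprintf("z_scores: dropped %d gene(s) missing from at least one layer",
                   n_all - length(shared)))
  }
  r <- rna[match(shared, rna$gene_id), ]
  t_rna <- r$logfc / r$se
  out <- tibble(gene_id = shared)
  for (mk in names(chips)) {
    ch <- chips[[mk]][match(shared, chips[[mk]]$gene_id), ]
    out[[mk]] <- t_rna * ch$logfc / ch$se
  }
  new_zscore_table(out, directions[names(chips)])
}

new_zscore_table <- function(tbl, directions) {
  structure(tbl, directions = directions,
            class = c("zscore_table", class(tbl)))
}

check_directions <- function(directions, marks) {
  if (is.null(names(directions)) || !all(marks %in% names(directions))) {
    abort("directions must be named and cover every mark")
  }
  if (!all(directions %in% c("activating", "repressive"))) {
    abort("directions must be \"activating\" or \"repressive\"")
  }
  invisible(directions)
}
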