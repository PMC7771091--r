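#' Build a pipeline run configuration
#'
#' Collects everything a full run needs: annotation, the sample table (one
#' row per RNA or ChIP sample with its file path), the mark panel, and the
#' tuning parameters of the matching and integration stages. Validation
#' happens up front so failures surface before any computation.
#'
#' @param annotation Path to the GTF annotation.
#' @param samples Tibble with columns `sample_id`, `condition`, `layer`
#'   (`"RNA"` or a mark name) and `path` (abundance TSV for RNA; SAM/BAM or
#'   region-count TSV for ChIP; for count TSVs one shared path per mark is
#'   allowed).
#' @param marks Mark panel tibble (`mark`, `direction`, `region_mode`);
#'   defaults to [default_marks()] restricted to the marks present in
#'   `samples`.
#' @param condition_a,condition_b Condition labels; fold changes are B over A.
#'   Default: first and second condition in `samples` order of appearance.
#' @param strategy Promoter matching strategy, `"highest"` or
#'   `"weighted.mean"`.
#' @param promoter_size,pseudocount,se_min,se_method,min_mapq,exclude_duplicates,shrink
#'   Stage parameters (see [derive_promoters()], [logfc_se()],
#'   [shrink_logfc()], [count_reads()]).
#' @param tx2gene Optional transcript-to-gene TSV path; derived from the GTF
#'   when `NULL`.
#' @param out_dir Output directory for stage TSVs and the run manifest.
#' @return A validated `run_config` list.
#' @export
run_config <- function(annotation, samples, marks = NULL,
                       condition_a = NULL, condition_b = NULL,
                       strategy = c("highest", "weighted.mean"),
                       promoter_size = 5000, pseudocount = 0.5,
                       se_min = 0.05, se_method = c("model", "welch"),
                       min_mapq = 0,
                       exclude_duplicates = FALSE, shrink = TRUE,
                       tx2gene = NULL, out_dir = tempfile("markfront_run")) {
  strategy <- match.arg(strategy)
  se_method <- match.arg(se_method)
  need <- c("sample_id", "condition", "layer", "path")
  if (!all(need %in% names(samples))) {
    abort(sprintf("samples table must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  conds <- unique(samples$condition)
  if (length(conds) != 2) abort("samples must span exactly two conditions")
  if (is.null(condition_a)) condition_a <- conds[1]
  if (is.null(condition_b)) condition_b <- conds[2]
  if (!all(c(condition_a, condition_b) %in% conds)) {
    abort("condition_a/condition_b must match the sample table")
  }
  sample_marks <- setdiff(unique(samples$layer), "RNA")
  if (is.null(marks)) {
    marks <- dplyr::filter(default_marks(), .data$mark %in% sample_marks)
  }
  if (!all(sample_marks %in% marks$mark)) {
    abort(sprintf("mark(s) without direction/region_mode: %s",
                  paste(setdiff(sample_marks, marks$mark), collapse = ", ")))
  }
  if (!any(samples$layer == "RNA")) abort("samples must include RNA samples")
  for (mk in sample_marks) {
    by_cond <- table(samples$condition[samples$layer == mk])
    if (length(by_cond) < 2 || any(by_cond < 1)) {
      abort(sprintf("mark %s needs at least one sample per condition", mk))
    }
  }
  missing_files <- unique(samples$path[!file.exists(samples$path)])
  if (length(missing_files) > 0) {
    abort(sprintf("sample file(s) not found: %s",
                  paste(head(missing_files, 5), collapse = ", ")))
  }
  if (!file.exists(annotation)) {
    abort(sprintf("annotation not found: %s", annotation))
  }
  structure(list(
    annotation = annotation, samples = as_tibble(samples),
    marks = dplyr::filter(marks, .data$mark %in% sample_marks),
    condition_a = condition_a, condition_b = condition_b,
    strategy = strategy, promoter_size = promoter_size,
    pseudocount = pseudocount, se_min = se_min, se_method = se_method,
    min_mapq = min_mapq,
    exclude_duplicates = exclude_duplicates, shrink = shrink,
    tx2gene = tx2gene, out_dir = out_dir
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The YAML mirrors [run_config()]'s arguments; `samples` is a list of
#' records or a path to a design TSV (`sample_id`, `condition`, `layer`,
#' `path`). Relative paths are resolved against the YAML's directory.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  samples <- if (is.character(y$samples)) {
    readr::read_tsv(resolve(y$samples), show_col_types = FALSE, progress = FALSE)
  } else {
    dplyr::bind_rows(lapply(y$samples, as_tibble))
  }
  samples$path <- resolve(samples$path)
  args <- y[setdiff(names(y), c("annotation", "samples", "marks"))]
  args$annotation <- resolve(y$annotation)
  args$samples <- samples
  if (!is.null(y$marks)) args$marks <- dplyr::bind_rows(lapply(y$marks, as_tibble))
  do.call(run_config, args)
}

#' Run the matching stage
#'
#' Loads the annotation, counts ChIP reads in promoter windows (or gene
#' bodies, per the mark's region mode), collapses promoter counts to gene
#' level with the configured strategy, aggregates RNA abundances to gene
#' counts, and computes the Spearman correlation QC matrix. Writes
#' `rna_counts.tsv`, `matched_<mark>.tsv`, `correlation.tsv` and the run
#' manifest to `cfg$out_dir`.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, a list with `rna_counts`, `matched`, `correlation`.
#' @export
run_match <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  genes <- load_annotation(cfg$annotation)
  promoters <- derive_promoters(genes, cfg$promoter_size)
  bodies <- gene_bodies(genes)

  rna_samples <- dplyr::filter(cfg$samples, .data$layer == "RNA")
  abundances <- purrr::map2(rna_samples$path, rna_samples$sample_id,
                            read_abundance)
  t2g <- if (is.null(cfg$tx2gene)) tx2gene_from_annotation(genes) else
    read_tx2gene(cfg$tx2gene)
  rna_counts <- aggregate_to_genes(abundances, t2g)

  matched <- list()
  for (i in seq_len(nrow(cfg$marks))) {
    mk <- cfg$marks$mark[i]
    mode_i <- cfg$marks$region_mode[i]
    rows <- dplyr::filter(cfg$samples, .data$layer == mk)
    counts <- chip_counts_for(rows, if (mode_i == "promoter") promoters else
      bodies, cfg)
    matched[[mk]] <- if (mode_i == "body") {
      structure(dplyr::arrange(counts, .data$gene_id), strategy = "body",
                class = class(counts))
    } else if (cfg$strategy == "highest") {
      match_highest(counts, genes = genes$gene_id)
    } else {
      match_weighted_mean(counts, genes = genes$gene_id)
    }
  }
  correlation <- correlation_matrix(rna_counts, matched)

  readr::write_tsv(rna_counts, file.path(cfg$out_dir, "rna_counts.tsv"),
                   progress = FALSE)
  for (mk in names(matched)) {
    readr::write_tsv(as_tibble(matched[[mk]]),
                     file.path(cfg$out_dir, paste0("matched_", mk, ".tsv")),
                     progress = FALSE)
  }
  cm <- as.data.frame(unclass(correlation))
  readr::write_tsv(dplyr::bind_cols(tibble(sample = rownames(cm)), cm),
                   file.path(cfg$out_dir, "correlation.tsv"), progress = FALSE)
  write_manifest(cfg, stage = "match")
  invisible(list(rna_counts = rna_counts, matched = matched,
                 correlation = correlation))
}

chip_counts_for <- function(rows, regions, cfg) {
  is_tsv <- grepl("\\.tsv$", rows$path, ignore.case = TRUE)
  if (all(is_tsv)) {
    tbl <- read_region_counts(rows$path[1])
    missing <- setdiff(rows$sample_id, names(tbl))
    if (length(missing) > 0) {
      abort(sprintf("count table %s lacks sample column(s): %s", rows$path[1],
                    paste(missing, collapse = ", ")))
    }
    keys <- intersect(c("gene_id", "tss"), names(tbl))
    tbl[c(keys, rows$sample_id)]
  } else {
    count_reads_samples(setNames(rows$path, rows$sample_id), regions,
                        min_mapq = cfg$min_mapq,
                        exclude_duplicates = cfg$exclude_duplicates)
  }
}

#' Run the integration stage
#'
#' Reads the matching stage's outputs from `cfg$out_dir`, computes per-layer
#' log2 fold changes with standard errors (median-of-ratios normalized,
#' optionally shrunk), and combines them into the gene-by-mark Z-score table.
#' Writes `diff_<layer>.tsv` and `zscores.tsv`.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, a list with `diff` (per layer) and `z` (zscore_table).
#' @export
run_integrate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  rc_path <- file.path(cfg$out_dir, "rna_counts.tsv")
  if (!file.exists(rc_path)) {
    abort("matching outputs not found in out_dir; run run_match(cfg) first")
  }
  design <- dplyr::select(cfg$samples, "sample_id", "condition")
  diff_one <- function(counts) {
    d <- logfc_se(counts, design, cfg$condition_a, cfg$condition_b,
                  pseudocount = cfg$pseudocount, se_min = cfg$se_min,
                  se_method = cfg$se_method)
    if (cfg$shrink) shrink_logfc(d) else d
  }
  rna_counts <- readr::read_tsv(rc_path, show_col_types = FALSE,
                                progress = FALSE)
  diffs <- list(RNA = diff_one(rna_counts))
  for (mk in cfg$marks$mark) {
    matched <- readr::read_tsv(file.path(cfg$out_dir,
                                         paste0("matched_", mk, ".tsv")),
                               show_col_types = FALSE, progress = FALSE)
    # matched signal is real-valued; the count contract needs integers
    m <- dplyr::mutate(matched, dplyr::across(-"gene_id", round_half_away))
    diffs[[mk]] <- diff_one(m)
  }
  directions <- setNames(cfg$marks$direction, cfg$marks$mark)
  z <- z_scores(diffs$RNA, diffs[cfg$marks$mark], directions)
  for (layer in names(diffs)) {
    readr::write_tsv(diffs[[layer]],
                     file.path(cfg$out_dir, paste0("diff_", layer, ".tsv")),
                     progress = FALSE)
  }
  readr::write_tsv(as_tibble(z), file.path(cfg$out_dir, "zscores.tsv"),
                   progress = FALSE)
  write_manifest(cfg, stage = "integrate")
  invisible(list(diff = diffs, z = z))
}

#' Run the prioritization stage
#'
#' Reads `zscores.tsv` from `cfg$out_dir`, ranks genes into Pareto fronts
#' over the signed Z scores and writes `ranking.tsv` sorted by ascending
#' front.
#'
#' @param cfg A `run_config`.
#' @param max_front Optional: keep only fronts up to this index in the output.
#' @return Invisibly, the `pareto_ranking`.
#' @export
run_prioritize <- function(cfg, max_front = Inf) {
  stopifnot(inherits(cfg, "run_config"))
  z_path <- file.path(cfg$out_dir, "zscores.tsv")
  if (!file.exists(z_path)) {
    abort("zscores.tsv not found in out_dir; run run_integrate(cfg) first")
  }
  z <- readr::read_tsv(z_path, show_col_types = FALSE, progress = FALSE)
  directions <- setNames(cfg$marks$direction, cfg$marks$mark)
  ranking <- assign_fronts(z, directions)
  out <- dplyr::filter(as_tibble(ranking), .data$front <= max_front)
  readr::write_tsv(out, file.path(cfg$out_dir, "ranking.tsv"),
                   progress = FALSE)
  write_manifest(cfg, stage = "prioritize")
  invisible(ranking)
}

#' Run the complete pipeline
#'
#' [run_match()], [run_integrate()] and [run_prioritize()] in sequence.
#'
#' @param cfg A `run_config`.
#' @inheritParams run_prioritize
#' @return Invisibly, a list with all stage results.
#' @export
run_all <- function(cfg, max_front = Inf) {
  matched <- run_match(cfg)
  integrated <- run_integrate(cfg)
  ranking <- run_prioritize(cfg, max_front = max_front)
  invisible(list(match = matched, integrate = integrated, ranking = ranking))
}

write_manifest <- function(cfg, stage) {
  manifest <- list(
    package = "markfront",
    version = as.character(utils::packageVersion("markfront")),
    stage = stage,
    parameters = cfg[c("condition_a", "condition_b", "strategy",
                       "promoter_size", "pseudocount", "se_min", "se_method", "min_mapq",
                       "exclude_duplicates", "shrink")],
    marks = cfg$marks,
    samples = dplyr::select(cfg$samples, "sample_id", "condition", "layer")
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
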