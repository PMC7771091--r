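#' Default histone-mark panel for simulations
#'
#' Four commonly profiled marks: H3K4me3 and H3K27ac (activating, counted in
#' promoter windows), H3K27me3 (repressive, promoter windows) and H3K36me3
#' (activating, counted over the gene body).
#'
#' @return Tibble `mark`, `direction`, `region_mode`.
#' @export
default_marks <- function() {
  tibble(
    mark = c("H3K4me3", "H3K27ac", "H3K27me3", "H3K36me3"),
    direction = c("activating", "activating", "repressive", "activating"),
    region_mode = c("promoter", "promoter", "promoter", "body")
  )
}

#' Configuration for a synthetic two-condition experiment
#'
#' Defines a replicated two-condition design with negative-binomial gene
#' counts and matched promoter/gene-body ChIP counts, containing planted
#' genes whose expression and mark changes are concordant (epigenome agrees
#' with transcriptome), discordant (epigenome contradicts it), or null.
#' Planted sets are disjoint. All randomness derives from `seed`.
#'
#' @param n_genes Number of genes (default 500).
#' @param n_promoters Integer range (min, max) of distinct TSSs per gene.
#' @param replicates Replicates per condition, for RNA and for every mark.
#' @param marks Mark panel tibble (`mark`, `direction`, `region_mode`).
#' @param dispersion Negative-binomial size parameter (default 10).
#' @param n_concordant_up,n_concordant_down,n_discordant Planted gene counts.
#' @param effect Planted |log2 fold change| (default 2).
#' @param rna_meanlog,rna_sdlog Lognormal baseline of RNA gene means.
#' @param chip_meanlog,chip_sdlog Lognormal baseline of per-promoter ChIP
#'   means (gene bodies get a proportionally larger baseline).
#' @param chip_rna_coupling Correlation (0 to 1) between a gene's baseline
#'   log expression and its baseline log mark abundance — positive for
#'   activating marks, negated for repressive ones. Emulates the
#'   expression/mark abundance relationship that sample-correlation QC
#'   detects in real data.
#' @param promoter_size Promoter window width (default 5000).
#' @param read_length Synthesized read length for SAM output.
#' @param seed Integer seed; same seed, same experiment.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 500, n_promoters = c(1, 3), replicates = 2,
                       marks = default_marks(), dispersion = 10,
                       n_concordant_up = 10, n_concordant_down = 10,
                       n_discordant = 10, effect = 2,
                       rna_meanlog = log(200), rna_sdlog = 1,
                       chip_meanlog = log(100), chip_sdlog = 0.7,
                       chip_rna_coupling = 0.5,
                       promoter_size = 5000, read_length = 50, seed = 1) {
  planted <- n_concordant_up + n_concordant_down + n_discordant
  if (n_genes <= 0 || replicates <= 0) abort("sizes must be positive")
  if (planted > n_genes) {
    abort("planted sets exceed the number of genes (they must be disjoint)")
  }
  if (length(n_promoters) != 2 || n_promoters[1] < 1 ||
      n_promoters[2] < n_promoters[1]) {
    abort("n_promoters must be an increasing positive (min, max) pair")
  }
  structure(list(
    n_genes = n_genes, n_promoters = n_promoters, replicates = replicates,
    marks = marks, dispersion = dispersion,
    n_concordant_up = n_concordant_up, n_concordant_down = n_concordant_down,
    n_discordant = n_discordant, effect = effect,
    rna_meanlog = rna_meanlog, rna_sdlog = rna_sdlog,
    chip_meanlog = chip_meanlog, chip_sdlog = chip_sdlog,
    chip_rna_coupling = chip_rna_coupling,
    promoter_size = promoter_size, read_length = read_length, seed = seed
  ), class = "sim_config")
}

#' Simulate a two-condition RNA + ChIP experiment in memory
#'
#' Draws the gene geometry (one chromosome, genes spaced so that all promoter
#' windows are pairwise disjoint), the truth table of planted classes, RNA
#' gene counts, transcript-level abundances that aggregate back to them, and
#' per-mark ChIP counts for promoter windows or gene bodies. Condition B
#' means are the condition A means times `2^(sign * effect)`, with the sign
#' per class and mark direction: concordant-up genes have RNA up, activating
#' marks up, repressive marks down; concordant-down the reverse; discordant
#' genes have RNA up but every mark moved the opposite way.
#'
#' @param cfg A [sim_config()].
#' @return List with `genes` (gene models), `promoters`, `bodies`,
#'   `rna_counts`, `rna_design`, `abundances` (per-sample transcript tables),
#'   `chip_counts` (named list per mark), `chip_design`, `truth`.
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, simulate_counts_impl(cfg))
}

simulate_counts_impl <- function(cfg) {
  n <- cfg$n_genes
  ids <- sprintf("gene%04d", seq_len(n))

  # geometry: TSSs spaced beyond the window width keeps all windows disjoint
  spacing <- cfg$promoter_size + 1000
  n_tss <- sample(seq(cfg$n_promoters[1], cfg$n_promoters[2]), n, replace = TRUE)
  body_len <- (n_tss - 1) * spacing + 4000
  gap <- cfg$promoter_size + 20000
  gene_start <- cumsum(c(cfg$promoter_size, head(body_len, -1) + gap))
  strand <- sample(c("+", "-"), n, replace = TRUE)

  genes <- tibble(
    gene_id = ids, chrom = "chr1", strand = strand,
    start = gene_start, end = gene_start + body_len,
    tss = purrr::pmap(list(gene_start, body_len, n_tss, strand),
                      function(s, l, k, st) {
                        if (st == "+") s + (seq_len(k) - 1) * spacing
                        else (s + l) - (seq_len(k) - 1) * spacing
                      }),
    transcript_ids = purrr::map2(ids, n_tss,
                                 function(g, k) paste0(g, ".t", seq_len(k)))
  )
  genes$tss <- purrr::map(genes$tss, function(x) sort(unique(x)))

  # truth: planted classes with per-layer fold-change signs
  classes <- rep("null", n)
  planted <- sample(n, cfg$n_concordant_up + cfg$n_concordant_down +
                       cfg$n_discordant)
  classes[planted] <- rep(c("concordant_up", "concordant_down", "discordant"),
                          times = c(cfg$n_concordant_up, cfg$n_concordant_down,
                                    cfg$n_discordant))
  rna_sign <- dplyr::case_match(classes, "concordant_up" ~ 1,
                                "concordant_down" ~ -1, "discordant" ~ 1,
                                "null" ~ 0)
  chip_sign_for <- function(direction) {
    base <- dplyr::case_match(classes, "concordant_up" ~ 1,
                              "concordant_down" ~ -1, "discordant" ~ -1,
                              "null" ~ 0)
    if (direction == "activating") base else -base
  }
  truth <- tibble(gene_id = ids, class = classes,
                  rna_log2fc = rna_sign * cfg$effect)

  # RNA counts and transcript-level abundances
  reps <- cfg$replicates
  rna_samples <- c(paste0("rna_a", seq_len(reps)), paste0("rna_b", seq_len(reps)))
  rna_design <- tibble(sample_id = rna_samples,
                       condition = rep(c("A", "B"), each = reps))
  mu <- rlnorm(n, cfg$rna_meanlog, cfg$rna_sdlog)
  rna_counts <- tibble(gene_id = ids)
  for (i in seq_along(rna_samples)) {
    m_s <- if (rna_design$condition[i] == "B") mu * 2^(rna_sign * cfg$effect) else mu
    rna_counts[[rna_samples[i]]] <- rnbinom(n, mu = m_s, size = cfg$dispersion)
  }

  tx_prop <- purrr::map(n_tss, function(k) {
    p <- rexp(k)
    p / sum(p)
  })
  tx_len <- purrr::map2(body_len, n_tss, function(l, k) {
    l - (seq_len(k) - 1) * spacing
  })
  abundances <- purrr::map(rna_samples, function(s) {
    tibble(
      target_id = unlist(genes$transcript_ids),
      length = unlist(tx_len),
      eff_length = pmax(unlist(tx_len) - 150, 10),
      est_counts = unlist(purrr::map2(rna_counts[[s]], tx_prop, `*`))
    ) |>
      dplyr::mutate(tpm = {
        r <- .data$est_counts / .data$eff_length
        1e6 * r / sum(r)
      })
  })
  names(abundances) <- rna_samples

  # ChIP counts per mark
  promoters <- derive_promoters(genes, cfg$promoter_size)
  bodies <- gene_bodies(genes)
  chip_counts <- list()
  chip_design <- list()
  for (i in seq_len(nrow(cfg$marks))) {
    mk <- cfg$marks$mark[i]
    dir_i <- cfg$marks$direction[i]
    mode_i <- cfg$marks$region_mode[i]
    samples <- c(paste0(mk, "_a", seq_len(reps)), paste0(mk, "_b", seq_len(reps)))
    des <- tibble(sample_id = samples, condition = rep(c("A", "B"), each = reps),
                  mark = mk)
    sgn <- chip_sign_for(dir_i)
    # baseline mark abundance tracks baseline expression: positively for
    # activating marks, negatively for repressive ones (what the Spearman
    # QC matrix is meant to pick up)
    expr_z <- (log(mu) - cfg$rna_meanlog) / cfg$rna_sdlog
    couple <- cfg$chip_rna_coupling * cfg$chip_sdlog *
      (if (dir_i == "activating") expr_z else -expr_z)
    resid_sd <- cfg$chip_sdlog * sqrt(max(0, 1 - cfg$chip_rna_coupling^2))
    if (mode_i == "promoter") {
      tbl <- promoters[c("gene_id", "tss")]
      idx <- match(tbl$gene_id, ids)
      lam <- rlnorm(nrow(tbl), cfg$chip_meanlog + couple[idx], resid_sd)
      gene_sign <- sgn[idx]
    } else {
      tbl <- bodies["gene_id"]
      lam <- rlnorm(nrow(tbl), cfg$chip_meanlog + log(4) + couple, resid_sd)
      gene_sign <- sgn
    }
    for (j in seq_along(samples)) {
      m_s <- if (des$condition[j] == "B") lam * 2^(gene_sign * cfg$effect) else lam
      tbl[[samples[j]]] <- rnbinom(length(lam), mu = m_s, size = cfg$dispersion)
    }
    truth[[paste0(mk, "_log2fc")]] <- sgn * cfg$effect
    chip_counts[[mk]] <- tbl
    chip_design[[mk]] <- des
  }

  list(genes = genes, promoters = promoters, bodies = bodies,
       rna_counts = rna_counts, rna_design = rna_design,
       abundances = abundances, chip_counts = chip_counts,
       chip_design = dplyr::bind_rows(chip_design), truth = truth)
}

#' Write a synthetic experiment to disk in standard formats
#'
#' Materializes a [simulate_counts()] draw as the files the pipeline
#' consumes: a GTF annotation, one kallisto-style abundance TSV per RNA
#' sample, per-mark ChIP data either as SAM alignment files whose reads
#' realize the simulated region counts exactly (reads are placed uniformly
#' inside each disjoint target window) or as region count TSVs, plus the
#' design table and the truth table.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param write_sam Emit SAM files per mark/sample instead of count TSVs.
#' @return List with the in-memory `bundle` and all file `paths`.
#' @export
simulate_experiment <- function(cfg, dir = tempfile("simexp"),
                                write_sam = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  bundle <- simulate_counts(cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(dir = dir)

  paths$gtf <- file.path(dir, "annotation.gtf")
  write_gtf(bundle$genes, paths$gtf)

  paths$abundance <- character(0)
  for (s in names(bundle$abundances)) {
    p <- file.path(dir, paste0("abundance_", s, ".tsv"))
    readr::write_tsv(bundle$abundances[[s]], p, progress = FALSE)
    paths$abundance[s] <- p
  }

  marks <- cfg$marks
  paths$chip <- list()
  if (write_sam) {
    chrom_len <- max(bundle$genes$end) + cfg$promoter_size + 1000
    for (i in seq_len(nrow(marks))) {
      mk <- marks$mark[i]
      regions <- if (marks$region_mode[i] == "promoter") {
        dplyr::left_join(bundle$chip_counts[[mk]][c("gene_id", "tss")],
                         bundle$promoters, by = c("gene_id", "tss"))
      } else {
        dplyr::left_join(bundle$chip_counts[[mk]]["gene_id"], bundle$bodies,
                         by = "gene_id")
      }
      samples <- setdiff(names(bundle$chip_counts[[mk]]), c("gene_id", "tss"))
      for (s in samples) {
        p <- file.path(dir, paste0(mk, "_", s, ".sam"))
        withr::with_seed(cfg$seed + 7919L * match(s, samples) + 104729L * i,
                         write_sam_reads(regions, bundle$chip_counts[[mk]][[s]],
                                         chrom_len, cfg$read_length, p))
        paths$chip[[mk]][s] <- p
      }
    }
  } else {
    for (mk in marks$mark) {
      p <- file.path(dir, paste0("chip_", mk, "_counts.tsv"))
      readr::write_tsv(bundle$chip_counts[[mk]], p, progress = FALSE)
      paths$chip[[mk]] <- p
    }
  }

  paths$truth <- file.path(dir, "truth.tsv")
  readr::write_tsv(bundle$truth, paths$truth, progress = FALSE)
  paths$design <- file.path(dir, "design.tsv")
  design <- dplyr::bind_rows(
    dplyr::mutate(bundle$rna_design, layer = "RNA"),
    dplyr::transmute(bundle$chip_design, .data$sample_id, .data$condition,
                     layer = .data$mark)
  )
  readr::write_tsv(design, paths$design, progress = FALSE)

  list(bundle = bundle, paths = paths)
}

# gene models -> minimal GTF (one transcript feature per transcript)
write_gtf <- function(genes, path) {
  rows <- genes |>
    dplyr::select("gene_id", "chrom", "strand", "start", "end",
                  "tss", "transcript_ids") |>
    tidyr::unnest(c("tss", "transcript_ids"))
  # transcript span: TSS-anchored on the gene's strand
  tstart <- ifelse(rows$strand == "+", rows$tss, rows$start)
  tend <- ifelse(rows$strand == "+", rows$end, rows$tss)
  lines <- sprintf('%s\tmarkfront_sim\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
                   rows$chrom, as.integer(tstart), as.integer(tend),
                   rows$strand, rows$gene_id, rows$transcript_ids)
  writeLines(lines, path)
  invisible(path)
}

# place `counts[i]` reads uniformly, fully inside region i; write sorted SAM
write_sam_reads <- function(regions, counts, chrom_len, read_length, path) {
  stopifnot(nrow(regions) == length(counts))
  pos_list <- purrr::map(seq_len(nrow(regions)), function(i) {
    k <- counts[i]
    if (k == 0) return(integer(0))
    lo <- regions$start[i]                       # 0-based window start
    hi <- regions$end[i] - read_length           # last admissible 0-based start
    lo + sample.int(hi - lo + 1L, k, replace = TRUE) - 1L
  })
  pos0 <- unlist(pos_list)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", unique(regions$chrom),
                      as.integer(chrom_len)))
  if (length(pos0) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  pos0 <- sort(pos0)
  records <- sprintf("read%07d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                     seq_along(pos0), regions$chrom[1], pos0 + 1L, read_length)
  writeLines(c(header, records), path)
  invisible(path)
}
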