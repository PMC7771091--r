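counts_tbl <- function(m) {
  tibble::tibble(gene_id = sprintf("g%03d", seq_len(nrow(m)))) |>
    dplyr::bind_cols(tibble::as_tibble(as.data.frame(m)))
}

test_that("a doubled sample gets sqrt(2)-symmetric size factors", {
  counts <- tibble::tibble(gene_id = c("g1", "g2"),
                           s1 = c(10, 100), s2 = c(20, 200))
  sf <- size_factors(counts)
  expect_equal(sf$size_factor, c(1 / sqrt(2), sqrt(2)))
})

test_that("identical samples get size factors of exactly 1", {
  counts <- tibble::tibble(gene_id = paste0("g", 1:4),
                           s1 = c(5, 10, 0, 7), s2 = c(5, 10, 0, 7),
                           s3 = c(5, 10, 0, 7))
  expect_equal(size_factors(counts)$size_factor, c(1, 1, 1))
})

test_that("size factors match the hand-coded oracle on random matrices", {
  withr::with_seed(101, {
    for (i in 1:100) {
      m <- matrix(rnbinom(50 * 4, mu = 80, size = 5), nrow = 50,
                  dimnames = list(NULL, paste0("s", 1:4)))
      sf <- size_factors(counts_tbl(m))$size_factor
      expect_equal(sf, oracle_size_factors(m), tolerance = 1e-12)
    }
  })
})

test_that("size factors agree with DESeq2's median-of-ratios estimator", {
  skip_if_not_installed("DESeq2")
  withr::with_seed(77, {
    # odd count of strictly positive genes: sample median is a single ratio,
    # so the arithmetic and geometric definitions of the median coincide
    m <- matrix(rnbinom(51 * 4, mu = 100, size = 10) + 1L, nrow = 51,
                dimnames = list(NULL, paste0("s", 1:4)))
    sf <- size_factors(counts_tbl(m))$size_factor
    expect_equal(sf, unname(DESeq2::estimateSizeFactorsForMatrix(m)),
                 tolerance = 1e-12)
  })
})

test_that("scaling one sample by c scales its factor by c", {
  withr::with_seed(19, {
    m <- matrix(rnbinom(40 * 3, mu = 60, size = 8) + 1L, nrow = 40,
                dimnames = list(NULL, c("s1", "s2", "s3")))
    sf0 <- size_factors(counts_tbl(m))$size_factor
    m2 <- m
    m2[, 2] <- m2[, 2] * 5L
    sf1 <- size_factors(counts_tbl(m2))$size_factor
    # gene-wise ratios in sample 2 all scale by 5 / 5^(1/3) relative shift of
    # the reference; the factor ratios across samples must match the oracle
    expect_equal(sf1, oracle_size_factors(m2), tolerance = 1e-12)
    expect_equal(sf1[2] / sf0[2], 5 / 5^(1 / 3), tolerance = 1e-10)
  })
})

test_that("no all-positive gene errors and suggests the pseudo-reference", {
  counts <- tibble::tibble(gene_id = c("g1", "g2"),
                           s1 = c(0, 5), s2 = c(5, 0))
  expect_error(size_factors(counts), "pseudo_reference")
  sf <- size_factors(counts, pseudo_reference = TRUE)
  expect_true(all(sf$size_factor > 0))
})

test_that("logfc follows the pseudocounted ratio of normalized means", {
  # nine flat genes pin every size factor at 1; the tenth carries the signal
  counts <- counts_tbl(rbind(
    matrix(rep(c(30, 30, 30, 30), each = 9), nrow = 9),
    c(10, 10, 40, 40)
  ))
  names(counts) <- c("gene_id", "a1", "a2", "b1", "b2")
  d <- logfc_se(counts, test_design(c("a1", "a2", "b1", "b2")), "A", "B")
  expect_equal(d$logfc[d$gene_id == "g010"], log2(40.5 / 10.5))
  expect_equal(d$logfc[d$gene_id == "g001"], 0)
})

test_that("swapping condition labels negates every logfc", {
  withr::with_seed(23, {
    counts <- counts_tbl(matrix(rnbinom(30 * 4, mu = 100, size = 10) + 1L,
                                nrow = 30))
    names(counts) <- c("gene_id", "a1", "a2", "b1", "b2")
    design <- test_design(c("a1", "a2", "b1", "b2"))
    ab <- logfc_se(counts, design, "A", "B")
    ba <- logfc_se(counts, design, "B", "A")
    expect_equal(ab$logfc, -ba$logfc)
    expect_equal(ab$se, ba$se)
  })
})

test_that("all-zero genes are excluded and the SE floor applies", {
  counts <- tibble::tibble(gene_id = c("g1", "g2"),
                           a1 = c(0, 10), a2 = c(0, 10),
                           b1 = c(0, 10), b2 = c(0, 10))
  d <- logfc_se(counts, test_design(c("a1", "a2", "b1", "b2")), "A", "B",
                se_method = "welch")
  expect_equal(d$gene_id, "g2")
  expect_equal(d$se, 0.05)  # zero empirical variance floored at se_min
  expect_error(
    logfc_se(counts, test_design(c("a1", "a2", "b1", "b2")), "A", "X"),
    "unknown|condition"
  )
})

test_that("single-replicate designs degrade as documented", {
  counts <- tibble::tibble(gene_id = c("g1", "g2"),
                           a1 = c(10, 50), b1 = c(40, 50))
  design <- tibble::tibble(sample_id = c("a1", "b1"), condition = c("A", "B"))
  # welch: no variance estimable -> uniform floor, reported
  expect_message(dw <- logfc_se(counts, design, "A", "B",
                                se_method = "welch"), "se_min")
  expect_equal(dw$se, c(0.05, 0.05))
  # model: dispersion not estimable -> Poisson fallback, reported
  expect_message(dm <- logfc_se(counts, design, "A", "B"), "Poisson")
  expect_true(all(dm$se > 0.05))
  expect_true(dm$se[1] > dm$se[2])   # lower counts, larger standard error
})

test_that("model-based SEs depend on the data only through the means", {
  withr::with_seed(29, {
    base <- matrix(rnbinom(20 * 4, mu = 100, size = 10) + 1L, nrow = 20)
    counts <- counts_tbl(base)
    names(counts) <- c("gene_id", "a1", "a2", "b1", "b2")
    design <- test_design(c("a1", "a2", "b1", "b2"))
    d <- logfc_se(counts, design, "A", "B")
    expect_true(all(d$se > 0))
    # swapping two replicates of the same condition leaves everything fixed
    perm <- counts[c("gene_id", "a2", "a1", "b1", "b2")]
    names(perm) <- names(counts)
    d2 <- logfc_se(perm, design, "A", "B")
    expect_equal(d$se, d2$se)
    expect_equal(d$logfc, d2$logfc)
    # a gene with larger normalized means gets a smaller standard error
    ord <- order(d$base_mean)
    expect_true(d$se[ord[1]] >= d$se[ord[length(ord)]])
  })
})

test_that("shrinkage halves logfc when the prior variance equals se^2", {
  d <- tibble::tibble(gene_id = c("g1", "g2"), base_mean = c(10, 10),
                      logfc = c(2, -1), se = c(0.3, 0.3))
  shrunk <- shrink_logfc(d, prior_scale = 0.3)
  expect_equal(shrunk$logfc, c(1, -0.5))
})

test_that("shrinkage attenuates toward zero without sign flips", {
  withr::with_seed(31, {
    d <- tibble::tibble(gene_id = sprintf("g%02d", 1:40),
                        base_mean = 10,
                        logfc = rnorm(40, sd = 1.5),
                        se = runif(40, 0.05, 1))
    shrunk <- shrink_logfc(d)
    expect_true(all(abs(shrunk$logfc) <= abs(d$logfc) + 1e-12))
    expect_true(all(sign(shrunk$logfc) == sign(d$logfc) |
                      shrunk$logfc == 0))
    # zero stays a fixed point; small se approaches no shrinkage
    d0 <- tibble::tibble(gene_id = "g", base_mean = 1, logfc = 0, se = 0.2)
    expect_equal(shrink_logfc(d0, prior_scale = 1)$logfc, 0)
    d1 <- tibble::tibble(gene_id = "g", base_mean = 1, logfc = 2, se = 1e-8)
    expect_equal(shrink_logfc(d1, prior_scale = 1)$logfc, 2, tolerance = 1e-6)
  })
})

test_that("pure-noise fold changes shrink to zero with a warning", {
  d <- tibble::tibble(gene_id = c("g1", "g2"), base_mean = 1,
                      logfc = c(0.01, -0.01), se = c(1, 1))
  expect_warning(shrunk <- shrink_logfc(d), "shrunk to 0")
  expect_equal(shrunk$logfc, c(0, 0))
})

test_that("Z is the product of the standardized fold changes", {
  rna <- tibble::tibble(gene_id = "g1", base_mean = 10, logfc = 1, se = 0.5)
  chip <- tibble::tibble(gene_id = "g1", base_mean = 10, logfc = -2, se = 1)
  z <- z_scores(rna, list(H3K4me3 = chip),
                c(H3K4me3 = "activating"))
  expect_equal(z$H3K4me3, -4)  # 2 * (-2)

  chip0 <- tibble::tibble(gene_id = "g1", base_mean = 10, logfc = 0, se = 1)
  z0 <- z_scores(rna, list(H3K4me3 = chip0), c(H3K4me3 = "activating"))
  expect_equal(z0$H3K4me3, 0)
})

test_that("genes missing from a layer are dropped; empty overlap errors", {
  rna <- tibble::tibble(gene_id = c("g1", "g2"), base_mean = 1,
                        logfc = c(1, 1), se = c(0.5, 0.5))
  chip <- tibble::tibble(gene_id = "g2", base_mean = 1, logfc = 1, se = 0.5)
  expect_message(z <- z_scores(rna, list(m = chip), c(m = "activating")),
                 "dropped 1")
  expect_equal(z$gene_id, "g2")

  chip_none <- tibble::tibble(gene_id = "g9", base_mean = 1, logfc = 1, se = 1)
  expect_error(z_scores(rna, list(m = chip_none), c(m = "activating")),
               "no gene")
})

test_that("Z signs follow the direction pairing of the two layers", {
  rna <- tibble::tibble(gene_id = paste0("g", 1:4), base_mean = 10,
                        logfc = c(2, 2, -2, -2), se = 0.5)
  chip <- tibble::tibble(gene_id = paste0("g", 1:4), base_mean = 10,
                         logfc = c(1.5, -1.5, -1.5, 1.5), se = 0.5)
  z <- z_scores(rna, list(m = chip), c(m = "activating"))
  # (up,up) -> +, (up,down) -> -, (down,down) -> +, (down,up) -> -
  expect_equal(sign(z$m), c(1, -1, 1, -1))
})
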