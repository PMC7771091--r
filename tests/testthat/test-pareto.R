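ztable <- function(m, ids = sprintf("g%03d", seq_len(nrow(m)))) {
  tibble::tibble(gene_id = ids) |>
    dplyr::bind_cols(tibble::as_tibble(as.data.frame(m))) |>
    stats::setNames(c("gene_id", paste0("m", seq_len(ncol(m)))))
}

front_of <- function(ranking) {
  stats::setNames(ranking$front, ranking$gene_id)
}

test_that("dominance follows the componentwise definition", {
  expect_true(dominates(c(2, 3), c(1, 3)))
  expect_false(dominates(c(1, 1), c(1, 1)))     # no strict component
  expect_false(dominates(c(2, 0), c(0, 2)))     # incomparable
  expect_false(dominates(c(0, 2), c(2, 0)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "length")
})

test_that("fronts match the exhaustively checked example", {
  zt <- ztable(rbind(c(2, 2), c(1, 3), c(3, 1), c(0, 0)))
  r <- assign_fronts(zt, all_activating(zt))
  expect_equal(unname(front_of(r)[sprintf("g%03d", 1:4)]), c(1, 1, 1, 2))

  single <- ztable(matrix(c(5, -3), nrow = 1))
  expect_equal(assign_fronts(single, all_activating(single))$front, 1L)
})

test_that("repressive marks are minimized through the sign flip", {
  zt <- tibble::tibble(gene_id = c("strong", "weak"),
                       act = c(5, 1), rep = c(-5, -1))
  dirs <- c(act = "activating", rep = "repressive")
  r <- assign_fronts(zt, dirs)
  # signed objectives: strong (5, 5) dominates weak (1, 1)
  expect_equal(unname(front_of(r)[c("strong", "weak")]), c(1, 2))
  # raw Z scores are reported unchanged
  expect_equal(r$rep[r$gene_id == "strong"], -5)
})

test_that("identical objective vectors share a front", {
  zt <- ztable(rbind(c(1, 1), c(1, 1), c(0, 0)))
  r <- assign_fronts(zt, all_activating(zt))
  expect_equal(unname(front_of(r)[c("g001", "g002", "g003")]), c(1, 1, 2))

  same <- ztable(matrix(2, nrow = 4, ncol = 3))
  expect_equal(assign_fronts(same, all_activating(same))$front, rep(1L, 4))
})

test_that("fast sort agrees with the brute-force oracle on random instances", {
  withr::with_seed(202, {
    for (i in 1:40) {
      n <- sample(2:120, 1)
      k <- sample(1:6, 1)
      zt <- random_ztable(n, k)
      dirs <- stats::setNames(
        sample(c("activating", "repressive"), k, replace = TRUE),
        paste0("m", seq_len(k))
      )
      expect_equal(front_of(assign_fronts(zt, dirs)),
                   front_of(brute_force_fronts(zt, dirs)))
    }
  })
})

test_that("removing front 1 shifts every remaining front down by one", {
  withr::with_seed(303, {
    for (i in 1:10) {
      zt <- random_ztable(sample(20:150, 1), sample(2:4, 1))
      dirs <- all_activating(zt)
      r1 <- assign_fronts(zt, dirs)
      rest <- zt[!zt$gene_id %in% r1$gene_id[r1$front == 1], ]
      if (nrow(rest) == 0) next
      r2 <- assign_fronts(rest, dirs)
      expect_equal(front_of(r2), front_of(r1)[names(front_of(r2))] - 1L)
    }
  })
})

test_that("strictly increasing transforms per objective preserve fronts", {
  withr::with_seed(404, {
    zt <- random_ztable(80, 3)
    dirs <- all_activating(zt)
    before <- front_of(assign_fronts(zt, dirs))
    zt2 <- zt
    zt2$m1 <- exp(zt2$m1)          # strictly increasing
    zt2$m2 <- zt2$m2^3             # strictly increasing (odd power)
    zt2$m3 <- 10 * zt2$m3 + 2      # affine increasing
    after <- front_of(assign_fronts(zt2, dirs))
    expect_equal(after, before)
  })
})

test_that("with one objective, fronts are the rank order of the signed Z", {
  zt <- tibble::tibble(gene_id = paste0("g", 1:6),
                       m1 = c(3, -1, 3, 0, 7, -1))
  r <- assign_fronts(zt, c(m1 = "activating"))
  f <- front_of(r)
  # descending value order with ties sharing a front: 7 -> 1, 3 -> 2, 0 -> 3, -1 -> 4
  expect_equal(unname(f[c("g5", "g1", "g3", "g4", "g2", "g6")]),
               c(1, 2, 2, 3, 4, 4))

  rrep <- assign_fronts(zt, c(m1 = "repressive"))
  expect_equal(unname(front_of(rrep)[c("g2", "g6", "g4", "g1", "g3", "g5")]),
               c(1, 1, 2, 3, 3, 4))
})

test_that("output is ordered by ascending front then gene id, fronts contiguous", {
  withr::with_seed(505, {
    zt <- random_ztable(60, 2)
    r <- assign_fronts(zt, all_activating(zt))
    expect_equal(sort(unique(r$front)), seq_len(max(r$front)))
    expect_false(is.unsorted(r$front))
    within_front_order <- tapply(r$gene_id, r$front, function(g) !is.unsorted(g))
    expect_true(all(within_front_order))
  })
})

test_that("genes with non-finite Z are excluded before ranking", {
  zt <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                       m1 = c(1, NA, 3), m2 = c(1, 2, Inf))
  expect_message(r <- assign_fronts(zt, all_activating(zt)), "excluding 2")
  expect_equal(r$gene_id, "g1")
  expect_error(assign_fronts(zt[0, ], all_activating(zt)), "empty")
})

test_that("tidy and glance summarize a ranking", {
  zt <- ztable(rbind(c(2, 2), c(1, 3), c(0, 0)))
  r <- assign_fronts(zt, all_activating(zt))
  td <- generics::tidy(r)
  expect_equal(nrow(td), 6)  # 3 genes x 2 marks
  expect_equal(sort(unique(td$mark)), c("m1", "m2"))
  gl <- generics::glance(r)
  expect_equal(gl$n_genes, 3L)
  expect_equal(gl$n_fronts, 2L)
  expect_equal(gl$front1_size, 2L)
})
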