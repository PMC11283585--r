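test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  withr::with_seed(42, {
    for (i in 1:200) {
      p <- runif(sample(1:50, 1))
      expect_equal(bh_adjust(p), bh_brute(p))
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("studentized outlier test finds a planted outlier and matches car", {
  x <- 1:10
  y <- 2 * x
  y[10] <- y[10] + 10
  res <- studentized_outlier_test(x, y)
  expect_identical(res$point_id[1], "10")
  expect_identical(which.min(res$p_adj), 1L)
  # an exact fit has zero residuals and p = 1 everywhere
  flat <- studentized_outlier_test(1:6, 1:6)
  expect_equal(flat$studentized_residual, rep(0, 6))
  expect_equal(flat$p, rep(1, 6))
  # cross-check statistic and df convention against car::outlierTest
  withr::with_seed(1, {
    xr <- rnorm(15)
    yr <- 1 + 2 * xr + rnorm(15)
  })
  ours <- studentized_outlier_test(xr, yr)
  ct <- car::outlierTest(lm(yr ~ xr), cutoff = Inf, n.max = 15)
  expect_equal(sort(ours$studentized_residual),
               sort(unname(ct$rstudent)), tolerance = 1e-10)
  expect_equal(ours$p[1], 2 * pt(abs(ours$studentized_residual[1]),
                                 df = 12, lower.tail = FALSE))
  expect_error(studentized_outlier_test(rep(1, 5), rnorm(5)), "degenerate")
  expect_error(studentized_outlier_test(1:3, 1:3), ">= 4")
})

test_that("enrichment formulas evaluate the median ratios", {
  s <- tibble::tibble(gene_a = "A", gene_b = "B",
                      d_tum = 2, d_cell = 8, a_tum = 1, a_cell = 2,
                      b_tum = 3, b_cell = 10, n_tum = 5, n_cell = 10)
  expect_equal(observed_dko_enrichment(s), 0.5)
  expect_equal(expected_dko_enrichment(s), 0.5 * 2 + 0.3 * 2)
  # no-change and normalization fixed points
  neutral <- tibble::tibble(gene_a = "A", gene_b = "B",
                            d_tum = 4, d_cell = 4, a_tum = 3, a_cell = 3,
                            b_tum = 7, b_cell = 7, n_tum = 2, n_cell = 2)
  expect_equal(observed_dko_enrichment(neutral), 1)
  expect_equal(expected_dko_enrichment(neutral), 2)
  # D behaving exactly like NTC is 1 even when both shift
  drift <- dplyr::mutate(neutral, d_tum = 1, d_cell = 2, n_tum = 3, n_cell = 6)
  expect_equal(observed_dko_enrichment(drift), 1)
  # symmetric genes double the single term
  sym <- dplyr::mutate(s, b_tum = a_tum, b_cell = a_cell)
  expect_equal(expected_dko_enrichment(sym), 2 * 0.5 * 2)
  bad <- dplyr::mutate(s, d_cell = 0)
  expect_error(observed_dko_enrichment(bad), "d_cell")
})

test_that("enrichment outlier calling flags planted synergy, not additivity", {
  # exactly additive pairs: zero significant calls
  withr::with_seed(3, {
    a <- runif(50, 0.2, 1.5)
    b <- runif(50, 0.2, 1.5)
  })
  addv <- tibble::tibble(
    gene_a = sprintf("A%02d", 1:50), gene_b = sprintf("B%02d", 1:50),
    d_tum = a + b, d_cell = 1, a_tum = a, a_cell = 1,
    b_tum = b, b_cell = 1, n_tum = 1, n_cell = 1)
  calls <- synergy_by_enrichment(addv)
  expect_equal(sum(calls$significant), 0L)
  expect_equal(calls$observed, calls$expected, tolerance = 1e-12)
  # one pair depleted far below additivity among noisy-but-additive pairs
  withr::with_seed(4, {
    noisy <- dplyr::mutate(addv, d_tum = (a + b) * exp(rnorm(50, 0, 0.05)))
  })
  noisy$d_tum[17] <- (a[17] + b[17]) * 2^-3
  calls2 <- synergy_by_enrichment(noisy)
  worst <- calls2[1, ]
  expect_identical(paste0(worst$gene_a, "__", worst$gene_b), "A17__B17")
  expect_true(worst$significant)
  expect_lt(worst$studentized_residual, 0)
  # pair order is irrelevant to the significant set
  withr::with_seed(5, shuf <- noisy[sample(nrow(noisy)), ])
  calls3 <- synergy_by_enrichment(shuf)
  sig2 <- paste0(calls2$gene_a, calls2$gene_b)[calls2$significant]
  sig3 <- paste0(calls3$gene_a, calls3$gene_b)[calls3$significant]
  expect_setequal(sig2, sig3)
})

test_that("rank-sum p-values match exact enumeration and are rank invariant", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p,
               wilcox_enum_p(c(1, 2, 3), c(4, 5, 6)))
  # identical multisets: p = 1 (or ~1 under the tied approximation)
  expect_gte(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 0.99)
  withr::with_seed(6, {
    for (n1 in 1:8) for (n2 in seq_len(min(8, 10 - n1))) {
      xs <- rnorm(n1)
      ys <- rnorm(n2)
      expect_equal(wilcoxon_rank_sum(xs, ys)$p, wilcox_enum_p(xs, ys),
                   info = paste(n1, n2))
      expect_equal(wilcoxon_rank_sum(xs, ys)$p, wilcoxon_rank_sum(ys, xs)$p)
      # doubling is a monotone transform: p unchanged
      expect_equal(wilcoxon_rank_sum(2 * xs, 2 * ys)$p,
                   wilcoxon_rank_sum(xs, ys)$p)
    }
  })
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("rank-sum synergy model recovers a planted DKO-specific depletion", {
  lib <- make_library(4, 4, 3)
  scr <- simulate_screen(
    lib, interactions = tibble::tibble(gene_a = "Kin01", gene_b = "Met01",
                                       epsilon = -3),
    n_tumours = 3, seed = 21)
  calls <- synergy_by_rank_test(screen_lfc(scr), lib)
  expect_identical(paste0(calls$gene_a[1], "__", calls$gene_b[1]),
                   "Kin01__Met01")
  expect_lt(calls$median_shift[1], 0)
  # DKO fold-changes identical to SKO fold-changes: nothing significant
  flat_lfc <- tidyr::expand_grid(
    array_id = lib$array_id,
    sample_id = sprintf("s%d", 1:4)) %>%
    dplyr::mutate(lfc = 0, fc = 1)
  flat <- synergy_by_rank_test(flat_lfc, lib)
  expect_equal(sum(flat$significant), 0L)
  # per-gene-minimum strategy keeps the smaller of the two single-gene tests
  lfc <- screen_lfc(scr)
  alt <- synergy_by_rank_test(lfc, lib, sko_strategy = "per_gene_min")
  xs <- lfc$lfc[lfc$array_id == "Kin01__Met01"]
  sko_of <- function(g) lib$array_id[lib$category == "SKO" & lib$gene1 == g]
  pa <- wilcoxon_rank_sum(xs, lfc$lfc[lfc$array_id %in% sko_of("Kin01")])$p
  pb <- wilcoxon_rank_sum(xs, lfc$lfc[lfc$array_id %in% sko_of("Met01")])$p
  expect_equal(alt$p[alt$gene_a == "Kin01" & alt$gene_b == "Met01"],
               min(pa, pb))
})

test_that("cell-vs-tumour regression flags depleted entities, affine invariant", {
  withr::with_seed(31, {
    cell <- rnorm(40, 10, 1)
    tum <- cell + rnorm(40, 0, 0.1)
  })
  tum[13] <- cell[13] - 2
  ents <- tibble::tibble(entity = sprintf("e%02d", 1:40), cell = cell,
                         tumour = tum)
  res <- regression_cell_vs_tumour(ents)
  expect_identical(res$point_id[1], "e13")
  expect_true(res$p_adj[1] < 0.05)
  expect_lt(res$studentized_residual[1], 0)
  shifted <- dplyr::mutate(ents, cell = cell + 5, tumour = tumour + 5)
  res2 <- regression_cell_vs_tumour(shifted)
  expect_equal(res$studentized_residual, res2$studentized_residual,
               tolerance = 1e-9)
  # identical axes: no outliers
  same <- tibble::tibble(entity = letters[1:6], cell = 1:6, tumour = 1:6)
  expect_equal(sum(regression_cell_vs_tumour(same)$p < 1), 0L)
})

test_that("screen entity table covers DKO pairs plus collapsed SKO genes", {
  lib <- make_library(2, 2, 2)
  scr <- simulate_screen(lib, n_cell_reps = 2, n_tumours = 2, seed = 5)
  rpm <- to_rpm(scr$counts)
  ents <- screen_entity_abundance(rpm, lib,
                                  cell_samples = screen_samples(scr, "cell", 14),
                                  tumour_samples = screen_samples(scr, "tumour"))
  expect_equal(sum(ents$type == "DKO"), 4L)
  expect_equal(sum(ents$type == "SKO_gene"), 4L)
  expect_true(all(is.finite(ents$cell)) && all(is.finite(ents$tumour)))
})
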