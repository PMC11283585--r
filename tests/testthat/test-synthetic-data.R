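test_that("noise-free screens reduce the enrichment formulas to closed form", {
  lib <- make_library(3, 3, 3)
  f <- zero_fitness(lib)
  f["Kin01"] <- -1
  f["Met02"] <- -0.5
  eps <- tibble::tibble(gene_a = "Kin01", gene_b = "Met01", epsilon = -2)
  scr <- simulate_screen(lib, fitness = f, interactions = eps,
                         noise = FALSE, seed = 1)
  rpm <- to_rpm(scr$counts)
  summ <- median_abundance_summary(
    rpm, lib, cell_samples = screen_samples(scr, "cell", 14),
    tumour_samples = screen_samples(scr, "tumour", 10))
  obs <- observed_dko_enrichment(summ)
  exp_ <- expected_dko_enrichment(summ)
  for (i in seq_len(nrow(summ))) {
    fa <- f[summ$gene_a[i]]
    fb <- f[summ$gene_b[i]]
    e <- if (summ$gene_a[i] == "Kin01" && summ$gene_b[i] == "Met01") -2 else 0
    expect_equal(obs[i], unname(2^(fa + fb + e)), tolerance = 1e-6)
    expect_equal(exp_[i], unname(2^fa + 2^fb), tolerance = 1e-6)
  }
  # replicate-paired fold-changes carry the per-round selection exactly,
  # relative to the NTC baseline (rpm renormalization adds a shared offset)
  lfc <- screen_lfc(scr, pseudocount_rpm = 0)
  ntc_ids <- lib$array_id[lib$category == "NTC_NTC"]
  baseline <- dplyr::summarise(
    dplyr::group_by(lfc[lfc$array_id %in% ntc_ids, ], sample_id),
    b = stats::median(lfc), .groups = "drop")
  dko <- dplyr::inner_join(lfc[lfc$array_id == "Kin01__Met01", ], baseline,
                           by = "sample_id")
  expect_equal(dko$lfc - dko$b, rep(-3, nrow(dko)),
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("null screens are flat and planted fitness is recovered", {
  lib <- make_library(3, 3, 3)
  scr <- simulate_screen(lib, n_tumours = 2, seed = 2)
  lfc <- screen_lfc(scr)
  expect_lt(abs(mean(lfc$lfc)), 0.1)
  # f = -1 on one gene shifts every array containing it by about -1
  f <- zero_fitness(lib)
  f["Kin02"] <- -1
  shifts <- vapply(1:20, function(s) {
    scr1 <- simulate_screen(lib, fitness = f, n_tumours = 2, seed = 100 + s)
    l <- screen_lfc(scr1)
    with_gene <- lib$array_id[lib$gene1 == "Kin02" | lib$gene2 == "Kin02"]
    mean(l$lfc[l$array_id %in% with_gene]) -
      mean(l$lfc[!l$array_id %in% with_gene])
  }, numeric(1))
  expect_equal(mean(shifts), -1, tolerance = 3 * sd(shifts) / sqrt(20))
})

test_that("screens are reproducible from the seed and structured as declared", {
  lib <- make_library(2, 2, 2)
  s1 <- simulate_screen(lib, seed = 9)
  s2 <- simulate_screen(lib, seed = 9)
  s3 <- simulate_screen(lib, seed = 10)
  expect_identical(s1$counts, s2$counts)
  expect_false(identical(s1$counts, s3$counts))
  expect_equal(nrow(s1$samples), 1 + 3 + 3 + 6 + 6)
  expect_setequal(unique(s1$samples$condition), c("plasmid", "cell", "tumour"))
  expect_true(all(s1$counts$count >= 0))
  expect_true(all(s1$counts$count == round(s1$counts$count)))
  expect_error(
    simulate_screen(lib, fitness = c(Kin01 = 0), seed = 1), "Missing fitness")
})

test_that("uniform noise-free libraries have full coverage and unit skew", {
  lib <- make_library(3, 3, 2)
  scr <- simulate_screen(lib, libskew_sdlog = 0, noise = FALSE, seed = 1)
  cnt <- scr$counts[scr$counts$sample_id == "plasmid", ]
  cs <- coverage_and_skew(cnt)
  expect_equal(cs$coverage, 1)
  expect_equal(cs$skew, 1)
})

test_that("simulated FASTQ round-trips the planted counts exactly", {
  lib <- make_library(2, 2, 2)
  withr::with_seed(5, {
    counts <- tibble::tibble(array_id = lib$array_id,
                             count = sample(0:30, nrow(lib), TRUE))
  })
  counts$count[3] <- 0
  prefix <- file.path(withr::local_tempdir(), "sim")
  fq <- simulate_fastq(counts, lib, prefix, seed = 6)
  rec <- count_fastq_sample(fq[["r1"]], fq[["r2"]], lib)
  expect_equal(rec$count[match(counts$array_id, rec$array_id)],
               as.integer(counts$count))
  qc <- attr(rec, "qc")
  expect_equal(qc$n_merged, sum(counts$count))
  expect_equal(qc$n_assigned, sum(counts$count))
  # byte-identical regeneration from the same seed
  prefix2 <- file.path(withr::local_tempdir(), "sim2")
  fq2 <- simulate_fastq(counts, lib, prefix2, seed = 6)
  expect_identical(readLines(fq[["r1"]]), readLines(fq2[["r1"]]))
  expect_identical(readLines(fq[["r2"]]), readLines(fq2[["r2"]]))
  # unmergeable geometry is refused
  expect_error(simulate_fastq(counts, lib, prefix, read_length = 80),
               "would not merge")
})

test_that("cohorts are seed-reproducible with planted hazard directions", {
  genes <- sprintf("G%02d", 1:5)
  c1 <- simulate_cohort(genes, n_samples = 50, seed = 3)
  c2 <- simulate_cohort(genes, n_samples = 50, seed = 3)
  expect_identical(c1, c2)
  expect_true(all(c1$time > 0))
  expect_true(all(c1$event %in% c(0, 1)))
  # censoring fraction is hit in expectation
  big <- simulate_cohort(genes, n_samples = 4000, censor_fraction = 0.3,
                         seed = 4)
  expect_lt(abs((1 - mean(big$event)) - 0.3), 0.03)
  # beta_g = 1: high expression group has worse survival in >= 90% of seeds
  worse <- vapply(1:20, function(s) {
    co <- simulate_cohort(genes, n_samples = 200, beta_gene = c(G01 = 1),
                          censor_fraction = 0.2, seed = 400 + s)
    grp <- percentile_groups(co$G01)
    keep <- grp != "excluded"
    low <- km_curve(co$time[keep][grp[keep] == "low"],
                    co$event[keep][grp[keep] == "low"])
    high <- km_curve(co$time[keep][grp[keep] == "high"],
                     co$event[keep][grp[keep] == "high"])
    direction_ok <- km_median(high)
    m_low <- km_median(low)
    is.na(m_low) || (!is.na(direction_ok) && direction_ok < m_low)
  }, logical(1))
  expect_gte(mean(worse), 0.9)
})

test_that("null cohorts produce uniform log-rank p-values", {
  genes <- "G1"
  ps <- vapply(1:500, function(s) {
    co <- simulate_cohort(genes, n_samples = 60, censor_fraction = 0.2,
                          seed = 7000 + s)
    grp <- percentile_groups(co$G1)
    keep <- grp != "excluded"
    logrank_p(co$time[keep], co$event[keep], grp[keep])$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("truth reports count planted recoveries and false flags", {
  lib <- make_library(2, 2, 2)
  eps <- tibble::tibble(gene_a = c("Kin01", "Kin02"),
                        gene_b = c("Met01", "Met02"), epsilon = c(-2, -1))
  scr <- simulate_screen(lib, interactions = eps, seed = 1)
  dko <- lib[lib$category == "DKO", ]
  perfect <- tibble::tibble(
    gene_a = dko$gene1, gene_b = dko$gene2,
    significant = paste0(dko$gene1, "__", dko$gene2) %in%
      paste0(eps$gene_a, "__", eps$gene_b))
  rep1 <- truth_report(scr, perfect)
  expect_equal(rep1$sensitivity, 1)
  expect_equal(rep1$fdr, 0)
  none <- dplyr::mutate(perfect, significant = FALSE)
  rep2 <- truth_report(scr, none)
  expect_equal(rep2$sensitivity, 0)
  expect_equal(rep2$fdr, 0)
  flipped <- dplyr::mutate(perfect, significant = !significant)
  rep3 <- truth_report(scr, flipped)
  expect_equal(rep3$sensitivity, 0)
  expect_equal(rep3$fdr, 1)
  alien <- tibble::tibble(gene_a = "NoSuch", gene_b = "Pair",
                          significant = TRUE)
  expect_error(truth_report(scr, alien), "outside")
})

test_that("tidiers and autoplot methods return well-formed objects", {
  lib <- make_library(3, 3, 2)
  scr <- simulate_screen(lib, n_tumours = 2, seed = 12)
  rpm <- to_rpm(scr$counts)
  summ <- median_abundance_summary(
    rpm, lib, screen_samples(scr, "cell", 14), screen_samples(scr, "tumour"))
  calls <- synergy_by_enrichment(summ)
  expect_s3_class(tidy(calls), "tbl_df")
  expect_false(inherits(tidy(calls), "interaction_calls"))
  g <- glance(calls)
  expect_identical(g$model, "enrichment")
  expect_equal(g$n_pairs, nrow(calls))
  expect_s3_class(autoplot(calls), "ggplot")
  km <- km_curve(c(3, 5, 9, 11), c(1, 1, 0, 1))
  expect_equal(glance(km)$n_events, 3)
  expect_s3_class(autoplot(km), "ggplot")
  ents <- screen_entity_abundance(rpm, lib,
                                  screen_samples(scr, "cell", 14),
                                  screen_samples(scr, "tumour"))
  reg <- regression_cell_vs_tumour(ents)
  expect_s3_class(autoplot(reg), "ggplot")
  expect_true(all(c("r_squared", "sigma") %in% names(glance(reg))))
})
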