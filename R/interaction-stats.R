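#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector (monotone,
#' capped at 1, original order preserved). Thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("`p` must be numeric in [0, 1] with no missing values.")
  }
  p.adjust(p, method = "BH")
}

#' Studentized-residual outlier test for a simple linear regression
#'
#' Fits ordinary least squares `y ~ x` and tests each point as a potential
#' outlier using its externally studentized residual, referenced to a
#' t distribution with `n - 3` degrees of freedom (the leave-one-out
#' convention for simple regression). Two-sided p-values are adjusted across
#' all points with Benjamini-Hochberg. When the fit is exact (zero residual
#' variance) every residual is 0 and every p-value 1.
#'
#' @param x,y Numeric vectors (`length >= 4`); `x` must not be constant.
#' @param point_id Optional point labels (defaults to `1..n`).
#' @return An `outlier_screen`: a tibble with columns `point_id`, `x`, `y`,
#'   `studentized_residual`, `p`, `p_adj`, sorted by decreasing `|residual|`,
#'   with the fitted `lm` in attribute `"model"`.
#' @export
studentized_outlier_test <- function(x, y, point_id = NULL) {
  if (length(x) != length(y) || length(x) < 4L) {
    abort("`x` and `y` must have equal length >= 4.")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("`x` and `y` must be finite.")
  }
  if (sd(x) == 0) abort("`x` is degenerate (zero variance); cannot regress.")
  if (is.null(point_id)) point_id <- as.character(seq_along(x))
  n <- length(x)
  fit <- lm(y ~ x)
  scale <- mean(abs(y)) + mean(abs(x)) + 1
  if (sqrt(mean(fit$residuals^2)) < 1e-10 * scale) {
    # numerically exact fit: residuals are floating-point noise, not signal
    t_i <- rep(0, n)
  } else {
    t_i <- rstudent(fit)
    # a point whose leave-one-out fit is exact gets a non-finite |t|: treat
    # it as an infinite outlier when its residual is real, as 0 otherwise
    bad <- !is.finite(t_i)
    if (any(bad)) {
      r <- fit$residuals
      t_i[bad] <- ifelse(abs(r[bad]) > 1e-10 * scale, sign(r[bad]) * Inf, 0)
    }
  }
  p <- ifelse(is.finite(t_i),
              2 * pt(abs(t_i), df = n - 3L, lower.tail = FALSE), 0)
  p <- pmin(p, 1)
  out <- tibble::tibble(
    point_id = point_id, x = x, y = y,
    studentized_residual = unname(t_i), p = unname(p),
    p_adj = bh_adjust(unname(p))
  )
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$studentized_residual)))
  structure(out, model = fit,
            class = c("outlier_screen", class(tibble::tibble())))
}

#' Median abundance summary for every double-knockout pair
#'
#' Collects, for each DKO gene pair (A, B), the eight medians that feed the
#' enrichment formulas: the DKO array's median rpm in the tumour and cell
#' screens (`d_tum`, `d_cell`), each gene's SKO median rpm (`a_tum`,
#' `a_cell`, `b_tum`, `b_cell`; median over all of that gene's SKO arrays x
#' samples of the condition) and the NTC-NTC median rpm (`n_tum`, `n_cell`;
#' median over all NTC-NTC arrays x samples).
#'
#' @param rpm A tibble with columns `array_id`, `sample_id`, `rpm`.
#' @param design A `crrna_library`.
#' @param cell_samples,tumour_samples Character vectors of sample ids
#'   defining the cell and tumour screens.
#' @return A tibble with one row per DKO pair: `gene_a`, `gene_b`, `d_tum`,
#'   `d_cell`, `a_tum`, `a_cell`, `b_tum`, `b_cell`, `n_tum`, `n_cell`.
#' @export
median_abundance_summary <- function(rpm, design, cell_samples, tumour_samples) {
  stopifnot(is.data.frame(rpm),
            all(c("array_id", "sample_id", "rpm") %in% names(rpm)),
            inherits(design, "crrna_library"))
  missing_s <- setdiff(c(cell_samples, tumour_samples), unique(rpm$sample_id))
  if (length(missing_s)) {
    abort(paste0("Sample(s) not in `rpm`: ", paste(missing_s, collapse = ", ")))
  }
  rpm <- tibble::as_tibble(rpm)
  med_of <- function(array_ids, sample_ids) {
    v <- rpm$rpm[rpm$array_id %in% array_ids & rpm$sample_id %in% sample_ids]
    stats::median(v)
  }
  sko_arrays <- function(gene) design$array_id[design$category == "SKO" &
                                                 design$gene1 == gene]
  ntc <- design$array_id[design$category == "NTC_NTC"]
  n_tum <- med_of(ntc, tumour_samples)
  n_cell <- med_of(ntc, cell_samples)
  dko <- design[design$category == "DKO", ]
  purrr::map_dfr(seq_len(nrow(dko)), function(i) {
    ga <- dko$gene1[i]
    gb <- dko$gene2[i]
    tibble::tibble(
      gene_a = ga, gene_b = gb,
      d_tum = med_of(dko$array_id[i], tumour_samples),
      d_cell = med_of(dko$array_id[i], cell_samples),
      a_tum = med_of(sko_arrays(ga), tumour_samples),
      a_cell = med_of(sko_arrays(ga), cell_samples),
      b_tum = med_of(sko_arrays(gb), tumour_samples),
      b_cell = med_of(sko_arrays(gb), cell_samples),
      n_tum = n_tum, n_cell = n_cell
    )
  })
}

check_positive_medians <- function(s, cols) {
  for (cl in cols) {
    if (any(!is.finite(s[[cl]]) | s[[cl]] <= 0)) {
      abort(paste0("Median `", cl, "` must be positive to compute enrichment."))
    }
  }
}

#' Observed and expected double-knockout enrichment
#'
#' Under NTC-NTC normalization the observed DKO enrichment of a pair is
#' `(D_t / D_c) * (N_c / N_t)` and the expected (additive) enrichment is the
#' sum of the two single-gene enrichments,
#' `(A_t / A_c) * (N_c / N_t) + (B_t / B_c) * (N_c / N_t)`, where `D`, `A`,
#' `B`, `N` are the medians collected by [median_abundance_summary()]
#' (`_t` tumour, `_c` cell). A pair whose DKO behaves exactly like NTC has
#' observed enrichment 1; two neutral genes have expected enrichment 2.
#'
#' @param summary A tibble as returned by [median_abundance_summary()]
#'   (one or more rows).
#' @return Numeric vector of enrichments, one per row.
#' @export
observed_dko_enrichment <- function(summary) {
  stopifnot(is.data.frame(summary))
  check_positive_medians(summary, c("d_cell", "n_tum"))
  (summary$d_tum / summary$d_cell) * (summary$n_cell / summary$n_tum)
}

#' @rdname observed_dko_enrichment
#' @export
expected_dko_enrichment <- function(summary) {
  stopifnot(is.data.frame(summary))
  check_positive_medians(summary, c("a_cell", "b_cell", "n_tum"))
  (summary$a_tum / summary$a_cell) * (summary$n_cell / summary$n_tum) +
    (summary$b_tum / summary$b_cell) * (summary$n_cell / summary$n_tum)
}

new_interaction_calls <- function(x, model, alpha, skipped = NULL) {
  structure(x, model = model, alpha = alpha, skipped = skipped,
            class = c("interaction_calls", class(tibble::tibble())))
}

#' Call synergistic pairs from expected-vs-observed enrichment outliers
#'
#' Regresses observed on expected DKO enrichment across all pairs and flags
#' significant outliers by the studentized-residual test with
#' Benjamini-Hochberg adjustment. A negative residual means the double
#' knockout is depleted beyond the additive single-gene expectation -
#' synergy under negative selection.
#'
#' @param summaries Tibble of per-pair medians from
#'   [median_abundance_summary()] (>= 4 usable pairs).
#' @param alpha Significance level on adjusted p-values.
#' @return An `interaction_calls` tibble: `gene_a`, `gene_b`, `observed`,
#'   `expected`, `studentized_residual`, `p`, `p_adj`, `significant`. Pairs
#'   with non-positive denominators are skipped and recorded in attribute
#'   `"skipped"`.
#' @export
synergy_by_enrichment <- function(summaries, alpha = 0.05) {
  stopifnot(is.data.frame(summaries))
  usable <- is.finite(summaries$d_cell) & summaries$d_cell > 0 &
    is.finite(summaries$a_cell) & summaries$a_cell > 0 &
    is.finite(summaries$b_cell) & summaries$b_cell > 0 &
    is.finite(summaries$n_tum) & summaries$n_tum > 0 &
    is.finite(summaries$n_cell) & summaries$n_cell > 0
  skipped <- NULL
  if (any(!usable)) {
    skipped <- tibble::tibble(
      gene_a = summaries$gene_a[!usable], gene_b = summaries$gene_b[!usable],
      reason = "non-positive median abundance")
    warn(paste0(sum(!usable), " pair(s) skipped: non-positive medians."))
    summaries <- summaries[usable, ]
  }
  if (nrow(summaries) < 4L) {
    abort("Need at least 4 usable pairs to regress observed on expected.")
  }
  obs <- observed_dko_enrichment(summaries)
  exp_ <- expected_dko_enrichment(summaries)
  pair_id <- paste0(summaries$gene_a, "__", summaries$gene_b)
  ot <- studentized_outlier_test(exp_, obs, point_id = pair_id)
  res <- tibble::as_tibble(ot) %>%
    dplyr::rename(observed = "y", expected = "x") %>%
    dplyr::mutate(significant = .data$p_adj < alpha)
  key <- match(res$point_id, pair_id)
  res <- dplyr::mutate(res,
                       gene_a = summaries$gene_a[key],
                       gene_b = summaries$gene_b[key]) %>%
    dplyr::select("gene_a", "gene_b", "observed", "expected",
                  "studentized_residual", "p", "p_adj", "significant")
  new_interaction_calls(res, model = "enrichment", alpha = alpha,
                        skipped = skipped)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Mann-Whitney/rank-sum comparison of two samples: the exact null
#' distribution is used when both groups have at most 8 observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections applies.
#'
#' @param xs,ys Non-empty numeric vectors.
#' @return A list with elements `W` (rank-sum statistic of `xs`) and `p`
#'   (two-sided p-value).
#' @export
wilcoxon_rank_sum <- function(xs, ys) {
  if (!length(xs) || !length(ys)) abort("Both samples must be non-empty.")
  ties <- anyDuplicated(c(xs, ys)) > 0L
  use_exact <- length(xs) <= 8L && length(ys) <= 8L && !ties
  wt <- suppressWarnings(
    wilcox.test(xs, ys, alternative = "two.sided",
                exact = use_exact, correct = TRUE))
  p <- wt$p.value
  # all observations tied: zero rank variance, no evidence either way
  if (!is.finite(p)) p <- 1
  list(W = unname(wt$statistic), p = min(p, 1))
}

#' Call synergistic pairs by rank-sum of DKO versus SKO fold-changes
#'
#' For each DKO pair, the per-sample log2 fold-changes of the pair's DKO
#' array are compared with the pooled per-sample fold-changes of both genes'
#' SKO arrays by a two-sided Wilcoxon rank-sum test, and p-values are
#' adjusted across pairs with Benjamini-Hochberg. A negative `median_shift`
#' (DKO median LFC below SKO median LFC) indicates the double knockout is
#' depleted beyond its single knockouts.
#'
#' @param lfc Tibble with columns `array_id`, `sample_id`, `lfc` (from
#'   [compute_lfc()], typically over all selected-endpoint samples).
#' @param design A `crrna_library`.
#' @param alpha Significance level on adjusted p-values.
#' @param sko_strategy `"pooled"` (default): SKO fold-changes of both genes
#'   pooled into one comparison group; `"per_gene_min"`: test against each
#'   gene's SKOs separately and keep the smaller p-value (anti-conservative;
#'   exploratory use).
#' @return An `interaction_calls` tibble: `gene_a`, `gene_b`, `w`, `p`,
#'   `p_adj`, `median_shift`, `significant`.
#' @export
synergy_by_rank_test <- function(lfc, design, alpha = 0.05,
                                 sko_strategy = c("pooled", "per_gene_min")) {
  sko_strategy <- match.arg(sko_strategy)
  stopifnot(is.data.frame(lfc),
            all(c("array_id", "sample_id", "lfc") %in% names(lfc)),
            inherits(design, "crrna_library"))
  lfc <- tibble::as_tibble(lfc)
  dko <- design[design$category == "DKO", ]
  sko_arrays <- function(gene) design$array_id[design$category == "SKO" &
                                                 design$gene1 == gene]
  rows <- list()
  skipped <- list()
  for (i in seq_len(nrow(dko))) {
    ga <- dko$gene1[i]; gb <- dko$gene2[i]
    xs <- lfc$lfc[lfc$array_id == dko$array_id[i]]
    ya <- lfc$lfc[lfc$array_id %in% sko_arrays(ga)]
    yb <- lfc$lfc[lfc$array_id %in% sko_arrays(gb)]
    if (!length(xs) || !length(ya) || !length(yb)) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(
        gene_a = ga, gene_b = gb, reason = "missing DKO or SKO fold-changes")
      next
    }
    if (sko_strategy == "pooled") {
      wt <- wilcoxon_rank_sum(xs, c(ya, yb))
      shift <- stats::median(xs) - stats::median(c(ya, yb))
    } else {
      wa <- wilcoxon_rank_sum(xs, ya)
      wb <- wilcoxon_rank_sum(xs, yb)
      wt <- if (wa$p <= wb$p) wa else wb
      shift <- stats::median(xs) -
        stats::median(if (wa$p <= wb$p) ya else yb)
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      gene_a = ga, gene_b = gb, w = wt$W, p = wt$p, median_shift = shift)
  }
  if (!length(rows)) abort("No testable pairs.")
  res <- dplyr::bind_rows(rows) %>%
    dplyr::mutate(p_adj = bh_adjust(.data$p),
                  significant = .data$p_adj < alpha) %>%
    dplyr::arrange(.data$p_adj, .data$p) %>%
    dplyr::select("gene_a", "gene_b", "w", "p", "p_adj", "median_shift",
                  "significant")
  new_interaction_calls(
    res, model = "ranksum", alpha = alpha,
    skipped = if (length(skipped)) dplyr::bind_rows(skipped) else NULL)
}

#' Per-entity log2 abundance for the cell-versus-tumour regression
#'
#' Builds the entity table for [regression_cell_vs_tumour()]: one row per
#' DKO pair (its array's abundance) and one per targeting gene (its SKO
#' arrays collapsed with [collapse_sko_per_gene()]), each summarized as the
#' mean `log2(rpm + pseudocount)` over the samples of each condition.
#'
#' @inheritParams median_abundance_summary
#' @param pseudocount_rpm Pseudocount (rpm) stabilizing the log for dropouts.
#' @return A tibble with columns `entity`, `type` (`"DKO"`/`"SKO_gene"`),
#'   `cell`, `tumour`.
#' @export
screen_entity_abundance <- function(rpm, design, cell_samples, tumour_samples,
                                    pseudocount_rpm = 1) {
  stopifnot(is.data.frame(rpm),
            all(c("array_id", "sample_id", "rpm") %in% names(rpm)))
  rpm <- dplyr::mutate(tibble::as_tibble(rpm),
                       log2rpm = log2(.data$rpm + pseudocount_rpm))
  cond_mean <- function(samples, ids) {
    sub <- rpm[rpm$sample_id %in% samples & rpm$array_id %in% ids, ]
    dplyr::summarise(dplyr::group_by(sub, .data$array_id),
                     value = mean(.data$log2rpm), .groups = "drop")
  }
  dko <- design[design$category == "DKO", ]
  dko_tbl <- dplyr::inner_join(
    cond_mean(cell_samples, dko$array_id) %>% dplyr::rename(cell = "value"),
    cond_mean(tumour_samples, dko$array_id) %>% dplyr::rename(tumour = "value"),
    by = "array_id") %>%
    dplyr::rename(entity = "array_id") %>%
    dplyr::mutate(type = "DKO")
  sko_gene <- function(samples) {
    collapse_sko_per_gene(
      rpm[rpm$sample_id %in% samples, ], design,
      statistic = "mean", value_col = "log2rpm") %>%
      dplyr::group_by(.data$gene) %>%
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  }
  sko_tbl <- dplyr::inner_join(
    sko_gene(cell_samples) %>% dplyr::rename(cell = "value"),
    sko_gene(tumour_samples) %>% dplyr::rename(tumour = "value"),
    by = "gene") %>%
    dplyr::rename(entity = "gene") %>%
    dplyr::mutate(type = "SKO_gene")
  dplyr::bind_rows(dko_tbl, sko_tbl)[, c("entity", "type", "cell", "tumour")]
}

#' Outlier screen of tumour versus cell abundance
#'
#' Regresses per-entity tumour abundance on cell abundance (entities are DKO
#' pairs plus collapsed SKO genes on the log2-rpm scale, see
#' [screen_entity_abundance()]) and ranks every entity by its studentized
#' residual; entities falling significantly below the regression line are
#' specifically depleted in tumours.
#'
#' @param entities A tibble with columns `entity`, `cell`, `tumour` (>= 4
#'   rows), e.g. from [screen_entity_abundance()].
#' @return An `outlier_screen` (see [studentized_outlier_test()]) whose
#'   `point_id` column holds the entity ids.
#' @export
regression_cell_vs_tumour <- function(entities) {
  stopifnot(is.data.frame(entities),
            all(c("entity", "cell", "tumour") %in% names(entities)))
  studentized_outlier_test(entities$cell, entities$tumour,
                           point_id = entities$entity)
}
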