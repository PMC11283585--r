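#' Per-sample mean expression of a gene pair
#'
#' Arithmetic mean of the two genes' normalized expression values for each
#' sample of the cohort - the stratification variable of the virtual
#' double-knockdown screen.
#'
#' @param cohort A cohort tibble: columns `sample_id`, `time`, `event` plus
#'   one numeric column per gene (upper-quartile-normalized FPKM semantics).
#' @param gene_a,gene_b Gene column names.
#' @return A tibble with columns `sample_id`, `mean_expr`.
#' @export
pair_mean_expression <- function(cohort, gene_a, gene_b) {
  stopifnot(is.data.frame(cohort))
  missing_g <- setdiff(c(gene_a, gene_b), names(cohort))
  if (length(missing_g)) {
    abort(paste0("Gene(s) not in cohort: ", paste(missing_g, collapse = ", ")))
  }
  tibble::tibble(sample_id = cohort$sample_id,
                 mean_expr = (cohort[[gene_a]] + cohort[[gene_b]]) / 2)
}

#' Quartile stratification into low / high / excluded groups
#'
#' Labels samples at or below the 25th percentile of `values` as `"low"`,
#' at or above the 75th percentile as `"high"`, and everything in between as
#' `"excluded"`. Percentiles use linear interpolation; samples exactly equal
#' to a boundary are included in the corresponding group.
#'
#' @param values Numeric vector (>= 8 values, not constant).
#' @param lower,upper Percentile cutoffs as fractions.
#' @return Character vector of labels `"low"` / `"high"` / `"excluded"`.
#' @examples
#' table(percentile_groups(1:100)) # 25 low, 25 high, 50 excluded
#' @export
percentile_groups <- function(values, lower = 0.25, upper = 0.75) {
  if (length(values) < 8L || any(!is.finite(values))) {
    abort("Need >= 8 finite values to stratify.")
  }
  if (max(values) == min(values)) {
    abort("Constant values; stratification is degenerate.")
  }
  q <- quantile(values, c(lower, upper), names = FALSE)
  ifelse(values <= q[1], "low", ifelse(values >= q[2], "high", "excluded"))
}

#' Kaplan-Meier product-limit survival curve
#'
#' Product-limit estimate of the survival function: right-continuous,
#' starting at S(0) = 1 and dropping only at event times. Computed with
#' [survival::survfit()].
#'
#' @param time Positive survival times.
#' @param event Event indicators (1 = death, 0 = censored).
#' @return A `km_curve`: a tibble with columns `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, with the `survfit` object in attribute `"fit"`.
#' @export
km_curve <- function(time, event) {
  if (!length(time)) abort("Empty survival data.")
  if (any(!is.finite(time)) || any(time <= 0)) {
    abort("All survival times must be positive.")
  }
  if (!all(event %in% c(0, 1))) abort("`event` must be 0/1.")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- tibble::tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, survival = fit$surv)
  structure(out, fit = fit, class = c("km_curve", class(tibble::tibble())))
}

#' Median survival of a Kaplan-Meier curve
#'
#' Smallest time at which the estimated survival drops to 0.5 or below;
#' `NA` when the curve never reaches 0.5.
#'
#' @param curve A `km_curve`.
#' @return A single time (possibly `NA`).
#' @export
km_median <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  idx <- which(curve$survival <= 0.5)
  if (!length(idx)) NA_real_ else curve$time[min(idx)]
}

#' Log-rank (Mantel-Cox) test between two survival groups
#'
#' One-degree-of-freedom log-rank comparison computed with
#' [survival::survdiff()]; the p-value is the upper chi-square tail. When
#' neither group has any event the comparison is degenerate and `chi2 = 0`,
#' `p = 1` are returned with `degenerate = TRUE`.
#'
#' @param time Positive survival times.
#' @param event Event indicators (1 = death, 0 = censored).
#' @param group Two-level group labels.
#' @return A list with `chi2`, `p`, `degenerate`.
#' @export
logrank_p <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) {
    abort("`group` must have exactly two non-empty levels.")
  }
  if (sum(event) == 0) {
    return(list(chi2 = 0, p = 1, degenerate = TRUE))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi2 <- unname(sd_$chisq)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Pair scores from survival p-value ratios
#'
#' Scores a gene pair against each of its genes by the ratio of log-rank
#' p-values, passed through `log1p` (natural log of one plus the ratio).
#' Orientation `"literal"` uses `p_pair / p_single`; `"reciprocal"` (the
#' package default elsewhere) uses `p_single / p_pair`, so that scores above
#' the classification threshold of 1 mark pairs whose joint stratification
#' is more prognostic than either single gene's. A score equals 1 exactly
#' when the ratio is `e - 1`.
#'
#' @param p_pair,p_a,p_b Log-rank p-values in `(0, 1]`.
#' @param orientation `"reciprocal"` or `"literal"`.
#' @return A list with `score_a`, `score_b` (both >= 0).
#' @export
pair_scores <- function(p_pair, p_a, p_b,
                        orientation = c("reciprocal", "literal")) {
  orientation <- match.arg(orientation)
  ps <- c(p_pair, p_a, p_b)
  if (any(!is.finite(ps)) || any(ps <= 0) || any(ps > 1)) {
    abort("All p-values must lie in (0, 1].")
  }
  ratio <- function(px) {
    if (orientation == "literal") p_pair / px else px / p_pair
  }
  list(score_a = log1p(ratio(p_a)), score_b = log1p(ratio(p_b)))
}

single_gene_logrank <- function(cohort, gene) {
  grp <- percentile_groups(cohort[[gene]])
  keep <- grp != "excluded"
  lr <- logrank_p(cohort$time[keep], cohort$event[keep], grp[keep])
  low <- km_curve(cohort$time[keep][grp[keep] == "low"],
                  cohort$event[keep][grp[keep] == "low"])
  high <- km_curve(cohort$time[keep][grp[keep] == "high"],
                   cohort$event[keep][grp[keep] == "high"])
  list(p = max(lr$p, 1e-300), direction = direction_of(low, high))
}

direction_of <- function(low_curve, high_curve) {
  m_low <- km_median(low_curve)
  m_high <- km_median(high_curve)
  if (is.na(m_low) && is.na(m_high)) {
    f_low <- min(low_curve$survival, 1)
    f_high <- min(high_curve$survival, 1)
    if (f_low == f_high) return("tied")
    return(if (f_low > f_high) "low_better" else "high_better")
  }
  if (is.na(m_low)) return("low_better")
  if (is.na(m_high)) return("high_better")
  if (m_low == m_high) return("tied")
  if (m_low > m_high) "low_better" else "high_better"
}

#' Run the virtual double-knockdown survival screen
#'
#' For every gene pair, samples are stratified into bottom- and top-quartile
#' groups of the pair-mean expression and compared by log-rank test; each
#' single gene is stratified and tested the same way. Pair scores are the
#' `log1p` p-value ratios against each gene (see [pair_scores()]), and a
#' pair is classified `"favourable"` when both scores exceed 1 and the
#' low-expression group survives longer, `"unfavourable"` when both scores
#' exceed 1 and the low-expression group survives worse, else `"neutral"`.
#' Pairs with non-finite scores are dropped and recorded in attribute
#' `"skipped"`.
#'
#' @param cohort A cohort tibble (`sample_id`, `time`, `event`, gene
#'   columns), e.g. from [simulate_cohort()]. Samples can be pre-filtered by
#'   `exclude`, the name of a logical column flagging samples to drop
#'   (e.g. viral-etiology exclusions).
#' @param pairs A data frame with columns `gene_a`, `gene_b`; defaults to
#'   all unordered gene pairs in the cohort.
#' @param orientation Score orientation, see [pair_scores()].
#' @param threshold Classification threshold on both scores.
#' @param exclude Optional name of a logical cohort column; flagged samples
#'   are removed before the screen.
#' @return A `pair_screen`: a tibble with columns `gene_a`, `gene_b`,
#'   `p_pair`, `p_a`, `p_b`, `score_a`, `score_b`, `direction`, `class`.
#' @export
run_virtual_screen <- function(cohort, pairs = NULL,
                               orientation = c("reciprocal", "literal"),
                               threshold = 1, exclude = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(is.data.frame(cohort),
            all(c("sample_id", "time", "event") %in% names(cohort)))
  cohort <- tibble::as_tibble(cohort)
  if (!is.null(exclude)) {
    if (!exclude %in% names(cohort) || !is.logical(cohort[[exclude]])) {
      abort("`exclude` must name a logical cohort column.")
    }
    cohort <- cohort[!cohort[[exclude]], ]
  }
  if (nrow(cohort) < 8L) abort("Need >= 8 usable samples.")
  genes_all <- setdiff(names(cohort),
                       c("sample_id", "time", "event", exclude))
  genes_all <- genes_all[vapply(cohort[genes_all], is.numeric, logical(1))]
  if (is.null(pairs)) {
    pairs <- tibble::as_tibble(t(utils::combn(genes_all, 2)),
                               .name_repair = ~c("gene_a", "gene_b"))
  }
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  genes_used <- unique(c(pairs$gene_a, pairs$gene_b))
  missing_g <- setdiff(genes_used, genes_all)
  if (length(missing_g)) {
    abort(paste0("Gene(s) not in cohort: ", paste(missing_g, collapse = ", ")))
  }
  singles <- purrr::map(setNames(genes_used, genes_used),
                        ~single_gene_logrank(cohort, .x))
  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(pairs))) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    me <- pair_mean_expression(cohort, ga, gb)$mean_expr
    res <- tryCatch({
      grp <- percentile_groups(me)
      keep <- grp != "excluded"
      lr <- logrank_p(cohort$time[keep], cohort$event[keep], grp[keep])
      p_pair <- max(lr$p, 1e-300)
      low <- km_curve(cohort$time[keep][grp[keep] == "low"],
                      cohort$event[keep][grp[keep] == "low"])
      high <- km_curve(cohort$time[keep][grp[keep] == "high"],
                       cohort$event[keep][grp[keep] == "high"])
      sc <- pair_scores(p_pair, singles[[ga]]$p, singles[[gb]]$p,
                        orientation = orientation)
      dir <- direction_of(low, high)
      cls <- if (is.finite(sc$score_a) && is.finite(sc$score_b) &&
                 sc$score_a > threshold && sc$score_b > threshold &&
                 dir != "tied") {
        if (dir == "low_better") "favourable" else "unfavourable"
      } else "neutral"
      tibble::tibble(gene_a = ga, gene_b = gb, p_pair = p_pair,
                     p_a = singles[[ga]]$p, p_b = singles[[gb]]$p,
                     score_a = sc$score_a, score_b = sc$score_b,
                     direction = dir, class = cls)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(
        gene_a = ga, gene_b = gb, reason = res)
    } else if (!is.finite(res$score_a) || !is.finite(res$score_b)) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(
        gene_a = ga, gene_b = gb, reason = "removing outlier value")
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows)) abort("No testable pairs.")
  structure(dplyr::bind_rows(rows),
            orientation = orientation, threshold = threshold,
            skipped = if (length(skipped)) dplyr::bind_rows(skipped) else NULL,
            class = c("pair_screen", class(tibble::tibble())))
}
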