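#' Plot methods for pairscreen results
#'
#' `autoplot()` methods returning ggplot objects: expected-vs-observed
#' enrichment (or a rank-sum volcano) for `interaction_calls`, a step
#' survival curve for `km_curve`, the tumour-vs-cell regression with
#' flagged outliers for `outlier_screen`, and the score plane coloured by
#' class for `pair_screen`.
#'
#' @param object A pairscreen result object.
#' @param ... Unused.
#' @return A `ggplot`.
#' @name pairscreen-plots
NULL

#' @rdname pairscreen-plots
#' @method autoplot interaction_calls
#' @export
autoplot.interaction_calls <- function(object, ...) {
  df <- tidy(object)
  df$label <- paste0(df$gene_a, "-", df$gene_b)
  if (attr(object, "model") == "enrichment") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed,
                                     colour = .data$significant)) +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::geom_smooth(ggplot2::aes(group = 1), method = "lm",
                           formula = y ~ x, colour = "grey40",
                           linewidth = 0.4, se = TRUE) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                              `TRUE` = "firebrick")) +
      ggplot2::labs(x = "expected DKO enrichment (additive)",
                    y = "observed DKO enrichment",
                    colour = "outlier (BH p < alpha)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$median_shift,
                                     y = -log10(.data$p_adj),
                                     colour = .data$significant)) +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                              `TRUE` = "firebrick")) +
      ggplot2::labs(x = "median LFC shift (DKO - SKO)",
                    y = "-log10 adjusted p (rank-sum)",
                    colour = "significant") +
      ggplot2::theme_minimal()
  }
}

#' @rdname pairscreen-plots
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    tidy(object)[, c("time", "survival")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' @rdname pairscreen-plots
#' @method autoplot outlier_screen
#' @export
autoplot.outlier_screen <- function(object, ...) {
  df <- tidy(object)
  df$flagged <- df$p_adj < 0.05
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$flagged)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(ggplot2::aes(group = 1), method = "lm",
                         formula = y ~ x, colour = "grey40",
                         linewidth = 0.4, se = TRUE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "cell abundance (log2 rpm)",
                  y = "tumour abundance (log2 rpm)",
                  colour = "outlier (BH p < 0.05)") +
    ggplot2::theme_minimal()
}

#' @rdname pairscreen-plots
#' @method autoplot pair_screen
#' @export
autoplot.pair_screen <- function(object, ...) {
  df <- tidy(object)
  thr <- attr(object, "threshold")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score_a, y = .data$score_b,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::scale_colour_manual(values = c(favourable = "steelblue",
                                            unfavourable = "firebrick",
                                            neutral = "grey60")) +
    ggplot2::labs(x = "score vs gene A", y = "score vs gene B",
                  colour = "class") +
    ggplot2::theme_minimal()
}
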