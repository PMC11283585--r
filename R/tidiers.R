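#' Tidy and glance methods for pairscreen result objects
#'
#' `tidy()` returns the per-point / per-pair result table as a plain tibble;
#' `glance()` returns a one-row summary of the analysis.
#'
#' @param x A result object (`outlier_screen`, `interaction_calls`,
#'   `km_curve` or `pair_screen`).
#' @param ... Unused.
#' @return A tibble.
#' @name pairscreen-tidiers
NULL

strip_tbl <- function(x) {
  out <- tibble::as_tibble(x)
  attributes(out)[setdiff(names(attributes(out)),
                          c("names", "row.names", "class"))] <- NULL
  out
}

#' @rdname pairscreen-tidiers
#' @method tidy outlier_screen
#' @export
tidy.outlier_screen <- function(x, ...) strip_tbl(x)

#' @rdname pairscreen-tidiers
#' @method glance outlier_screen
#' @export
glance.outlier_screen <- function(x, ...) {
  fit <- attr(x, "model")
  s <- summary(fit)
  tibble::tibble(
    n = nrow(x),
    r_squared = s$r.squared,
    sigma = s$sigma,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    n_outliers_05 = sum(x$p_adj < 0.05)
  )
}

#' @rdname pairscreen-tidiers
#' @method tidy interaction_calls
#' @export
tidy.interaction_calls <- function(x, ...) strip_tbl(x)

#' @rdname pairscreen-tidiers
#' @method glance interaction_calls
#' @export
glance.interaction_calls <- function(x, ...) {
  skipped <- attr(x, "skipped")
  tibble::tibble(
    model = attr(x, "model"),
    alpha = attr(x, "alpha"),
    n_pairs = nrow(x),
    n_significant = sum(x$significant),
    n_skipped = if (is.null(skipped)) 0L else nrow(skipped)
  )
}

#' @rdname pairscreen-tidiers
#' @method tidy km_curve
#' @export
tidy.km_curve <- function(x, ...) strip_tbl(x)

#' @rdname pairscreen-tidiers
#' @method glance km_curve
#' @export
glance.km_curve <- function(x, ...) {
  tibble::tibble(
    n = attr(x, "fit")$n,
    n_events = sum(x$n_event),
    median_survival = km_median(x),
    final_survival = min(c(1, x$survival))
  )
}

#' @rdname pairscreen-tidiers
#' @method tidy pair_screen
#' @export
tidy.pair_screen <- function(x, ...) strip_tbl(x)

#' @rdname pairscreen-tidiers
#' @method glance pair_screen
#' @export
glance.pair_screen <- function(x, ...) {
  skipped <- attr(x, "skipped")
  tibble::tibble(
    orientation = attr(x, "orientation"),
    threshold = attr(x, "threshold"),
    n_pairs = nrow(x),
    n_favourable = sum(x$class == "favourable"),
    n_unfavourable = sum(x$class == "unfavourable"),
    n_skipped = if (is.null(skipped)) 0L else nrow(skipped)
  )
}
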