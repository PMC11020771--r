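#' Tukey-fence (boxplot) outlier test
#'
#' A non-parametric outlier test for small samples: values more than
#' `coef` times the interquartile range below the first quartile or above
#' the third quartile are flagged, with the side recorded. Quartiles use
#' linear interpolation between order statistics (`stats::quantile`
#' type 7 by default; configurable because only the 1.5 x IQR rule, not
#' the quartile estimator, is canonical).
#'
#' @param data Data frame with at least a value column and a label column.
#' @param value Column (bare name or string) of the values to test.
#' @param id Column of specimen / taxon labels. Default `specimen_id`.
#' @param variable_id Name recorded for the tested variable; defaults to
#'   the value column name.
#' @param coef Fence multiplier (1.5 = standard Tukey fences).
#' @param quantile_type Quantile algorithm passed to [stats::quantile()].
#' @return An `outlier_report`: list with `variable_id`, `lower_fence`,
#'   `upper_fence`, and `outliers` (tibble of `specimen_id`, `value`,
#'   `side`).
#' @export
#' @examples
#' d <- data.frame(specimen_id = letters[1:5], v = c(1, 2, 3, 4, 100))
#' boxplot_outliers(d, v)$outliers
boxplot_outliers <- function(data, value, id = specimen_id,
                             variable_id = NULL, coef = 1.5,
                             quantile_type = 7) {
  val_q <- enquo(value); id_q <- enquo(id)
  vals <- dplyr::pull(data, !!val_q)
  labs <- as.character(dplyr::pull(data, !!id_q))
  if (is.null(variable_id)) variable_id <- as_name(val_q)
  if (length(vals) < 4) abort("outlier test needs at least 4 values")
  if (anyNA(vals)) abort("outlier test values must not be missing")
  q <- quantile(vals, c(0.25, 0.75), type = quantile_type, names = FALSE)
  iqr <- q[2] - q[1]
  lower <- q[1] - coef * iqr
  upper <- q[2] + coef * iqr
  side <- dplyr::case_when(vals < lower ~ "lower",
                           vals > upper ~ "upper",
                           TRUE ~ NA_character_)
  hit <- !is.na(side)
  structure(
    list(variable_id = variable_id, lower_fence = lower, upper_fence = upper,
         outliers = tibble(specimen_id = labs[hit], value = vals[hit],
                           side = side[hit])),
    class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report '%s'>: fences [%.4g, %.4g], %d outlier(s)\n",
              x$variable_id, x$lower_fence, x$upper_fence, nrow(x$outliers)))
  if (nrow(x$outliers)) print(x$outliers)
  invisible(x)
}

#' @describeIn boxplot_outliers Flat tibble of flagged values with fences.
#' @param x An `outlier_report`.
#' @param ... Unused.
#' @exportS3Method
tidy.outlier_report <- function(x, ...) {
  if (nrow(x$outliers) == 0) {
    return(tibble(variable_id = character(), specimen_id = character(),
                  value = numeric(), side = character(),
                  lower_fence = numeric(), upper_fence = numeric()))
  }
  dplyr::mutate(x$outliers, variable_id = x$variable_id,
                lower_fence = x$lower_fence, upper_fence = x$upper_fence,
                .before = 1)
}

#' Outlier tests across many variables
#'
#' Runs [boxplot_outliers()] on every requested column (e.g. all PC
#' scores) and binds the flagged rows.
#'
#' @param data Data frame with an id column and value columns.
#' @param cols <tidy-select> columns to test.
#' @param id Label column.
#' @inheritParams boxplot_outliers
#' @return Tibble of outliers across variables (possibly empty).
#' @export
outlier_table <- function(data, cols, id = specimen_id, coef = 1.5,
                          quantile_type = 7) {
  id_q <- enquo(id)
  sel <- names(dplyr::select(data, {{ cols }}))
  purrr::map_dfr(sel, function(v) {
    tidy(boxplot_outliers(data, !!rlang::sym(v), id = !!id_q,
                          variable_id = v, coef = coef,
                          quantile_type = quantile_type))
  })
}

#' Ordinary least-squares allometry regression
#'
#' Regresses a response (e.g. a PC score) on a predictor (e.g. centroid
#' size) by OLS with a two-sided t-test on the slope, as used to probe
#' allometric signal in shape components.
#'
#' @param data Data frame.
#' @param response,predictor Columns (bare names or strings).
#' @return One-row tibble: `slope`, `intercept`, `p_value` (slope t-test),
#'   `adj_r_squared`, `n`.
#' @export
regress_allometry <- function(data, response, predictor) {
  y <- dplyr::pull(data, {{ response }})
  x <- dplyr::pull(data, {{ predictor }})
  if (length(y) != length(x)) abort("response and predictor lengths differ")
  if (length(y) < 3) abort("allometry regression needs n >= 3")
  if (isTRUE(all.equal(var(x), 0)) || var(x) == 0) {
    abort("predictor has zero variance")
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  tibble(slope = coef(fit)[["x"]],
         intercept = coef(fit)[["(Intercept)"]],
         p_value = sm$coefficients["x", "Pr(>|t|)"],
         adj_r_squared = sm$adj.r.squared,
         n = length(y))
}
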