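#' Build regression points from a tissue table
#'
#' For each tissue with complete data, pairs the response
#' `ln(risk / n_sc)` with the model predictor: `ln(D t / R)` for the Levy
#' model or `ln(D sqrt(t) / R) - 2 (R / (D sqrt(t)))^2` for the Brownian
#' model, with `t` from [total_generations()] under the chosen time
#' convention. The minimal walk length is taken from the table's `r_walk`
#' where present, else derived as `xbar1 - rn - rt`.
#'
#' @param table A `tissue_table`.
#' @param model `"levy"` or `"brownian"`.
#' @param age Exposure age in years (default 80).
#' @param time_convention `"with-t0"` (default) or `"msc-only"`; see
#'   [total_generations()].
#' @return A tibble with columns `tissue`, `predictor`, `response`, `model`.
#' @export
build_regression <- function(table, model = c("levy", "brownian"), age = 80,
                             time_convention = c("with-t0", "msc-only")) {
  model <- match.arg(model)
  time_convention <- match.arg(time_convention)
  tab <- complete_rows(table)
  if (nrow(tab) < 3) {
    stop("need at least 3 tissues with complete data, got ", nrow(tab))
  }
  r_walk <- ifelse(is.na(tab$r_walk),
                   minimal_walk_length(tab$xbar1, tab$rn, tab$rt),
                   tab$r_walk)
  t <- total_generations(tab$n_sc, tab$m_sc, age, time_convention)
  predictor <- switch(model,
    levy = levy_predictor(tab$d_scale, r_walk, t),
    brownian = brownian_predictor(tab$d_scale, r_walk, t))
  tibble(tissue = tab$tissue,
         predictor = predictor,
         response = log(tab$risk / tab$n_sc),
         model = model)
}

#' Drop tissues from a regression point set
#'
#' @param points Tibble from [build_regression()].
#' @param labels_to_drop Tissue labels to remove; every label must be
#'   present in `points`.
#' @return The remaining points, order preserved.
#' @export
exclude_tissues <- function(points, labels_to_drop) {
  unknown <- setdiff(labels_to_drop, points$tissue)
  if (length(unknown) > 0) {
    stop("unknown tissue label(s): ", paste(unknown, collapse = ", "))
  }
  points[!points$tissue %in% labels_to_drop, , drop = FALSE]
}

#' Ordinary least-squares line through regression points
#'
#' Unweighted OLS of `response` on `predictor` via [stats::lm()], with the
#' Pearson correlation of the point set and the two-sided p-value of the
#' slope t-test (emitted only for `n >= 3`). An optional `weights` vector
#' (e.g. `1 / sigma^2` with `sigma = dev / risk`, the log-scale risk
#' uncertainty) gives a weighted variant for error-bar-aware exploration;
#' the unweighted fit is the canonical one.
#'
#' For the Levy model the intercept estimates the log of the effective jump
#' rate times normalization and should be negative; a positive intercept is
#' reported as a diagnostic (`intercept_negative = FALSE`), not an error.
#'
#' @param points Tibble with `predictor` and `response` columns (and
#'   optionally `tissue`, `model`).
#' @param weights Optional nonnegative OLS weights.
#' @return A `risk_fit`: list with `model`, `tissues_used`, `slope`,
#'   `intercept`, `pearson_r`, `r_squared`, `p_value`, `n`,
#'   `intercept_negative`, `points`.
#' @export
fit_line <- function(points, weights = NULL) {
  n <- nrow(points)
  if (n < 2) stop("need at least 2 points")
  if (var(points$predictor) == 0) {
    stop("zero predictor variance: all predictors equal")
  }
  fit <- lm(response ~ predictor, data = points, weights = weights)
  coefs <- coef(fit)
  r <- cor(points$predictor, points$response)
  p_value <- if (n >= 3) summary(fit)$coefficients["predictor", 4] else NA_real_
  structure(list(
    model = if ("model" %in% names(points)) points$model[1] else NA_character_,
    tissues_used = if ("tissue" %in% names(points)) points$tissue else NULL,
    slope = unname(coefs["predictor"]),
    intercept = unname(coefs["(Intercept)"]),
    pearson_r = r,
    r_squared = r^2,
    p_value = unname(p_value),
    n = n,
    intercept_negative = unname(coefs["(Intercept)"] < 0),
    points = points
  ), class = "risk_fit")
}

#' Fit a risk model to a tissue table
#'
#' Convenience wrapper: [build_regression()], optional [exclude_tissues()],
#' then [fit_line()]. With the packaged [tissue_parameters()] table this
#' reproduces the headline contrast between the two regimes: the Levy fit
#' has slope near one (0.82) while the Brownian fit is nearly flat
#' (slope ~ 2e-5), so rare large jumps — not small-amplitude expression
#' noise — carry the risk signal.
#'
#' @inheritParams build_regression
#' @param exclude Optional tissue labels to leave out of the fit.
#' @param weights Optional OLS weights, see [fit_line()].
#' @return A `risk_fit`.
#' @examples
#' fit_risk_model(tissue_parameters(), "levy")$slope
#' fit_risk_model(tissue_parameters(), "brownian", exclude = c("LUAD", "THCA"))
#' @export
fit_risk_model <- function(table, model = c("levy", "brownian"), age = 80,
                           time_convention = c("with-t0", "msc-only"),
                           exclude = NULL, weights = NULL) {
  points <- build_regression(table, model, age, time_convention)
  if (!is.null(exclude)) points <- exclude_tissues(points, exclude)
  fit_line(points, weights = weights)
}

#' @export
print.risk_fit <- function(x, ...) {
  cat("<risk_fit> ", x$model, " model, n = ", x$n, "\n", sep = "")
  cat(sprintf("  slope = %.4g, intercept = %.4g%s\n", x$slope, x$intercept,
              if (isTRUE(x$intercept_negative)) "" else
                " [diagnostic: intercept not negative]"))
  cat(sprintf("  pearson_r = %.3f, r_squared = %.3f, p = %.3g\n",
              x$pearson_r, x$r_squared, x$p_value))
  invisible(x)
}
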