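#' Model parameters for one tissue
#'
#' Validated container for the quantities entering the risk formulas: the
#' per-generation fluctuation scale `d_scale` (D), the minimal walk length
#' `r_walk` (R, in PC1 units), the stem-cell count `n_sc`, the yearly
#' turnover rate `m_sc`, the exposure `age` (years, default 80), the Pareto
#' tail exponent `nu` (default 2, the value suggested by the expression
#' distribution tails), the per-generation large-jump rate `mu` (usually
#' unknown and absorbed into the regression constant; optional), and the
#' reference rate `a_ref` (default 2e-14 per generation) used by the extra
#' risk score.
#'
#' The tail formulas assume `r_walk` sits deep in the jump-size tail; a
#' warning is raised when `r_walk / d_scale <= 10`.
#'
#' @param d_scale,r_walk,n_sc,m_sc,age,nu,mu,a_ref See description.
#' @return A `model_params` list.
#' @export
model_params <- function(d_scale, r_walk, n_sc, m_sc, age = 80, nu = 2,
                         mu = NULL, a_ref = 2e-14) {
  stopifnot(d_scale > 0, r_walk > 0, n_sc >= 1, m_sc >= 0, age >= 0,
            nu > 1, a_ref > 0)
  if (!is.null(mu)) stopifnot(mu >= 0)
  if (r_walk / d_scale <= 10) {
    warning("r_walk / d_scale = ", format(r_walk / d_scale, digits = 3),
            " <= 10: the tail approximation for large jumps may be poor")
  }
  structure(list(d_scale = d_scale, r_walk = r_walk, n_sc = n_sc,
                 m_sc = m_sc, age = age, nu = nu, mu = mu, a_ref = a_ref),
            class = "model_params")
}

#' Developmental time in stem-cell generations
#'
#' `t0 = log2(n_sc)` is the number of doubling generations needed to grow a
#' tissue of `n_sc` stem cells from a single cell — the moment the tissue is
#' formed. Returned continuous (e.g. 27.57 for 2e8 cells); round or floor
#' for display.
#'
#' @param n_sc Stem-cell count, `>= 1`.
#' @return `log2(n_sc)`.
#' @export
t0_generations <- function(n_sc) {
  if (any(n_sc < 1)) stop("n_sc must be >= 1")
  log2(n_sc)
}

#' Total elapsed stem-cell generations
#'
#' `t = t0 + m_sc * age`: development plus lifetime turnover. The `t0` term
#' matters in tissues with slow renewal but many stem cells (in lung,
#' `t0 ~ 30` while `m_sc * 80` is only 5.6). Setting
#' `time_convention = "msc-only"` drops `t0` and uses lifetime turnover
#' alone.
#'
#' @param n_sc Stem-cell count.
#' @param m_sc Turnover rate (1/year).
#' @param age Age in years (default 80).
#' @param time_convention `"with-t0"` (default) or `"msc-only"`.
#' @return Elapsed generations.
#' @export
total_generations <- function(n_sc, m_sc, age = 80,
                              time_convention = c("with-t0", "msc-only")) {
  time_convention <- match.arg(time_convention)
  if (any(age < 0)) stop("age must be >= 0")
  if (any(m_sc < 0)) stop("m_sc must be >= 0")
  t0 <- if (time_convention == "with-t0") t0_generations(n_sc) else 0
  t0 + m_sc * age
}

#' Minimal walk length between the normal and tumor clouds
#'
#' `R = xbar1 - rn - rt`: the shortest PC1 distance a microstate must travel
#' from the edge of the normal cloud to the edge of the tumor cloud.
#'
#' @param xbar1 Tumor-cloud center along PC1.
#' @param rn,rt r.m.s. radii of the normal and tumor clouds.
#' @return The walk length, in PC1 units.
#' @export
minimal_walk_length <- function(xbar1, rn, rt) {
  stopifnot(all(xbar1 > 0), all(rn > 0), all(rt > 0))
  r <- xbar1 - rn - rt
  if (any(r <= 0)) stop("clouds overlap: xbar1 - rn - rt <= 0")
  r
}

#' Gaussian density parameter of the small-step walk
#'
#' After `t` generations of bounded steps of scale D the displacement is
#' approximately Gaussian with density `sqrt(a/pi) exp(-a x^2)` where
#' `a = 2 / (D^2 t)` (variance `D^2 t / 4`).
#'
#' @param d_scale Fluctuation scale D.
#' @param t Elapsed generations, `> 0`.
#' @return The parameter `a`.
#' @export
brownian_density_param <- function(d_scale, t) {
  stopifnot(all(d_scale > 0))
  if (any(t <= 0)) stop("t must be > 0")
  2 / (d_scale^2 * t)
}

#' Log of the complementary error function, underflow-free
#'
#' `ln Erfc(z)` computed on the log scale for any `z >= 0`: the exact value
#' via the log-scale normal tail for `z <= 25`, and the large-`z` asymptotic
#' expansion `-z^2 - ln(sqrt(pi) z) + ln(1 - 1/(2 z^2) + 3/(4 z^4))` beyond,
#' so the deep-tail regime (z of order 10^2 and far beyond, where Erfc
#' underflows to 0 in double precision) stays finite. The two branches agree
#' to better than 1e-10 relative at the switch.
#'
#' @param z Nonnegative argument.
#' @return `log(erfc(z))`, finite for all finite `z`.
#' @export
ln_erfc <- function(z) {
  stopifnot(all(z >= 0))
  out <- numeric(length(z))
  small <- z <= 25
  # erfc(z) = 2 * Phi(-z * sqrt(2))
  out[small] <- log(2) + pnorm(z[small] * sqrt(2), lower.tail = FALSE,
                               log.p = TRUE)
  if (any(!small)) {
    zz <- z[!small]
    out[!small] <- -zz^2 - log(sqrt(pi) * zz) +
      log1p(-1 / (2 * zz^2) + 3 / (4 * zz^4))
  }
  out
}

#' Log-scale Brownian escape probability
#'
#' The probability that `t` generations of small-step diffusion carry a
#' microstate across the minimal walk length R is `Erfc(z)` with
#' `z = sqrt(2/t) R / D`. For realistic tissues z is huge (COAD at a
#' lifetime's generations has z ~ 40, escape probability ~ e^-1650), so the
#' value is returned as a log probability via [ln_erfc()].
#'
#' @param d_scale Fluctuation scale D.
#' @param r_walk Minimal walk length R (0 allowed: escape is certain).
#' @param t Elapsed generations.
#' @return `log` of the escape probability (`<= 0`).
#' @export
brownian_escape_log_probability <- function(d_scale, r_walk, t) {
  stopifnot(all(d_scale > 0), all(r_walk >= 0), all(t > 0))
  z <- sqrt(2 / t) * r_walk / d_scale
  ln_erfc(z)
}

#' Brownian (small-step) risk predictor
#'
#' The regressor of the small-step model:
#' `ln(D sqrt(t) / R) - 2 (R / (D sqrt(t)))^2`, against which
#' `ln(risk / N_sc)` should be linear with slope near one if small
#' gene-expression fluctuations drove carcinogenesis. On real tissue
#' parameters it is dominated by the exponential-suppression term and the
#' fitted slope is tiny — diffusion alone cannot reach the tumor cloud.
#'
#' @inheritParams brownian_escape_log_probability
#' @return Predictor value(s).
#' @export
brownian_predictor <- function(d_scale, r_walk, t) {
  stopifnot(all(d_scale > 0), all(r_walk > 0), all(t > 0))
  ratio <- d_scale * sqrt(t) / r_walk
  log(ratio) - 2 / ratio^2
}

#' Single-jump tail probability of the Levy model
#'
#' Probability that one Pareto-tailed jump of scale D and exponent `nu`
#' reaches at least R: `(D / R)^(nu - 1)` (the survival function of a Pareto
#' with minimum D). At `nu = 2` this is exactly `D / R`. The overall
#' normalization of the unscaled tail integral is absorbed into the
#' effective jump rate.
#'
#' @param d_scale Jump scale D.
#' @param r_walk Threshold R, `>= d_scale`.
#' @param nu Pareto exponent, `> 1`.
#' @return Exceedance probability in (0, 1].
#' @export
levy_tail_probability <- function(d_scale, r_walk, nu = 2) {
  if (any(nu <= 1)) stop("nu must be > 1 for the tail integral to converge")
  stopifnot(all(d_scale > 0), all(r_walk >= d_scale))
  (d_scale / r_walk)^(nu - 1)
}

#' Levy (large-jump) risk predictor
#'
#' The regressor of the rare-jump model at `nu = 2`: `ln(D t / R)`, against
#' which `ln(risk / N_sc)` is expected to be linear with slope near one and
#' a negative constant (the log of the small effective jump rate).
#'
#' @inheritParams brownian_escape_log_probability
#' @return Predictor value(s).
#' @export
levy_predictor <- function(d_scale, r_walk, t) {
  stopifnot(all(d_scale > 0), all(r_walk > 0), all(t > 0))
  log(d_scale * t / r_walk)
}

#' Absolute Levy-model risk estimate
#'
#' `risk = N_sc * mu * (D/R)^(nu-1) * t` with `t = t0 + m_sc * age`: the
#' expected number of stem-cell lineages hit by a jump that clears the
#' normal-to-tumor gap. Requires the effective jump rate `mu` in `params`
#' (it is not identifiable from a single tissue and is usually fitted or
#' supplied). The linear estimate is clamped to `[0, 1]` with a warning.
#'
#' @param params A [model_params()] with `mu` set.
#' @param time_convention Passed to [total_generations()].
#' @return Estimated lifetime risk in `[0, 1]`.
#' @export
levy_risk <- function(params, time_convention = c("with-t0", "msc-only")) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(params$mu)) {
    stop("mu is not set: fit or supply an effective jump rate mu")
  }
  t <- total_generations(params$n_sc, params$m_sc, params$age,
                         match.arg(time_convention))
  risk <- params$n_sc * params$mu *
    levy_tail_probability(params$d_scale, params$r_walk, params$nu) * t
  if (risk > 1) {
    warning("linear risk estimate ", format(risk, digits = 3),
            " clamped to 1")
    risk <- 1
  }
  risk
}

#' Extra risk score (ERS)
#'
#' Rescales an observed lifetime risk by the number of stem-cell generations:
#' `ERS = (risk / n_sc) / (a_ref * (t0 + m_sc * age))`. With the reference
#' rate `a_ref = 2e-14` per generation, tissues whose risk is explained by
#' baseline replication noise fall in the band `1 < ERS < 6`; strong
#' deviations flag tissue-specific enhancement (viral, genetic, external) or
#' suppression (immune) of the effective jump rate.
#'
#' @param risk Observed lifetime risk in (0, 1).
#' @param n_sc Stem-cell count.
#' @param m_sc Turnover rate (1/year).
#' @param age Age in years (default 80).
#' @param a_ref Reference rate per generation (default 2e-14).
#' @return The dimensionless score.
#' @seealso [ers_in_normal_band()]
#' @export
ers_score <- function(risk, n_sc, m_sc, age = 80, a_ref = 2e-14) {
  stopifnot(all(risk > 0), all(risk < 1), all(n_sc >= 1), all(m_sc >= 0),
            all(a_ref > 0))
  t <- t0_generations(n_sc) + m_sc * age
  (risk / n_sc) / (a_ref * t)
}

#' Is an ERS value in the baseline band?
#'
#' The band `1 < ERS < 6` contains the tissues whose lifetime risk is
#' compatible with baseline replication-driven jump rates.
#'
#' @param ers Score(s) from [ers_score()].
#' @return Logical vector.
#' @export
ers_in_normal_band <- function(ers) {
  ers > 1 & ers < 6
}
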