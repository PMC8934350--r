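#' Simulation configuration
#'
#' Parameters of the discrete-time microstate walk: per generation every
#' walker takes a small uniform step `D * r`, `r ~ U(-1, 1)`, and with
#' probability `mu` additionally a Pareto-tailed jump of scale `D` and tail
#' exponent `nu` (survival `(D/x)^(nu-1)` for `x >= D`), signed per
#' `jump_symmetry`. A walker is absorbed the first generation its position
#' reaches the boundary `r_walk`.
#'
#' @param d_scale Small-step scale D, `>= 0`.
#' @param r_walk Absorbing-boundary distance R, `> 0`.
#' @param mu Per-generation jump probability in `[0, 1]`.
#' @param nu Pareto exponent, `> 1`.
#' @param n_walkers Ensemble size, `>= 1`.
#' @param n_generations Time horizon in generations, `>= 1`.
#' @param seed RNG seed (integer); recorded in the output.
#' @param jump_symmetry `"two-sided"` (default; sign +/- with probability
#'   1/2) or `"positive-only"`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(d_scale, r_walk, mu = 0, nu = 2, n_walkers,
                       n_generations, seed = 1L,
                       jump_symmetry = c("two-sided", "positive-only")) {
  jump_symmetry <- match.arg(jump_symmetry)
  stopifnot(d_scale >= 0, r_walk > 0, mu >= 0, mu <= 1, nu > 1,
            n_walkers >= 1, n_generations >= 1)
  structure(list(d_scale = d_scale, r_walk = r_walk, mu = mu, nu = nu,
                 n_walkers = as.integer(n_walkers),
                 n_generations = as.integer(n_generations),
                 seed = as.integer(seed), jump_symmetry = jump_symmetry),
            class = "sim_config")
}

#' Small-step substep
#'
#' Adds one bounded uniform displacement `D * r`, `r ~ U(-1, 1)`, to each
#' position. Per-step mean 0, variance `D^2 / 3`, support `(-D, D)`.
#'
#' @param x1 Numeric vector of positions.
#' @param d_scale Step scale D.
#' @return Updated positions.
#' @export
step_small <- function(x1, d_scale) {
  x1 + d_scale * runif(length(x1), -1, 1)
}

#' Levy-jump substep
#'
#' With probability `mu` per walker, adds a jump whose magnitude is drawn
#' from a Pareto distribution with minimum `d_scale` and exponent `nu`
#' (inverse-CDF: `d_scale * u^(-1/(nu-1))`, `u ~ U(0,1)`), with sign +/-
#' equiprobable under `"two-sided"` symmetry or always + under
#' `"positive-only"`. At `nu = 2` the median jump magnitude is `2 D` and
#' `P(magnitude >= R | jump) = D / R`.
#'
#' @param x1 Numeric vector of positions.
#' @param mu Per-generation jump probability.
#' @param nu Pareto exponent, `> 1`.
#' @param d_scale Jump scale (Pareto minimum).
#' @param jump_symmetry `"two-sided"` or `"positive-only"`.
#' @return Updated positions.
#' @export
step_levy <- function(x1, mu, nu, d_scale,
                      jump_symmetry = c("two-sided", "positive-only")) {
  jump_symmetry <- match.arg(jump_symmetry)
  if (mu == 0) return(x1)
  n <- length(x1)
  jumps <- runif(n) < mu
  nj <- sum(jumps)
  if (nj == 0) return(x1)
  mag <- d_scale * runif(nj)^(-1 / (nu - 1))
  sign <- if (jump_symmetry == "two-sided") {
    ifelse(runif(nj) < 0.5, -1, 1)
  } else {
    rep(1, nj)
  }
  x1[jumps] <- x1[jumps] + sign * mag
  x1
}

#' Run a walker ensemble to first passage
#'
#' All walkers start at the origin (the normal-cloud center). Each
#' generation applies the small-step substep then the jump substep; a walker
#' whose position reaches `r_walk` is absorbed (counted escaped, recorded
#' with its 0-based generation index) and stops evolving. Identical
#' config + seed reproduce the summary exactly.
#'
#' @param config A [sim_config()].
#' @return A `trajectory_ensemble_summary`: list with `n_escaped`,
#'   `escape_fraction`, `mean_displacement` and `displacement_variance`
#'   (over surviving walkers at the horizon), `first_passage_times`
#'   (0-based generation indices, one per escaped walker), `config`.
#' @examples
#' cfg <- sim_config(d_scale = 1, r_walk = 100, mu = 1e-3, nu = 2,
#'                   n_walkers = 1000, n_generations = 200, seed = 7)
#' run_ensemble(cfg)$escape_fraction
#' @export
run_ensemble <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_walkers
  x <- numeric(n)
  alive <- rep(TRUE, n)
  fpt <- rep(NA_integer_, n)
  for (gen in seq_len(config$n_generations)) {
    idx <- which(alive)
    if (length(idx) == 0) break
    xi <- step_small(x[idx], config$d_scale)
    xi <- step_levy(xi, config$mu, config$nu, config$d_scale,
                    config$jump_symmetry)
    x[idx] <- xi
    escaped <- idx[xi >= config$r_walk]
    if (length(escaped) > 0) {
      alive[escaped] <- FALSE
      fpt[escaped] <- gen - 1L
    }
  }
  survivors <- x[alive]
  structure(list(
    n_escaped = sum(!alive),
    escape_fraction = sum(!alive) / n,
    mean_displacement = if (length(survivors) > 0) mean(survivors) else NA_real_,
    displacement_variance = if (length(survivors) > 1) {
      mean((survivors - mean(survivors))^2)
    } else NA_real_,
    first_passage_times = sort(fpt[!is.na(fpt)]),
    config = config
  ), class = "trajectory_ensemble_summary")
}

#' @export
print.trajectory_ensemble_summary <- function(x, ...) {
  cfg <- x$config
  cat("<trajectory_ensemble_summary> ", cfg$n_walkers, " walkers x ",
      cfg$n_generations, " generations (seed ", cfg$seed, ")\n", sep = "")
  cat(sprintf("  escaped: %d (fraction %.3g)\n", x$n_escaped,
              x$escape_fraction))
  cat(sprintf("  survivors: mean displacement %.3g, variance %.3g\n",
              x$mean_displacement, x$displacement_variance))
  invisible(x)
}
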