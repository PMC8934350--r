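#' Specification of a synthetic two-cloud expression cohort
#'
#' Describes a cohort emulating the geometry the model rests on: a normal
#' cloud centered at the origin of log2 fold-change space and a tumor cloud
#' displaced by `planted_xbar1` along a planted unit direction, with
#' along-axis r.m.s. radii `planted_rn` and `planted_rt` and isotropic
#' off-axis scatter `noise_sd_per_gene`. An optional fraction of genes gets
#' symmetric Pareto-tailed noise (tail exponent 3) to mimic the heavy tails
#' of real expression distributions, and `zero_fraction` injects zero
#' expression values to exercise pseudocount handling.
#'
#' @param n_genes,n_normal,n_tumor Dimensions; at least 2 samples per class.
#' @param planted_direction `"random"` (default) or a numeric vector over
#'   genes (normalized internally).
#' @param planted_xbar1,planted_rn,planted_rt Planted tumor center and cloud
#'   radii along the direction; clouds must be separated
#'   (`planted_xbar1 > planted_rn + planted_rt`).
#' @param noise_sd_per_gene Isotropic per-gene log2-space noise s.d.
#'   (default 1); must not exceed the planted radii.
#' @param heavy_tail_fraction Fraction of genes with Pareto-tailed noise
#'   (default 0).
#' @param zero_fraction Fraction of expression entries forced to zero
#'   (default 0).
#' @param seed RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_genes, n_normal, n_tumor,
                        planted_direction = "random",
                        planted_xbar1, planted_rn, planted_rt,
                        noise_sd_per_gene = 1, heavy_tail_fraction = 0,
                        zero_fraction = 0, seed = 1L) {
  stopifnot(n_genes >= 2, n_normal >= 2, n_tumor >= 2,
            planted_xbar1 > 0, planted_rn >= 0, planted_rt >= 0,
            noise_sd_per_gene >= 0,
            heavy_tail_fraction >= 0, heavy_tail_fraction <= 1,
            zero_fraction >= 0, zero_fraction < 1)
  if (planted_xbar1 <= planted_rn + planted_rt) {
    stop("clouds overlap: need planted_xbar1 > planted_rn + planted_rt")
  }
  if (noise_sd_per_gene > min(planted_rn, planted_rt)) {
    stop("noise_sd_per_gene must not exceed the planted radii")
  }
  if (is.numeric(planted_direction)) {
    if (length(planted_direction) != n_genes) {
      stop("planted_direction must have one component per gene")
    }
    planted_direction <- planted_direction / sqrt(sum(planted_direction^2))
  } else if (!identical(planted_direction, "random")) {
    stop("planted_direction must be 'random' or a numeric vector")
  }
  structure(list(n_genes = n_genes, n_normal = n_normal, n_tumor = n_tumor,
                 planted_direction = planted_direction,
                 planted_xbar1 = planted_xbar1, planted_rn = planted_rn,
                 planted_rt = planted_rt,
                 noise_sd_per_gene = noise_sd_per_gene,
                 heavy_tail_fraction = heavy_tail_fraction,
                 zero_fraction = zero_fraction, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic expression cohort
#'
#' Draws log2 fold-change coordinates per the planted geometry of
#' [cohort_spec()], then maps them to positive expression values
#' `e = e_ref * 2^ehat` with lognormal per-gene reference levels, so the
#' geometric-mean reference of the geometry stage is well defined by
#' construction. Along the planted direction the total variance is topped
#' up to exactly `planted_rn^2` (normals) / `planted_rt^2` (tumors), so the
#' planted radii are the population values [ge_geometry()] estimates.
#' Reproducible by `seed`.
#'
#' @param spec A [cohort_spec()].
#' @return An [expression_cohort()] with the realized unit direction
#'   attached as attribute `"planted_direction"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  g <- spec$n_genes
  n_samples <- spec$n_normal + spec$n_tumor
  labels <- rep(c("normal", "tumor"), c(spec$n_normal, spec$n_tumor))

  u <- spec$planted_direction
  if (identical(u, "random")) {
    u <- rnorm(g)
    u <- u / sqrt(sum(u^2))
  }

  sd0 <- spec$noise_sd_per_gene
  ehat <- matrix(rnorm(g * n_samples, sd = sd0), nrow = g)
  n_heavy <- round(spec$heavy_tail_fraction * g)
  if (n_heavy > 0) {
    heavy <- sample.int(g, n_heavy)
    n_draw <- n_heavy * n_samples
    mag <- sd0 * runif(n_draw)^(-1 / 2)  # Pareto tail, exponent 3
    ehat[heavy, ] <- sample(c(-1, 1), n_draw, replace = TRUE) * mag
  }

  # top up the along-axis variance to the planted radii and add the shift
  extra_n <- sqrt(max(spec$planted_rn^2 - sd0^2, 0))
  extra_t <- sqrt(max(spec$planted_rt^2 - sd0^2, 0))
  along_n <- rnorm(spec$n_normal, 0, extra_n)
  along_n <- along_n - mean(along_n)   # planted offset is exact in-sample
  along <- c(along_n, spec$planted_xbar1 + rnorm(spec$n_tumor, 0, extra_t))
  ehat <- ehat + u %o% along
  # plant the normal-cloud center exactly at the origin: the geometry stage
  # defines the origin as the (geometric-mean) normal center, so aligning
  # them here removes an O(rn / sqrt(n_normal)) offset from every summary
  ehat <- ehat - rowMeans(ehat[, seq_len(spec$n_normal), drop = FALSE])

  e_ref <- exp(rnorm(g, mean = 5, sd = 1))
  values <- e_ref * 2^ehat
  if (spec$zero_fraction > 0) {
    nz <- round(spec$zero_fraction * length(values))
    values[sample.int(length(values), nz)] <- 0
  }
  cohort <- expression_cohort(values, labels)
  attr(cohort, "planted_direction") <- u
  cohort
}

#' Specification of a synthetic tissue table with a planted risk law
#'
#' Describes a randomized tissue table whose risks obey the large-jump law
#' exactly up to Gaussian scatter:
#' `ln(risk / n_sc) = intercept_true + slope_true * ln(D t / R) + N(0,
#' scatter_sd)` with `t = log2(n_sc) + m_sc * 80`. Used for end-to-end
#' recovery tests of the regression stage.
#'
#' @param n_tissues Number of rows, `>= 2`.
#' @param slope_true Planted slope (default 1).
#' @param intercept_true Planted intercept, `< 0` (default -26; the
#'   intercept is the log of a small effective jump rate times
#'   normalization, hence negative).
#' @param scatter_sd Response noise s.d. (default 0.5).
#' @param d_range,r_range Uniform ranges for the fluctuation scale and walk
#'   length (defaults 0.04-0.08 and 25-150, the span of observed tissues).
#' @param n_sc_range,m_sc_range Log-uniform ranges for stem-cell count and
#'   turnover rate (defaults 1e7-3e9 and 0.05-80).
#' @param seed RNG seed.
#' @return A `planted_table_spec` list.
#' @export
planted_table_spec <- function(n_tissues, slope_true = 1,
                               intercept_true = -26, scatter_sd = 0.5,
                               d_range = c(0.04, 0.08),
                               r_range = c(25, 150),
                               n_sc_range = c(1e7, 3e9),
                               m_sc_range = c(0.05, 80), seed = 1L) {
  stopifnot(n_tissues >= 2, intercept_true < 0, scatter_sd >= 0,
            all(d_range > 0), all(r_range > 0), all(n_sc_range >= 1),
            all(m_sc_range > 0), diff(d_range) >= 0, diff(r_range) >= 0,
            diff(n_sc_range) >= 0, diff(m_sc_range) >= 0)
  structure(list(n_tissues = as.integer(n_tissues), slope_true = slope_true,
                 intercept_true = intercept_true, scatter_sd = scatter_sd,
                 d_range = d_range, r_range = r_range,
                 n_sc_range = n_sc_range, m_sc_range = m_sc_range,
                 seed = as.integer(seed)),
            class = "planted_table_spec")
}

#' Generate a tissue table with a planted risk law
#'
#' Draws per-tissue parameters from the spec's ranges, builds a consistent
#' geometry (`xbar1 = r_walk + rn + rt`), and sets the lifetime risk by the
#' planted law of [planted_table_spec()]. Risks that would reach 1 are
#' clamped just below with a warning. Reproducible by `seed`.
#'
#' @param spec A [planted_table_spec()].
#' @return A `tissue_table` with all optional columns filled.
#' @export
generate_planted_table <- function(spec) {
  stopifnot(inherits(spec, "planted_table_spec"))
  set.seed(spec$seed)
  n <- spec$n_tissues
  runif_log <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))
  d_scale <- runif(n, spec$d_range[1], spec$d_range[2])
  r_walk <- runif(n, spec$r_range[1], spec$r_range[2])
  n_sc <- runif_log(n, spec$n_sc_range)
  m_sc <- runif_log(n, spec$m_sc_range)
  rn <- runif(n, 10, 40)
  rt <- runif(n, 20, 45)

  t <- log2(n_sc) + m_sc * 80
  response <- spec$intercept_true + spec$slope_true * log(d_scale * t / r_walk) +
    rnorm(n, 0, spec$scatter_sd)
  risk <- n_sc * exp(response)
  if (any(risk >= 1)) {
    warning(sum(risk >= 1), " planted risk value(s) clamped below 1")
    risk <- pmin(risk, 1 - 1e-9)
  }
  tab <- tibble(
    tissue = sprintf("T%02d", seq_len(n)),
    xbar1 = r_walk + rn + rt,
    rn = rn,
    rt = rt,
    r_walk = r_walk,
    d_scale = d_scale,
    n_sc = n_sc,
    m_sc = m_sc,
    risk = risk,
    dev = 0.2 * risk
  )
  new_tissue_table(tab, provenance = "synthetic planted table")
}
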