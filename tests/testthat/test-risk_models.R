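# COAD parameters used repeatedly below
coad <- list(d = 0.0526, r = 115.65, n_sc = 2e8, m_sc = 73, risk = 0.04264)
coad$t <- log2(coad$n_sc) + coad$m_sc * 80   # 5867.58 generations

test_that("time scales follow t = log2(n_sc) + m_sc * age", {
  expect_equal(t0_generations(2), 1)
  expect_equal(floor(t0_generations(2e8)), 27)
  expect_equal(round(t0_generations(1.22e9)), 30)
  expect_equal(t0_generations(2e8), 27.5754, tolerance = 1e-4)

  expect_equal(0.07 * 80, 5.6)  # lung lifetime turnover is tiny next to t0
  expect_equal(total_generations(1.22e9, 0.07, 80),
               log2(1.22e9) + 5.6)
  expect_equal(total_generations(2e8, 73, 80), 5867.575, tolerance = 1e-3)
  expect_equal(total_generations(2e8, 73, 0), t0_generations(2e8))
  expect_equal(total_generations(2e8, 73, 80, "msc-only"), 5840)

  expect_error(t0_generations(0.5), "n_sc")
  expect_error(total_generations(2e8, 73, -1), "age")
})

test_that("minimal walk length is the gap between cloud edges", {
  expect_equal(minimal_walk_length(155.89, 11.71, 28.53), 115.65)
  expect_equal(minimal_walk_length(137.37, 20.97, 31.66), 84.74)
  expect_equal(minimal_walk_length(100, 0.1, 0.1), 99.8)
  expect_error(minimal_walk_length(30, 20, 15), "overlap")
})

test_that("the Gaussian density parameter is a = 2 / (D^2 t)", {
  expect_equal(brownian_density_param(1, 2), 1)
  expect_equal(brownian_density_param(coad$d, coad$t), 0.1232,
               tolerance = 1e-3)
  # identity a * D^2 t = 2 on a grid
  d <- c(0.01, 0.05, 1, 3)
  t <- c(10, 5867.58, 1e6, 2)
  expect_equal(brownian_density_param(d, t) * d^2 * t, rep(2, 4))
  expect_error(brownian_density_param(1, 0), "t must be")
})

test_that("ln Erfc matches a quadrature oracle over z in [0, 30]", {
  z <- seq(0, 30, by = 0.5)
  got <- ln_erfc(z)
  want <- ln_erfc_quadrature(z)
  expect_lt(max(abs(got - want) / pmax(abs(want), 1)), 1e-8)
  expect_equal(ln_erfc(0), 0)
  expect_true(all(got <= 0))
})

test_that("the asymptotic branch joins the exact branch continuously", {
  z <- 25
  exact <- log(2) + pnorm(z * sqrt(2), lower.tail = FALSE, log.p = TRUE)
  asym <- -z^2 - log(sqrt(pi) * z) + log1p(-1 / (2 * z^2) + 3 / (4 * z^4))
  expect_lt(abs(exact - asym) / abs(exact), 1e-10)
  # leading-order asymptotic is already within 2% at z = 5
  expect_lt(abs(ln_erfc(5) - (-25 - log(sqrt(pi) * 5))) / abs(ln_erfc(5)),
            0.02)
  # deep-tail values stay finite
  expect_true(is.finite(ln_erfc(1e3)))
})

test_that("Brownian escape probability behaves as a first-passage bound", {
  expect_equal(brownian_escape_log_probability(1, 0, 10), 0)  # Erfc(0) = 1
  # COAD at lifetime generations: z ~ 40.6, deep underflow but finite
  lp <- brownian_escape_log_probability(coad$d, coad$r, coad$t)
  z <- sqrt(2 / coad$t) * coad$r / coad$d
  expect_equal(z, 40.58, tolerance = 1e-3)
  expect_equal(lp, -z^2 - log(sqrt(pi) * z), tolerance = 1e-4)
  expect_lt(lp, -1600)

  # monotone: increasing in t and D, decreasing in R
  t_grid <- c(10, 100, 1000, 1e4)
  expect_true(all(diff(brownian_escape_log_probability(1, 50, t_grid)) > 0))
  d_grid <- c(0.5, 1, 2, 4)
  expect_true(all(diff(brownian_escape_log_probability(d_grid, 50, 100)) > 0))
  r_grid <- c(10, 20, 40, 80)
  expect_true(all(diff(brownian_escape_log_probability(1, r_grid, 100)) < 0))
  # always a valid log probability
  expect_true(all(brownian_escape_log_probability(d_grid, 50, 100) <= 0))
})

test_that("Brownian predictor matches direct arithmetic and is scale-free", {
  expect_equal(brownian_predictor(1, 1, 1), -2)        # D sqrt(t) = R
  expect_equal(brownian_predictor(coad$d, coad$r, coad$t), -1650.9,
               tolerance = 1e-3)
  t_grid <- c(10, 100, 1000)
  expect_true(all(diff(brownian_predictor(0.05, 100, t_grid)) > 0))
  # invariant under common rescaling of D and R
  expect_equal(brownian_predictor(0.05, 100, 500),
               brownian_predictor(0.05 * 7, 100 * 7, 500))
})

test_that("Levy tail probability is the Pareto survival function", {
  expect_equal(levy_tail_probability(1, 1, 2), 1)
  expect_equal(levy_tail_probability(coad$d, coad$r, 2), 4.548e-4,
               tolerance = 1e-3)
  expect_equal(levy_tail_probability(1, 10, 3), 0.01)
  # at nu = 2 it is exactly D / R
  d <- c(0.01, 0.05, 0.2)
  r <- c(10, 100, 3)
  expect_identical(levy_tail_probability(d, r, 2), d / r)
  expect_error(levy_tail_probability(1, 10, 1), "nu must be")
})

test_that("Levy predictor matches direct arithmetic from tissue parameters", {
  expect_equal(levy_predictor(1, 1, 1), 0)             # D t = R
  expect_equal(levy_predictor(coad$d, coad$r, coad$t), 0.9816,
               tolerance = 1e-3)
  t_luad <- log2(1.22e9) + 0.07 * 80
  expect_equal(levy_predictor(0.0581, 99.75, t_luad), -3.871,
               tolerance = 1e-3)
  # unit-free in (D, R)
  expect_equal(levy_predictor(0.05, 100, 500),
               levy_predictor(0.05 * 7, 100 * 7, 500))
})

test_that("absolute Levy risk is linear in mu and consistent with ERS", {
  p0 <- model_params(d_scale = coad$d, r_walk = coad$r, n_sc = coad$n_sc,
                     m_sc = coad$m_sc, mu = 0)
  expect_equal(levy_risk(p0), 0)

  # doubling R halves the risk at nu = 2
  mu <- 1e-15
  p1 <- model_params(coad$d, coad$r, coad$n_sc, coad$m_sc, mu = mu)
  p2 <- model_params(coad$d, 2 * coad$r, coad$n_sc, coad$m_sc, mu = mu)
  expect_equal(levy_risk(p1), 2 * levy_risk(p2))

  # mu chosen so risk / n_sc = a_ref * t  =>  ERS = 1
  a_ref <- 2e-14
  mu_star <- a_ref / (coad$d / coad$r)
  p3 <- model_params(coad$d, coad$r, coad$n_sc, coad$m_sc, mu = mu_star)
  risk3 <- levy_risk(p3)
  expect_equal(ers_score(risk3, coad$n_sc, coad$m_sc), 1)

  pna <- model_params(coad$d, coad$r, coad$n_sc, coad$m_sc)
  expect_error(levy_risk(pna), "mu")
  expect_warning(
    model_params(d_scale = 10, r_walk = 50, n_sc = 100, m_sc = 1),
    "tail approximation")
  # clamping of the unbounded linear estimate
  pbig <- model_params(coad$d, coad$r, coad$n_sc, coad$m_sc, mu = 1)
  expect_warning(rbig <- levy_risk(pbig), "clamped")
  expect_equal(rbig, 1)
})

test_that("the extra risk score rescales risk by stem-cell generations", {
  ers_coad <- ers_score(coad$risk, coad$n_sc, coad$m_sc)
  expect_equal(ers_coad, 1.817, tolerance = 1e-3)
  expect_true(ers_in_normal_band(ers_coad))
  # linear in risk
  expect_equal(ers_score(2 * coad$risk, coad$n_sc, coad$m_sc), 2 * ers_coad)
  expect_error(ers_score(1.5, coad$n_sc, coad$m_sc), "risk")
})

test_that("ERS band calls are stable under dev-sized risk perturbations", {
  comp <- complete_rows(tissue_parameters())
  for (i in seq_len(nrow(comp))) {
    risks <- comp$risk[i] + c(-1, 0, 1) * comp$dev[i]
    risks <- pmin(pmax(risks, 1e-12), 1 - 1e-12)
    ers <- ers_score(risks, comp$n_sc[i], comp$m_sc[i])
    calls <- ers_in_normal_band(ers)
    if (length(unique(calls)) > 1) {
      # a flipped call is only allowed when the ERS interval straddles an edge
      expect_true(min(ers) < 1 && max(ers) > 1 ||
                    min(ers) < 6 && max(ers) > 6,
                  label = comp$tissue[i])
    }
  }
})
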