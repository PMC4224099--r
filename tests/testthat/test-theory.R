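test_that("decay factor and signal probability match the closed form", {
  p100 <- model_params(N = 5000, n = 100, rho_aff = 0.2, r_aff = 0.1,
                       p_plus = 0.6)
  p140 <- fig_params()
  expect_equal(decay_factor_beta(p100), 0.9976, tolerance = 1e-10)
  expect_equal(decay_factor_beta(p140), 0.995296, tolerance = 1e-10)
  p0 <- model_params(N = 5000, n = 100, rho_aff = 0.2, r_aff = 0.1,
                     p_plus = 0)
  expect_identical(decay_factor_beta(p0), 1)

  expect_equal(signal_probability(0, p100), 0.64)
  expect_equal(signal_probability(5000, p140), p140$r_aff, tolerance = 1e-4)

  # closed form equals the one-step recursion iterated 1000 times
  ps <- 0.64
  fac <- (p140$n / p140$N)^2 * p140$p_plus
  for (i in 1:1000) ps <- ps * (1 - fac / p140$r_aff) + fac
  expect_equal(signal_probability(1000, p140), ps, tolerance = 1e-12)
})

test_that("degree moments are binomial and match simulated networks", {
  p <- fig_params()
  mom <- degree_moments(p, p$r_aff)
  expect_equal(mom$noise$mean, 2.8)
  expect_equal(mom$noise$sd, 1.6565, tolerance = 1e-4)
  expect_equal(mom$noise, mom$signal)   # p_signal = r_aff degenerates

  set.seed(41)
  N <- 400; ps <- small_params(N = N, n = 60, rec_degree = NULL, rho_rec = 0)
  a <- build_afferent_state(N, ps$rho_aff, ps$r_aff)
  deg <- afferent_strong_degrees(a, sample_pattern(N, ps$n))
  m <- degree_moments(ps, ps$r_aff)$noise
  expect_lt(abs(mean(deg) - m$mean), 4 * m$sd / sqrt(N))
})

test_that("the admissible threshold window matches the tail bounds", {
  p100 <- model_params(N = 5000, n = 100, rho_aff = 0.2, r_aff = 0.1,
                       p_plus = 0.6)
  kb <- k_bounds(p100, 0.64, "half-fidelity")
  expect_equal(unname(kb["K_max"]), 12.8)          # n rho_aff p_signal

  p140 <- fig_params()
  kb140 <- k_bounds(p140, 0.64, "half-fidelity")
  expect_equal(unname(kb140["K_min"]), 6.237, tolerance = 1e-3)

  # more noise candidates => higher K_min
  pbig <- model_params(N = 20000, n = 140, rho_aff = 0.2, r_aff = 0.1,
                       p_plus = 0.6)
  expect_gt(k_bounds(pbig, 0.64)["K_min"], kb140["K_min"])

  # full-fidelity bound sits below the mean signal degree
  kbf <- k_bounds(p140, 0.64, "full-fidelity")
  expect_lt(kbf["K_max"], kb140["K_max"])
})

test_that("minimal difference bounds behave per mode", {
  p <- fig_params()
  # half-fidelity closed form equals (K_min - mu_spc) / (n rho_aff)
  kb <- k_bounds(p, p$r_aff + 0.01, "half-fidelity")
  mom <- degree_moments(p, p$r_aff)
  d_half <- minimal_delta(p, "half-fidelity")
  expect_equal(d_half, (unname(kb["K_min"]) - mom$noise$mean) /
                 (p$n * p$rho_aff), tolerance = 1e-10)

  # percolation bound subtracts the fidelity term the full bound adds
  for (psig in c(0.3, 0.5, 0.7)) {
    expect_lt(percmem:::.delta_rhs(p, psig, "percolation-bound"),
              percmem:::.delta_rhs(p, psig, "full-fidelity"))
  }

  # margins are probabilities: regimes implying delta >= 1 are rejected
  tiny <- model_params(N = 1e6, n = 10, rho_aff = 0.1, r_aff = 0.5,
                       p_plus = 0)
  expect_error(minimal_delta(tiny, "half-fidelity"), "invalid regime")
})

test_that("the percolation condition is monotone and matches a grid search", {
  p <- fig_params()
  expect_true(janson_percolates(0.01, model_params(
    N = 5000, n = 140, rho_aff = 0.2, r_aff = 0.1, rec_degree = 8,
    p_plus = 0.6, K = 0)))

  thr <- percolation_threshold(p, "binomial")
  expect_false(janson_percolates(thr - 0.01, p))
  expect_true(janson_percolates(thr + 0.01, p))

  # monotone: threshold falls with recurrent density, rises with K
  p_lowrec <- fig_params(rec_degree = 4)
  p_highK <- fig_params(K = 14)
  expect_gt(percolation_threshold(p_lowrec), thr)
  expect_gt(percolation_threshold(p_highK), thr)

  # no-recurrent special case cross-checked against a direct grid search
  p0 <- fig_params(rec_degree = NULL, rho_rec = 0)
  thr0 <- percolation_threshold(p0, "binomial")
  grid <- seq(p0$r_aff, 1, by = 1e-3)
  tmax <- ceiling(p0$alpha_fid * p0$n - 1e-9)
  ok <- vapply(grid, function(pp) {
    pr <- pbinom(p0$K - 1, p0$n, p0$rho_aff * pp, lower.tail = FALSE)
    all(p0$n * pr > 0:tmax)
  }, logical(1))
  expect_equal(thr0, grid[which(ok)[1]], tolerance = 2e-3)

  # normal approximation converges to the binomial solver as n grows
  gaps <- vapply(c(50, 140, 400), function(nn) {
    pn <- model_params(N = 5000, n = nn, rho_aff = 0.2, r_aff = 0.1,
                       rec_degree = 8, p_plus = 0.6, K = 12)
    abs(percolation_threshold(pn, "binomial") -
          percolation_threshold(pn, "normal"))
  }, numeric(1))
  expect_lt(gaps[3], gaps[1])
  expect_lt(max(gaps), 0.06)
})

test_that("capacity prediction follows the logarithmic decay law", {
  expect_identical(predicted_capacity(0.23, 0.23, 0.995296), 0L)
  expect_identical(predicted_capacity(0.54, 0.23, 0.995296), 181L)
  # halving the minimal difference adds log(2)/log(1/beta)
  beta <- 0.995296
  gain <- predicted_capacity(0.54, 0.115, beta) -
    predicted_capacity(0.54, 0.23, beta)
  expect_lt(abs(gain - log(2) / log(1 / beta)), 1)
  expect_warning(cap0 <- predicted_capacity(0.1, 0.2, 0.99), "no storage")
  expect_identical(cap0, 0L)

  # invariance under N -> cN, n -> cn (beta depends on n/N only)
  p1 <- model_params(N = 2500, n = 70, rho_aff = 0.2, r_aff = 0.1,
                     p_plus = 0.6)
  p2 <- model_params(N = 5000, n = 140, rho_aff = 0.2, r_aff = 0.1,
                     p_plus = 0.6)
  expect_equal(decay_factor_beta(p1), decay_factor_beta(p2))
})

test_that("optimal plasticity maximizes the capacity formula", {
  p <- fig_params()
  opt <- optimal_plasticity(0.23, p)
  expect_equal(opt$p_plus_opt, 0.695, tolerance = 1e-3)
  expect_equal(opt$M_max, 183.6, tolerance = 0.05)

  # numeric grid over p+ of the capacity formula peaks at e*delta/(1-r)
  delta <- 0.23; r <- p$r_aff
  grid <- seq(0.3, 1, by = 0.001)
  # asymptotic capacity formula: log(1/beta) ~ (n/N)^2 p+ / r_aff
  M_of <- function(pp) {
    log((1 - r) * pp / delta) * p$N^2 * r / (p$n^2 * pp)
  }
  peak <- grid[which.max(vapply(grid, M_of, numeric(1)))]
  expect_equal(peak, opt$p_plus_opt, tolerance = 2e-3)

  expect_warning(optimal_plasticity(0.5, p), "clamping")
})

test_that("query noise analysis gives the capacity-loss formula", {
  p <- fig_params()
  qa1 <- query_noise_analysis(1, 0, p, 0.23)
  expect_identical(qa1$capacity_loss, 0)
  expect_true(qa1$recallable)
  qa8 <- query_noise_analysis(0.8, 0, p, 0.23)
  expect_equal(qa8$capacity_loss, 47.3, tolerance = 0.05)
  # monotone in lambda, anti-monotone in insertions
  expect_false(query_noise_analysis(0.4, 0, p, 0.23)$recallable)
  expect_false(query_noise_analysis(0.8, 500, p, 0.23)$recallable)
})

test_that("the theory report assembles consistent quantities", {
  p <- fig_params()
  tq <- theory_quantities(p)
  expect_equal(tq$p_noise, p$r_aff)
  expect_equal(tq$delta0, (1 - p$r_aff) * p$p_plus)
  expect_equal(tq$p_signal_0, signal_probability(0, p))
  expect_true(tq$percolation_threshold_binomial > p$r_aff)
  expect_true(is.finite(tq$M_pred) && tq$M_pred > 0)
})
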