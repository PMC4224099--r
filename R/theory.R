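# Closed-form theory: signal/noise edge probabilities, degree moments,
# admissible threshold windows, minimal retrievable differences, the
# Janson-type percolation condition and threshold solvers, capacity
# predictions, optimal plasticity and noise-tolerance formulas. All
# logarithms are natural (they arise from Gaussian tail asymptotics).

#' Per-insertion decay factor of the signal margin
#'
#' Each presentation of a competing association shrinks the margin
#' \eqn{\Delta(i) = p_{signal}(i) - r_{aff}} by the factor
#' \deqn{\beta = 1 - (n/N)^2 \, p^+ / r_{aff}.}
#'
#' @param params a [model_params()] object.
#' @return The decay factor, in (0, 1\] for valid regimes.
#' @export
decay_factor_beta <- function(params) {
  if (params$r_aff <= 0) stop("invalid regime: r_aff must be > 0")
  beta <- 1 - (params$n / params$N)^2 * params$p_plus / params$r_aff
  if (beta <= 0)
    stop(sprintf("invalid regime: decay factor beta = %.4g <= 0 (plasticity too strong for this n/N, r_aff)", beta))
  beta
}

#' Signal edge probability after i competing insertions
#'
#' Probability that a present afferent edge from \eqn{A_0} into \eqn{B_0}
#' is strong after `i` further associations have been presented:
#' \deqn{p_{signal}(i) = r_{aff} + \beta^i (1-r_{aff}) p^+.}
#' The noise probability (edges into \eqn{\mathcal{B}\setminus B_0}) stays
#' at \eqn{r_{aff}} for all i by the pruning normalization.
#'
#' @param i number of competing insertions (vectorized, >= 0).
#' @param params a [model_params()] object.
#' @return Probability (vectorized over `i`).
#' @export
signal_probability <- function(i, params) {
  stopifnot(all(i >= 0))
  beta <- decay_factor_beta(params)
  params$r_aff + beta^i * (1 - params$r_aff) * params$p_plus
}

#' Degree distribution moments
#'
#' Under the independence (Erdős–Rényi) assumption the afferent strong
#' degree into \eqn{A_0} of a vertex outside the target pattern is
#' Binomial(n, rho_aff * r_aff) and that of a vertex inside it is
#' Binomial(n, rho_aff * p_signal).
#'
#' @param params a [model_params()] object.
#' @param p_signal signal edge probability.
#' @return List with components `noise` and `signal`, each `list(mean, sd)`.
#' @export
degree_moments <- function(params, p_signal) {
  stopifnot(p_signal >= 0, p_signal <= 1)
  n <- params$n; rho <- params$rho_aff
  qn <- rho * params$r_aff
  qs <- rho * p_signal
  list(noise = list(mean = n * qn, sd = sqrt(n * qn * (1 - qn))),
       signal = list(mean = n * qs, sd = sqrt(n * qs * (1 - qs))))
}

# Gaussian-tail log arguments; both must exceed 1 for the bounds to exist.
.spc_log_arg <- function(params, sigma_spc) {
  params$N / (params$alpha_spc * params$n * sqrt(2 * pi * sigma_spc^2))
}
.fid_log_arg <- function(n, sigma_fid) {
  # full-fidelity budget: at most one vertex of the pattern may fail,
  # i.e. failure probability 1/n per vertex (alpha_fid = 1 - 1/n)
  n / sqrt(2 * pi * sigma_fid^2)
}

#' Admissible activation-threshold window
#'
#' `K_min` is the smallest threshold that keeps the expected number of
#' spuriously activated outside vertices below the specificity budget
#' (normal approximation of the noise degree tail); `K_max` is the largest
#' threshold that still activates the required fraction of the target:
#' for `mode = "half-fidelity"` (`alpha_fid` = 0.5) the mean signal degree
#' itself, for `mode = "full-fidelity"` (`alpha_fid` = 1 - 1/n) the mean
#' minus a Gaussian-tail term.
#'
#' @param params a [model_params()] object.
#' @param p_signal signal edge probability (>= `r_aff`).
#' @param mode `"half-fidelity"` or `"full-fidelity"`.
#' @return Named numeric vector `c(K_min, K_max)` (real-valued bounds).
#' @export
k_bounds <- function(params, p_signal,
                     mode = c("half-fidelity", "full-fidelity")) {
  mode <- match.arg(mode)
  stopifnot(p_signal >= params$r_aff)
  mom <- degree_moments(params, p_signal)
  arg_spc <- .spc_log_arg(params, mom$noise$sd)
  if (arg_spc <= 1)
    stop("invalid regime: specificity tail log argument <= 1")
  K_min <- mom$noise$mean + mom$noise$sd * sqrt(2 * log(arg_spc))
  K_max <- if (mode == "half-fidelity") {
    mom$signal$mean
  } else {
    arg_fid <- .fid_log_arg(params$n, mom$signal$sd)
    if (arg_fid <= 1)
      stop("invalid regime: fidelity tail log argument <= 1")
    mom$signal$mean - mom$signal$sd * sqrt(2 * log(arg_fid))
  }
  c(K_min = K_min, K_max = K_max)
}

# Right-hand side of the minimal-difference bounds. `p_signal` fixes the
# signal variance entering the fidelity term; the percolation bound differs
# from the full-fidelity bound only in the sign of that term.
.delta_rhs <- function(params, p_signal,
                       mode = c("half-fidelity", "full-fidelity",
                                "percolation-bound")) {
  mode <- match.arg(mode)
  n <- params$n; rho <- params$rho_aff
  mom <- degree_moments(params, p_signal)
  arg_spc <- .spc_log_arg(params, mom$noise$sd)
  if (arg_spc <= 1) stop("invalid regime: specificity tail log argument <= 1")
  t_spc <- mom$noise$sd / (n * rho) * sqrt(2 * log(arg_spc))
  if (mode == "half-fidelity") return(t_spc)
  arg_fid <- .fid_log_arg(n, mom$signal$sd)
  if (arg_fid <= 1) stop("invalid regime: fidelity tail log argument <= 1")
  t_fid <- mom$signal$sd / (n * rho) * sqrt(2 * log(arg_fid))
  if (mode == "full-fidelity") t_spc + t_fid else t_spc - t_fid
}

#' Minimal retrievable signal-noise difference
#'
#' The smallest margin \eqn{\Delta = p_{signal} - r_{aff}} at which recall
#' is still possible. For `"half-fidelity"` there is a closed form (the
#' specificity term alone). For `"full-fidelity"` and `"percolation-bound"`
#' the bound's right-hand side depends on the signal variance at
#' \eqn{p_{signal} = r_{aff} + \Delta}, so the fixed point is solved by
#' bisection on (0, 1 - r_aff) to absolute tolerance `tol`.
#'
#' @param params a [model_params()] object.
#' @param mode `"half-fidelity"`, `"full-fidelity"` or
#'   `"percolation-bound"`.
#' @param tol bisection tolerance for the fixed-point modes.
#' @return The minimal difference (a probability margin < 1).
#' @export
minimal_delta <- function(params,
                          mode = c("half-fidelity", "full-fidelity",
                                   "percolation-bound"),
                          tol = 1e-6) {
  mode <- match.arg(mode)
  r <- params$r_aff
  if (mode == "half-fidelity") {
    d <- .delta_rhs(params, r, mode)
    if (d >= 1) stop("invalid regime: minimal difference >= 1 (n too small for this N)")
    return(d)
  }
  g <- function(d) d - .delta_rhs(params, r + d, mode)
  lo <- 1e-9; hi <- 1 - r - 1e-9
  glo <- tryCatch(g(lo), error = function(e) NA_real_)
  ghi <- tryCatch(g(hi), error = function(e) NA_real_)
  if (!is.finite(glo) || !is.finite(ghi) || glo >= 0 || ghi <= 0)
    stop("invalid regime: no fixed point for the minimal difference in (0, 1 - r_aff)")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  d <- (lo + hi) / 2
  if (d >= 1) stop("invalid regime: minimal difference >= 1")
  d
}

# Probability that a target vertex is active at exposure time t:
# Pr[Bin(n, rho_aff p) + Bin(t, rho_rec) >= K], computed by exact
# convolution over the first binomial's sub-threshold mass.
.two_binomial_tail <- function(p_signal, t, params) {
  K <- params$K
  if (K == 0L) return(1)
  q <- params$rho_aff * p_signal
  tail1 <- pbinom(K - 1L, params$n, q, lower.tail = FALSE)
  j <- 0:(K - 1L)
  tail1 + sum(dbinom(j, params$n, q) *
              pbinom(K - j - 1L, t, params$rho_rec, lower.tail = FALSE))
}

.two_normal_tail <- function(p_signal, t, params) {
  q <- params$rho_aff * p_signal
  rr <- params$rho_rec
  mu <- params$n * q + t * rr
  v <- params$n * q * (1 - q) + t * rr * (1 - rr)
  if (v <= 0) return(as.numeric(mu >= params$K))
  pnorm(params$K, mu, sqrt(v), lower.tail = FALSE)
}

#' Janson-type percolation condition
#'
#' Replacing the generation-size binomial of the exposure process by its
#' expectation, activity percolates to the required fraction of the target
#' pattern if and only if
#' \deqn{n \Pr[Bin(n, \rho_{aff} p_{signal}) + Bin(t, \rho_{rec}) \ge K] > t}
#' for every integer exposure time t in `0..t_max`.
#'
#' @param p_signal signal edge probability.
#' @param params a [model_params()] object.
#' @param t_max largest exposure time checked; defaults to
#'   `ceiling(alpha_fid * n)`, the fidelity target.
#' @param approx `"binomial"` for the exact two-binomial tail,
#'   `"normal"` to replace the binomials by normal distributions of
#'   matching mean and variance (no continuity correction).
#' @return Logical flag.
#' @export
janson_percolates <- function(p_signal, params, t_max = NULL,
                              approx = c("binomial", "normal")) {
  approx <- match.arg(approx)
  if (is.null(t_max)) t_max <- .ceil_count(params$alpha_fid * params$n)
  stopifnot(t_max >= 0)
  tailf <- if (approx == "binomial") .two_binomial_tail else .two_normal_tail
  for (t in 0:t_max) {
    if (params$n * tailf(p_signal, t, params) <= t) return(FALSE)
  }
  TRUE
}

#' Percolation threshold on the signal density
#'
#' Smallest signal edge probability in `[r_aff, 1]` satisfying the
#' percolation condition of [janson_percolates()], found by bisection.
#'
#' @param params a [model_params()] object.
#' @param approx `"binomial"` or `"normal"` (see [janson_percolates()]).
#' @param t_max passed to [janson_percolates()].
#' @param tol absolute bisection tolerance.
#' @return The threshold probability.
#' @export
percolation_threshold <- function(params, approx = c("binomial", "normal"),
                                  t_max = NULL, tol = 1e-4) {
  approx <- match.arg(approx)
  lo <- params$r_aff; hi <- 1
  if (janson_percolates(lo, params, t_max, approx)) return(lo)
  if (!janson_percolates(hi, params, t_max, approx))
    stop("invalid regime: no signal density <= 1 percolates at these parameters")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (janson_percolates(mid, params, t_max, approx)) hi <- mid else lo <- mid
  }
  hi
}

#' Predicted memory capacity
#'
#' Number of competing associations until the signal margin decays from its
#' initial value to the minimal retrievable one:
#' \deqn{M = \lfloor \log(\Delta(0)/\Delta) / \log(1/\beta) \rfloor.}
#'
#' @param delta0 initial margin \eqn{\Delta(0) = (1-r_{aff})p^+}.
#' @param delta_min minimal retrievable margin.
#' @param beta per-insertion decay factor in (0,1).
#' @return Integer capacity (0 with a warning if `delta_min > delta0`).
#' @export
predicted_capacity <- function(delta0, delta_min, beta) {
  stopifnot(beta > 0, beta < 1, delta_min > 0)
  if (delta_min > delta0) {
    warning("minimal difference exceeds initial difference: no storage possible")
    return(0L)
  }
  as.integer(floor(log(delta0 / delta_min) / log(1 / beta)))
}

#' Optimal plasticity and maximal capacity
#'
#' The capacity as a function of \eqn{p^+} has the form
#' \eqn{\log(c_1 p^+) \cdot c_2/p^+}, maximized at \eqn{p^+ = e/c_1}:
#' \deqn{p^{+*} = e\Delta/(1-r_{aff}), \qquad
#'       M_{max} = \frac{N^2 r_{aff}(1-r_{aff})}{n^2 e \Delta}.}
#'
#' @param delta_min minimal retrievable margin, in (0,1).
#' @param params a [model_params()] object.
#' @return List with `p_plus_opt` (clamped to 1 with a warning if the
#'   formula exceeds 1) and `M_max`.
#' @export
optimal_plasticity <- function(delta_min, params) {
  stopifnot(delta_min > 0, delta_min < 1)
  r <- params$r_aff
  p_opt <- exp(1) * delta_min / (1 - r)
  if (p_opt > 1) {
    warning(sprintf("optimal p_plus %.3f exceeds 1; clamping", p_opt))
    p_opt <- 1
  }
  M_max <- params$N^2 * r * (1 - r) / (params$n^2 * exp(1) * delta_min)
  list(p_plus_opt = p_opt, M_max = M_max)
}

#' Query-noise analysis
#'
#' With the query activated at precision `lam`, target vertices expect
#' \eqn{\lambda n p_{signal} + (1-\lambda) n r_{aff}} strong inputs, so the
#' association is still recallable after `i` competing insertions iff
#' \eqn{\lambda (p_{signal}(i) - r_{aff}) > \Delta}. The induced capacity
#' loss relative to a clean query is \eqn{\log(1/\lambda)/\log(1/\beta)}.
#'
#' @param lam query precision in (0,1\].
#' @param i number of competing insertions.
#' @param params a [model_params()] object.
#' @param delta_min minimal retrievable margin.
#' @return List with `recallable` (flag) and `capacity_loss`.
#' @export
query_noise_analysis <- function(lam, i, params, delta_min) {
  stopifnot(lam > 0, lam <= 1)
  beta <- decay_factor_beta(params)
  list(
    recallable = lam * (signal_probability(i, params) - params$r_aff) > delta_min,
    capacity_loss = log(1 / lam) / log(1 / beta)
  )
}

#' All closed-form quantities in one report
#'
#' Convenience wrapper assembling the theory quantities for a parameter
#' set: decay factor, initial margin, noise probability, degree moments at
#' insertion 0, the admissible K window, minimal differences per mode
#' (`NA` where the regime is invalid), percolation thresholds in both
#' approximations and the resulting capacity prediction.
#'
#' @param params a [model_params()] object.
#' @return Named list of theory quantities.
#' @export
theory_quantities <- function(params) {
  beta <- decay_factor_beta(params)
  delta0 <- (1 - params$r_aff) * params$p_plus
  p0 <- signal_probability(0, params)
  mom <- degree_moments(params, p0)
  try_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  kb <- try_na(k_bounds(params, p0, "half-fidelity"))
  thr_bin <- try_na(percolation_threshold(params, "binomial"))
  thr_norm <- try_na(percolation_threshold(params, "normal"))
  delta_perc <- if (is.finite(thr_bin)) thr_bin - params$r_aff else NA_real_
  M_pred <- if (is.finite(delta_perc) && delta_perc > 0 && delta_perc <= delta0)
    predicted_capacity(delta0, delta_perc, beta) else NA_integer_
  list(
    beta = beta,
    delta0 = delta0,
    p_noise = params$r_aff,
    p_signal_0 = p0,
    mu_spc = mom$noise$mean, sigma_spc = mom$noise$sd,
    mu_fid = mom$signal$mean, sigma_fid = mom$signal$sd,
    K_min = if (all(is.finite(kb))) unname(kb["K_min"]) else NA_real_,
    K_max_half = if (all(is.finite(kb))) unname(kb["K_max"]) else NA_real_,
    delta_min_half = try_na(minimal_delta(params, "half-fidelity")),
    delta_min_full = try_na(minimal_delta(params, "full-fidelity")),
    delta_min_percolation = try_na(minimal_delta(params, "percolation-bound")),
    percolation_threshold_binomial = thr_bin,
    percolation_threshold_normal = thr_norm,
    M_pred = M_pred,
    log_convention = "natural"
  )
}
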