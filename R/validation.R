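# Error-decomposition study: how far do the independence (Erdős–Rényi)
# assumption, the expectation (Janson) assumption and the normal
# approximation each move the capacity prediction away from simulation.

#' Empirical percolation threshold on Erdős–Rényi instances
#'
#' For each instance an independent bipartite present-edge set between the
#' source and target pattern (n x n, probability `rho_aff`) and an
#' independent recurrent graph within the target pattern (probability
#' `rho_rec`, all within-pattern present edges strong) are generated. Each
#' present afferent edge carries one uniform variate; at candidate signal
#' density p the edge is strong iff its variate is below p, so the
#' per-instance threshold -- the minimal p at which percolation activates
#' at least `ceiling(alpha_fid * n)` vertices -- is well defined and
#' monotone, and is found by bisection. Returns the mean over instances.
#'
#' @param params a [model_params()] object.
#' @param trials number of instances.
#' @param tol bisection granularity on p.
#' @param seed optional master seed.
#' @return List with `threshold` (mean), `sd`, `per_instance`, `trials`.
#' @export
er_percolation_threshold_sim <- function(params, trials, tol = 1e-3,
                                         seed = NULL) {
  stopifnot(trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- params$n
  target <- .ceil_count(params$alpha_fid * n)
  thr <- rep(NA_real_, trials)
  for (tr in seq_len(trials)) {
    nnz <- rbinom(1L, n * n, params$rho_aff)
    pos <- sample.int(n * n, nnz)
    tgt_col <- (pos - 1L) %/% n + 1L
    u <- runif(nnz)
    rec <- build_recurrent_state(n, params$rho_rec)
    store_recurrent_pattern(rec, seq_len(n))
    reaches <- function(p) {
      affdeg <- tabulate(tgt_col[u < p], n)
      res <- percolate(rec, affdeg, integer(0), params$K)
      length(res$final_active_B) >= target
    }
    if (!reaches(1)) next  # instance cannot percolate; excluded below
    lo <- 0; hi <- 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (reaches(mid)) hi <- mid else lo <- mid
    }
    thr[tr] <- hi
  }
  ok <- is.finite(thr)
  if (!all(ok))
    warning(sprintf("%d of %d instances never percolated and were excluded",
                    sum(!ok), trials))
  list(threshold = mean(thr[ok]), sd = sd(thr[ok]),
       per_instance = thr, trials = trials)
}

#' Simulated capacity versus three theoretical predictions
#'
#' For each population size the mean simulated capacity (a) is compared
#' with the capacity formula evaluated at three increasingly idealized
#' percolation thresholds: (b) the empirical Erdős–Rényi instance
#' threshold from [er_percolation_threshold_sim()], (c) the expectation
#' (Janson) condition with exact binomial tails, and (d) the same with
#' normal approximations. The pairwise differences a-b, b-c and c-d
#' estimate the independence, expectation and normal-approximation errors;
#' they sum to the total error a-d by construction.
#'
#' @param params a [model_params()] object; `N` is overridden per row.
#' @param N_values population sizes.
#' @param trials simulation trials per population size.
#' @param er_trials instances for the empirical threshold.
#' @param M_max presentation budget; defaults to a multiple of the Janson
#'   prediction at the largest N.
#' @param seed optional master seed.
#' @return Data frame with columns `N`, `sim`, `pred_er_sim`,
#'   `pred_janson`, `pred_normal`, `err_independence`, `err_expectation`,
#'   `err_normal`, `err_total`.
#' @export
capacity_prediction_comparison <- function(params, N_values, trials,
                                           er_trials = 100, M_max = NULL,
                                           seed = NULL) {
  seeds <- derive_trial_seeds(seed, length(N_values) * trials + 1L)
  thr_c <- percolation_threshold(params, "binomial")
  thr_d <- percolation_threshold(params, "normal")
  er <- er_percolation_threshold_sim(params, er_trials,
                                     seed = seeds[length(seeds)])
  thr_b <- er$threshold
  delta0 <- (1 - params$r_aff) * params$p_plus
  rows <- vector("list", length(N_values))
  for (ni in seq_along(N_values)) {
    pN <- model_params(N = N_values[ni], n = params$n,
                       rho_aff = params$rho_aff, r_aff = params$r_aff,
                       rho_rec = params$rho_rec, p_plus = params$p_plus,
                       K = params$K, alpha_fid = params$alpha_fid,
                       alpha_spc = params$alpha_spc)
    beta <- decay_factor_beta(pN)
    pred <- function(thr) predicted_capacity(delta0, thr - params$r_aff, beta)
    mm <- if (is.null(M_max)) max(100L, 4L * pred(thr_c)) else M_max
    caps <- numeric(trials)
    for (tr in seq_len(trials)) {
      set.seed(seeds[(ni - 1L) * trials + tr])
      caps[tr] <- measure_capacity(pN, mm, reliability_probes = FALSE)$capacity
    }
    rows[[ni]] <- data.frame(
      N = N_values[ni], sim = mean(caps),
      pred_er_sim = pred(thr_b), pred_janson = pred(thr_c),
      pred_normal = pred(thr_d)
    )
  }
  out <- do.call(rbind, rows)
  out$err_independence <- out$sim - out$pred_er_sim
  out$err_expectation <- out$pred_er_sim - out$pred_janson
  out$err_normal <- out$pred_janson - out$pred_normal
  out$err_total <- out$sim - out$pred_normal
  out
}

#' Noise-density invariance check
#'
#' The pruning normalization keeps the strong fraction of present edges
#' from \eqn{A_0} into \eqn{\mathcal{B} \setminus B_0} at `r_aff`
#' regardless of how many competing associations are learned. This runs
#' learning sequences and z-tests the pooled empirical noise density
#' against `r_aff` at competing-insertion checkpoints 0, `M_max/2` and
#' `M_max`. Passing `p_minus_override` (e.g. half the normalizing value)
#' breaks the balance and serves as a positive control.
#'
#' @param params a [model_params()] object.
#' @param M_max competing insertions per trial.
#' @param trials number of independent trials.
#' @param p_minus_override optional prune probability replacing the
#'   normalizing value.
#' @param alpha significance level of the two-sided z-test.
#' @param seed optional master seed.
#' @return Data frame with one row per checkpoint (`checkpoint`,
#'   `n_present`, `n_strong`, `density`, `z`, `pass`); attribute
#'   `overall_pass` is `TRUE` iff every checkpoint passes.
#' @export
noise_invariance_check <- function(params, M_max, trials,
                                   p_minus_override = NULL, alpha = 0.001,
                                   seed = NULL) {
  seeds <- derive_trial_seeds(seed, trials)
  p_minus <- if (is.null(p_minus_override)) params$p_minus else p_minus_override
  checkpoints <- unique(c(0L, as.integer(M_max / 2), as.integer(M_max)))
  N <- params$N; n <- params$n
  tot_strong <- tot_present <- setNames(numeric(length(checkpoints)),
                                        checkpoints)
  for (tr in seq_len(trials)) {
    set.seed(seeds[tr])
    aff <- build_afferent_state(N, params$rho_aff, params$r_aff)
    rec <- build_recurrent_state(N, params$rho_rec)
    A0 <- sample_pattern(N, n); B0 <- sample_pattern(N, n)
    store_recurrent_pattern(rec, B0)
    learn_association(aff, A0, B0, params$p_plus, p_minus)
    outside <- setdiff(seq_len(N), B0)
    done <- 0L
    for (ci in seq_along(checkpoints)) {
      while (done < checkpoints[ci]) {
        Ai <- sample_pattern(N, n); Bi <- sample_pattern(N, n)
        store_recurrent_pattern(rec, Bi)
        learn_association(aff, Ai, Bi, params$p_plus, p_minus)
        done <- done + 1L
      }
      dens <- strong_density(aff, A0, outside)
      tot_strong[ci] <- tot_strong[ci] + dens$n_strong
      tot_present[ci] <- tot_present[ci] + dens$n_present
    }
  }
  r <- params$r_aff
  density <- tot_strong / tot_present
  z <- (density - r) / sqrt(r * (1 - r) / tot_present)
  crit <- qnorm(1 - alpha / 2)
  out <- data.frame(
    checkpoint = checkpoints, n_present = tot_present,
    n_strong = tot_strong, density = density, z = z,
    pass = abs(z) < crit, row.names = NULL
  )
  attr(out, "overall_pass") <- all(out$pass)
  out
}
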