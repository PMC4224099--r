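#' Normalizing prune probability
#'
#' The pruning probability that keeps the expected strong in-degree of a
#' target vertex constant under one presentation: insertion is expected to
#' strengthen \eqn{(1-r_{aff})\rho_{aff} n p^+} edges per target vertex,
#' pruning to weaken \eqn{r_{aff}\rho_{aff}(N-n) p^-}, so
#' \deqn{p^- = \frac{1-r_{aff}}{r_{aff}} \cdot \frac{n}{N-n} \cdot p^+.}
#'
#' @param p_plus insertion probability in \[0,1\].
#' @param r_aff initial strong fraction of afferent edges, in (0,1\].
#' @param n pattern size, `1 <= n < N`.
#' @param N population size.
#' @return The prune probability, a scalar in \[0,1\].
#' @examples
#' derive_prune_probability(0.6, 0.1, 140, 5000)
#' @export
derive_prune_probability <- function(p_plus, r_aff, n, N) {
  stopifnot(is.numeric(p_plus), is.numeric(r_aff), is.numeric(n), is.numeric(N))
  if (r_aff <= 0)
    stop("invalid parameters: r_aff must be > 0 (prune normalization divides by r_aff)")
  if (r_aff > 1 || p_plus < 0 || p_plus > 1)
    stop("invalid parameters: probabilities must lie in [0, 1]")
  if (n < 1 || n >= N)
    stop("invalid parameters: need 1 <= n < N")
  p_minus <- (1 - r_aff) / r_aff * n / (N - n) * p_plus
  if (p_minus > 1)
    stop(sprintf(paste0(
      "invalid parameters: prune probability %.4f > 1 for ",
      "(p_plus = %g, r_aff = %g, n = %g, N = %g)"), p_minus, p_plus, r_aff, n, N))
  p_minus
}

#' Model parameter set
#'
#' Bundles all scalar parameters of the model and derives the normalizing
#' prune probability `p_minus` from [derive_prune_probability()].
#'
#' @param N size of each population.
#' @param n pattern size, `1 <= n < N`.
#' @param rho_aff afferent presence probability.
#' @param r_aff initial strong fraction of afferent edges.
#' @param rho_rec recurrent presence probability. Alternatively give
#'   `rec_degree`, the expected strong in-degree within a stored pattern;
#'   then `rho_rec = rec_degree / n` (the convention used when a "recurrent
#'   degree" is held fixed while `n` varies).
#' @param p_plus insertion probability.
#' @param K activation threshold (non-negative integer).
#' @param alpha_fid fidelity fraction in (0,1\]: recall must activate at
#'   least `ceiling(alpha_fid * n)` vertices of the target pattern.
#' @param alpha_spc specificity fraction (>= 0): at most
#'   `floor(alpha_spc * n)` vertices outside the target may end up active.
#' @param rec_degree optional expected within-pattern strong in-degree; see
#'   `rho_rec`.
#' @return An object of class `model_params`: a named list with the above
#'   fields plus the derived `p_minus`.
#' @examples
#' model_params(N = 5000, n = 140, rho_aff = 0.2, r_aff = 0.1,
#'              rec_degree = 8, p_plus = 0.6, K = 12)
#' @export
model_params <- function(N, n, rho_aff, r_aff, rho_rec = 0, p_plus = 0,
                         K = 1, alpha_fid = 0.8, alpha_spc = 1.0,
                         rec_degree = NULL) {
  if (!is.null(rec_degree)) {
    stopifnot(rec_degree >= 0)
    rho_rec <- rec_degree / n
  }
  stopifnot(
    length(N) == 1, length(n) == 1, N == round(N), n == round(n),
    n >= 1, n < N,
    rho_aff >= 0, rho_aff <= 1, rho_rec >= 0, rho_rec <= 1,
    r_aff >= 0, r_aff <= 1, p_plus >= 0, p_plus <= 1,
    K >= 0, K == round(K),
    alpha_fid > 0, alpha_fid <= 1, alpha_spc >= 0
  )
  p_minus <- derive_prune_probability(p_plus, r_aff, n, N)
  structure(list(
    N = as.integer(N), n = as.integer(n),
    rho_aff = rho_aff, r_aff = r_aff, rho_rec = rho_rec,
    p_plus = p_plus, p_minus = p_minus, K = as.integer(K),
    alpha_fid = alpha_fid, alpha_spc = alpha_spc,
    rec_degree = if (is.null(rec_degree)) NA_real_ else rec_degree
  ), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters (one-shot associative memory)\n")
  cat(sprintf("  populations N = %d, pattern size n = %d\n", x$N, x$n))
  cat(sprintf("  afferent: rho_aff = %g, r_aff = %g, p+ = %g, p- = %g\n",
              x$rho_aff, x$r_aff, x$p_plus, x$p_minus))
  cat(sprintf("  recurrent: rho_rec = %g (expected in-pattern degree %.3g)\n",
              x$rho_rec, x$rho_rec * x$n))
  cat(sprintf("  retrieval: K = %d, alpha_fid = %g, alpha_spc = %g\n",
              x$K, x$alpha_fid, x$alpha_spc))
  invisible(x)
}

# "at least"/"at most" thresholds with a fuzz guard: 0.8*140 is 112 + 6e-15
# in doubles, and a bare ceiling would demand 113 vertices.
.ceil_count <- function(x) as.integer(ceiling(x - 1e-9))
.floor_count <- function(x) as.integer(floor(x + 1e-9))

# Derive independent per-trial seeds from one master seed (documented
# splitting rule: seeds are drawn from the master-seeded stream).
derive_trial_seeds <- function(seed, k) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(2147483646L, k)
}
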