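#' Measure memory capacity in one trial
#'
#' Runs a fresh learning sequence and probes recall of the first
#' association \eqn{(A_0, B_0)} with a clean query after every
#' presentation. The capacity is the largest number of *competing*
#' associations after which association 0 is still memorized, i.e. one
#' less than the insertion count at the first failure. Optionally each
#' association is also probed immediately after its own insertion
#' (insertion-success flags, used for the reliability bookkeeping of the
#' sweep experiments).
#'
#' @param params a [model_params()] object.
#' @param M_max maximum number of presentations; it is an error if
#'   association 0 is still memorized after `M_max` presentations (raise
#'   `M_max` to observe the failure).
#' @param reliability_probes probe each association right after its own
#'   insertion (doubles the probe cost).
#' @param prestore clip all target patterns into the recurrent network
#'   before learning instead of at presentation.
#' @return A `capacity_record`: list with `capacity`, `insertion_success`
#'   (logical, one flag per performed insertion; `NA` where not probed),
#'   `reliability`, `n_insertions`, `density_at_failure` (empirical signal
#'   strong-edge density from \eqn{A_0} into \eqn{B_0} at the failing
#'   probe) and `params`.
#' @export
measure_capacity <- function(params, M_max, reliability_probes = TRUE,
                             prestore = FALSE) {
  stopifnot(inherits(params, "model_params"), M_max >= 1)
  N <- params$N; n <- params$n
  aff <- build_afferent_state(N, params$rho_aff, params$r_aff)
  rec <- build_recurrent_state(N, params$rho_rec)
  pairs <- lapply(seq_len(M_max), function(i)
    list(A = sample_pattern(N, n), B = sample_pattern(N, n)))
  if (prestore) for (pr in pairs) store_recurrent_pattern(rec, pr$B)
  A0 <- pairs[[1L]]$A; B0 <- pairs[[1L]]$B
  success <- rep(NA, M_max)
  capacity <- NA_integer_
  density_at_failure <- NA_real_
  m <- 0L
  for (i in seq_len(M_max)) {
    m <- i
    if (!prestore) store_recurrent_pattern(rec, pairs[[i]]$B)
    learn_association(aff, pairs[[i]]$A, pairs[[i]]$B,
                      params$p_plus, params$p_minus)
    if (reliability_probes || i == 1L) {
      ri <- recall(aff, rec, pairs[[i]]$A, integer(0), params,
                   target = pairs[[i]]$B)
      success[i] <- ri$memorized
    }
    r0 <- if (i == 1L && !is.na(success[1L])) success[1L] else {
      recall(aff, rec, A0, integer(0), params, target = B0)$memorized
    }
    if (!r0) {
      capacity <- i - 2L      # memorized up to i-2 competing insertions
      if (capacity < 0L) capacity <- 0L
      density_at_failure <- strong_density(aff, A0, B0)$fraction
      break
    }
  }
  if (is.na(capacity))
    stop(sprintf("association 0 still memorized after M_max = %d presentations; increase M_max", M_max))
  probed <- success[seq_len(m)]
  structure(list(
    capacity = capacity,
    insertion_success = probed,
    reliability = if (reliability_probes) mean(probed) else NA_real_,
    n_insertions = m,
    density_at_failure = density_at_failure,
    params = params
  ), class = "capacity_record")
}

#' @export
print.capacity_record <- function(x, ...) {
  cat(sprintf("Capacity record: %d competing associations (probed %d insertions)\n",
              x$capacity, x$n_insertions))
  if (!is.na(x$reliability))
    cat(sprintf("  insertion reliability %.3f\n", x$reliability))
  invisible(x)
}

.sweep_axes <- c("n", "p_plus", "r_aff", "K", "rho_rec", "rho_aff")

# Rebuild a parameter set with one axis changed. When the sweep varies n
# and the base set was built from a fixed expected recurrent degree, the
# degree (not rho_rec) is held across the axis.
.set_axis <- function(base, axis, value) {
  args <- list(N = base$N, n = base$n, rho_aff = base$rho_aff,
               r_aff = base$r_aff, rho_rec = base$rho_rec,
               p_plus = base$p_plus, K = base$K,
               alpha_fid = base$alpha_fid, alpha_spc = base$alpha_spc)
  args[[axis]] <- value
  if (axis == "n" && is.finite(base$rec_degree)) {
    args$rho_rec <- NULL
    args$rec_degree <- base$rec_degree
  }
  do.call(model_params, args)
}

#' Capacity parameter sweep
#'
#' Runs `trials` independent [measure_capacity()] trials for every value on
#' one parameter axis and aggregates mean capacity, standard error and
#' insertion reliability. Cells whose reliability falls below
#' `reliability_floor` are flagged excluded (the convention under which
#' capacity figures are reported). Trials use independent derived seeds,
#' so results do not depend on execution order.
#'
#' @param base a [model_params()] object giving the fixed parameters.
#' @param axis one of `"n"`, `"p_plus"`, `"r_aff"`, `"K"`, `"rho_rec"`,
#'   `"rho_aff"`.
#' @param values axis values.
#' @param trials trials per cell.
#' @param M_max presentation budget per trial.
#' @param reliability_floor minimum fraction of successful insertions.
#' @param seed optional master seed.
#' @return A `sweep_result` data frame with one row per cell: `axis`,
#'   `value`, `mean_capacity`, `se_capacity`, `reliability`, `trials`,
#'   `n_censored` (trials whose capacity exceeded `M_max`), `excluded`.
#' @export
run_sweep <- function(base, axis, values, trials, M_max,
                      reliability_floor = 0.99, seed = NULL) {
  axis <- match.arg(axis, .sweep_axes)
  if (!length(values)) {
    out <- data.frame(axis = character(0), value = numeric(0),
                      mean_capacity = numeric(0), se_capacity = numeric(0),
                      reliability = numeric(0), trials = integer(0),
                      n_censored = integer(0), excluded = logical(0))
    class(out) <- c("sweep_result", "data.frame")
    return(out)
  }
  seeds <- derive_trial_seeds(seed, length(values) * trials)
  rows <- vector("list", length(values))
  for (vi in seq_along(values)) {
    p <- .set_axis(base, axis, values[[vi]])
    caps <- rep(NA_real_, trials); rel <- rep(NA_real_, trials)
    censored <- 0L
    for (tr in seq_len(trials)) {
      set.seed(seeds[(vi - 1L) * trials + tr])
      rec <- tryCatch(measure_capacity(p, M_max), error = function(e) NULL)
      if (is.null(rec)) { censored <- censored + 1L; next }
      caps[tr] <- rec$capacity
      rel[tr] <- rec$reliability
    }
    ok <- !is.na(caps)
    rows[[vi]] <- data.frame(
      axis = axis, value = values[[vi]],
      mean_capacity = if (any(ok)) mean(caps[ok]) else NA_real_,
      se_capacity = if (sum(ok) > 1) sd(caps[ok]) / sqrt(sum(ok)) else NA_real_,
      reliability = if (any(ok)) mean(rel[ok]) else NA_real_,
      trials = sum(ok), n_censored = censored
    )
  }
  out <- do.call(rbind, rows)
  out$excluded <- is.na(out$reliability) | out$reliability < reliability_floor
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Track the first association through the palimpsest
#'
#' Repeats a tracked learning sequence `trials` times and averages, per
#' presentation index, the number of vertices of \eqn{B_0} activated by
#' afferent drive alone, the number active after percolation, and the
#' empirical signal and noise strong-edge densities.
#'
#' @param params a [model_params()] object.
#' @param M_max presentations per trial.
#' @param trials number of independent trials.
#' @param seed optional master seed.
#' @return Data frame with one row per insertion index.
#' @export
track_association_zero <- function(params, M_max, trials, seed = NULL) {
  seeds <- derive_trial_seeds(seed, trials)
  acc <- NULL
  for (tr in seq_len(trials)) {
    set.seed(seeds[tr])
    run <- run_learning_sequence(params, M_max, track = TRUE,
                                 probe_recall = TRUE)
    cols <- c("afferent_active", "recall_active_count",
              "signal_density", "noise_density")
    block <- as.matrix(run$log[, cols])
    acc <- if (is.null(acc)) block else acc + block
  }
  out <- data.frame(insertion = seq_len(M_max) - 1L, acc / trials)
  names(out) <- c("insertion", "afferent_active_B0", "percolated_active_B0",
                  "signal_density", "noise_density")
  out
}

#' Noise-tolerance experiment
#'
#' Measures recall robustness of the first association against two noise
#' kinds. `kind = "query"`: the query activates \eqn{A_0} with precision
#' lambda (levels) and the outcome is the fraction of trials in which the
#' association is memorized. `kind = "recurrent"`: the clean query is
#' accompanied by m extra initially active vertices outside \eqn{B_0}
#' (levels) and the outcome is the fraction of trials in which percolation
#' spreads beyond the specificity bound. Each checkpoint is a number of
#' competing insertions after which all levels are probed (probes are
#' side-effect-free, so one learned network serves every level).
#'
#' @param params a [model_params()] object.
#' @param kind `"query"` or `"recurrent"`.
#' @param levels lambda values (query) or extra-seed counts (recurrent).
#' @param checkpoints competing-insertion counts at which to probe.
#' @param trials number of independent trials.
#' @param seed optional master seed.
#' @return Data frame with columns `kind`, `checkpoint`, `level`,
#'   `outcome` (`"memorized"` or `"spurious_percolation"`), `fraction`,
#'   `trials`.
#' @export
noise_tolerance_experiment <- function(params, kind = c("query", "recurrent"),
                                       levels, checkpoints, trials,
                                       seed = NULL) {
  kind <- match.arg(kind)
  checkpoints <- sort(as.integer(checkpoints))
  seeds <- derive_trial_seeds(seed, trials)
  N <- params$N; n <- params$n
  hits <- matrix(0L, length(checkpoints), length(levels))
  for (tr in seq_len(trials)) {
    set.seed(seeds[tr])
    aff <- build_afferent_state(N, params$rho_aff, params$r_aff)
    rec <- build_recurrent_state(N, params$rho_rec)
    A0 <- sample_pattern(N, n); B0 <- sample_pattern(N, n)
    store_recurrent_pattern(rec, B0)
    learn_association(aff, A0, B0, params$p_plus, params$p_minus)
    done <- 0L
    outside <- setdiff(seq_len(N), B0)
    for (ci in seq_along(checkpoints)) {
      while (done < checkpoints[ci]) {
        Ai <- sample_pattern(N, n); Bi <- sample_pattern(N, n)
        store_recurrent_pattern(rec, Bi)
        learn_association(aff, Ai, Bi, params$p_plus, params$p_minus)
        done <- done + 1L
      }
      for (li in seq_along(levels)) {
        if (kind == "query") {
          q <- make_noisy_query(A0, levels[li], N)
          res <- recall(aff, rec, q, integer(0), params, target = B0)
          hit <- isTRUE(res$memorized)
        } else {
          seeds_B <- sample(outside, levels[li])
          res <- recall(aff, rec, A0, seeds_B, params, target = B0)
          hit <- res$specificity_count > .floor_count(params$alpha_spc * n)
        }
        hits[ci, li] <- hits[ci, li] + hit
      }
    }
  }
  data.frame(
    kind = kind,
    checkpoint = rep(checkpoints, times = length(levels)),
    level = rep(levels, each = length(checkpoints)),
    outcome = if (kind == "query") "memorized" else "spurious_percolation",
    fraction = as.vector(hits) / trials,
    trials = trials
  )
}
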