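#' Clip a pattern into the recurrent network
#'
#' Willshaw-style storage: every *present* recurrent edge with both
#' endpoints inside `pattern` is turned strong. No other edge changes and
#' presence never changes, so storing is idempotent.
#'
#' @param rec a `recurrent_state` (modified in place).
#' @param pattern vertex indices of the pattern.
#' @return Invisibly, the number of edges newly turned strong.
#' @export
store_recurrent_pattern <- function(rec, pattern) {
  pattern <- as.integer(pattern)
  if (length(pattern) && (min(pattern) < 1L || max(pattern) > rec$N))
    stop("pattern contains vertex indices outside 1..N")
  idx <- .col_entries(rec$p, pattern)
  m <- logical(rec$N); m[pattern] <- TRUE
  sel <- idx[m[rec$i[idx]]]
  newly <- sel[rec$x[sel] == 0L]
  rec$x[newly] <- 1L
  invisible(length(newly))
}

#' One-shot learning of an association
#'
#' Stochastic binary Hebbian learning with normalizing pruning, applied as
#' one atomic presentation step: each present-weak afferent edge from `A_i`
#' into `B_i` independently turns strong with probability `p_plus`
#' (insertion), and each present-strong edge into `B_i` from a source
#' outside `A_i` independently turns weak with probability `p_minus`
#' (pruning). Edges into targets outside `B_i` are untouched; presence never
#' changes. Insertion and pruning touch disjoint edge sets, so their order
#' is immaterial.
#'
#' @param aff an `afferent_state` (modified in place).
#' @param A_i source pattern in \eqn{\mathcal{A}}.
#' @param B_i target pattern in \eqn{\mathcal{B}}.
#' @param p_plus insertion probability.
#' @param p_minus prune probability (use the [derive_prune_probability()]
#'   value for palimpsest normalization).
#' @return Invisibly, a list with counts `edges_strengthened` and
#'   `edges_pruned`.
#' @export
learn_association <- function(aff, A_i, B_i, p_plus, p_minus) {
  stopifnot(p_plus >= 0, p_plus <= 1, p_minus >= 0, p_minus <= 1)
  A_i <- as.integer(A_i); B_i <- as.integer(B_i)
  if (length(c(A_i, B_i)) && (min(c(A_i, B_i)) < 1L || max(c(A_i, B_i)) > aff$N))
    stop("pattern contains vertex indices outside 1..N")
  idx <- .col_entries(aff$p, B_i)
  inA <- logical(aff$N); inA[A_i] <- TRUE
  m <- inA[aff$i[idx]]
  xs <- aff$x[idx]
  ins_cand <- idx[m & xs == 0L]
  ins <- ins_cand[runif(length(ins_cand)) < p_plus]
  prn_cand <- idx[!m & xs == 1L]
  prn <- prn_cand[runif(length(prn_cand)) < p_minus]
  aff$x[ins] <- 1L
  aff$x[prn] <- 0L
  invisible(list(edges_strengthened = length(ins), edges_pruned = length(prn)))
}

#' Run a palimpsest learning sequence
#'
#' Builds fresh afferent and recurrent states, samples `M_max` association
#' pairs, and presents them once each: the target pattern is clipped into
#' the recurrent network and the afferent edges are updated by
#' [learn_association()]. Association 1 is the tracked association
#' \eqn{(A_0, B_0)}.
#'
#' @param params a [model_params()] object.
#' @param M_max number of presentations (>= 1).
#' @param track if `TRUE`, log per-presentation strong-edge densities from
#'   \eqn{A_0} into \eqn{B_0} (signal) and into a fixed random reference
#'   subset of \eqn{\mathcal{B} \setminus B_0} (noise), plus update counts.
#' @param probe_recall if `TRUE`, after every presentation probe recall of
#'   association 1 with a clean query (side-effect-free) and log the number
#'   of afferently activated and percolated vertices inside \eqn{B_0} and
#'   the memorization flag.
#' @param prestore if `TRUE`, clip all `M_max` target patterns into the
#'   recurrent network before any afferent learning; otherwise (default)
#'   each pattern is clipped at its own presentation.
#' @param noise_ref_cols number of reference columns used for the tracked
#'   noise density.
#' @return List with `aff`, `rec`, `pairs` (list of `list(A, B)`), `log`
#'   (data frame, one row per presentation; columns beyond the update counts
#'   are `NA` unless the corresponding tracking was requested) and `params`.
#' @export
run_learning_sequence <- function(params, M_max, track = FALSE,
                                  probe_recall = FALSE, prestore = FALSE,
                                  noise_ref_cols = 200L) {
  stopifnot(inherits(params, "model_params"), M_max >= 1)
  N <- params$N; n <- params$n
  aff <- build_afferent_state(N, params$rho_aff, params$r_aff)
  rec <- build_recurrent_state(N, params$rho_rec)
  pairs <- lapply(seq_len(M_max), function(i)
    list(A = sample_pattern(N, n), B = sample_pattern(N, n)))
  if (prestore) for (pr in pairs) store_recurrent_pattern(rec, pr$B)
  A0 <- pairs[[1L]]$A; B0 <- pairs[[1L]]$B
  noise_ref <- if (track) {
    outside <- setdiff(seq_len(N), B0)
    sort(sample(outside, min(noise_ref_cols, length(outside))))
  }
  log <- data.frame(
    insertion = seq_len(M_max) - 1L,
    edges_strengthened = NA_integer_, edges_pruned = NA_integer_,
    signal_density = NA_real_, noise_density = NA_real_,
    afferent_active = NA_integer_, recall_active_count = NA_integer_,
    memorized = NA
  )
  for (i in seq_len(M_max)) {
    if (!prestore) store_recurrent_pattern(rec, pairs[[i]]$B)
    upd <- learn_association(aff, pairs[[i]]$A, pairs[[i]]$B,
                             params$p_plus, params$p_minus)
    log$edges_strengthened[i] <- upd$edges_strengthened
    log$edges_pruned[i] <- upd$edges_pruned
    if (track) {
      log$signal_density[i] <- strong_density(aff, A0, B0)$fraction
      log$noise_density[i] <- strong_density(aff, A0, noise_ref)$fraction
    }
    if (probe_recall) {
      deg <- afferent_strong_degrees(aff, A0)
      log$afferent_active[i] <- sum(deg[B0] >= params$K)
      res <- percolate(rec, deg, integer(0), params$K)
      log$recall_active_count[i] <- length(intersect(res$final_active_B, B0))
      log$memorized[i] <- is_memorized(res, B0, n, params$alpha_fid,
                                       params$alpha_spc)
    }
  }
  list(aff = aff, rec = rec, pairs = pairs, log = log, params = params)
}
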