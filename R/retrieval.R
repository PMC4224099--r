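#' Afferent strong degrees
#'
#' For every vertex b of population \eqn{\mathcal{B}}, the number of strong
#' afferent edges from the currently active source set into b -- the
#' quantity deg(b; S) that is compared against the activation threshold K.
#'
#' @param aff an `afferent_state`.
#' @param active_A active source vertices in \eqn{\mathcal{A}}.
#' @return Integer vector of length `N`.
#' @export
afferent_strong_degrees <- function(aff, active_A) {
  active_A <- as.integer(active_A)
  if (length(active_A) && (min(active_A) < 1L || max(active_A) > aff$N))
    stop("active set contains vertex indices outside 1..N")
  idx <- .col_entries(aff$tp, active_A)
  strong <- aff$x[aff$tmap[idx]] == 1L
  tabulate(aff$ti[idx][strong], aff$N)
}

#' Bootstrap percolation with first-spike semantics
#'
#' Synchronous-round spreading of activity through the strong recurrent
#' edges: round 0 activates the seed vertices and every vertex whose
#' afferent strong degree reaches K; each later round activates every
#' inactive vertex whose afferent degree plus strong recurrent in-degree
#' from the currently active set reaches K. Active vertices never
#' deactivate, so the process is monotone and halts in at most N rounds.
#'
#' @param rec a `recurrent_state`, or `NULL` for the no-recurrent baseline
#'   (one-step threshold rule).
#' @param afferent_degrees per-vertex afferent strong degree (length N).
#' @param seeds_B extra initially active vertices in \eqn{\mathcal{B}}
#'   (recurrent noise).
#' @param K activation threshold (>= 0; K = 0 activates everything).
#' @return A `recall_result`: list with `seeds_B`, `newly_active_per_round`
#'   (list of integer vectors, round 0 first), `final_active_B`, `rounds`,
#'   and fidelity/specificity fields left `NA` until a target is designated
#'   (see [recall()]).
#' @export
percolate <- function(rec, afferent_degrees, seeds_B = integer(0), K) {
  stopifnot(K >= 0)
  N <- length(afferent_degrees)
  if (!is.null(rec)) stopifnot(rec$N == N)
  deg <- as.integer(afferent_degrees)
  active <- logical(N)
  init <- sort(unique(c(which(deg >= K), as.integer(seeds_B))))
  newly <- list(init)
  active[init] <- TRUE
  frontier <- init
  if (!is.null(rec)) {
    repeat {
      if (!length(frontier)) break
      idx <- .col_entries(rec$tp, frontier)
      strong <- rec$x[rec$tmap[idx]] == 1L
      tgt <- rec$ti[idx][strong]
      if (length(tgt)) deg <- deg + tabulate(tgt, N)
      new <- which(!active & deg >= K)
      if (!length(new)) break
      active[new] <- TRUE
      newly[[length(newly) + 1L]] <- new
      frontier <- new
    }
  }
  structure(list(
    query = NULL, seeds_B = as.integer(seeds_B),
    newly_active_per_round = newly,
    final_active_B = which(active),
    fidelity_count = NA_integer_, specificity_count = NA_integer_,
    memorized = NA, rounds = length(newly)
  ), class = "recall_result")
}

#' Noisy query construction
#'
#' Activates the tracked source pattern with precision `lam`: the query is
#' the union of `round(lam * n)` vertices drawn uniformly from `A_0` and
#' `n - round(lam * n)` vertices drawn uniformly from outside `A_0`, so the
#' query always has size n (ties in `lam * n` resolve by R's `round`).
#'
#' @param A_0 the clean source pattern.
#' @param lam precision in \[0,1\].
#' @param N population size.
#' @return Sorted integer vector of size `length(A_0)`.
#' @export
make_noisy_query <- function(A_0, lam, N) {
  stopifnot(lam >= 0, lam <= 1)
  n <- length(A_0)
  k <- as.integer(round(lam * n))
  keep <- if (k > 0) sample(A_0, k) else integer(0)
  fill <- if (k < n) sample(setdiff(seq_len(N), A_0), n - k) else integer(0)
  sort(c(keep, fill))
}

#' Recall an association
#'
#' Activates the query in \eqn{\mathcal{A}} (source vertices are clamped;
#' no propagation happens on the source side), computes afferent strong
#' degrees and runs bootstrap percolation through \eqn{\mathcal{B}}. The
#' synaptic state is never modified. If a `target` pattern is given, the
#' fidelity count (active inside the target) and specificity count (active
#' outside it) are filled in and the memorization flag evaluated.
#'
#' @param aff an `afferent_state`.
#' @param rec a `recurrent_state` or `NULL`.
#' @param query active source pattern.
#' @param seeds_B extra initially active target-side vertices.
#' @param params a [model_params()] object (supplies K and the
#'   fidelity/specificity fractions).
#' @param target optional target pattern \eqn{B_0} against which
#'   fidelity/specificity are counted.
#' @return A `recall_result`.
#' @export
recall <- function(aff, rec, query, seeds_B = integer(0), params,
                   target = NULL) {
  deg <- afferent_strong_degrees(aff, query)
  res <- percolate(rec, deg, seeds_B, params$K)
  res$query <- as.integer(query)
  if (!is.null(target)) {
    res$fidelity_count <- length(intersect(res$final_active_B, target))
    res$specificity_count <- length(res$final_active_B) - res$fidelity_count
    res$memorized <- is_memorized(res, target, params$n,
                                  params$alpha_fid, params$alpha_spc)
  }
  res
}

#' Memorization predicate
#'
#' An association counts as memorized if the final active set contains at
#' least `ceiling(alpha_fid * n)` vertices of the target pattern (fidelity)
#' and at most `floor(alpha_spc * n)` vertices outside it (specificity).
#'
#' @param result a `recall_result`.
#' @param B_0 the target pattern.
#' @param n pattern size.
#' @param alpha_fid fidelity fraction.
#' @param alpha_spc specificity fraction.
#' @return Logical flag.
#' @export
is_memorized <- function(result, B_0, n, alpha_fid, alpha_spc) {
  fid <- length(intersect(result$final_active_B, B_0))
  spc <- length(result$final_active_B) - fid
  fid >= .ceil_count(alpha_fid * n) && spc <= .floor_count(alpha_spc * n)
}

#' @export
print.recall_result <- function(x, ...) {
  cat(sprintf("Recall result: %d active after %d round(s)\n",
              length(x$final_active_B), x$rounds))
  if (!is.na(x$fidelity_count))
    cat(sprintf("  fidelity %d, specificity %d, memorized: %s\n",
                x$fidelity_count, x$specificity_count, x$memorized))
  invisible(x)
}

#' Serialize a recall result to JSON
#'
#' Explicit vertex lists are kept for small populations and replaced by
#' per-round counts for large ones (diagnostics vs. bulk runs).
#'
#' @param result a `recall_result`.
#' @param path file to write.
#' @param full_lists keep explicit vertex lists regardless of size.
#' @return The path, invisibly.
#' @export
write_recall_result <- function(result, path, full_lists = NULL) {
  keep <- if (is.null(full_lists)) length(result$final_active_B) <= 1000 else full_lists
  obj <- list(
    indexing = "1-based vertex indices",
    seeds_B = result$seeds_B,
    rounds = result$rounds,
    fidelity_count = result$fidelity_count,
    specificity_count = result$specificity_count,
    memorized = result$memorized,
    active_per_round = lengths(result$newly_active_per_round)
  )
  if (keep) {
    obj$query <- result$query
    obj$final_active_B <- result$final_active_B
    obj$newly_active_per_round <- result$newly_active_per_round
  } else {
    obj$final_active_count <- length(result$final_active_B)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
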