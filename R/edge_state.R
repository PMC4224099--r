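# Sparse synaptic edge state.
#
# A directed edge set over N source and N target vertices is stored in
# compressed-sparse-column form twice: `p`/`i` index present edges by target
# column (i = source row), `tp`/`ti` index the same edges by source column
# (ti = target row), and `tmap` maps each source-ordered entry to its
# position in the target-ordered arrays. Strengths live in a single 0/1
# integer vector `x` aligned with the target-ordered arrays, so "strong"
# is by construction a subset of "present". The whole structure sits in an
# environment: learning flips entries of `x` in place, which keeps a
# 5-million-edge state update at constant memory.

.new_edge_state <- function(N, col, row, x, kind) {
  ord <- order(col, row, method = "radix")
  col <- col[ord]; row <- row[ord]; x <- x[ord]
  p <- c(0L, cumsum(tabulate(col, N)))
  tord <- order(row, method = "radix")       # stable: col ascending within row
  tp <- c(0L, cumsum(tabulate(row, N)))
  e <- new.env(parent = emptyenv())
  e$N <- as.integer(N)
  e$p <- p; e$i <- row; e$x <- as.integer(x)
  e$tp <- tp; e$ti <- col[tord]; e$tmap <- tord
  e$kind <- kind
  class(e) <- c(paste0(kind, "_state"), "edge_state")
  e
}

# Entry indices (into i/x) of the target-ordered CSC for a set of columns,
# or of the source-ordered CSC when given `tp`.
.col_entries <- function(p, cols) {
  if (!length(cols)) return(integer(0))
  cols <- as.integer(cols)
  sequence(p[cols + 1L] - p[cols], from = p[cols] + 1L)
}

# Bernoulli(rho) presence over all ordered pairs, realized exactly as a
# binomial total with uniformly placed positions (the two constructions give
# the same product measure). Self-pairs are excluded unless allowed.
.sample_pairs <- function(N, rho, self_pairs) {
  npos <- if (self_pairs) N * N else N * (N - 1)
  stopifnot(npos < 2^31)
  nnz <- rbinom(1L, npos, rho)
  pos <- sample.int(npos, nnz)
  if (self_pairs) {
    col <- (pos - 1L) %/% N + 1L
    row <- (pos - 1L) %% N + 1L
  } else {
    col <- (pos - 1L) %/% (N - 1L) + 1L
    r0 <- (pos - 1L) %% (N - 1L) + 1L
    row <- r0 + (r0 >= col)
  }
  list(col = col, row = row)
}

#' Build the afferent synaptic state
#'
#' Each of the \eqn{N^2} ordered pairs (a, b) with a in population
#' \eqn{\mathcal{A}} and b in \eqn{\mathcal{B}} carries a present edge
#' independently with probability `rho_aff`; each present edge is
#' independently strong with probability `r_aff`.
#'
#' @param N population size.
#' @param rho_aff afferent presence probability.
#' @param r_aff initial strong fraction.
#' @return An `afferent_state` environment (reference semantics).
#' @export
build_afferent_state <- function(N, rho_aff, r_aff) {
  stopifnot(N >= 1, rho_aff >= 0, rho_aff <= 1, r_aff >= 0, r_aff <= 1)
  pr <- .sample_pairs(N, rho_aff, self_pairs = TRUE)
  x <- as.integer(runif(length(pr$col)) < r_aff)
  .new_edge_state(N, pr$col, pr$row, x, "afferent")
}

#' Build the recurrent synaptic state
#'
#' Each ordered pair of distinct vertices within population
#' \eqn{\mathcal{B}} carries a present directed edge independently with
#' probability `rho_rec`; all recurrent edges start weak and are clipped
#' strong pattern by pattern via [store_recurrent_pattern()].
#'
#' @param N population size.
#' @param rho_rec recurrent presence probability.
#' @return A `recurrent_state` environment (reference semantics).
#' @export
build_recurrent_state <- function(N, rho_rec) {
  stopifnot(N >= 1, rho_rec >= 0, rho_rec <= 1)
  pr <- .sample_pairs(N, rho_rec, self_pairs = FALSE)
  .new_edge_state(N, pr$col, pr$row, integer(length(pr$col)), "recurrent")
}

#' Sample a random pattern
#'
#' A uniformly random size-`n` subset of the vertex indices `1:N`.
#'
#' @param N population size.
#' @param n pattern size, `0 <= n <= N`.
#' @return Sorted integer vector of length `n`.
#' @export
sample_pattern <- function(N, n) {
  if (n > N) stop("invalid parameters: pattern size n exceeds population size N")
  if (n < 0) stop("invalid parameters: n must be non-negative")
  if (n == 0) return(integer(0))
  sort(sample.int(N, n))
}

#' Number of present / strong edges
#'
#' @param state an `edge_state`.
#' @return Edge count.
#' @export
n_present <- function(state) length(state$i)

#' @rdname n_present
#' @export
n_strong <- function(state) sum(state$x)

#' Strong-edge density between vertex sets
#'
#' Fraction of *present* edges from `from` into `to` that are currently
#' strong -- the empirical counterpart of the signal probability (when
#' `from`, `to` are an association's patterns) or the noise probability
#' (when `to` lies outside the target pattern).
#'
#' @param state an `edge_state`.
#' @param from source vertex indices.
#' @param to target vertex indices.
#' @return List with `fraction`, `n_strong`, `n_present`.
#' @export
strong_density <- function(state, from, to) {
  idx <- .col_entries(state$p, to)
  m <- logical(state$N); m[from] <- TRUE
  sel <- idx[m[state$i[idx]]]
  ns <- sum(state$x[sel]); np <- length(sel)
  list(fraction = if (np > 0) ns / np else NA_real_,
       n_strong = ns, n_present = np)
}

#' @export
print.edge_state <- function(x, ...) {
  cat(sprintf("%s synaptic state: N = %d, %d present edges (%d strong)\n",
              x$kind, x$N, n_present(x), n_strong(x)))
  invisible(x)
}

# Deep copy (states are environments, so `<-` aliases them).
edge_state_copy <- function(state) {
  e <- new.env(parent = emptyenv())
  for (nm in ls(state, all.names = TRUE)) assign(nm, get(nm, envir = state), envir = e)
  class(e) <- class(state)
  e
}
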