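# Shared fixtures and independent oracles for the test suite.

# Small, fast parameter set with a healthy percolation regime:
# capacity ~ 25-30, single trial ~ 0.1 s.
small_params <- function(...) {
  args <- modifyList(
    list(N = 1000, n = 50, rho_aff = 0.2, r_aff = 0.1,
         rec_degree = 5, p_plus = 0.6, K = 5),
    list(...))
  do.call(model_params, args)
}

# Figure-scale parameter set (used sparingly).
fig_params <- function(...) {
  args <- modifyList(
    list(N = 5000, n = 140, rho_aff = 0.2, r_aff = 0.1,
         rec_degree = 8, p_plus = 0.6, K = 12,
         alpha_fid = 0.8, alpha_spc = 1.0),
    list(...))
  do.call(model_params, args)
}

# Dense 0/1 matrices from an edge state (rows = sources, cols = targets).
state_present_matrix <- function(state) {
  M <- matrix(0L, state$N, state$N)
  cols <- rep.int(seq_len(state$N), diff(state$p))
  M[cbind(state$i, cols)] <- 1L
  M
}

state_strong_matrix <- function(state) {
  M <- matrix(0L, state$N, state$N)
  cols <- rep.int(seq_len(state$N), diff(state$p))
  M[cbind(state$i, cols)] <- state$x
  M
}

# Asynchronous one-vertex-at-a-time percolation oracle on a dense strong
# recurrent matrix. Activation is monotone, so the fixed point must agree
# with the synchronous implementation regardless of update order.
async_percolate_oracle <- function(strong_rec, affdeg, seeds, K) {
  N <- length(affdeg)
  active <- logical(N)
  active[seeds] <- TRUE
  repeat {
    indeg <- affdeg + as.vector(crossprod(strong_rec, active))
    cand <- which(!active & indeg >= K)
    if (!length(cand)) break
    active[cand[sample.int(length(cand), 1L)]] <- TRUE
  }
  which(active)
}

# The documented per-trial seed-splitting rule, restated independently.
derive_seed_oracle <- function(master, k) {
  set.seed(master)
  sample.int(2147483646L, k)
}

# Hand-constructable edge state from explicit edge lists (tests only).
edge_state_from_edges <- function(N, from, to, strong, kind = "recurrent") {
  percmem:::.new_edge_state(N, as.integer(to), as.integer(from),
                            as.integer(strong), kind)
}
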