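test_that("afferent strong degrees equal brute-force edge counting", {
  set.seed(31)
  a <- build_afferent_state(10, 0.5, 0.5)
  expect_identical(afferent_strong_degrees(a, integer(0)), integer(10))
  S <- state_strong_matrix(a)
  for (k in 1:5) {
    act <- sample_pattern(10, sample(0:10, 1))
    brute <- if (length(act)) colSums(S[act, , drop = FALSE]) else numeric(10)
    expect_equal(afferent_strong_degrees(a, act), as.integer(brute))
  }
  expect_error(afferent_strong_degrees(a, 11L), "outside")
})

test_that("percolation edge cases follow the threshold rule", {
  set.seed(32)
  g <- build_recurrent_state(15, 0.2)
  affdeg <- rep(0L, 15)
  res <- percolate(g, affdeg, integer(0), K = 0)
  expect_identical(res$final_active_B, 1:15)      # K = 0 activates all
  expect_identical(res$rounds, 1L)

  # no strong recurrent edges: one-step rule plus seeds
  affdeg <- c(3L, 1L, 0L, 2L, rep(0L, 11))
  res <- percolate(g, affdeg, seeds_B = 7L, K = 2)
  expect_identical(res$final_active_B, sort(c(1L, 4L, 7L)))

  # NULL recurrent state is the no-recurrent baseline
  res0 <- percolate(NULL, affdeg, integer(0), K = 2)
  expect_identical(res0$final_active_B, c(1L, 4L))
})

test_that("synchronous percolation reaches the asynchronous fixed point", {
  set.seed(33)
  for (k in 1:50) {
    N <- 20
    rec <- build_recurrent_state(N, 0.25)
    for (j in 1:2) store_recurrent_pattern(rec, sample_pattern(N, 8))
    affdeg <- rbinom(N, 4, 0.4)
    seeds <- sample_pattern(N, sample(0:3, 1))
    K <- sample(1:3, 1)
    res <- percolate(rec, affdeg, seeds, K)
    oracle <- async_percolate_oracle(state_strong_matrix(rec), affdeg,
                                     seeds, K)
    expect_identical(res$final_active_B, oracle)
    # first-spike semantics: rounds grow monotonically, bounded by N
    expect_lte(res$rounds, N)
    expect_identical(sort(unlist(res$newly_active_per_round)),
                     res$final_active_B)
  }
})

test_that("activation is monotone in edges, seeds and threshold", {
  set.seed(34)
  N <- 30
  rec <- build_recurrent_state(N, 0.2)
  store_recurrent_pattern(rec, sample_pattern(N, 12))
  affdeg <- rbinom(N, 5, 0.3)
  base <- percolate(rec, affdeg, integer(0), K = 2)$final_active_B
  withseed <- percolate(rec, affdeg, seeds_B = 3L, K = 2)$final_active_B
  lowerK <- percolate(rec, affdeg, integer(0), K = 1)$final_active_B
  expect_true(all(base %in% withseed))
  expect_true(all(base %in% lowerK))
})

test_that("noisy queries mix pattern and non-pattern vertices exactly", {
  set.seed(35)
  A0 <- sample_pattern(500, 100)
  expect_identical(make_noisy_query(A0, 1, 500), A0)
  q0 <- make_noisy_query(A0, 0, 500)
  expect_length(intersect(q0, A0), 0)
  expect_length(q0, 100)
  q7 <- make_noisy_query(A0, 0.7, 500)
  expect_length(intersect(q7, A0), 70)
  expect_length(q7, 100)
})

test_that("recall composes degrees and percolation on a hand-built net", {
  # 6 + 6 vertices, K = 2. Afferent strong: a1,a2 -> b1; a1 -> b2.
  # Weak afferent a3 -> b4 must not count. Recurrent strong: b1 -> b2,
  # b1 -> b3, b2 -> b3; present-weak b3 -> b4 must not count.
  aff <- edge_state_from_edges(6, from = c(1, 2, 1, 3), to = c(1, 1, 2, 4),
                               strong = c(1, 1, 1, 0), kind = "afferent")
  rec <- edge_state_from_edges(6, from = c(1, 1, 2, 3), to = c(2, 3, 3, 4),
                               strong = c(1, 1, 1, 0))
  p <- model_params(N = 6, n = 3, rho_aff = 0.5, r_aff = 0.5, rho_rec = 0.5,
                    p_plus = 0, K = 2, alpha_fid = 0.6, alpha_spc = 1)
  res <- recall(aff, rec, query = c(1L, 2L, 3L), integer(0), p,
                target = c(1L, 2L, 3L))
  expect_identical(res$newly_active_per_round,
                   list(1L, 2L, 3L))         # b1, then b2 (aff 1 + rec 1), then b3
  expect_identical(res$final_active_B, 1:3)
  expect_identical(res$fidelity_count, 3L)
  expect_identical(res$specificity_count, 0L)
  expect_true(res$memorized)

  # empty query with K >= 1 activates nothing
  res0 <- recall(aff, rec, integer(0), integer(0), p)
  expect_length(res0$final_active_B, 0)
})

test_that("without recurrent edges recall reduces to one-step retrieval", {
  set.seed(36)
  p <- small_params(rho_rec = 0, rec_degree = NULL)
  aff <- build_afferent_state(p$N, p$rho_aff, p$r_aff)
  rec <- build_recurrent_state(p$N, 0)
  A0 <- sample_pattern(p$N, p$n)
  deg <- afferent_strong_degrees(aff, A0)
  res <- recall(aff, rec, A0, integer(0), p)
  expect_identical(res$final_active_B, which(deg >= p$K))
  expect_identical(res$rounds, 1L)
})

test_that("memorization thresholds use at-least / at-most semantics", {
  mk <- function(fid, spc, B0, N = 5000) {
    structure(list(final_active_B = c(B0[seq_len(fid)],
                                      setdiff(seq_len(N), B0)[seq_len(spc)]),
                   seeds_B = integer(0)), class = "recall_result")
  }
  B0 <- 1:140
  expect_true(is_memorized(mk(112, 0, B0), B0, 140, 0.8, 1.0))
  expect_false(is_memorized(mk(111, 0, B0), B0, 140, 0.8, 1.0))
  expect_false(is_memorized(mk(112, 141, B0), B0, 140, 0.8, 1.0))
  B0s <- 1:100
  expect_true(is_memorized(mk(100, 100, B0s, 500), B0s, 100, 1.0, 1.0))
  expect_false(is_memorized(mk(100, 101, B0s, 500), B0s, 100, 1.0, 1.0))
})

test_that("recall never mutates synaptic state", {
  set.seed(37)
  p <- small_params()
  aff <- build_afferent_state(p$N, p$rho_aff, p$r_aff)
  rec <- build_recurrent_state(p$N, p$rho_rec)
  B0 <- sample_pattern(p$N, p$n)
  store_recurrent_pattern(rec, B0)
  xa <- aff$x; xr <- rec$x
  recall(aff, rec, sample_pattern(p$N, p$n), 5L, p, target = B0)
  expect_identical(aff$x, xa)
  expect_identical(rec$x, xr)
})
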