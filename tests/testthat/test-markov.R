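pooled3 <- pool_counts(table2_counts())

test_that("stationary solves simple chains in closed form", {
  u <- matrix(1 / 3, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unname(stationary(u)), rep(1 / 3, 3), tolerance = 1e-12)

  p2 <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  # closed form: pi_b = p_ab / (p_ab + p_ba)
  expect_equal(unname(stationary(p2)), c(0.75, 0.25), tolerance = 1e-12)
})

test_that("stationary of the pooled reference matrix matches the oracle", {
  P <- to_probabilities(pooled3)
  pi <- stationary(P)
  expect_equal(unname(round(pi, 4)), c(0.5008, 0.2101, 0.2891))
  expect_equal(unname(pi), power_iteration(P$probs), tolerance = 1e-9)
  expect_lt(max(abs(pi %*% P$probs - pi)), 1e-10)
})

test_that("stationary agrees with power iteration on random chains", {
  set.seed(42)
  for (i in 1:500) {
    K <- if (i %% 2) 3 else 6
    P <- random_stochastic(K)
    dimnames(P) <- list(seq_len(K), seq_len(K))
    expect_equal(unname(stationary(P)), power_iteration(P),
                 tolerance = 1e-8)
  }
})

test_that("reducible chains raise an error naming unreachable states", {
  P <- matrix(c(1, 0, 0.5, 0.5), 2, 2, byrow = TRUE,
              dimnames = list(c("sink", "src"), c("sink", "src")))
  expect_error(stationary(P), "reducible.*src")
})

test_that("bootstrap replicates are deterministic in the seed", {
  b1 <- bootstrap_matrices(pooled3, n_boot = 50, seed = 11)
  b2 <- bootstrap_matrices(pooled3, n_boot = 50, seed = 11)
  expect_identical(b1$matrices, b2$matrices)
  b3 <- bootstrap_matrices(pooled3, n_boot = 50, seed = 12)
  expect_false(identical(b1$matrices, b3$matrices))
  # and the bootstrap leaves the session RNG state alone
  set.seed(5); before <- .Random.seed
  invisible(bootstrap_matrices(pooled3, n_boot = 5, seed = 1))
  expect_identical(before, .Random.seed)
})

test_that("degenerate counts are rejected until the redraw cap", {
  m <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  m[1, 1] <- 10L
  expect_error(
    bootstrap_matrices(as_transition_counts(m), n_boot = 1, seed = 1,
                       max_reject = 50),
    "50 consecutive replicates")
  expect_error(
    bootstrap_matrices(as_transition_counts(m * 0L), n_boot = 1, seed = 1),
    "all-zero")
})

test_that("replicate cell means are unbiased for the observed probabilities", {
  obs <- to_probabilities(pooled3)$probs
  for (scheme in c("pooled", "row-stratified")) {
    boot <- bootstrap_matrices(pooled3, n_boot = 5000, seed = 3,
                               scheme = scheme)
    means <- Reduce(`+`, boot$matrices) / length(boot$matrices)
    # Monte-Carlo SE of each cell mean, from the replicate spread
    sims <- vapply(boot$matrices, as.vector, numeric(9))
    se <- apply(sims, 1, sd) / sqrt(ncol(sims))
    expect_true(all(abs(as.vector(means - obs)) < 3 * se + 1e-4))
  }
})

test_that("steady-state result satisfies its invariants", {
  ss <- steady_state_test(pooled3, n_boot = 400, seed = 9)
  expect_equal(sum(ss$point), 1, tolerance = 1e-9)
  expect_equal(sum(ss$boot_mean), 1, tolerance = 1e-9)
  expect_true(all(ss$ci_low <= ss$boot_mean & ss$boot_mean <= ss$ci_high))
  expect_false(any(ss$exceeds_null & ss$below_null))
  df <- as.data.frame(ss)
  expect_equal(df$state, c("F", "M", "HALL"))
})

test_that("a symmetric chain shows no departure from the uniform null", {
  # large balanced counts from an exchangeable 3-state chain
  m <- matrix(500L, 3, 3, dimnames = list(c("a", "b", "c"),
                                          c("a", "b", "c")))
  ss <- steady_state_test(as_transition_counts(m), n_boot = 400, seed = 2)
  expect_false(any(ss$exceeds_null))
  expect_false(any(ss$below_null))
})

test_that("per-cell CIs cover the observed probabilities sensibly", {
  tab <- transition_prob_cis(pooled3, n_boot = 2000, seed = 4)
  ff <- tab[tab$from == "F" & tab$to == "F", ]
  expect_lt(abs(ff$boot_mean - 0.9524), 0.01)
  expect_true(all(tab$ci_low <= tab$ci_high))
  # a row with a single destination is pinned at probability 1
  m <- matrix(c(0L, 10L, 5L, 5L), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  one <- transition_prob_cis(as_transition_counts(m), n_boot = 100,
                             seed = 1, scheme = "row-stratified")
  ab <- one[one$from == "a" & one$to == "b", ]
  expect_equal(c(ab$ci_low, ab$ci_high), c(1, 1))
})

test_that("percentile intervals achieve near-nominal coverage", {
  # true chain = the pooled reference matrix; datasets at its sample sizes
  P <- to_probabilities(pooled3)$probs
  truth <- unname(stationary(P))
  rt <- rowSums(pooled3$counts)
  set.seed(77)
  cover <- 0L
  n_sim <- 150
  for (s in 1:n_sim) {
    m <- t(sapply(1:3, function(r) stats::rmultinom(1, rt[r], P[r, ])))
    dimnames(m) <- dimnames(P)
    if (any(rowSums(m) == 0)) next
    ss <- steady_state_test(as_transition_counts(m), n_boot = 300,
                            seed = s)
    if (ss$ci_low[1] <= truth[1] && truth[1] <= ss$ci_high[1])
      cover <- cover + 1L
  }
  expect_gte(cover / n_sim, 0.90)
})
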