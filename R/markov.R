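#' Stationary distribution of a transition matrix
#'
#' Solves \eqn{\pi P = \pi, \sum \pi = 1} by the linear system
#' \eqn{(P' - I)\pi = 0} augmented with the normalisation constraint
#' (least-squares via QR). The chain must be irreducible on its label set,
#' which is verified by reachability on the positive-support graph before
#' solving; reducible chains raise an error naming the states that cannot
#' reach every other state.
#'
#' @param P a `transition_matrix` object or a row-stochastic numeric matrix.
#' @return named probability vector \eqn{\pi} with residual
#'   \eqn{\|\pi P - \pi\|_\infty \le 10^{-10}}.
#' @examples
#' P <- to_probabilities(pool_counts(table2_counts()))
#' round(stationary(P), 4)
#' @export
stationary <- function(P) {
  mat <- if (inherits(P, "transition_matrix")) P$probs else as.matrix(P)
  K <- nrow(mat)
  if (anyNA(mat)) stop("transition matrix has undefined rows")
  if (any(abs(rowSums(mat) - 1) > 1e-8)) stop("matrix is not row-stochastic")
  bad <- reducible_states(mat)
  if (length(bad))
    stop("chain is reducible; states not reaching/reached by all others: ",
         paste(bad, collapse = ", "))
  A <- rbind(t(mat) - diag(K), rep(1, K))
  pi <- qr.solve(A, c(rep(0, K), 1))
  pi[pi < 0 & pi > -1e-12] <- 0
  pi <- pi / sum(pi)
  res <- max(abs(pi %*% mat - pi))
  if (res > 1e-10) stop("stationary solve residual too large: ", res)
  stats::setNames(as.vector(pi), rownames(mat))
}

# labels (or indices) of states violating strong connectivity of the
# positive-support graph; empty when the chain is irreducible
reducible_states <- function(mat) {
  K <- nrow(mat)
  R <- (mat > 0) | diag(K) > 0
  M <- R
  for (i in seq_len(ceiling(log2(K)) + 1)) M <- (M %*% M) > 0
  bad <- which(!(apply(M, 1, all) & apply(M, 2, all)))
  if (is.null(rownames(mat))) bad else rownames(mat)[bad]
}

#' Bootstrap replicates of a transition matrix
#'
#' Resamples the observed transition events and row-normalises each
#' replicate. Two schemes:
#' \describe{
#'   \item{`pooled`}{all `n_pairs` (origin, destination) events are treated
#'     as one exchangeable multiset and resampled with replacement
#'     (multinomial over all cells); the default.}
#'   \item{`row-stratified`}{each origin row is resampled with replacement
#'     conditional on its observed row total (independent multinomials per
#'     row).}
#' }
#' Replicates with an empty row or a reducible chain are rejected and
#' redrawn; after `max_reject` consecutive rejections an error is raised.
#'
#' @param counts a `transition_counts` object with at least one event.
#' @param n_boot number of replicates (>= 1).
#' @param seed integer seed; the replicate set is a deterministic function
#'   of it.
#' @param scheme resampling scheme, see above.
#' @param max_reject cap on consecutive rejected replicates.
#' @return a `bootstrap_replicates` object: list of probability matrices
#'   (`matrices`), `labels`, `scheme`, `seed`, `n_redraws`.
#' @export
bootstrap_matrices <- function(counts, n_boot, seed,
                               scheme = c("pooled", "row-stratified"),
                               max_reject = 1000) {
  stopifnot(inherits(counts, "transition_counts"), n_boot >= 1)
  scheme <- match.arg(scheme)
  m <- counts$counts
  n <- sum(m)
  if (n == 0) stop("cannot bootstrap an all-zero count matrix")
  K <- nrow(m)
  rt <- rowSums(m)
  withr::with_seed(seed, {
    mats <- vector("list", n_boot)
    redraws <- 0L
    consec <- 0L
    i <- 0L
    while (i < n_boot) {
      rep_m <- if (scheme == "pooled") {
        matrix(stats::rmultinom(1, n, as.vector(m) / n), K, K)
      } else {
        t(vapply(seq_len(K), function(r) {
          if (rt[r] == 0) rep(0L, K) else
            as.integer(stats::rmultinom(1, rt[r], m[r, ] / rt[r]))
        }, integer(K)))
      }
      rowt <- rowSums(rep_m)
      ok <- all(rowt > 0)
      P <- NULL
      if (ok) {
        P <- rep_m / rowt
        ok <- length(reducible_states(P)) == 0
      }
      if (!ok) {
        redraws <- redraws + 1L
        consec <- consec + 1L
        if (consec >= max_reject)
          stop("bootstrap rejected ", max_reject,
               " consecutive replicates (degenerate counts?)")
        next
      }
      consec <- 0L
      i <- i + 1L
      dimnames(P) <- dimnames(m)
      mats[[i]] <- P
    }
    structure(list(matrices = mats, labels = counts$labels, scheme = scheme,
                   seed = seed, n_redraws = redraws),
              class = "bootstrap_replicates")
  })
}

#' Steady-state sex ratio with bootstrap CI and uniform-null test
#'
#' Computes the stationary distribution of the observed matrix, then of
#' every bootstrap replicate; reports the replicate mean and percentile
#' confidence interval per state and calls each state significantly above
#' (below) the null value iff its whole interval lies above (below) it.
#' No p-value is computed: significance is the null falling outside the
#' percentile interval.
#'
#' @param counts pooled `transition_counts` (typically 3-state; any K works).
#' @param n_boot bootstrap replicates, default 5000.
#' @param seed integer seed (required).
#' @param null_value null probability per state, default 1/3.
#' @param level confidence level, default 0.95.
#' @param scheme passed to [bootstrap_matrices()].
#' @return a `steady_state_result` with fields `labels`, `point`,
#'   `boot_mean`, `ci_low`, `ci_high`, `exceeds_null`, `below_null`,
#'   `n_boot`, `seed`, `null_value`, `level`, `scheme`, `n_redraws`.
#' @examples
#' \donttest{
#' cnt <- pool_counts(table2_counts())
#' steady_state_test(cnt, n_boot = 500, seed = 1)
#' }
#' @export
steady_state_test <- function(counts, n_boot = 5000, seed,
                              null_value = 1 / 3, level = 0.95,
                              scheme = c("pooled", "row-stratified")) {
  scheme <- match.arg(scheme)
  point <- stationary(to_probabilities(counts))
  boot <- bootstrap_matrices(counts, n_boot, seed, scheme = scheme)
  sims <- t(vapply(boot$matrices, stationary, numeric(length(point))))
  alpha <- (1 - level) / 2
  ci <- apply(sims, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  bm <- colMeans(sims)
  structure(list(
    labels = counts$labels,
    point = point,
    boot_mean = stats::setNames(bm, counts$labels),
    ci_low = stats::setNames(ci[1, ], counts$labels),
    ci_high = stats::setNames(ci[2, ], counts$labels),
    exceeds_null = stats::setNames(ci[1, ] > null_value, counts$labels),
    below_null = stats::setNames(ci[2, ] < null_value, counts$labels),
    n_boot = n_boot, seed = seed, null_value = null_value, level = level,
    scheme = scheme, n_redraws = boot$n_redraws
  ), class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, digits = 4, ...) {
  cat("Steady-state (stationary) sex ratio, ", x$n_boot,
      " bootstrap replicates (scheme: ", x$scheme, ", seed ", x$seed,
      ")\n", sep = "")
  df <- data.frame(
    state = x$labels,
    point = round(x$point, digits),
    boot_mean = round(x$boot_mean, digits),
    ci_low = round(x$ci_low, digits),
    ci_high = round(x$ci_high, digits),
    vs_null = ifelse(x$exceeds_null, sprintf("> %.4f", x$null_value),
                     ifelse(x$below_null, sprintf("< %.4f", x$null_value),
                            "ns")),
    row.names = NULL
  )
  print(df)
  invisible(x)
}

#' Convert a steady-state result to a data frame
#' @param x a `steady_state_result`.
#' @param ... unused.
#' @return data frame, one row per state.
#' @export
as.data.frame.steady_state_result <- function(x, ...) {
  data.frame(state = x$labels, point = unname(x$point),
             boot_mean = unname(x$boot_mean), ci_low = unname(x$ci_low),
             ci_high = unname(x$ci_high),
             exceeds_null = unname(x$exceeds_null),
             below_null = unname(x$below_null), row.names = NULL)
}

#' Bootstrap mean and CI per transition probability
#'
#' Replicate mean and percentile confidence interval for every ordered state
#' pair of the transition matrix.
#'
#' @inheritParams steady_state_test
#' @return data frame: `from`, `to`, `observed`, `boot_mean`, `ci_low`,
#'   `ci_high`.
#' @export
transition_prob_cis <- function(counts, n_boot = 5000, seed, level = 0.95,
                                scheme = c("pooled", "row-stratified")) {
  scheme <- match.arg(scheme)
  obs <- to_probabilities(counts)
  boot <- bootstrap_matrices(counts, n_boot, seed, scheme = scheme)
  K <- length(counts$labels)
  sims <- vapply(boot$matrices, as.vector, numeric(K * K))
  alpha <- (1 - level) / 2
  data.frame(
    from = rep(counts$labels, times = K),
    to = rep(counts$labels, each = K),
    observed = as.vector(obs$probs),
    boot_mean = rowMeans(sims),
    ci_low = apply(sims, 1, stats::quantile, probs = alpha, names = FALSE),
    ci_high = apply(sims, 1, stats::quantile, probs = 1 - alpha,
                    names = FALSE),
    row.names = NULL
  )
}
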