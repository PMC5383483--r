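# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# stationary distribution by brute-force power iteration
power_iteration <- function(P, tol = 1e-13, max_iter = 1e6) {
  K <- nrow(P)
  v <- rep(1 / K, K)
  for (i in seq_len(max_iter)) {
    v2 <- as.vector(v %*% P)
    v2 <- v2 / sum(v2)
    if (max(abs(v2 - v)) < tol) return(v2)
    v <- v2
  }
  v
}

# G statistic by a naive double loop over cells
g_naive <- function(m) {
  total <- sum(m)
  g <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (m[i, j] > 0) {
      e <- sum(m[i, ]) * sum(m[, j]) / total
      g <- g + m[i, j] * log(m[i, j] / e)
    }
  }
  2 * g
}

# random strictly positive (hence irreducible) row-stochastic matrix
random_stochastic <- function(K) {
  m <- matrix(stats::rexp(K * K) + 1e-3, K, K)
  m / rowSums(m)
}

# quick trajectory constructor for unit tests
traj <- function(years, states, id = "x", plot = "p") {
  structure(list(individual_id = id, plot_id = plot,
                 years = as.integer(years), states = states,
                 dbh_cm = rep(NA_real_, length(years)),
                 rppfd_winter = rep(NA_real_, length(years)),
                 rppfd_summer = rep(NA_real_, length(years))),
            class = "trajectory")
}

# minimal valid census data frame
census_df <- function(...) {
  df <- data.frame(...)
  for (col in c("dbh_cm", "rppfd_winter", "rppfd_summer"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  df
}
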