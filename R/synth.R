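#' Transition counts of the six-state census (printed reference table)
#'
#' The observed 6x6 transition count matrix of the five-year census, in the
#' internal rows = origin convention (937 transition events). These counts
#' are the input for all desk-scale reference analyses shipped with the
#' package.
#'
#' @return a `transition_counts` object over the six expressed states.
#' @examples
#' table2_counts()$n_pairs
#' @export
table2_counts <- function() {
  lab <- expressed_states()
  # columns = origin (previous year), rows = destination, as printed
  printed <- matrix(c(
    300,   5,  0,  22,  1,  0,
      4, 274,  0,   1,  6,  2,
      1,   1, 30,  10,  1,  1,
     10,   1, 22, 168,  2,  6,
      0,  10,  3,   3, 22,  4,
      0,   3,  3,   8,  3, 10
  ), nrow = 6, byrow = TRUE, dimnames = list(lab, lab))
  as_transition_counts(t(printed))
}

#' Reference pattern counts of the five-year census
#'
#' Canonical pattern -> number of individuals (309 total; 224 constant),
#' as tabulated over the five-year census.
#'
#' @return named integer vector.
#' @export
table1_pattern_counts <- function() {
  c("A" = 224L, "A→B" = 37L, "A→B→C" = 13L, "A→B→C→D" = 2L,
    "A→B→A" = 17L, "A→B→A→B" = 11L, "A→B→A→C" = 3L,
    "A→B→A→C→D" = 1L, "A→B→C→D→C" = 1L)
}

#' Simulation configuration for the synthetic census generator
#'
#' Defaults emulate the study population: four 20 x 20 m plots of 74, 81,
#' 102 and 52 individuals censused yearly 2010-2014, initial states drawn
#' from the observed average proportions of the six sexual types (F 33.2%,
#' M 30.1%, H 5.1%, HF 22.6%, HM 4.0%, HFM 2.4%), and occasional
#' non-flowering years. Two generating modes:
#' \describe{
#'   \item{`matrix`}{next year's state is drawn from the row of a supplied
#'     row-stochastic transition matrix (6x6 or 3x3); the default matrix is
#'     the observed probability matrix of [table2_counts()].}
#'   \item{`covariate`}{a change happens with probability
#'     \eqn{\mathrm{logit}^{-1}(\beta_0 + \beta'x + u_{plot})} on
#'     standardised covariates, with \eqn{u_{plot} \sim N(0,
#'     \sigma_{plot}^2)}; if a change happens the destination is drawn from
#'     the origin row's off-diagonal distribution (`dest`). Default
#'     \eqn{\beta} uses the reported standardised occurrence effects
#'     (rPPFD-winter 0.343, rPPFD-summer 0.025, growth 0.164, size not
#'     retained) with an intercept of -2.1, matching the observed overall
#'     yearly change rate of roughly 0.11.}
#' }
#' Covariates per individual: DBH ~ lognormal(log 3, 0.5) cm; rPPFD-winter
#' ~ Beta(2, 4) and rPPFD-summer ~ Beta(1.5, 6) (leafy season darker), both
#' drawn once per individual; yearly growth ~ Gamma(shape 2, scale 0.5) mm,
#' redrawn every year and accumulated onto DBH.
#'
#' @param n_per_plot integer vector, individuals per plot.
#' @param years calendar years of the census.
#' @param mode `"matrix"` or `"covariate"`.
#' @param matrix row-stochastic transition matrix for matrix mode.
#' @param beta named coefficients (intercept, dbh, rppfd_winter,
#'   rppfd_summer, growth) on the standardised scale, covariate mode.
#' @param dest row-stochastic destination matrix (diagonal 0) for covariate
#'   mode; default: off-diagonal of the reference matrix, normalised.
#' @param init named initial state distribution.
#' @param sigma_plot SD of the Gaussian plot random intercept.
#' @param p_nonflower probability an individual-year is non-flowering.
#' @param dbh_meanlog,dbh_sdlog lognormal DBH parameters (cm).
#' @param rppfd_winter_shape,rppfd_summer_shape Beta (a, b) parameters.
#' @param growth_shape,growth_scale Gamma parameters for yearly growth (mm).
#' @param seed integer seed; the generated census is a deterministic
#'   function of the config.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_per_plot = c(74, 81, 102, 52),
                       years = 2010:2014,
                       mode = c("matrix", "covariate"),
                       matrix = NULL,
                       beta = c(intercept = -2.1, dbh = 0,
                                rppfd_winter = 0.343, rppfd_summer = 0.025,
                                growth = 0.164),
                       dest = NULL,
                       init = c(F = 0.332, M = 0.301, H = 0.051,
                                HF = 0.226, HM = 0.040, HFM = 0.024),
                       sigma_plot = 0.5,
                       p_nonflower = 0.08,
                       dbh_meanlog = log(3), dbh_sdlog = 0.5,
                       rppfd_winter_shape = c(2, 4),
                       rppfd_summer_shape = c(1.5, 6),
                       growth_shape = 2, growth_scale = 0.5,
                       seed = 1) {
  mode <- match.arg(mode)
  if (is.null(matrix)) matrix <- to_probabilities(table2_counts())$probs
  if (inherits(matrix, "transition_matrix")) matrix <- matrix$probs
  states <- rownames(matrix)
  if (mode == "covariate" && is.null(dest)) {
    off <- matrix
    diag(off) <- 0
    dest <- off / rowSums(off)
  }
  if (!all(states %in% names(init)) && setequal(states, pooled_states())) {
    # pool a 6-state initial distribution for a 3-state matrix
    init <- tapply(init, pool_hermaphrodites(names(init)), sum)[states]
  }
  if (!all(states %in% names(init)))
    stop("init must name every matrix state")
  init <- init[states]
  init <- init / sum(init)
  cfg <- list(n_per_plot = n_per_plot, years = as.integer(years),
              mode = mode, matrix = matrix, beta = beta, dest = dest,
              init = init, states = states, sigma_plot = sigma_plot,
              p_nonflower = p_nonflower, dbh_meanlog = dbh_meanlog,
              dbh_sdlog = dbh_sdlog,
              rppfd_winter_shape = rppfd_winter_shape,
              rppfd_summer_shape = rppfd_summer_shape,
              growth_shape = growth_shape, growth_scale = growth_scale,
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (any(abs(rowSums(cfg$matrix) - 1) > 1e-9))
    stop("transition matrix rows must sum to 1")
  if (!is.null(cfg$dest)) {
    if (any(abs(rowSums(cfg$dest) - 1) > 1e-9))
      stop("destination matrix rows must sum to 1")
    if (any(diag(cfg$dest) != 0))
      stop("destination matrix must have a zero diagonal")
  }
  if (cfg$p_nonflower < 0 || cfg$p_nonflower >= 1)
    stop("p_nonflower must be in [0, 1)")
  if (abs(sum(cfg$init) - 1) > 1e-9)
    stop("initial distribution must sum to 1 over the matrix states")
  if (length(cfg$years) < 1 || any(diff(cfg$years) != 1))
    stop("years must be consecutive")
  structure(cfg, class = "sim_config")
}

# theoretical mean/sd used to put simulated covariates on the standardised
# scale the coefficients are declared on
covariate_moments <- function(cfg) {
  ln_m <- exp(cfg$dbh_meanlog + cfg$dbh_sdlog^2 / 2)
  ln_s <- ln_m * sqrt(exp(cfg$dbh_sdlog^2) - 1)
  bmom <- function(sh) {
    a <- sh[1]; b <- sh[2]
    c(a / (a + b), sqrt(a * b / ((a + b)^2 * (a + b + 1))))
  }
  bw <- bmom(cfg$rppfd_winter_shape)
  bs <- bmom(cfg$rppfd_summer_shape)
  g_m <- cfg$growth_shape * cfg$growth_scale
  g_s <- sqrt(cfg$growth_shape) * cfg$growth_scale
  list(dbh = c(ln_m, ln_s), rppfd_winter = bw, rppfd_summer = bs,
       growth = c(g_m, g_s))
}

#' Simulate a sex-expression census
#'
#' Generates a long-format census with the statistical structure the
#' analysis pipeline assumes: per individual, a plot random effect,
#' covariates and an initial state; per year, a non-flowering indicator and
#' a Markov (matrix mode) or covariate-driven (covariate mode) state
#' transition. Output is deterministic given the config (seed included).
#'
#' @param config a [sim_config()].
#' @return a validated `census` data frame.
#' @examples
#' cfg <- sim_config(n_per_plot = c(10, 10), years = 2010:2012, seed = 7)
#' head(simulate_census(cfg))
#' @export
simulate_census <- function(config) {
  cfg <- validate_sim_config(config)
  states <- cfg$states
  mom <- covariate_moments(cfg)
  withr::with_seed(cfg$seed, {
    rows <- list()
    id_n <- 0L
    for (p in seq_along(cfg$n_per_plot)) {
      plot_id <- sprintf("P%d", p)
      u_plot <- stats::rnorm(1, 0, cfg$sigma_plot)
      for (k in seq_len(cfg$n_per_plot[p])) {
        id_n <- id_n + 1L
        ind <- sprintf("I%04d", id_n)
        dbh0 <- stats::rlnorm(1, cfg$dbh_meanlog, cfg$dbh_sdlog)
        rw <- stats::rbeta(1, cfg$rppfd_winter_shape[1],
                           cfg$rppfd_winter_shape[2])
        rs <- stats::rbeta(1, cfg$rppfd_summer_shape[1],
                           cfg$rppfd_summer_shape[2])
        ny <- length(cfg$years)
        growth <- stats::rgamma(ny, cfg$growth_shape,
                                scale = cfg$growth_scale)
        dbh <- dbh0 + cumsum(growth) / 10  # growth is mm, DBH cm
        nf <- stats::runif(ny) < cfg$p_nonflower
        st <- character(ny)
        st[1] <- sample(names(cfg$init), 1, prob = cfg$init)
        if (ny > 1) for (t in 2:ny) {
          if (cfg$mode == "matrix") {
            st[t] <- sample(states, 1, prob = cfg$matrix[st[t - 1], ])
          } else {
            z <- c(1,
                   (dbh[t - 1] - mom$dbh[1]) / mom$dbh[2],
                   (rw - mom$rppfd_winter[1]) / mom$rppfd_winter[2],
                   (rs - mom$rppfd_summer[1]) / mom$rppfd_summer[2],
                   (growth[t - 1] - mom$growth[1]) / mom$growth[2])
            eta <- sum(cfg$beta * z) + u_plot
            if (stats::runif(1) < stats::plogis(eta)) {
              st[t] <- sample(states, 1, prob = cfg$dest[st[t - 1], ])
            } else {
              st[t] <- st[t - 1]
            }
          }
        }
        sex <- ifelse(nf, "NF", st)
        rows[[id_n]] <- data.frame(
          plot_id = plot_id, individual_id = ind, year = cfg$years,
          sex = sex, dbh_cm = dbh, rppfd_winter = rw, rppfd_summer = rs)
      }
    }
    validate_census(do.call(rbind, rows))
  })
}

#' Reference fixture: independent two-year pairs reproducing the printed
#' transition table
#'
#' One two-year pseudo-individual per observed transition event (937
#' events, 1874 rows), so that [count_transitions()] on the result equals
#' [table2_counts()] cell for cell. Synthetic reconstruction: the real
#' five-year trajectories are unpublished.
#'
#' @return a validated `census` data frame (no covariates).
#' @export
make_fixture_table2 <- function() {
  cnt <- table2_counts()
  lab <- cnt$labels
  idx <- which(cnt$counts > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  from <- rep(lab[idx[, 1]], cnt$counts[idx])
  to <- rep(lab[idx[, 2]], cnt$counts[idx])
  n <- length(from)
  ids <- sprintf("T2_%04d", seq_len(n))
  df <- data.frame(
    plot_id = "P1",
    individual_id = rep(ids, each = 2),
    year = rep(c(2010L, 2011L), n),
    sex = as.vector(rbind(from, to)),
    dbh_cm = NA_real_, rppfd_winter = NA_real_, rppfd_summer = NA_real_)
  validate_census(df)
}

#' Reference fixture: 309 trajectories reproducing the printed pattern table
#'
#' Builds one trajectory per individual so that [tabulate_patterns()]
#' reproduces the reference pattern counts ([table1_pattern_counts()]):
#' 224 constant, 85 changing at least once. Concrete states are chosen
#' arbitrarily but only ever use transitions observed at least once in
#' [table2_counts()] (never a never-observed ordered pair). Synthetic
#' reconstruction: the real trajectories are unpublished.
#'
#' @return a validated `census` data frame (no covariates).
#' @export
make_fixture_table1 <- function() {
  # concrete state sequences realising each canonical pattern; every
  # consecutive pair has a positive cell in table2_counts()
  real <- list(
    "A" = list(c("F"), c("M"), c("HF"), c("H"), c("HM"), c("HFM")),
    "A→B" = list(c("H", "HF"), c("HF", "F"), c("M", "HM")),
    "A→B→C" = list(c("H", "HF", "F"), c("M", "HM", "HF")),
    "A→B→C→D" = list(c("H", "HF", "HM", "M")),
    "A→B→A" = list(c("H", "HF", "H"), c("F", "M", "F")),
    "A→B→A→B" = list(c("H", "HF", "H", "HF"), c("M", "F", "M", "F")),
    "A→B→A→C" = list(c("HF", "H", "HF", "F")),
    "A→B→A→C→D" = list(c("HF", "H", "HF", "F", "M")),
    "A→B→C→D→C" = list(c("H", "HF", "F", "M", "F"))
  )
  want <- table1_pattern_counts()
  # constant individuals spread over the six states roughly like the
  # observed average sex-type proportions
  const_n <- c(F = 75, M = 68, H = 11, HF = 51, HM = 12, HFM = 7)
  stopifnot(sum(const_n) == want[["A"]])
  seqs <- list()
  for (s in names(const_n))
    seqs <- c(seqs, rep(list(c(s)), const_n[[s]]))
  for (pat in setdiff(names(want), "A")) {
    reals <- real[[pat]]
    n <- want[[pat]]
    pick <- rep(seq_along(reals), length.out = n)
    seqs <- c(seqs, reals[pick])
  }
  # plot sizes of the study design; long trajectories need the plots
  # censused all five years, so assign longest first to plots 2 and 3
  len <- vapply(seqs, length, integer(1))
  seqs <- seqs[order(-len)]
  sizes <- c(P2 = 81, P3 = 102, P1 = 74, P4 = 52)
  plot_of <- rep(names(sizes), sizes)
  start_of <- ifelse(plot_of == "P4", 2012L, 2010L)
  rows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    data.frame(
      plot_id = plot_of[i],
      individual_id = sprintf("T1_%03d", i),
      year = seq(start_of[i], length.out = length(s)),
      sex = s,
      dbh_cm = NA_real_, rppfd_winter = NA_real_, rppfd_summer = NA_real_)
  })
  validate_census(do.call(rbind, rows))
}
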