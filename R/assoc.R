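#' G (likelihood-ratio) test of independence
#'
#' \eqn{G = 2 \sum O \ln(O/E)} over cells with \eqn{O > 0}, expected counts
#' from the independence margins, referred to a chi-square distribution with
#' \eqn{(R-1)(C-1)} degrees of freedom. No continuity or Williams
#' correction is applied.
#'
#' @param table R x C matrix of nonnegative counts (>= 2 rows and columns,
#'   all margins positive).
#' @return a `g_test_result`: `G`, `df`, `p`.
#' @examples
#' g_test(rbind(c(10, 20), c(20, 10)))
#' @export
g_test <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least 2 rows and 2 columns")
  if (any(m < 0)) stop("negative counts")
  rt <- rowSums(m); ct <- colSums(m)
  if (any(rt == 0) || any(ct == 0))
    stop("G-test undefined: zero row or column total")
  E <- outer(rt, ct) / sum(m)
  pos <- m > 0
  G <- 2 * sum(m[pos] * log(m[pos] / E[pos]))
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  structure(list(G = G, df = df,
                 p = stats::pchisq(G, df, lower.tail = FALSE)),
            class = "g_test_result")
}

#' @export
print.g_test_result <- function(x, ...) {
  cat(sprintf("G-test: G = %.4g, df = %d, p = %.4g\n", x$G, x$df, x$p))
  invisible(x)
}

#' Kruskal-Wallis rank-sum test
#'
#' Thin wrapper around [stats::kruskal.test()] (rank-based H with tie
#' correction, chi-square reference with k-1 df) returning a plain list.
#' Degenerate data (every pooled value identical) yield `H = 0` with a
#' warning rather than `NaN`.
#'
#' @param groups list of numeric vectors, one per group (>= 2 nonempty
#'   groups).
#' @return list with `H`, `df`, `p`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("every group must be nonempty")
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1) {
    warning("all values identical; H = 0")
    return(list(H = 0, df = length(groups) - 1, p = 1))
  }
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Individual-year data for sex-change occurrence models
#'
#' Builds one model row per individual-year pair (t, t+1) where both years
#' are consecutive, both states expressed, and all covariates are measured
#' at year t. The response is whether the state changed between t and t+1.
#' Covariates: DBH (cm) at t, rPPFD in the leafless (winter) and leafy
#' (summer) seasons, and growth rate (mm/yr) measured as the absolute DBH
#' difference between year t and t-1 (so the first observed year of an
#' individual never yields a row). Covariates are standardised to mean 0,
#' sd 1; the constants are stored in `attr(, "standardization")`.
#'
#' @param census validated census data frame with covariates.
#' @param from_state optional origin filter for pattern-specific models:
#'   the at-risk subset, e.g. `from_state = c("H","HF","HM","HFM")`.
#' @param to_state optional focal destination (after pooling via
#'   `pooling`); when given, the response is "the focal change occurred"
#'   rather than "any change occurred".
#' @param pooling optional named map applied to states before the
#'   `from_state`/`to_state` comparison (e.g. `hall_pooling()`).
#' @return data frame `response`, `dbh`, `rppfd_winter`, `rppfd_summer`,
#'   `growth`, `plot_id`, `individual_id`, `year`; standardised covariates.
#' @export
change_model_data <- function(census, from_state = NULL, to_state = NULL,
                              pooling = NULL) {
  d <- validate_census(as.data.frame(census))
  d <- d[order(d$individual_id, d$year), , drop = FALSE]
  n <- nrow(d)
  if (n < 3) stop("no usable individual-year pairs")
  st <- d$sex
  if (!is.null(pooling)) {
    mapped <- !is.na(match(st, names(pooling)))
    st[mapped] <- pooling[st[mapped]]
  }
  # row t is usable iff rows t-1 and t+1 belong to the same individual in
  # the adjacent calendar years (t-1 supplies the growth measurement, t+1
  # the response)
  same_prev <- c(FALSE, d$individual_id[-1] == d$individual_id[-n] &
                   d$year[-1] == d$year[-n] + 1)
  same_next <- c(same_prev[-1], FALSE)
  growth <- rep(NA_real_, n)
  growth[same_prev] <- 10 * abs(d$dbh_cm[same_prev] -
                                  d$dbh_cm[which(same_prev) - 1])
  cur_expr <- is_expressed(d$sex)
  next_expr <- c(cur_expr[-1], FALSE)
  next_state <- c(st[-1], NA)
  ok <- same_prev & same_next & cur_expr & next_expr &
    !is.na(d$dbh_cm) & !is.na(d$rppfd_winter) & !is.na(d$rppfd_summer) &
    !is.na(growth)
  if (!is.null(from_state)) ok <- ok & st %in% from_state
  if (!any(ok)) stop("no usable individual-year pairs")
  resp <- if (is.null(to_state)) next_state != st else
    next_state %in% to_state & next_state != st
  df <- data.frame(
    response = as.integer(resp[ok]), dbh = d$dbh_cm[ok],
    rppfd_winter = d$rppfd_winter[ok], rppfd_summer = d$rppfd_summer[ok],
    growth = growth[ok], plot_id = d$plot_id[ok],
    individual_id = d$individual_id[ok], year = d$year[ok],
    row.names = NULL)
  std <- lapply(df[c("dbh", "rppfd_winter", "rppfd_summer", "growth")],
                function(x) c(mean = mean(x), sd = stats::sd(x)))
  for (v in names(std)) {
    s <- std[[v]]["sd"]
    if (is.na(s) || s == 0) s <- 1
    df[[v]] <- (df[[v]] - std[[v]]["mean"]) / s
  }
  attr(df, "standardization") <- std
  df
}

#' Logistic random-intercept model of sex-change occurrence
#'
#' Bernoulli-logit model with a Gaussian random intercept per plot,
#' maximised by adaptive Gauss-Hermite quadrature via [lme4::glmer()]
#' (default 15 quadrature nodes). With fewer than two plots, or with
#' `random_effect = FALSE`, the model reduces to a plain logistic
#' regression via [stats::glm()] (the zero-variance limit).
#'
#' @param data data frame from [change_model_data()] (or any data frame
#'   with a binary `response`, the covariate columns, and `plot_id`).
#' @param terms character vector of covariates to include (subset of
#'   `c("dbh","rppfd_winter","rppfd_summer","growth")`); may be empty for
#'   an intercept-only model.
#' @param nAGQ number of adaptive Gauss-Hermite quadrature nodes.
#' @param random_effect fit the plot random intercept (default TRUE).
#' @return a `mixed_logistic_fit`: `coefficients` (fixed effects),
#'   `sigma_plot` (random-intercept SD; 0 for the glm path), `logLik`,
#'   `AIC`, `converged`, `separation` flag, `terms`, `n`, and the
#'   underlying `fit` object.
#' @export
fit_mixed_logistic <- function(data, terms = c("dbh", "rppfd_winter",
                                               "rppfd_summer", "growth"),
                               nAGQ = 15, random_effect = TRUE) {
  stopifnot(all(c("response", "plot_id") %in% names(data)))
  if (length(unique(data$response)) < 2)
    stop("response has no variation")
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  use_re <- random_effect && length(unique(data$plot_id)) >= 2
  if (use_re) {
    fo <- stats::as.formula(paste("response ~", rhs, "+ (1 | plot_id)"))
    fit <- suppressMessages(lme4::glmer(fo, data = data, family =
      stats::binomial(), nAGQ = nAGQ))
    conv <- length(fit@optinfo$conv$lme4$messages) == 0 &&
      fit@optinfo$conv$opt == 0
    co <- lme4::fixef(fit)
    sigma_plot <- sqrt(unname(lme4::VarCorr(fit)$plot_id[1, 1]))
    ll <- as.numeric(stats::logLik(fit))
    aic <- stats::AIC(fit)
  } else {
    fo <- stats::as.formula(paste("response ~", rhs))
    fit <- stats::glm(fo, data = data, family = stats::binomial())
    conv <- fit$converged
    co <- stats::coef(fit)
    sigma_plot <- 0
    ll <- as.numeric(stats::logLik(fit))
    aic <- stats::AIC(fit)
  }
  separation <- any(abs(co) > 15)
  structure(list(coefficients = co, sigma_plot = sigma_plot, logLik = ll,
                 AIC = aic, converged = conv && !separation,
                 separation = separation, terms = terms,
                 n = nrow(data), fit = fit),
            class = "mixed_logistic_fit")
}

#' @export
print.mixed_logistic_fit <- function(x, digits = 4, ...) {
  cat("Mixed logistic fit (n =", x$n, ")\n")
  print(round(x$coefficients, digits))
  cat("plot random-intercept SD:", round(x$sigma_plot, digits),
      "  AIC:", round(x$AIC, 2), "\n")
  if (!x$converged) cat("WARNING: fit flagged (non-convergence/separation)\n")
  invisible(x)
}

#' Backward stepwise selection by AIC
#'
#' Starting from the full model, repeatedly drops the single term whose
#' removal lowers AIC the most, until no removal lowers AIC. Ties are
#' broken deterministically by dropping the term latest in the declared
#' order. Fits flagged as non-converged are excluded as candidates (with a
#' warning).
#'
#' @inheritParams fit_mixed_logistic
#' @param full_terms nonempty character vector, the starting terms.
#' @return the final `mixed_logistic_fit` with an extra `trace` element:
#'   a data frame (step, dropped, AIC) of the selection path, first row the
#'   full model.
#' @export
backward_aic <- function(data, full_terms = c("dbh", "rppfd_winter",
                                              "rppfd_summer", "growth"),
                         nAGQ = 15, random_effect = TRUE) {
  stopifnot(length(full_terms) >= 1)
  current <- full_terms
  fit <- fit_mixed_logistic(data, current, nAGQ, random_effect)
  trace <- data.frame(step = 1L, dropped = NA_character_, AIC = fit$AIC,
                      stringsAsFactors = FALSE)
  repeat {
    if (!length(current)) break
    cands <- lapply(seq_along(current), function(i) {
      f <- try(fit_mixed_logistic(data, current[-i], nAGQ, random_effect),
               silent = TRUE)
      if (inherits(f, "try-error") || !f$converged) NULL else f
    })
    failed <- vapply(cands, is.null, logical(1))
    if (any(failed))
      warning("dropping candidate(s) excluded for non-convergence: ",
              paste(current[failed], collapse = ", "))
    aics <- vapply(cands, function(f) if (is.null(f)) Inf else f$AIC,
                   numeric(1))
    if (min(aics) >= fit$AIC) break
    # tie-break: among minimal AICs, drop the term latest in declared order
    best <- which(aics <= min(aics) + 1e-12)
    drop_i <- max(best)
    dropped <- current[drop_i]
    fit <- cands[[drop_i]]
    current <- current[-drop_i]
    trace <- rbind(trace, data.frame(step = nrow(trace) + 1L,
                                     dropped = dropped, AIC = fit$AIC))
  }
  fit$trace <- trace
  fit
}
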