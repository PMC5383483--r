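#' Count year-to-year sex transitions
#'
#' Tallies transitions between consecutive calendar years over a set of
#' trajectories. A pair (year t, year t+1) contributes one count iff both
#' years are present, consecutive, and both states are expressed (not NF/NA).
#' Non-flowering or unobserved years break the pair but not later pairs.
#' An optional pooling map (state -> pooled label) is applied to the states
#' before counting.
#'
#' @param trajectories list of trajectories from [build_trajectories()].
#' @param states ordered state label set for the matrix; defaults to the six
#'   expressed states, or to [pooled_states()] when `pooling` is given.
#' @param pooling optional named character vector mapping expressed states to
#'   pooled labels, e.g. `hall_pooling()`.
#' @return a `transition_counts` object: `labels`, integer `counts` matrix
#'   (rows = origin), and `n_pairs = sum(counts)`.
#' @examples
#' traj <- build_trajectories(make_fixture_table2())
#' count_transitions(traj)$n_pairs
#' @export
count_transitions <- function(trajectories, states = NULL, pooling = NULL) {
  if (is.null(states))
    states <- if (is.null(pooling)) expressed_states() else
      unique(unname(pooling))
  K <- length(states)
  counts <- matrix(0L, K, K, dimnames = list(states, states))
  for (tr in trajectories) {
    st <- tr$states
    if (!is.null(pooling)) {
      mapped <- !is.na(match(st, names(pooling)))
      st[mapped] <- pooling[st[mapped]]
    }
    ok <- st %in% states
    n <- length(tr$years)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      if (tr$years[i + 1] == tr$years[i] + 1 && ok[i] && ok[i + 1]) {
        counts[st[i], st[i + 1]] <- counts[st[i], st[i + 1]] + 1L
      }
    }
  }
  new_transition_counts(counts)
}

#' Pooling map from six expressed states to \{F, M, HALL\}
#' @return named character vector usable as the `pooling` argument of
#'   [count_transitions()].
#' @export
hall_pooling <- function() {
  stats::setNames(pool_hermaphrodites(expressed_states()), expressed_states())
}

new_transition_counts <- function(counts) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts),
            all(counts >= 0))
  storage.mode(counts) <- "integer"
  structure(list(labels = rownames(counts), counts = counts,
                 n_pairs = sum(counts)),
            class = "transition_counts")
}

#' Build a transition_counts object from a labelled matrix
#'
#' @param m square nonnegative integer matrix with identical row and column
#'   labels, rows = origin state.
#' @return a `transition_counts` object.
#' @export
as_transition_counts <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) stop("matrix must be labelled")
  new_transition_counts(m)
}

#' Aggregate a 6-state count matrix into pooled classes
#'
#' Equivalent (and tested to be equivalent) to pooling states before
#' counting.
#'
#' @param counts a `transition_counts` object.
#' @param pooling named map from current labels to pooled labels.
#' @return a pooled `transition_counts` object, labels in first-appearance
#'   order of the pooled classes.
#' @export
pool_counts <- function(counts, pooling = hall_pooling()) {
  stopifnot(inherits(counts, "transition_counts"))
  lab <- counts$labels
  to <- ifelse(is.na(match(lab, names(pooling))), lab, pooling[lab])
  newlab <- unique(to)
  K <- length(newlab)
  out <- matrix(0L, K, K, dimnames = list(newlab, newlab))
  for (i in seq_along(lab)) for (j in seq_along(lab)) {
    out[to[i], to[j]] <- out[to[i], to[j]] + counts$counts[i, j]
  }
  new_transition_counts(out)
}

#' @export
print.transition_counts <- function(x, ...) {
  cat("<transition_counts> ", x$n_pairs, " pairs, states: ",
      paste(x$labels, collapse = ", "), "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Convert transition counts to a row-stochastic probability matrix
#'
#' Each row is divided by its total. Rows with zero total are flagged and
#' filled with `NaN`; row totals are retained for bootstrapping. Full
#' precision is kept internally; round only for display.
#'
#' @param counts a `transition_counts` object.
#' @return a `transition_matrix` object: `labels`, `probs`, `row_totals`,
#'   `undefined_rows` (labels of zero-total rows).
#' @examples
#' cnt <- pool_counts(table2_counts())
#' round(to_probabilities(cnt)$probs, 4)
#' @export
to_probabilities <- function(counts) {
  stopifnot(inherits(counts, "transition_counts"))
  tot <- rowSums(counts$counts)
  probs <- counts$counts / ifelse(tot > 0, tot, NA_real_)
  probs[tot == 0, ] <- NaN
  structure(list(labels = counts$labels, probs = probs,
                 row_totals = as.integer(tot),
                 undefined_rows = counts$labels[tot == 0]),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 4, ...) {
  cat("<transition_matrix> states:", paste(x$labels, collapse = ", "), "\n")
  print(round(x$probs, digits))
  if (length(x$undefined_rows))
    cat("undefined rows:", paste(x$undefined_rows, collapse = ", "), "\n")
  invisible(x)
}

#' Structural summaries of an observed transition matrix
#'
#' On the unpooled state space, reports (a) how many distinct off-diagonal
#' transition types were observed at least once, (b) which ordered pairs were
#' never observed, and (c) the off-diagonal maximum count with all pairs
#' attaining it.
#'
#' @param counts a `transition_counts` object.
#' @return list with `n_observed_types`, `never_observed` (character
#'   "from->to"), `max_count`, `max_pairs`.
#' @examples
#' observed_summaries(table2_counts())$n_observed_types
#' @export
observed_summaries <- function(counts) {
  stopifnot(inherits(counts, "transition_counts"))
  m <- counts$counts
  off <- row(m) != col(m)
  lab <- counts$labels
  pair_name <- function(idx) paste0(lab[idx[, 1]], "->", lab[idx[, 2]])
  obs <- which(off & m > 0, arr.ind = TRUE)
  never <- which(off & m == 0, arr.ind = TRUE)
  mx <- if (any(off & m > 0)) max(m[off]) else 0L
  at <- which(off & m == mx & mx > 0, arr.ind = TRUE)
  ord <- function(idx) idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  list(
    n_observed_types = nrow(obs),
    never_observed = pair_name(ord(never)),
    max_count = as.integer(mx),
    max_pairs = pair_name(ord(at))
  )
}
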