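#' Canonical sex-change pattern of one trajectory
#'
#' Reduces a trajectory to its canonical change pattern: take the
#' year-ordered expressed states (non-flowering and unobserved years are
#' skipped when `collapse_gaps = TRUE`), collapse consecutive repeats, and
#' relabel the distinct successive states A, B, C, ... in order of first
#' appearance. So `[F, M, F]` becomes `"A->B->A"`. Direction is `constant`
#' with no change, `bidirectional` if any letter reappears after a different
#' letter intervened (a reversal to a previously expressed sex), otherwise
#' `unidirectional`.
#'
#' With `collapse_gaps = FALSE` only the first maximal run of
#' consecutive-year expressed observations is used, so no change is ever
#' scored across a non-flowering or missing year.
#'
#' @param trajectory a `trajectory` object.
#' @param collapse_gaps skip NF/NA years (default) instead of truncating at
#'   the first gap.
#' @return a `pattern_result`: `individual_id`, `pattern` (letters joined by
#'   `"→"`), `direction`, `n_changes`, `n_expressed_years`; or, for a
#'   trajectory with no expressed observation, a result with
#'   `pattern = NA` and `direction = "no expressed sex"`, excluded from
#'   tabulation.
#' @examples
#' tr <- structure(list(individual_id = "x", plot_id = "p",
#'                      years = 2010:2012, states = c("F", "M", "F")),
#'                 class = "trajectory")
#' canonicalize(tr)
#' @export
canonicalize <- function(trajectory, collapse_gaps = TRUE) {
  st <- trajectory$states
  yr <- trajectory$years
  keep <- is_expressed(st)
  st <- st[keep]
  yr <- yr[keep]
  if (length(st) == 0) {
    return(structure(list(individual_id = trajectory$individual_id,
                          pattern = NA_character_,
                          direction = "no expressed sex",
                          n_changes = NA_integer_,
                          n_expressed_years = 0L),
                     class = "pattern_result"))
  }
  if (!collapse_gaps) {
    run_end <- c(which(diff(yr) > 1), length(yr))[1]
    st <- st[seq_len(run_end)]
  }
  # collapse consecutive repeats, then relabel by first appearance
  seqs <- st[c(TRUE, st[-1] != st[-length(st)])]
  letters_for <- LETTERS[match(seqs, unique(seqs))]
  n_changes <- length(seqs) - 1L
  direction <- if (n_changes == 0) "constant"
  else if (anyDuplicated(letters_for)) "bidirectional"
  else "unidirectional"
  structure(list(
    individual_id = trajectory$individual_id,
    pattern = paste(letters_for, collapse = "→"),
    direction = direction,
    n_changes = n_changes,
    n_expressed_years = length(st)
  ), class = "pattern_result")
}

#' @export
print.pattern_result <- function(x, ...) {
  cat("<pattern> ", x$individual_id, ": ", x$pattern, " (", x$direction,
      ", ", x$n_changes, " changes)\n", sep = "")
  invisible(x)
}

#' Tabulate sex-change patterns over a population
#'
#' Counts trajectories per canonical pattern and summarises how many
#' individuals changed sex at all and how often. Trajectories with no
#' expressed observation are excluded from the percentage base.
#'
#' @param trajectories list of trajectories.
#' @param collapse_gaps passed to [canonicalize()].
#' @return a `pattern_table`: data frame `patterns` (pattern, direction,
#'   n_changes, count, percent), `n_classifiable`, `n_changed`,
#'   `n_constant`, `changes_distribution` (count by number of changes) and
#'   `span_distribution` (count by number of expressed years).
#' @examples
#' tabulate_patterns(build_trajectories(make_fixture_table1()))
#' @export
tabulate_patterns <- function(trajectories, collapse_gaps = TRUE) {
  res <- lapply(trajectories, canonicalize, collapse_gaps = collapse_gaps)
  res <- Filter(function(r) !is.na(r$pattern), res)
  n <- length(res)
  if (n == 0) {
    return(structure(list(
      patterns = data.frame(pattern = character(), direction = character(),
                            n_changes = integer(), count = integer(),
                            percent = numeric()),
      n_classifiable = 0L, n_changed = 0L, n_constant = 0L,
      changes_distribution = integer(), span_distribution = integer()),
      class = "pattern_table"))
  }
  pat <- vapply(res, `[[`, character(1), "pattern")
  dirn <- vapply(res, `[[`, character(1), "direction")
  nch <- vapply(res, `[[`, integer(1), "n_changes")
  span <- vapply(res, `[[`, integer(1), "n_expressed_years")
  key <- !duplicated(pat)
  tab <- data.frame(pattern = pat[key], direction = dirn[key],
                    n_changes = nch[key], row.names = NULL)
  tab$count <- as.integer(table(pat)[tab$pattern])
  tab$percent <- 100 * tab$count / n
  tab <- tab[order(tab$n_changes, tab$pattern), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(
    patterns = tab,
    n_classifiable = n,
    n_changed = sum(nch > 0),
    n_constant = sum(nch == 0),
    changes_distribution = table(nch),
    span_distribution = table(span)
  ), class = "pattern_table")
}

#' @export
print.pattern_table <- function(x, digits = 1, ...) {
  cat("Sex-change patterns over", x$n_classifiable, "individuals:",
      x$n_changed, "changed at least once,", x$n_constant, "constant\n")
  tab <- x$patterns
  tab$percent <- round(tab$percent, digits)
  print(tab)
  invisible(x)
}

#' Sex-change events of one trajectory
#'
#' One event per consecutive-expressed-year pair whose states differ; the
#' same consecutive-year rule as [count_transitions()], so over a population
#' the aggregated events equal the off-diagonal transition counts.
#'
#' @param trajectory a `trajectory` object.
#' @return data frame with columns `year_from`, `year_to`, `state_from`,
#'   `state_to` (zero rows when nothing changed).
#' @export
change_events <- function(trajectory) {
  st <- trajectory$states
  yr <- trajectory$years
  n <- length(yr)
  out <- data.frame(year_from = integer(), year_to = integer(),
                    state_from = character(), state_to = character())
  if (n < 2) return(out)
  i <- seq_len(n - 1)
  hit <- yr[i + 1] == yr[i] + 1 & is_expressed(st[i]) &
    is_expressed(st[i + 1]) & st[i] != st[i + 1]
  if (!any(hit)) return(out)
  i <- i[hit]
  data.frame(year_from = yr[i], year_to = yr[i + 1],
             state_from = st[i], state_to = st[i + 1], row.names = NULL)
}
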