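#' Read a longitudinal sex-expression census
#'
#' Reads a long-format census CSV: one row per individual-year with columns
#' `plot_id,individual_id,year,sex,dbh_cm,rppfd_winter,rppfd_summer`.
#' Missing numeric values are blank; the `sex` column must use the 8 codes of
#' [sex_states()]. Relative PPFD values are fractions of the open-site flux
#' and must lie in \[0, 1\].
#'
#' @param path path to a CSV file.
#' @return a `census` data frame, validated (see [validate_census()]).
#' @seealso [write_census()], [build_trajectories()]
#' @export
read_census <- function(path) {
  if (!file.exists(path)) stop("census file not found: ", path)
  df <- utils::read.csv(path, colClasses = c(
    plot_id = "character", individual_id = "character", year = "integer",
    sex = "character", dbh_cm = "numeric", rppfd_winter = "numeric",
    rppfd_summer = "numeric"
  ), na.strings = c("", "NA"))
  # blank sex means not observed; keep the explicit "NA" code
  df$sex[is.na(df$sex)] <- "NA"
  validate_census(df)
}

census_columns <- function() {
  c("plot_id", "individual_id", "year", "sex",
    "dbh_cm", "rppfd_winter", "rppfd_summer")
}

#' Validate a census data frame
#'
#' Checks column presence, sex codes, uniqueness of (individual, year) and
#' the \[0, 1\] range of the rPPFD fractions. Errors name the offending rows.
#'
#' @param df data frame with the columns of [read_census()].
#' @return the validated data frame, with class `census` prepended.
#' @export
validate_census <- function(df) {
  miss <- setdiff(census_columns(), names(df))
  if (length(miss))
    stop("census is missing columns: ", paste(miss, collapse = ", "))
  df <- df[census_columns()]
  # HALL is admitted for censuses simulated on the pooled 3-state space
  bad <- which(!df$sex %in% c(sex_states(), "HALL"))
  if (length(bad))
    stop("unknown sex code ", dQuote(df$sex[bad[1]]), " in row ", bad[1])
  key <- paste(df$individual_id, df$year, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (individual_id, year) = (", df$individual_id[dup[1]],
         ", ", df$year[dup[1]], ") in row ", dup[1])
  for (col in c("rppfd_winter", "rppfd_summer")) {
    out <- which(!is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 1))
    if (length(out))
      stop(col, " outside [0, 1] in row ", out[1])
  }
  neg <- which(!is.na(df$dbh_cm) & df$dbh_cm < 0)
  if (length(neg)) stop("negative dbh_cm in row ", neg[1])
  if (!inherits(df, "census")) class(df) <- c("census", class(df))
  df
}

#' Write a census CSV
#'
#' Deterministic writer for the census format of [read_census()]: fixed
#' column order, blank for missing numerics, `%.6f` float format, so that
#' write followed by read is the identity on validated data.
#'
#' @param census validated census data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_census <- function(census, path) {
  census <- validate_census(as.data.frame(census))
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))
  out <- data.frame(
    plot_id = census$plot_id, individual_id = census$individual_id,
    year = census$year, sex = census$sex,
    dbh_cm = fmt(census$dbh_cm),
    rppfd_winter = fmt(census$rppfd_winter),
    rppfd_summer = fmt(census$rppfd_summer),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a census into individual trajectories
#'
#' One trajectory per individual, observations sorted by year. Non-flowering
#' and not-observed years are retained; downstream stages decide how to treat
#' them (transition counting breaks pairs on them, pattern classification
#' skips them by default).
#'
#' @param census validated census data frame.
#' @return a list of `trajectory` objects, each with fields `individual_id`,
#'   `plot_id`, `years` (strictly increasing) and `states`.
#' @export
build_trajectories <- function(census) {
  census <- validate_census(as.data.frame(census))
  idx <- split(seq_len(nrow(census)), census$individual_id)
  # keep first-appearance order of individuals, not alphabetical
  idx <- idx[unique(census$individual_id)]
  lapply(idx, function(i) {
    rows <- census[i, , drop = FALSE]
    rows <- rows[order(rows$year), , drop = FALSE]
    structure(list(
      individual_id = rows$individual_id[1],
      plot_id = rows$plot_id[1],
      years = rows$year,
      states = rows$sex,
      dbh_cm = rows$dbh_cm,
      rppfd_winter = rows$rppfd_winter,
      rppfd_summer = rows$rppfd_summer
    ), class = "trajectory")
  })
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> individual", x$individual_id, "plot", x$plot_id, "\n")
  cat(paste(sprintf("%d:%s", x$years, x$states), collapse = "  "), "\n")
  invisible(x)
}

#' Write a labelled transition matrix as CSV
#'
#' The internal convention is rows = origin state, columns = destination
#' (row-stochastic for probability matrices). The field's printed tables are
#' often transposed (columns = previous year); `orientation = "paper"`
#' writes that transposed layout. Counts are written as integers,
#' probabilities with `%.6f`.
#'
#' @param m labelled numeric matrix, a [count_transitions()] result, or a
#'   [to_probabilities()] result.
#' @param path output path.
#' @param orientation `"rows-from"` (internal; rows = origin) or `"paper"`
#'   (transposed; columns = origin).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, orientation = c("rows-from", "paper")) {
  orientation <- match.arg(orientation)
  if (inherits(m, "transition_counts")) {
    mat <- m$counts
  } else if (inherits(m, "transition_matrix")) {
    mat <- m$probs
  } else {
    mat <- as.matrix(m)
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("matrix must be labelled")
  if (orientation == "paper") mat <- t(mat)
  is_int <- all(is.na(mat) | mat == round(mat))
  cell <- function(x) {
    ifelse(is.na(x), "", if (is_int) sprintf("%d", as.integer(round(x)))
           else sprintf("%.6f", x))
  }
  lines <- c(
    paste(c("state", colnames(mat)), collapse = ","),
    vapply(seq_len(nrow(mat)), function(i) {
      paste(c(rownames(mat)[i], cell(mat[i, ])), collapse = ",")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a labelled matrix written by [write_matrix()]
#'
#' @param path CSV path.
#' @param orientation orientation the file was written in; the returned
#'   matrix is always in the internal rows-from convention.
#' @return labelled numeric matrix, rows = origin state.
#' @export
read_matrix <- function(path, orientation = c("rows-from", "paper")) {
  orientation <- match.arg(orientation)
  df <- utils::read.csv(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  if (orientation == "paper") mat <- t(mat)
  mat
}
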