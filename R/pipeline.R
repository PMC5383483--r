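#' Run the full sex-change analysis on a census file
#'
#' End-to-end pipeline: reads and validates the census, counts 6-state and
#' pooled transitions, derives probability matrices, runs the bootstrap
#' steady-state test against the uniform null, tabulates sex-change
#' patterns, G-tests the first-vs-last-year sex ratio over the six
#' categories (categories absent from both years are dropped with a note),
#' and -- when covariates are present -- fits the occurrence model with
#' backward AIC selection. All outputs are CSV plus a JSON run manifest;
#' given the same census and seed the analysis outputs are byte-identical.
#'
#' @param census_path path to a census CSV.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the bootstrap.
#' @param n_boot bootstrap replicates for the steady-state test.
#' @param scheme bootstrap scheme, see [bootstrap_matrices()].
#' @return invisibly, a list with the in-memory results (`counts6`,
#'   `counts3`, `steady`, `patterns`, `gtest`, `occurrence`, `manifest`).
#' @export
run_full_analysis <- function(census_path, out_dir, seed, n_boot = 5000,
                              scheme = c("pooled", "row-stratified")) {
  scheme <- match.arg(scheme)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  notes <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", dQuote(name), " failed on ", census_path, ": ",
           conditionMessage(e), call. = FALSE)
    })
  }
  census <- stage("read_census", read_census(census_path))
  trajs <- stage("build_trajectories", build_trajectories(census))

  counts6 <- stage("count_transitions", count_transitions(trajs))
  counts3 <- stage("pool_counts", pool_counts(counts6))
  write_matrix(counts6, file.path(out_dir, "transition_counts_6state.csv"))
  write_matrix(counts3, file.path(out_dir, "transition_counts_pooled.csv"))
  write_matrix(to_probabilities(counts6),
               file.path(out_dir, "transition_probs_6state.csv"))
  write_matrix(to_probabilities(counts3),
               file.path(out_dir, "transition_probs_pooled.csv"))

  steady <- stage("steady_state_test",
                  steady_state_test(counts3, n_boot = n_boot, seed = seed,
                                    scheme = scheme))
  utils::write.csv(as.data.frame(steady),
                   file.path(out_dir, "steady_state.csv"), row.names = FALSE)
  meta <- c(sprintf("seed,%d", seed), sprintf("n_boot,%d", n_boot),
            sprintf("scheme,%s", scheme),
            sprintf("n_redraws,%d", steady$n_redraws))
  writeLines(meta, file.path(out_dir, "steady_state_meta.csv"))

  pat <- stage("tabulate_patterns", tabulate_patterns(trajs))
  utils::write.csv(pat$patterns, file.path(out_dir, "patterns.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")

  gt <- stage("g_test_first_vs_last", {
    yrs <- range(census$year)
    sub <- census[census$year %in% yrs & is_expressed(census$sex), ]
    tab <- table(factor(sub$year, levels = yrs),
                 factor(sub$sex, levels = expressed_states()))
    empty <- colnames(tab)[colSums(tab) == 0]
    if (length(empty)) {
      notes <<- c(notes, paste("dropped categories absent in both",
                               "boundary years:",
                               paste(empty, collapse = ", ")))
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
    }
    if (any(rowSums(tab) == 0) || ncol(tab) < 2) {
      notes <<- c(notes, "first-vs-last-year G-test skipped (degenerate)")
      NULL
    } else g_test(tab)
  })
  if (!is.null(gt)) {
    utils::write.csv(data.frame(G = gt$G, df = gt$df, p = gt$p),
                     file.path(out_dir, "gtest_first_vs_last.csv"),
                     row.names = FALSE)
  }

  occurrence <- NULL
  covars_present <- !all(is.na(census$dbh_cm)) &&
    !all(is.na(census$rppfd_winter)) && !all(is.na(census$rppfd_summer))
  if (covars_present) {
    occurrence <- stage("occurrence_model", {
      md <- change_model_data(census)
      backward_aic(md)
    })
    utils::write.csv(occurrence$trace,
                     file.path(out_dir, "occurrence_selection_trace.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(term = names(occurrence$coefficients),
                 estimate = unname(occurrence$coefficients)),
      file.path(out_dir, "occurrence_coefficients.csv"), row.names = FALSE)
  } else {
    notes <- c(notes, "covariates absent; occurrence model skipped")
  }

  manifest <- list(
    input = census_path,
    input_md5 = unname(tools::md5sum(census_path)),
    seed = seed, n_boot = n_boot, scheme = scheme,
    package_version = as.character(utils::packageVersion("sexlability")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    notes = notes
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(counts6 = counts6, counts3 = counts3, steady = steady,
                 patterns = pat, gtest = gt, occurrence = occurrence,
                 manifest = manifest))
}
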