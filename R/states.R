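#' Sexual state codes
#'
#' The six expressed sexual categories of a subdioecious census --
#' female (`F`), male (`M`), hermaphrodite with only perfect flowers (`H`),
#' and hermaphrodites mixing perfect flowers with pistillate (`HF`),
#' staminate (`HM`), or both (`HFM`) flower types -- plus the two
#' non-expressed codes: `NF` (alive but non-flowering that year) and `NA`
#' (not observed). Only expressed states ever enter transition counts.
#'
#' @return `sex_states()` returns all 8 codes; `expressed_states()` the 6
#'   expressed ones; `pooled_states()` the 3-state pooled label set.
#' @export
sex_states <- function() c("F", "M", "H", "HF", "HM", "HFM", "NF", "NA")

#' @rdname sex_states
#' @export
expressed_states <- function() c("F", "M", "H", "HF", "HM", "HFM")

#' @rdname sex_states
#' @export
pooled_states <- function() c("F", "M", "HALL")

#' Pool hermaphrodite categories
#'
#' Maps the four hermaphrodite categories (H, HF, HM, HFM) onto the single
#' class `HALL`, leaving `F` and `M` (and the non-expressed codes) unchanged.
#' This is the pooling used for all 3-state sex-ratio and steady-state
#' analyses.
#'
#' @param state character vector of state codes.
#' @return character vector over \{F, M, HALL\} (plus NF/NA passed through).
#' @examples
#' pool_hermaphrodites(c("F", "HF", "HFM", "M"))
#' @export
pool_hermaphrodites <- function(state) {
  ifelse(state %in% c("H", "HF", "HM", "HFM"), "HALL", state)
}

# HALL appears in censuses simulated directly on the pooled state space
is_expressed <- function(state) {
  state %in% c(expressed_states(), "HALL")
}
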