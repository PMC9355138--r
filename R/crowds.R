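#' The five measured peer crowds
#'
#' Canonical crowd labels, in the fixed order used throughout the package
#' (score columns, affinity matrices, the MTMM axes).
#'
#' @return Character vector of length 5:
#'   `"Alternative", "Country", "HipHop", "Mainstream", "Popular"`.
#' @export
#' @examples
#' peer_crowds()
peer_crowds <- function() {
  c("Alternative", "Country", "HipHop", "Mainstream", "Popular")
}

#' Rank-2 point weights for the mindset survey
#'
#' A rank-1 choice is always worth 2 points for its crowd. A rank-2 choice is
#' worth 1 point, except for the Alternative and Mainstream crowds, whose
#' rank-2 choices are down-weighted to 0.5 points to counter the social
#' desirability of those response options.
#'
#' @return Named numeric vector of per-crowd rank-2 weights.
#' @export
vmls_rank2_weights <- function() {
  c(Alternative = 0.5, Country = 1, HipHop = 1, Mainstream = 0.5, Popular = 1)
}

# Six past-30-day substances, in battery order; sad/hopeless is the seventh
# dichotomous outcome but has no use-days column.
substances <- function() {
  c("cigarettes", "lcc", "smokeless", "vape", "alcohol", "marijuana")
}

binary_outcomes <- function() c(substances(), "sad_hopeless")

trait_outcomes <- function() c("ace", "brs", "spi", "bsss")

gender_levels <- function() c("Female", "Male", "Another identity")

race_levels <- function() {
  c("NH white", "Hispanic", "NH Black", "NH API", "NH other/multiracial")
}

region_levels <- function() c("North", "Central", "Southeast", "Southwest")

# internal: column names of the ten crowd scores on a scored table
score_columns <- function(instrument) {
  paste0(instrument, "_", tolower(peer_crowds()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid cohort configuration: field '%s' %s", field, msg),
       call. = FALSE)
}
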