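# Published per-patient summary tables of the motivating feasibility
# study (22 outpatients with recurrent major depressive disorder who kept
# daily sleep and depression diaries). The raw diaries are not public;
# these printed summaries are shipped so the aggregation conventions of
# the cohort report can be exercised and reproduced exactly.

study_file <- function(name) {
  system.file("extdata", name, package = "idiovar", mustWork = TRUE)
}

#' Demographics of the motivating study cohort
#'
#' @return data frame with `patient`, `days` (collection period), `sex`,
#'   `age` for the 22 analyzed patients.
#' @export
study_demographics <- function() {
  utils::read.csv(study_file("study_demographics.csv"),
                  stringsAsFactors = FALSE)
}

#' Reported cumulative impulse responses
#'
#' Per-patient cumulative orthogonalized impulse responses (1-SD shock,
#' horizons 0-10 days) for every significant association reported by the
#' motivating study. Units: minutes where sleep responds, scale units
#' where the depression score responds.
#'
#' @return data frame with `association` (`tib_to_dep`, `dep_to_tib`,
#'   `tst_to_dep`, `dep_to_tst`), `patient`, and `lag0` .. `lag10`.
#' @export
study_cumulative_irf <- function() {
  utils::read.csv(study_file("study_cum_irf.csv"), stringsAsFactors = FALSE)
}

#' Reported forecast-error variance shares
#'
#' Per-patient FEVD shares (fraction of forecast-error variance of the
#' effect variable explained by the cause variable) for every
#' significant association reported by the motivating study. Horizons as
#' printed: days 1-6 and 8-10.
#'
#' @return data frame with `association`, `patient`, and `lag1` ..
#'   `lag10` (no `lag7` column, as printed).
#' @export
study_fevd_shares <- function() {
  utils::read.csv(study_file("study_fevd.csv"), stringsAsFactors = FALSE)
}
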