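#' Published factorial responses
#'
#' The 27-run response table as printed in the reference study: full
#' decoloration time `R1`, day of maximum aromatic-metabolite concentration
#' `R2` and full aromatics-depletion time `R3` (days), for every combination
#' of initial glucose `alpha`, initial dye `beta` and inoculation day `gamma`.
#' Values are verbatim from the printed table, including its rounding (note
#' the high-glucose/low-dye `R1` cell, printed as 2.33 where the study's own
#' abstract gives 2.375).
#'
#' @return a 27-row tibble `run, alpha, beta, gamma, R1, R2, R3` with a
#'   `source` attribute `"fixture"`.
#' @export
published_response_table <- function() {
  path <- system.file("extdata", "published_responses.csv", package = "azokin")
  tab <- tibble::as_tibble(read.csv(path))
  attr(tab, "source") <- "fixture"
  tab
}

#' Published response-surface coefficients
#'
#' The printed quadratic-polynomial coefficients and correlation coefficients
#' of the three response surfaces.
#'
#' @return a named list (`R1`, `R2`, `R3`), each with `basis` (name),
#'   `coefficients` (named vector in [rsm_basis()] term order) and
#'   `r.squared`.
#' @export
published_rsm_coefficients <- function() {
  path <- system.file("extdata", "published_coefficients.json", package = "azokin")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(m) {
    list(basis = m$basis, coefficients = unlist(m$coefficients),
         r.squared = m$r.squared)
  })
}

#' Designed factor levels
#'
#' The three levels per factor of the full-factorial design: initial glucose
#' 10/14/20 g/l, initial dye 0.2/0.5/1.0 g/l, inoculation day 1/2/3.
#'
#' @return a named list `alpha`, `beta`, `gamma` of numeric level vectors.
#' @export
design_levels <- function() {
  path <- system.file("extdata", "factor_levels.yaml", package = "azokin")
  yaml::read_yaml(path)
}
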