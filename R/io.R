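#' Export a trajectory as CSV
#'
#' Writes the uniform-grid trajectory with header
#' `t,X_T,X_P,C_glc,C_enz,C_col,C_aro`, optionally thinned.
#'
#' @param traj a `dye_trajectory`.
#' @param path output file.
#' @param stride keep every `stride`-th grid point (the last point is always
#'   kept).
#' @return the path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, stride = 1) {
  idx <- seq(1, nrow(traj), by = stride)
  if (idx[length(idx)] != nrow(traj)) idx <- c(idx, nrow(traj))
  write.csv(as.data.frame(traj)[idx, c("t", STATE_VARS)], path,
            row.names = FALSE)
  invisible(path)
}

#' Read / write a factorial response table
#'
#' CSV with columns `run, alpha, beta, gamma, R1, R2, R3` (extra columns are
#' preserved on write and ignored on read validation).
#'
#' @param path CSV file.
#' @return `read_response_table()`: a tibble; `write_response_table()`: the
#'   path, invisibly.
#' @export
read_response_table <- function(path) {
  tab <- tibble::as_tibble(read.csv(path))
  needed <- c("alpha", "beta", "gamma", "R1", "R2", "R3")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    abort(paste0("response table ", path, " lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tab
}

#' @rdname read_response_table
#' @param tab a response table (e.g. from [run_factorial()]).
#' @export
write_response_table <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' Export a fitted response surface as JSON
#'
#' @param model an `rsm_model`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_model_json <- function(model, path) {
  out <- list(
    response = model$response,
    terms = names(model$coefficients),
    coefficients = as.list(model$coefficients),
    r.squared = model$r.squared,
    region = model$region,
    n = model$n
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# allowed keys of the run-configuration file
RUN_CONFIG_BLOCKS <- list(
  params = names(yaml::yaml.load(
    "mu_max_T: 0\nKs_glc_T: 0\nKd_T: 0\nY_T_glc: 0\nV_max: 0\nK_ME_col: 0\nK_enz: 0\nY_enz_glc: 0\nK_d: 0\nK_dec: 0\nY_col_enz: 0\nmu_max_P: 0\nKs_glc_P: 0\nY_P_glc: 0\nmu_max_aP: 0\nKs_aro: 0\nK_i: 0\nKd_P: 0\nY_P_aro: 0\na_stoich: 0")),
  scenario = c("alpha", "beta", "gamma", "X_T0", "X_P_inoc", "V_t", "t_end",
               "dt", "eps_col", "eps_glc", "eps_aro"),
  factorial = c("alpha", "beta", "gamma"),
  rsm = c("n_grid", "r1_full"),
  output = c("outdir", "stride")
)

#' Read a run configuration file
#'
#' A nested YAML document with optional blocks `params` (kinetic-parameter
#' overrides), `scenario` ([scenario_config()] fields), `factorial` (level
#' vectors per factor), `rsm` (`n_grid`, `r1_full`) and `output` (`outdir`,
#' `stride`). Every key is optional — defaults reproduce the reference
#' configuration — and unknown keys are rejected.
#'
#' @param path YAML file (missing/NULL path yields the all-defaults config).
#' @return a named list of the five blocks, each fully defaulted.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(RUN_CONFIG_BLOCKS))
  if (length(unknown)) {
    abort(paste0("unknown configuration block(s): ", paste(unknown, collapse = ", ")))
  }
  for (blk in names(raw)) {
    bad <- setdiff(names(raw[[blk]]), RUN_CONFIG_BLOCKS[[blk]])
    if (length(bad)) {
      abort(paste0("unknown key(s) in block '", blk, "': ",
                   paste(bad, collapse = ", ")))
    }
  }
  defaults <- list(
    params = list(),
    scenario = list(),
    factorial = design_levels(),
    rsm = list(n_grid = 101, r1_full = FALSE),
    output = list(outdir = ".", stride = 1)
  )
  for (blk in names(raw)) {
    defaults[[blk]] <- modifyList(defaults[[blk]], raw[[blk]])
  }
  defaults
}
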