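#' Read and validate a run configuration
#'
#' Plain-text YAML configuration: model selection plus parameter overrides,
#' integrator tolerances and protocol blocks. Unknown keys are rejected
#' before any computation starts. All tolerances are surfaced; defaults
#' follow the package-wide conventions (1e-8 steady-state criterion, 1%
#' sweep steps, 80 pA/pF / 1 ms / 2000 ms pacing).
#'
#' @param path path to a YAML file.
#' @return validated configuration list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("model", "bistable", "pctGKr", "pctGKs", "nai_clamp",
               "pacing", "integrator", "steady_tol", "max_beats",
               "sweep", "continue", "census", "clamp_scan", "out_dir",
               "log_level")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$pacing)) {
    bad <- setdiff(names(cfg$pacing),
                   c("amplitude", "duration", "cycle_length"))
    if (length(bad)) stop("unknown pacing key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$integrator)) {
    bad <- setdiff(names(cfg$integrator), c("rtol", "atol"))
    if (length(bad))
      stop("unknown integrator key(s): ", paste(bad, collapse = ", "))
  }
  defaults <- list(model = "surrogate", bistable = TRUE, pctGKr = 100,
                   pctGKs = 100, nai_clamp = NA,
                   pacing = list(amplitude = 80, duration = 1,
                                 cycle_length = 2000),
                   integrator = list(rtol = 1e-10, atol = 1e-12),
                   steady_tol = 1e-8, max_beats = 1000, out_dir = ".")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in names(defaults$pacing))
    if (is.null(cfg$pacing[[nm]])) cfg$pacing[[nm]] <- defaults$pacing[[nm]]
  structure(cfg, class = c("run_config", "list"))
}

#' Build the configured system
#'
#' @param cfg a [read_run_config()] result.
#' @return a [dynsys()].
#' @export
system_from_config <- function(cfg) {
  pac <- pacing_protocol(cfg$pacing$amplitude, cfg$pacing$duration,
                         cfg$pacing$cycle_length)
  if (!identical(cfg$model, "surrogate"))
    stop("unsupported model '", cfg$model,
         "'; the bundled surrogate is the supported model definition")
  make_paced_surrogate_ap(
    bistable = isTRUE(cfg$bistable),
    params = model_params(pctGKr = cfg$pctGKr, pctGKs = cfg$pctGKs,
                          pacing = pac,
                          nai_clamp = cfg$nai_clamp %||% NA))
}

#' Export beat traces as tidy CSV
#'
#' One row per sample: \code{beat_index}, \code{t_ms}, then the state
#' variables with units suffixed in the header (deterministic column
#' order).
#'
#' @param traces list of beat traces from [simulate_beats()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_traces <- function(traces, path) {
  unit_of <- function(nm)
    switch(nm, Vm = "Vm_mV", Nai = "Nai_mM", Cai = "Cai_mM", nm)
  rows <- lapply(traces, function(tr) {
    df <- tr
    names(df) <- c("t_ms", vapply(names(tr)[-1], unit_of, character(1)))
    cbind(beat_index = attr(tr, "beat_index"), df)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a bifurcation diagram table as CSV
#'
#' @param diagram a [build_bifurcation_diagram()] result (or a plain
#'   data.frame such as a sweep table).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_diagram <- function(diagram, path) {
  tab <- if (inherits(diagram, "bifurcation_diagram")) diagram$table else
    diagram
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export localized bifurcation points as JSON
#'
#' Multipliers and states serialize with complex values as re/im pairs.
#'
#' @param bif_points list of [localize_bifurcation()] results.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_bifurcations <- function(bif_points, path) {
  enc <- lapply(bif_points, function(b) {
    list(param_value = b$param_value, type = b$type,
         critical_multiplier = list(re = Re(b$critical_multiplier),
                                    im = Im(b$critical_multiplier)),
         state = as.list(b$state), k = b$k,
         localization_width = b$localization_width)
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export a fixed point as JSON
#'
#' @param fp a [newton_shoot()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fixed_point <- function(fp, path) {
  enc <- list(x = as.list(fp$x), k = fp$k,
              multipliers = lapply(fp$multipliers,
                                   function(m) list(re = Re(m), im = Im(m))),
              stable = fp$stable, residual = fp$residual,
              converged = fp$converged)
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
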