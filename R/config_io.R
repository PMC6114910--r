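#' Write a simulation configuration to a YAML file
#'
#' All module sections are written under their parameter names (units are cgs
#' throughout: cm, g, s, dyn). Derived quantities (the precomputed coupling
#' matrix) are not stored; [read_sim_config()] rebuilds them through the
#' module constructors, so the round trip revalidates every invariant.
#'
#' @param config A [simulation_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  cpg <- config$cpg
  cpg$coupling <- NULL
  out <- list(
    cpg = unclass(cpg),
    feedback = unclass(config$feedback),
    muscle = unclass(config$muscle),
    body = config$body,
    fluid = config$fluid,
    run = config$run,
    units = "cgs"
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Read a simulation configuration from a YAML file
#'
#' @param path A file written by [write_sim_config()].
#' @return A validated [simulation_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (s in c("cpg", "feedback", "muscle")) {
    if (is.null(raw[[s]])) stop("config file misses section '", s, "'",
                                call. = FALSE)
  }
  simulation_config(
    cpg = do.call(cpg_params, raw$cpg),
    feedback = do.call(feedback_config, raw$feedback),
    muscle = do.call(muscle_params, raw$muscle),
    body = raw$body %||% list(),
    fluid = raw$fluid %||% list(),
    run = raw$run %||% list()
  )
}
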