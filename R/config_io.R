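#' Configuration file round-trip
#'
#' A configuration is stored as a single YAML document. It may name a
#' `preset` (see [sim_preset()]) and override individual blocks, or spell
#' out the design inline. [read_config()] resolves the preset first and then
#' applies whatever blocks are present.
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `read_config()`: a [sim_config()]; `write_config()`: `path`,
#'   invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

config_to_list <- function(config) {
  list(
    design = design_to_list(config$design),
    repair = config$repair[c("kappa", "alpha", "beta", "kappa_dep",
                             "alpha_dep", "beta_dep", "grna_deposition",
                             "shadow_drive", "tt_mode")],
    fitness = list(
      dominant = lapply(config$fitness$dominant, as.list),
      recessive = lapply(config$fitness$recessive, as.list)
    ),
    migration = config$migration[c("m12", "m21", "m2w")],
    release = config$release[c("fraction", "sex", "heterozygous")],
    generations = config$generations,
    populations = config$populations
  )
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  config_from_list(x)
}

config_from_list <- function(x) {
  if (!is.null(x$preset)) {
    config <- sim_preset(x$preset)
  } else {
    if (is.null(x$design)) stop("config needs a 'preset' or a 'design' block")
    config <- sim_config(design_from_list(x$design))
  }
  if (!is.null(x$design) && !is.null(x$preset)) {
    config$design <- design_from_list(x$design)
  }
  if (!is.null(x$repair)) config$repair <- do.call(repair_params, x$repair)
  if (!is.null(x$fitness)) {
    config$fitness <- fitness_params(
      dominant = lapply(x$fitness$dominant, function(d) unlist(d)),
      recessive = lapply(x$fitness$recessive, function(r) unlist(r))
    )
  }
  if (!is.null(x$migration)) {
    config$migration <- do.call(migration_spec, x$migration)
  }
  if (!is.null(x$release)) config$release <- do.call(release_spec, x$release)
  if (!is.null(x$generations)) config$generations <- as.integer(x$generations)
  if (!is.null(x$populations)) config$populations <- as.integer(x$populations)
  config
}
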