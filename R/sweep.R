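#' Modify one configuration value by dotted path
#'
#' Recognised paths: `repair.<kappa|alpha|beta|kappa_dep|alpha_dep|beta_dep|
#' grna_deposition|shadow_drive|tt_mode>`, `release.<fraction|sex|
#' heterozygous>`, `migration.<m12|m21|m2w>`, `fitness.dominant.<locus>`
#' (sets the dominant fitness of that locus's drive allele),
#' `fitness.recessive.<locus>`, `generations`, `populations`. Derived repair
#' quantities (`mu`, `nu`, ...) are recomputed.
#'
#' @param config a [sim_config()].
#' @param path dotted parameter path.
#' @param value new value.
#' @return the modified configuration.
#' @export
config_modify <- function(config, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  head <- parts[1]
  if (head == "generations") {
    config$generations <- as.integer(value)
  } else if (head == "populations") {
    config$populations <- as.integer(value)
  } else if (head == "repair") {
    fields <- config$repair[c("kappa", "alpha", "beta", "kappa_dep",
                              "alpha_dep", "beta_dep", "grna_deposition",
                              "shadow_drive", "tt_mode")]
    if (!parts[2] %in% names(fields)) stop("unknown repair field: ", parts[2])
    fields[[parts[2]]] <- value
    config$repair <- do.call(repair_params, fields)
  } else if (head == "release") {
    if (!parts[2] %in% c("fraction", "sex", "heterozygous")) {
      stop("unknown release field: ", parts[2])
    }
    config$release[[parts[2]]] <- value
  } else if (head == "migration") {
    if (!parts[2] %in% c("m12", "m21", "m2w")) {
      stop("unknown migration field: ", parts[2])
    }
    config$migration[[parts[2]]] <- value
  } else if (head == "fitness") {
    locus <- parts[3]
    if (!locus %in% design_loci(config$design)) stop("unknown locus: ", locus)
    if (parts[2] == "dominant") {
      da <- config$design$loci[[locus]]$drive_allele
      if (is.null(config$fitness$dominant[[locus]])) {
        config$fitness$dominant[[locus]] <- stats::setNames(numeric(), character())
      }
      config$fitness$dominant[[locus]][[da]] <- value
    } else if (parts[2] == "recessive") {
      config$fitness$recessive[[locus]] <- value
    } else stop("unknown fitness field: ", parts[2])
  } else {
    stop("unknown configuration path: ", path)
  }
  config
}

#' Run a deterministic parameter sweep
#'
#' Runs one simulation per cell of the cartesian grid defined by `axes` and
#' collects the [summarize_trajectory()] metrics. Cells are independent and
#' the whole sweep is deterministic, so any subset rerun reproduces the full
#' run's rows. A failing cell is recorded with `NA` metrics and its error
#' message rather than aborting the sweep.
#'
#' @param config base [sim_config()].
#' @param axes named list: [config_modify()] path -> vector of values.
#' @param locus,threshold passed to [summarize_trajectory()].
#' @return data.frame with one row per cell: the axis values, then per
#'   population `max_drive`, `peak_generation`, `r1_at_peak`, `max_r1`,
#'   `generations_above`, `end_of_run` (prefixed `pop1_` / `pop2_`),
#'   `difference` (two-population runs) and `error`.
#' @export
run_sweep <- function(config, axes, locus = "A", threshold = 0.9) {
  stopifnot(length(axes) >= 1L, !is.null(names(axes)))
  grid <- do.call(expand.grid, c(axes, list(KEEP.OUT.ATTRS = FALSE,
                                            stringsAsFactors = FALSE)))
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    cfg <- config
    for (ax in names(axes)) cfg <- config_modify(cfg, ax, grid[r, ax])
    cell <- grid[r, , drop = FALSE]
    res <- tryCatch({
      s <- summarize_trajectory(run_simulation(cfg), locus, threshold)
      flat <- do.call(cbind, lapply(seq_len(nrow(s)), function(p) {
        row <- s[p, setdiff(names(s), "population"), drop = FALSE]
        names(row) <- paste0("pop", s$population[p], "_", names(row))
        row
      }))
      if (!is.null(attr(s, "difference"))) flat$difference <- attr(s, "difference")
      flat$error <- NA_character_
      flat
    }, error = function(e) data.frame(error = conditionMessage(e),
                                      stringsAsFactors = FALSE))
    cbind(cell, res, row.names = NULL)
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    # pad failed cells to the full column set
    missing <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    for (m in missing) r[[m]] <- NA
    r[, unique(unlist(lapply(rows, names)))]
  }))
  rownames(out) <- NULL
  out
}
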