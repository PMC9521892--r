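#' Migration between the two populations
#'
#' Each generation a fraction of the surviving adults is exchanged:
#' population one receives `m12` of its composition from population two;
#' population two receives `m21` from population one and `m2w` of pure
#' wild-types from an unmodelled general population; the remainder of each
#' population is retained.
#'
#' @param m12 fraction of population one replaced by population two.
#' @param m21 fraction of population two replaced by population one.
#' @param m2w fraction of population two replaced by wild-type immigrants.
#' @return an object of class `migration_spec`.
#' @export
migration_spec <- function(m12 = 0.01, m21 = 0.005, m2w = 0.005) {
  stopifnot(m12 >= 0, m12 <= 1, m21 >= 0, m2w >= 0, m21 + m2w <= 1)
  structure(list(m12 = m12, m21 = m21, m2w = m2w), class = "migration_spec")
}

#' Release scenario
#'
#' At the start of the simulation (generation 1) a fraction of one sex of
#' population one is replaced by drive-carrying individuals; population two
#' starts fully wild-type. Released individuals carry no deposition tag
#' (lab-reared) and pass through selection before their first mating.
#'
#' @param fraction fraction of the released sex that carries the drive.
#' @param sex which sex is released (`"male"` by default).
#' @param heterozygous release drive/wild-type heterozygotes instead of
#'   individuals homozygous for every drive element.
#' @return an object of class `release_spec`.
#' @export
release_spec <- function(fraction = 0.25, sex = c("male", "female", "both"),
                         heterozygous = FALSE) {
  sex <- match.arg(sex)
  if (fraction < 0 || fraction > 1) stop("release fraction must lie in [0, 1]")
  structure(list(fraction = fraction, sex = sex,
                 heterozygous = isTRUE(heterozygous)),
            class = "release_spec")
}

#' Assemble a complete simulation configuration
#'
#' @param design a [drive_design()].
#' @param repair a [repair_params()].
#' @param fitness a [fitness_params()]; defaults to the package's standard
#'   preset for the design ([fitness_preset()] `"fig_defaults"`).
#' @param migration a [migration_spec()].
#' @param release a [release_spec()].
#' @param generations number of discrete generations to simulate.
#' @param populations 1 (single closed population) or 2 (linked by
#'   migration).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(design, repair = repair_params(),
                       fitness = fitness_preset("fig_defaults", design),
                       migration = migration_spec(),
                       release = release_spec(),
                       generations = 100L, populations = 2L) {
  stopifnot(inherits(design, "drive_design"), inherits(repair, "repair_params"),
            inherits(fitness, "fitness_params"), populations %in% c(1L, 2L),
            generations >= 1L)
  structure(list(design = design, repair = repair, fitness = fitness,
                 migration = migration, release = release,
                 generations = as.integer(generations),
                 populations = as.integer(populations)),
            class = "sim_config")
}

#' Ready-made simulation configurations
#'
#' Returns the full default configuration for a named drive architecture:
#' the [drive_preset()] design, saturating germline cut-rate (1.0), HDR 0.95,
#' type-1 fraction 0.1, no deposition, default fitness
#' ([fitness_preset()] `"fig_defaults"`), two populations with default
#' migration, 100 generations, and a male release of drive homozygotes --
#' 25% of males for the multi-element drives, 0.25% for the
#' self-perpetuating drive.
#'
#' @param name one of `"spd"`, `"split"`, `"noble_dcd"`, `"direct_dcd"`,
#'   `"indirect_dcd"`.
#' @return a [sim_config()].
#' @export
sim_preset <- function(name) {
  design <- drive_preset(name)
  release <- release_spec(fraction = if (name == "spd") 0.0025 else 0.25)
  sim_config(design, release = release)
}

# precompute everything a run needs; class "drive_engine"
build_engine <- function(config) {
  deposition <- config$repair$kappa_dep > 0
  space <- enumerate_states(config$design, deposition = deposition)
  C <- conversion_matrix(space, config$repair, "germline")
  K <- if (deposition) conversion_matrix(space, config$repair, "embryo")
       else Matrix::Diagonal(space$d)
  theta <- fitness_vector(space, config$fitness)
  H <- gamete_matrix(space, config$repair)
  zmap <- zygote_index_map(space)

  null_tag <- tag_index(space, 0L, 0L, "")
  wt_geno <- geno_index_from_pairs(
    space, vapply(space$loci, function(l) unname(space$pairmap[[l]]["T/T"]),
                  integer(1)))
  rel_pairs <- vapply(space$loci, function(l) {
    da <- space$design$loci[[l]]$drive_allele
    key <- if (config$release$heterozygous) {
      a <- sort_alleles(c("T", da)); paste(a[1], a[2], sep = "/")
    } else paste(da, da, sep = "/")
    unname(space$pairmap[[l]][key])
  }, integer(1))
  rel_geno <- geno_index_from_pairs(space, rel_pairs)

  # per-locus allele-class count matrices (d0 x class), counts out of 2
  counts <- lapply(space$loci, function(l) {
    cls1 <- allele_class(space$geno_a1[, l])
    cls2 <- allele_class(space$geno_a2[, l])
    drv <- c("E", "G", "N")
    cbind(T = (cls1 == "T") + (cls2 == "T"),
          R1 = (cls1 == "R1") + (cls2 == "R1"),
          R2 = (cls1 == "R2") + (cls2 == "R2"),
          D = (cls1 %in% drv) + (cls2 %in% drv))
  })
  names(counts) <- space$loci

  structure(list(
    config = config, space = space, C = C, K = K, theta = theta,
    D_f = build_D(K, theta$female), D_m = build_D(K, theta$male),
    H = H, zmap = zmap,
    wt_state = state_index(space, wt_geno, null_tag),
    release_state = state_index(space, rel_geno, null_tag),
    counts = counts
  ), class = "drive_engine")
}

#' Combine parental gamete pools into the zygote vector
#'
#' `z` is the outer product of the paternal and maternal haploid frequency
#' vectors, accumulated onto canonical diploid states: per-locus pairs are
#' unordered, the paternal Cas9 marker comes from the father's gamete, and
#' the maternal Cas9 marker and deposited gRNA set from the mother's.
#'
#' @param p_male,p_female haploid state frequency vectors (each summing
#'   to 1), in the order of `space`'s haploid index.
#' @param space a [enumerate_states()] result.
#' @param zmap optional precomputed index map (internal use).
#' @return zygote frequency vector of length `space$d`, summing to 1.
#' @export
form_zygotes <- function(p_male, p_female, space, zmap = NULL) {
  if (is.null(zmap)) zmap <- zygote_index_map(space)
  M <- outer(as.numeric(p_male), as.numeric(p_female))
  z <- numeric(space$d)
  agg <- rowsum(as.vector(M), as.vector(zmap))
  z[as.integer(rownames(agg))] <- agg
  z
}

#' Migration step
#'
#' Applied to same-stage (post-selection adult) frequency distributions, one
#' sex at a time; see [migration_spec()].
#'
#' @param pop1,pop2 frequency vectors for the two populations.
#' @param wildtype frequency vector of the wild-type immigrant pool.
#' @param spec a [migration_spec()].
#' @return list with elements `pop1` and `pop2`.
#' @export
apply_migration <- function(pop1, pop2, wildtype, spec) {
  list(
    pop1 = (1 - spec$m12) * pop1 + spec$m12 * pop2,
    pop2 = (1 - spec$m21 - spec$m2w) * pop2 + spec$m21 * pop1 +
      spec$m2w * wildtype
  )
}

.normalize <- function(x, what) {
  s <- sum(x)
  if (!is.finite(s) || s <= 0) {
    stop("population collapse: ", what, " has zero total frequency ",
         "(all genotypes inviable)")
  }
  x / s
}

#' Run a deterministic drive simulation
#'
#' Iterates the discrete-generation life cycle: zygotes are formed from the
#' previous generation's gamete pools and normalised to total frequency 1
#' (the one normalisation per generation); maternal-deposition conversion
#' and selection act on each sex's embryos (`e = z D`), whose total mass
#' thereafter equals the cohort's mean survival; germline expression
#' converts genotypes (`g = e C`); surviving adults migrate between the
#' populations, pools mixing in proportion to their surviving mass; meiosis
#' produces the next gamete pools (`p = g H`). Generation 1 instead seeds
#' the embryonic vectors from the release scenario (released individuals
#' experience selection before mating). The reported per-generation state is
#' the zygote-stage genotype frequency, before that generation's deposition,
#' selection, and expression -- summed over deposition tags.
#'
#' @param config a [sim_config()].
#' @return an object of class `drive_trajectory`: list with `allele` (long
#'   data.frame: generation, population, locus, class, frequency), `zygote`
#'   (per population, a generations x genotypes frequency matrix), `space`,
#'   `config`.
#' @examples
#' traj <- run_simulation(sim_preset("spd"))
#' summarize_trajectory(traj)
#' @export
run_simulation <- function(config) {
  engine <- build_engine(config)
  run_engine(engine)
}

run_engine <- function(engine) {
  config <- engine$config
  space <- engine$space
  G <- config$generations
  npop <- config$populations
  d <- space$d

  wt <- numeric(d); wt[engine$wt_state] <- 1
  wt_hap <- as.numeric(wt %*% engine$H)

  # generation-1 embryos from the release scenario
  rel <- config$release
  mix_rel <- numeric(d)
  mix_rel[engine$release_state] <- rel$fraction
  mix_rel[engine$wt_state] <- mix_rel[engine$wt_state] + 1 - rel$fraction
  mix_m <- if (rel$sex %in% c("male", "both")) mix_rel else wt
  mix_f <- if (rel$sex %in% c("female", "both")) mix_rel else wt

  zrep <- lapply(seq_len(npop), function(p) matrix(0, G, space$d0))
  e_f <- vector("list", npop); e_m <- vector("list", npop)
  p_f <- vector("list", npop); p_m <- vector("list", npop)

  for (t in seq_len(G)) {
    for (p in seq_len(npop)) {
      if (t == 1L) {
        z <- if (p == 1L) 0.5 * (mix_m + mix_f) else wt
        ef <- if (p == 1L) mix_f * engine$theta$female else wt
        em <- if (p == 1L) mix_m * engine$theta$male else wt
      } else {
        z <- .normalize(form_zygotes(p_m[[p]], p_f[[p]], space, engine$zmap),
                        sprintf("zygotes, generation %d", t))
        # embryonic vectors keep their post-selection mass (mean survival of
        # the cohort); the single per-generation normalisation happens at the
        # zygote stage, so migrant pools mix in proportion to their survivors
        ef <- as.numeric(z %*% engine$D_f)
        em <- as.numeric(z %*% engine$D_m)
      }
      zrep[[p]][t, ] <- rowSums(matrix(z, space$d0, space$nt))
      if (sum(ef) <= 0 || sum(em) <= 0) {
        stop("population collapse: no viable embryos in population ", p,
             ", generation ", t)
      }
      e_f[[p]] <- ef
      e_m[[p]] <- em
    }
    g_f <- lapply(e_f, function(e) as.numeric(e %*% engine$C))
    g_m <- lapply(e_m, function(e) as.numeric(e %*% engine$C))
    if (npop == 2L) {
      mf <- apply_migration(g_f[[1]], g_f[[2]], wt, config$migration)
      mm <- apply_migration(g_m[[1]], g_m[[2]], wt, config$migration)
      g_f <- list(mf$pop1, mf$pop2)
      g_m <- list(mm$pop1, mm$pop2)
    }
    p_f <- lapply(g_f, function(g) as.numeric(g %*% engine$H))
    p_m <- lapply(g_m, function(g) as.numeric(g %*% engine$H))
  }

  allele <- do.call(rbind, lapply(seq_len(npop), function(p) {
    do.call(rbind, lapply(space$loci, function(l) {
      freq <- zrep[[p]] %*% engine$counts[[l]] / 2
      data.frame(
        generation = rep(seq_len(G), times = ncol(freq)),
        population = p, locus = l,
        class = rep(colnames(freq), each = G),
        frequency = as.vector(freq),
        stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(allele) <- NULL

  structure(list(allele = allele, zygote = zrep, space = space,
                 config = config),
            class = "drive_trajectory")
}

#' @export
print.drive_trajectory <- function(x, ...) {
  cat("<drive_trajectory>", x$config$design$name,
      sprintf("- %d generations, %d population(s), %d genotypes\n",
              x$config$generations, x$config$populations, x$space$d0))
  invisible(x)
}

#' Export a trajectory
#'
#' Writes the long-format allele-frequency table
#' (generation, population, locus, class, frequency) as CSV, and optionally
#' the full genotype-frequency table and a JSON sidecar echoing the
#' configuration.
#'
#' @param traj a [run_simulation()] result.
#' @param file path of the allele-frequency CSV.
#' @param genotypes_file optional path for the per-genotype zygote
#'   frequencies (long CSV).
#' @param metadata_file optional path for the JSON run-metadata sidecar
#'   (needs the jsonlite package).
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(traj, file, genotypes_file = NULL,
                             metadata_file = NULL) {
  utils::write.csv(traj$allele, file, row.names = FALSE)
  if (!is.null(genotypes_file)) {
    sp <- traj$space
    labels <- vapply(seq_len(sp$d0), function(i) state_label(sp, i, 1L),
                     character(1))
    long <- do.call(rbind, lapply(seq_along(traj$zygote), function(p) {
      m <- traj$zygote[[p]]
      data.frame(
        generation = rep(seq_len(nrow(m)), times = ncol(m)),
        population = p,
        genotype = rep(labels, each = nrow(m)),
        frequency = as.vector(m), stringsAsFactors = FALSE
      )
    }))
    utils::write.csv(long, genotypes_file, row.names = FALSE)
  }
  if (!is.null(metadata_file)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("the jsonlite package is required for metadata export")
    }
    meta <- list(package = "daisydrive",
                 version = as.character(utils::packageVersion("daisydrive")),
                 config = config_to_list(traj$config))
    jsonlite::write_json(meta, metadata_file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}
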