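#' Fitness parameters
#'
#' Fitness is multiplicative over alleles. Each (locus, allele) pair can
#' carry a dominant fitness value in `[0, 1]` applied once if the genotype
#' carries one or two copies of that allele at that locus; alleles without an
#' entry have fitness 1 (wild-type). A locus may additionally carry a
#' recessive fitness value triggered when both alleles at that locus are
#' loss-of-function (the locus's drive allele or `R2` -- e.g. at locus A the
#' trigger set is `{EE, E2, 22}` for a direct daisy chain). Every value can
#' be sex-specific: supply a named vector `c(female = , male = )` instead of
#' a scalar.
#'
#' @param dominant named list: locus label -> named numeric of per-allele
#'   dominant fitness values (scalar or `c(female=, male=)`).
#' @param recessive named list: locus label -> fitness value (scalar or
#'   `c(female=, male=)`) applied when both alleles at that locus are
#'   loss-of-function.
#' @return an object of class `fitness_params`.
#' @examples
#' fitness_preset("fig_defaults", drive_preset("direct_dcd"))
#' @export
fitness_params <- function(dominant = list(), recessive = list()) {
  chk <- unlist(dominant, use.names = FALSE)
  if (length(chk) && any(chk < 0 | chk > 1)) stop("fitness values must lie in [0, 1]")
  structure(list(dominant = dominant, recessive = recessive),
            class = "fitness_params")
}

.fitness_value <- function(x, sex) {
  if (length(x) == 1L && is.null(names(x))) return(as.numeric(x))
  if (!is.null(names(x)) && sex %in% names(x)) return(as.numeric(x[[sex]]))
  as.numeric(x[[1]])
}

#' Named fitness presets
#'
#' \describe{
#'   \item{`"fig_defaults"`}{the package defaults: A drive allele 0.90
#'     (imperfect haploinsufficient-gene rescue plus general costs), B and C
#'     drive alleles 0.95 each, `R2` at A dominant lethal (0); everything
#'     else neutral. A triple drive carrier has fitness
#'     0.90 * 0.95 * 0.95 = 0.81.}
#'   \item{`"noble"`}{the Noble et al.-style parameterisation: A drive 0.92,
#'     `R2` at A lethal, B and C drives 0.9999, `R2` at B neutral (1).}
#'   \item{`"suppression"`}{population-suppression variant: the A element has
#'     no rescue, so the A drive allele and `R2` at A are neutral dominantly
#'     but the locus is recessive lethal (both-LOF fitness 0); B/C as
#'     defaults.}
#'   \item{`"suppression_female"`}{as `"suppression"` but the recessive
#'     lethality applies to females only.}
#' }
#'
#' @param name preset name.
#' @param design the [drive_design()] the preset is attached to (determines
#'   which drive allele sits at each locus).
#' @return a [fitness_params()].
#' @export
fitness_preset <- function(name, design) {
  loci <- design_loci(design)
  drv <- function(l) design$loci[[l]]$drive_allele
  bc <- setdiff(loci, "A")
  dom_bc <- lapply(bc, function(l) stats::setNames(0.95, drv(l)))
  names(dom_bc) <- bc
  switch(
    name,
    fig_defaults = fitness_params(
      dominant = c(list(A = stats::setNames(c(0.90, 0), c(drv("A"), "R2"))), dom_bc)
    ),
    noble = {
      dom_bc99 <- lapply(bc, function(l) stats::setNames(0.9999, drv(l)))
      names(dom_bc99) <- bc
      fitness_params(
        dominant = c(list(A = stats::setNames(c(0.92, 0), c(drv("A"), "R2"))), dom_bc99)
      )
    },
    suppression = fitness_params(
      dominant = dom_bc,
      recessive = list(A = 0)
    ),
    suppression_female = fitness_params(
      dominant = dom_bc,
      recessive = list(A = c(female = 0, male = 1))
    ),
    stop("unknown fitness preset: ", name)
  )
}

#' Fitness of a diploid genotype
#'
#' Multiplies the dominant fitness values of the distinct cost-bearing
#' (locus, allele) combinations present (each applied once regardless of copy
#' number), times any triggered recessive value.
#'
#' @param g a [genotype()].
#' @param sex `"female"` or `"male"`.
#' @param fp a [fitness_params()].
#' @param design the [drive_design()] (needed to identify loss-of-function
#'   alleles for recessive costs).
#' @return fitness in `[0, 1]`.
#' @examples
#' d <- drive_preset("direct_dcd")
#' fp <- fitness_preset("fig_defaults", d)
#' g <- genotype(A = c("E", "T"), B = c("N^A", "T"), C = c("G^B", "T"))
#' genotype_fitness(g, "female", fp, d)  # 0.81
#' @export
genotype_fitness <- function(g, sex = c("female", "male"), fp, design) {
  sex <- match.arg(sex)
  w <- 1
  for (l in names(g$pairs)) {
    dom <- fp$dominant[[l]]
    if (!is.null(dom)) {
      for (a in unique(g$pairs[[l]])) {
        if (a %in% names(dom)) w <- w * .fitness_value(dom[[a]], sex)
      }
    }
    rec <- fp$recessive[[l]]
    if (!is.null(rec)) {
      lof <- c(design$loci[[l]]$drive_allele, "R2")
      if (all(g$pairs[[l]] %in% lof)) w <- w * .fitness_value(rec, sex)
    }
  }
  w
}

#' Sex-specific fitness vectors over a state space
#'
#' @param space a [enumerate_states()] result.
#' @param fp a [fitness_params()].
#' @return list with numeric vectors `female` and `male` of length `space$d`
#'   (fitness depends only on the genotype, so values repeat across
#'   deposition tags).
#' @export
fitness_vector <- function(space, fp) {
  design <- space$design
  theta0 <- vapply(c("female", "male"), function(sex) {
    vapply(seq_len(space$d0), function(i) {
      w <- 1
      for (l in space$loci) {
        a1 <- space$geno_a1[i, l]; a2 <- space$geno_a2[i, l]
        dom <- fp$dominant[[l]]
        if (!is.null(dom)) {
          for (a in unique(c(a1, a2))) {
            if (a %in% names(dom)) w <- w * .fitness_value(dom[[a]], sex)
          }
        }
        rec <- fp$recessive[[l]]
        if (!is.null(rec)) {
          lof <- c(design$loci[[l]]$drive_allele, "R2")
          if (a1 %in% lof && a2 %in% lof) w <- w * .fitness_value(rec, sex)
        }
      }
      w
    }, numeric(1))
  }, numeric(space$d0))
  list(female = rep(theta0[, "female"], space$nt),
       male = rep(theta0[, "male"], space$nt))
}

#' Mosaic fitness of deposition-affected zygotes
#'
#' Embryonic cutting happens in a developing individual, so the genotype
#' fractions in row i of the deposition matrix K describe tissues of one
#' mosaic organism, not independent offspring. Its survival is the
#' frequency-weighted mean fitness of those fractions,
#' `w_i = sum_j K_ij * theta_j`, applied uniformly to everything arising from
#' zygote i.
#'
#' @param K embryonic conversion matrix (row-stochastic, from
#'   [conversion_matrix()] with `stage = "embryo"`).
#' @param theta fitness vector (one sex) of matching length.
#' @return numeric vector of mosaic fitness values `w`.
#' @export
mosaic_fitness <- function(K, theta) {
  as.numeric(K %*% theta)
}

#' Combined embryonic transition matrix D
#'
#' `D_ij = K_ij * w_i` with `w` the [mosaic_fitness()]; applying D to a
#' zygote frequency vector and renormalising gives the post-selection
#' embryonic vector: `e = normalise(z D)`.
#'
#' @inheritParams mosaic_fitness
#' @return sparse matrix of the same shape as K.
#' @export
build_D <- function(K, theta) {
  w <- mosaic_fitness(K, theta)
  Matrix::Diagonal(x = w) %*% K
}
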