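#' Per-locus allele-class frequencies of a genotype frequency vector
#'
#' Each diploid state contributes its allele counts at the locus divided
#' by 2. Classes: `T`, `R1`, `R2` and `D` (the union of the drive classes E,
#' G, N); the four frequencies sum to 1.
#'
#' @param z genotype frequency vector: length `space$d` (full state vector)
#'   or `space$d0` (already summed over deposition tags).
#' @param space a [enumerate_states()] result.
#' @param locus locus label.
#' @return named numeric `(T, R1, R2, D)`.
#' @export
allele_frequencies <- function(z, space, locus) {
  if (length(z) == space$d && space$nt > 1L) {
    z <- rowSums(matrix(z, space$d0, space$nt))
  } else if (length(z) != space$d0 && length(z) != space$d) {
    stop("z has the wrong length for this state space")
  }
  cls1 <- allele_class(space$geno_a1[, locus])
  cls2 <- allele_class(space$geno_a2[, locus])
  drv <- c("E", "G", "N")
  cnt <- cbind(T = (cls1 == "T") + (cls2 == "T"),
               R1 = (cls1 == "R1") + (cls2 == "R1"),
               R2 = (cls1 == "R2") + (cls2 == "R2"),
               D = (cls1 %in% drv) + (cls2 %in% drv))
  drop(z %*% cnt) / 2
}

#' Summary metrics of a trajectory
#'
#' For each population, at the chosen locus: the maximum drive-allele
#' frequency and the generation at which it occurs, the type-1 resistance
#' frequency at that generation, the overall maximum type-1 frequency, the
#' number of generations with drive frequency strictly above `threshold`,
#' and whether the maximum falls on the final generation (in which case a
#' longer simulation might change the outcome). The `difference` attribute
#' holds max(population one) - max(population two) when two populations were
#' simulated.
#'
#' @param traj a [run_simulation()] result.
#' @param locus locus label (default `"A"`, the effector locus).
#' @param threshold drive-frequency threshold for the generations-above
#'   count (strict inequality).
#' @return data.frame with one row per population and columns `population`,
#'   `max_drive`, `peak_generation`, `r1_at_peak`, `max_r1`,
#'   `generations_above`, `end_of_run`.
#' @export
summarize_trajectory <- function(traj, locus = "A", threshold = 0.9) {
  a <- traj$allele
  a <- a[a$locus == locus, ]
  pops <- sort(unique(a$population))
  rows <- lapply(pops, function(p) {
    dr <- a[a$population == p & a$class == "D", ]
    r1 <- a[a$population == p & a$class == "R1", ]
    dr <- dr[order(dr$generation), ]
    r1 <- r1[order(r1$generation), ]
    peak <- which.max(dr$frequency)
    data.frame(
      population = p,
      max_drive = dr$frequency[peak],
      peak_generation = dr$generation[peak],
      r1_at_peak = r1$frequency[peak],
      max_r1 = max(r1$frequency),
      generations_above = sum(dr$frequency > threshold),
      end_of_run = peak == nrow(dr)
    )
  })
  out <- do.call(rbind, rows)
  if (length(pops) == 2L) {
    attr(out, "difference") <- out$max_drive[1] - out$max_drive[2]
  }
  out
}

#' Frequency trajectory of one allele class
#'
#' @param traj a [run_simulation()] result.
#' @param locus locus label.
#' @param class allele class: `"D"`, `"T"`, `"R1"` or `"R2"`.
#' @param population population index.
#' @return numeric vector over generations.
#' @export
class_trajectory <- function(traj, locus = "A", class = "D", population = 1L) {
  a <- traj$allele
  sel <- a$locus == locus & a$class == class & a$population == population
  a$frequency[sel][order(a$generation[sel])]
}
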