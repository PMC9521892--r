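# Independent stochastic oracles. These re-implement the cut/repair rules by
# sampling individual events; they never call the package's matrix builders.

# Sample the germline fate of one cuttable T allele with drive machinery:
# cut with probability kappa, repaired by HDR (copying `homolog`), to R1,
# or to R2. Returns the post-repair allele per draw.
sample_repair <- function(n, homolog, kappa, alpha, beta) {
  u <- stats::runif(n)
  out <- rep("T", n)
  cut <- u < kappa
  r <- stats::runif(n)
  hdr <- cut & r < alpha
  out[hdr] <- homolog[hdr]
  r1 <- cut & !hdr & r < alpha + (1 - alpha) * beta
  out[r1] <- "R1"
  out[cut & !hdr & !r1] <- "R2"
  out
}

# Individual-based Wright-Fisher simulation of the single-locus
# self-perpetuating drive (alleles T, R1, R2, N = N^A). Viability selection
# by binomial thinning, random mating with replacement, germline conversion
# sampled per sampled parent, one allele transmitted per gamete. Returns
# the zygote-stage drive-allele frequency per generation.
mc_spd <- function(n_ind, generations, release, kappa = 1, alpha = 0.95,
                   beta = 0.1, fit_drive = 0.9) {
  fitness <- function(a1, a2) {
    w <- rep(1, length(a1))
    w[a1 == "N" | a2 == "N"] <- fit_drive
    w[a1 == "R2" | a2 == "R2"] <- 0
    w
  }
  gametes_from <- function(a1, a2) {
    n <- length(a1)
    out <- character(n)
    # only a (T, N) heterozygote has gRNA, nuclease and a cuttable T
    het <- (a1 == "T" & a2 == "N") | (a1 == "N" & a2 == "T")
    if (any(het)) {
      conv <- sample_repair(sum(het), rep("N", sum(het)), kappa, alpha, beta)
      pick <- stats::runif(sum(het)) < 0.5
      out[het] <- ifelse(pick, conv, "N")
    }
    if (any(!het)) {
      pick <- stats::runif(sum(!het)) < 0.5
      out[!het] <- ifelse(pick, a1[!het], a2[!het])
    }
    out
  }
  draw_offspring <- function(m_a1, m_a2, f_a1, f_a2, n) {
    surv_m <- which(stats::runif(length(m_a1)) < fitness(m_a1, m_a2))
    surv_f <- which(stats::runif(length(f_a1)) < fitness(f_a1, f_a2))
    if (!length(surv_m) || !length(surv_f)) stop("oracle population collapsed")
    dads <- sample(surv_m, n, replace = TRUE)
    mums <- sample(surv_f, n, replace = TRUE)
    list(a1 = gametes_from(m_a1[dads], m_a2[dads]),
         a2 = gametes_from(f_a1[mums], f_a2[mums]))
  }
  # generation 1: release males, wild-type females
  n_rel <- round(n_ind * release)
  males <- list(a1 = c(rep("N", n_rel), rep("T", n_ind - n_rel)))
  males$a2 <- males$a1
  females <- list(a1 = rep("T", n_ind), a2 = rep("T", n_ind))
  freq_of <- function(m, f) {
    (sum(m$a1 == "N") + sum(m$a2 == "N") + sum(f$a1 == "N") + sum(f$a2 == "N")) /
      (2 * (length(m$a1) + length(f$a1)))
  }
  drive_freq <- numeric(generations)
  drive_freq[1] <- freq_of(males, females)
  for (t in 2:generations) {
    sons <- draw_offspring(males$a1, males$a2, females$a1, females$a2, n_ind)
    daughters <- draw_offspring(males$a1, males$a2, females$a1, females$a2, n_ind)
    males <- sons
    females <- daughters
    drive_freq[t] <- freq_of(males, females)
  }
  drive_freq
}
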