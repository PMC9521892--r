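#' Cut-and-repair parameters
#'
#' Germline cutting of an eligible wild-type `T` allele happens with
#' probability `kappa`; a cut is resolved by interhomolog HDR (fraction
#' `alpha`), a type-1 resistance mutation (fraction `mu = (1 - alpha) * beta`)
#' or a type-2 resistance mutation (fraction `nu = (1 - alpha) * (1 - beta)`),
#' so `alpha + mu + nu = 1` by construction. The embryonic
#' (maternal-deposition) stage has its own `kappa_dep`, `alpha_dep`,
#' `beta_dep`; early-embryo breaks are assumed not to undergo HDR, hence
#' `alpha_dep = 0` unless shadow drive is modelled. At a neutral locus every
#' resistance mutation is silently functional, so the type-1 fraction is
#' forced to 1 there regardless of `beta` (see [locus_spec()]).
#'
#' @param kappa germline cut probability per eligible `T` allele, in `[0, 1]`.
#' @param alpha germline HDR fraction of cuts.
#' @param beta type-1 fraction of non-HDR germline repair.
#' @param kappa_dep embryonic (deposition) cut probability; 0 disables
#'   deposition entirely.
#' @param alpha_dep embryonic HDR fraction (default 0: no HDR in the early
#'   embryo).
#' @param beta_dep type-1 fraction of non-HDR embryonic repair.
#' @param grna_deposition can maternal gRNAs be co-deposited with Cas9? Set
#'   `FALSE` to model deposition of the Cas9 protein alone.
#' @param shadow_drive when maternally deposited Cas9 pairs with a
#'   genomically expressed (typically paternally inherited) gRNA, use the
#'   germline HDR rate `alpha` for repair instead of `alpha_dep`;
#'   simultaneous co-deposition of that gRNA takes precedence and keeps
#'   `alpha_dep`.
#' @param tt_mode how a doubly wild-type (`TT`) locus is cut when eligible:
#'   `"no_hdr"` cuts each `T` independently with HDR disabled; `"sequential"`
#'   cuts the two alleles one after the other, the second repair using the
#'   first allele's post-repair state as HDR template (HDR from a still-`T`
#'   homolog regenerates `T`).
#' @return an object of class `repair_params` with derived fields `mu`, `nu`,
#'   `mu_dep`, `nu_dep`.
#' @export
repair_params <- function(kappa = 1, alpha = 0.95, beta = 0.1,
                          kappa_dep = 0, alpha_dep = 0, beta_dep = 0.1,
                          grna_deposition = TRUE, shadow_drive = FALSE,
                          tt_mode = c("no_hdr", "sequential")) {
  tt_mode <- match.arg(tt_mode)
  probs <- c(kappa, alpha, beta, kappa_dep, alpha_dep, beta_dep)
  if (any(probs < 0 | probs > 1)) stop("all rate parameters must lie in [0, 1]")
  structure(list(
    kappa = kappa, alpha = alpha, beta = beta,
    mu = (1 - alpha) * beta, nu = (1 - alpha) * (1 - beta),
    kappa_dep = kappa_dep, alpha_dep = alpha_dep, beta_dep = beta_dep,
    mu_dep = (1 - alpha_dep) * beta_dep, nu_dep = (1 - alpha_dep) * (1 - beta_dep),
    grna_deposition = isTRUE(grna_deposition),
    shadow_drive = isTRUE(shadow_drive), tt_mode = tt_mode
  ), class = "repair_params")
}

#' Fate of a single eligible T allele
#'
#' @param params a [repair_params()].
#' @param stage `"germline"` or `"embryo"` rates.
#' @return named numeric `(hdr, r1, r2, uncut)` =
#'   `(kappa * alpha, kappa * mu, kappa * nu, 1 - kappa)`; always sums to 1.
#' @examples
#' repair_split(repair_params())  # 0.95 0.005 0.045 0
#' @export
repair_split <- function(params, stage = c("germline", "embryo")) {
  stage <- match.arg(stage)
  k <- if (stage == "germline") params$kappa else params$kappa_dep
  a <- if (stage == "germline") params$alpha else params$alpha_dep
  b <- if (stage == "germline") params$beta else params$beta_dep
  c(hdr = k * a, r1 = k * (1 - a) * b, r2 = k * (1 - a) * (1 - b), uncut = 1 - k)
}

# outcome distribution for one locus pair under given effective rates.
# a1 <= a2 canonically; beta already locus-adjusted. Returns list(a1, a2, p)
# with canonical, aggregated pairs.
.pair_dist <- function(a1, a2, kappa, alpha, beta, tt_mode) {
  if (kappa == 0) return(list(a1 = a1, a2 = a2, p = 1))
  mu <- (1 - alpha) * beta
  nu <- (1 - alpha) * (1 - beta)
  if (a1 == "T" && a2 != "T") {
    out1 <- c(a2, "R1", "R2", "T")
    p <- c(kappa * alpha, kappa * mu, kappa * nu, 1 - kappa)
    keep <- p > 0
    return(.aggregate_pairs(out1[keep], rep(a2, sum(keep)), p[keep]))
  }
  if (a1 == "T" && a2 == "T") {
    if (tt_mode == "no_hdr") {
      # each T cut independently, HDR impossible
      states <- c("T", "R1", "R2")
      q <- c(1 - kappa, kappa * beta, kappa * (1 - beta))
      grid <- expand.grid(i = 1:3, j = 1:3)
      return(.aggregate_pairs(states[grid$i], states[grid$j], q[grid$i] * q[grid$j]))
    }
    # sequential: first allele, HDR template is the (still T) homolog
    first <- c(T = 1 - kappa + kappa * alpha, R1 = kappa * mu, R2 = kappa * nu)
    o1 <- character(); o2 <- character(); p <- numeric()
    for (s in names(first)) {
      # second allele: HDR template is the first allele's post-repair state
      second <- c(1 - kappa, kappa * alpha, kappa * mu, kappa * nu)
      names(second) <- c("T", s, "R1", "R2")
      second <- tapply(second, names(second), sum)
      o1 <- c(o1, rep(s, length(second)))
      o2 <- c(o2, names(second))
      p <- c(p, first[[s]] * as.numeric(second))
    }
    return(.aggregate_pairs(o1, o2, p))
  }
  # no cuttable T in this pair
  list(a1 = a1, a2 = a2, p = 1)
}

.aggregate_pairs <- function(x1, x2, p) {
  keep <- p > 0
  x1 <- x1[keep]; x2 <- x2[keep]; p <- p[keep]
  swap <- match(allele_class(x1), .allele_class_order) >
    match(allele_class(x2), .allele_class_order)
  tmp <- x1[swap]; x1[swap] <- x2[swap]; x2[swap] <- tmp
  key <- paste(x1, x2, sep = "/")
  agg <- tapply(p, key, sum)
  parts <- strsplit(names(agg), "/", fixed = TRUE)
  list(a1 = vapply(parts, `[`, character(1), 1L),
       a2 = vapply(parts, `[`, character(1), 2L),
       p = as.numeric(agg))
}

# effective (kappa, alpha, beta) for one locus at one stage; `shadow` marks
# the shadow-drive combination (deposited Cas9 + genomic gRNA, not
# co-deposited) which borrows the germline HDR rate.
.locus_rates <- function(params, locus, stage, shadow = FALSE) {
  r1_only <- locus$resistance == "r1_only"
  if (stage == "germline") {
    list(kappa = params$kappa, alpha = params$alpha,
         beta = if (r1_only) 1 else params$beta)
  } else {
    list(kappa = params$kappa_dep,
         alpha = if (shadow) params$alpha else params$alpha_dep,
         beta = if (r1_only) 1 else params$beta_dep)
  }
}

#' Is a genotype eligible for cutting at a locus?
#'
#' Cutting at a locus requires three things in the same individual: a gRNA
#' targeting that locus, at least one `T` allele there, and a nuclease. In
#' the germline both the gRNA and the nuclease must be genomically encoded;
#' in the embryo they come from maternal deposition -- either the
#' co-deposited Cas9:gRNA complex, or deposited Cas9 protein paired with a
#' gRNA genomically expressed in the zygote itself.
#'
#' @param g a [genotype()].
#' @param locus locus label.
#' @param stage `"germline"` or `"embryo"`.
#' @param design the [drive_design()] the genotype belongs to.
#' @param params a [repair_params()] (its `grna_deposition` flag is honoured
#'   at the embryo stage).
#' @return logical scalar.
#' @export
cut_eligible <- function(g, locus, stage = c("germline", "embryo"),
                         design, params = repair_params()) {
  stage <- match.arg(stage)
  stopifnot(inherits(g, "drive_genotype"))
  lspec <- design$loci[[locus]]
  if (is.null(lspec) || !lspec$cuttable) return(FALSE)
  alleles <- unlist(g$pairs, use.names = FALSE)
  if (sum(g$pairs[[locus]] == "T") < 1L) return(FALSE)
  if (stage == "germline") {
    has_grna <- any(allele_target(alleles) == locus, na.rm = TRUE)
    has_nuc <- any(allele_class(alleles) == "N")
    return(has_grna && has_nuc)
  }
  if (g$cas9_maternal != 1L) return(FALSE)
  deposited <- params$grna_deposition &&
    grna_set_contains(g$grnas_maternal, locus)
  genomic <- any(allele_target(alleles) == locus, na.rm = TRUE)
  deposited || genomic
}

# vectorised eligibility over a state space (d0 x loci logical matrix).
# For the embryo stage `tag` selects the deposition-tag row.
.eligible_matrix <- function(space, params, stage, tag = 1L) {
  loci <- space$loci
  design <- space$design
  el <- matrix(FALSE, space$d0, length(loci), dimnames = list(NULL, loci))
  shadow <- el
  for (l in loci) {
    if (!design$loci[[l]]$cuttable) next
    hasT <- space$nT[, l] >= 1L
    if (stage == "germline") {
      el[, l] <- hasT & space$genomic_grna[, l] & space$has_N
    } else {
      tg <- space$gtags[tag, ]
      if (tg$cas9_mat != 1L) next
      deposited <- params$grna_deposition && grna_set_contains(tg$grnas, l)
      genomic <- space$genomic_grna[, l]
      el[, l] <- hasT & (deposited | genomic)
      if (params$shadow_drive && !deposited) shadow[el[, l], l] <- TRUE
    }
  }
  list(eligible = el, shadow = shadow)
}

# distribution over diploid genotype indices reachable from genotype row i
# via cutting at the eligible loci (independent across loci).
# Returns list(j = target geno indices, p = probabilities).
.geno_row <- function(space, params, stage, i, eligible, shadow) {
  loci <- space$loci
  el <- which(eligible[i, ])
  if (!length(el)) return(list(j = i, p = 1))
  dists <- lapply(el, function(k) {
    l <- loci[k]
    rates <- .locus_rates(params, space$design$loci[[l]], stage,
                          shadow = shadow[i, k])
    dd <- .pair_dist(space$geno_a1[i, l], space$geno_a2[i, l],
                     rates$kappa, rates$alpha, rates$beta, params$tt_mode)
    idx <- space$pairmap[[l]][paste(dd$a1, dd$a2, sep = "/")]
    if (anyNA(idx)) stop("cut outcome leaves the enumerated state space at locus ", l)
    list(idx = as.integer(idx), p = dd$p)
  })
  combo <- expand.grid(lapply(dists, function(dd) seq_along(dd$p)),
                       KEEP.OUT.ATTRS = FALSE)
  p <- rep(1, nrow(combo))
  base <- space$geno_pair_idx[i, ]
  delta <- integer(nrow(combo))
  for (m in seq_along(el)) {
    dd <- dists[[m]]
    sel <- combo[[m]]
    p <- p * dd$p[sel]
    delta <- delta + (dd$idx[sel] - base[el[m]]) * space$geno_stride[el[m]]
  }
  list(j = as.integer(i + delta), p = p)
}

#' Germline conversion distribution of one genotype
#'
#' For each cuttable locus where the genotype genomically expresses a gRNA
#' targeting it, carries at least one `T` allele there, and carries a
#' nuclease, every `T` allele is cut with probability `kappa` and repaired to
#' the homologous allele (HDR), `R1`, or `R2`; loci convert independently.
#' Non-eligible genotypes map to themselves with probability 1.
#'
#' @param g a [genotype()].
#' @param design a [drive_design()].
#' @param params a [repair_params()].
#' @return named numeric vector: probabilities over reachable canonical
#'   genotype keys (deposition tag unchanged); sums to 1.
#' @examples
#' g <- genotype(A = c("T", "N^A"))
#' germline_row(g, drive_preset("spd"), repair_params())
#' @export
germline_row <- function(g, design, params = repair_params()) {
  .single_row(g, design, params, stage = "germline")
}

#' Embryonic (deposition) conversion distribution of one genotype
#'
#' As [germline_row()], but cut eligibility comes from the maternal
#' deposition tag (deposited Cas9, plus either a co-deposited gRNA or a
#' genomically expressed one) and the `*_dep` rates apply. Under
#' `shadow_drive = TRUE` the deposited-Cas9 + genomic-gRNA combination
#' borrows the germline HDR rate; co-deposition takes precedence.
#'
#' @inheritParams germline_row
#' @return named numeric vector over canonical genotype keys; sums to 1.
#' @export
deposition_row <- function(g, design, params = repair_params()) {
  .single_row(g, design, params, stage = "embryo")
}

.single_row <- function(g, design, params, stage) {
  space <- enumerate_states(design,
                            deposition = g$cas9_maternal == 1L ||
                              g$cas9_paternal == 1L || nzchar(g$grnas_maternal))
  at <- resolve_genotype(space, g)
  em <- .eligible_matrix(space, params, stage, tag = at[["tag"]])
  row <- .geno_row(space, params, stage, at[["geno"]], em$eligible, em$shadow)
  keys <- vapply(row$j, function(j) {
    canonical_key(genotype_from_index(space, j, at[["tag"]]))
  }, character(1))
  out <- stats::setNames(row$p, keys)
  if (abs(sum(out) - 1) > 1e-12) stop("conversion row does not sum to 1")
  out
}

#' Build a germline or embryonic conversion matrix over a state space
#'
#' The germline matrix C applies the genomic cut/repair rules to every
#' diploid state; it is block-diagonal over deposition tags (expression in
#' the germline neither reads nor writes the tag). The embryonic matrix K
#' applies the deposition rules, which depend on the maternal components of
#' each state's tag.
#'
#' @param space a [enumerate_states()] result.
#' @param params a [repair_params()].
#' @param stage `"germline"` (C) or `"embryo"` (K).
#' @return a sparse row-stochastic `space$d` x `space$d` matrix
#'   ([Matrix::sparseMatrix()]).
#' @export
conversion_matrix <- function(space, params, stage = c("germline", "embryo")) {
  stage <- match.arg(stage)
  d0 <- space$d0
  if (stage == "germline") {
    em <- .eligible_matrix(space, params, "germline")
    block <- .conversion_block(space, params, "germline", em)
    mat <- Matrix::kronecker(Matrix::Diagonal(space$nt), block)
  } else {
    blocks <- vector("list", space$nt)
    for (t in seq_len(space$nt)) {
      if (space$gtags$cas9_mat[t] != 1L || params$kappa_dep == 0) {
        blocks[[t]] <- Matrix::Diagonal(d0)
      } else {
        em <- .eligible_matrix(space, params, "embryo", tag = t)
        blocks[[t]] <- .conversion_block(space, params, "embryo", em)
      }
    }
    mat <- Matrix::bdiag(blocks)
  }
  mat <- methods::as(mat, "CsparseMatrix")
  rs <- Matrix::rowSums(mat)
  if (any(abs(rs - 1) > 1e-12)) stop("conversion matrix rows do not sum to 1")
  mat
}

.conversion_block <- function(space, params, stage, em) {
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (i in seq_len(space$d0)) {
    row <- .geno_row(space, params, stage, i, em$eligible, em$shadow)
    ii <- c(ii, rep.int(i, length(row$j)))
    jj <- c(jj, row$j)
    xx <- c(xx, row$p)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(space$d0, space$d0))
}
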