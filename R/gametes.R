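#' Gamete distribution of a diploid genotype
#'
#' Unlinked loci segregate independently: each locus contributes either
#' allele with probability 1/2 (or its single allele if homozygous), and the
#' per-locus choices multiply. Every gamete of a nuclease-carrying parent is
#' tagged with Cas9 deposition marker 1; if the parent also genomically
#' expresses gRNAs, their target labels are recorded as co-deposited with the
#' Cas9 -- even when the gRNA-carrying element itself is not inherited. A
#' gRNA expressed in a parent without a nuclease is never deposited (no
#' complex to ride in) and is not flagged. Markers only annotate gametes;
#' they never alter segregation probabilities.
#'
#' @param g a [genotype()] (its own deposition tag is irrelevant here: gamete
#'   markers derive from the parent's genotype).
#' @param design a [drive_design()].
#' @param params a [repair_params()]; with `grna_deposition = FALSE` gametes
#'   carry no gRNA flags.
#' @param parent_sex informational only -- segregation and marker bookkeeping
#'   are identical for both sexes; the zygote combines the father's marker
#'   with the mother's marker and gRNA set.
#' @return data.frame with columns `haplotype` (alleles joined by `|` in
#'   locus order), `cas9` (0/1), `grnas` (comma-joined locus labels) and
#'   `prob`; probabilities sum to 1.
#' @examples
#' gametes_from_diploid(genotype(A = c("T", "N^A")), drive_preset("spd"))
#' @export
gametes_from_diploid <- function(g, design, params = repair_params(),
                                 parent_sex = c("female", "male")) {
  parent_sex <- match.arg(parent_sex)
  loci <- design_loci(design)
  alleles <- unlist(g$pairs, use.names = FALSE)
  cas9 <- as.integer(any(allele_class(alleles) == "N"))
  grnas <- ""
  if (cas9 == 1L && params$grna_deposition) {
    tg <- allele_target(alleles)
    grnas <- normalize_grna_set(tg[!is.na(tg)])
  }
  per_locus <- lapply(loci, function(l) {
    a <- g$pairs[[l]]
    if (a[1] == a[2]) list(allele = a[1], p = 1)
    else list(allele = a, p = c(0.5, 0.5))
  })
  combo <- expand.grid(lapply(per_locus, function(x) seq_along(x$p)),
                       KEEP.OUT.ATTRS = FALSE)
  hap <- vapply(seq_len(nrow(combo)), function(r) {
    paste(vapply(seq_along(loci), function(k) {
      per_locus[[k]]$allele[combo[r, k]]
    }, character(1)), collapse = "|")
  }, character(1))
  p <- rep(1, nrow(combo))
  for (k in seq_along(loci)) p <- p * per_locus[[k]]$p[combo[, k]]
  agg <- tapply(p, hap, sum)
  data.frame(haplotype = names(agg), cas9 = cas9, grnas = grnas,
             prob = as.numeric(agg), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Meiosis matrix H over a state space
#'
#' Row-stochastic `space$d` x `space$h` matrix mapping each diploid adult
#' state to its gamete (haploid state) distribution, including the deposition
#' markers assigned by [gametes_from_diploid()]. Identical for both sexes;
#' the sexes differ only in how the zygote interprets the markers.
#'
#' @param space a [enumerate_states()] result.
#' @param params a [repair_params()] (`grna_deposition` controls gRNA flags).
#' @return sparse matrix ([Matrix::sparseMatrix()]).
#' @export
gamete_matrix <- function(space, params = repair_params()) {
  loci <- space$loci
  d0 <- space$d0; h0 <- space$h0
  # per-genotype gamete tag
  gtag_cas9 <- as.integer(space$has_N)
  gtag_grnas <- character(d0)
  if (params$grna_deposition) {
    for (i in seq_len(d0)) {
      if (gtag_cas9[i] == 1L) {
        gtag_grnas[i] <- normalize_grna_set(loci[space$genomic_grna[i, ]])
      }
    }
  }
  if (!space$deposition) {
    gtag_cas9[] <- 0L
    gtag_grnas[] <- ""
  }
  ptag <- ptag_index(space, gtag_cas9, gtag_grnas)

  ii <- integer(); jj <- integer(); xx <- numeric()
  for (i in seq_len(d0)) {
    opts <- lapply(loci, function(l) {
      a1 <- space$geno_a1[i, l]; a2 <- space$geno_a2[i, l]
      if (a1 == a2) list(idx = match(a1, space$alleles[[l]]), p = 1)
      else list(idx = match(c(a1, a2), space$alleles[[l]]), p = c(0.5, 0.5))
    })
    combo <- expand.grid(lapply(opts, function(x) seq_along(x$p)),
                         KEEP.OUT.ATTRS = FALSE)
    hidx <- rep(1L, nrow(combo))
    p <- rep(1, nrow(combo))
    for (k in seq_along(loci)) {
      o <- opts[[k]]
      hidx <- hidx + (o$idx[combo[, k]] - 1L) * space$hap_stride[k]
      p <- p * o$p[combo[, k]]
    }
    jfull <- hap_state_index(space, as.integer(hidx), ptag[i])
    ii <- c(ii, rep.int(i, length(jfull)))
    jj <- c(jj, jfull)
    xx <- c(xx, p)
  }
  # rows are identical for every deposition tag of the same genotype
  nt <- space$nt
  H <- Matrix::sparseMatrix(
    i = rep(ii, nt) + rep((seq_len(nt) - 1L) * d0, each = length(ii)),
    j = rep(jj, nt), x = rep(xx, nt),
    dims = c(space$d, space$h)
  )
  rs <- Matrix::rowSums(H)
  if (any(abs(rs - 1) > 1e-12)) stop("gamete matrix rows do not sum to 1")
  H
}

# h x h integer matrix: entry [i, j] is the diploid state formed by father
# gamete i and mother gamete j (paternal marker from i; maternal marker and
# gRNA set from j).
zygote_index_map <- function(space) {
  h0 <- space$h0; np <- space$np; loci <- space$loci
  geno_part <- matrix(0L, h0, h0)
  for (i in seq_len(h0)) {
    for (j in seq_len(h0)) {
      pair_idx <- vapply(loci, function(l) {
        a <- sort_alleles(c(space$hap[i, l], space$hap[j, l]))
        unname(space$pairmap[[l]][paste(a[1], a[2], sep = "/")])
      }, integer(1))
      geno_part[i, j] <- geno_index_from_pairs(space, pair_idx)
    }
  }
  tag_part <- matrix(0L, np, np)
  for (pi in seq_len(np)) {
    for (pj in seq_len(np)) {
      tag_part[pi, pj] <- tag_index(space, space$ptags$cas9[pi],
                                    space$ptags$cas9[pj], space$ptags$grnas[pj])
    }
  }
  zmap <- matrix(0L, space$h, space$h)
  for (pi in seq_len(np)) {
    for (pj in seq_len(np)) {
      rows <- (pi - 1L) * h0 + seq_len(h0)
      cols <- (pj - 1L) * h0 + seq_len(h0)
      zmap[rows, cols] <- (tag_part[pi, pj] - 1L) * space$d0 + geno_part
    }
  }
  zmap
}
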