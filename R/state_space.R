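#' Admissible alleles at one locus of a design
#'
#' Returns, in canonical order, the wild-type target `T`, the admissible
#' resistance classes (none at a never-cut locus; `R1` only at a neutral
#' locus; `R1` and `R2` where both arise), and the locus's drive allele.
#'
#' @param locus a locus label (looked up in `design`) or a [locus_spec()].
#' @param design a [drive_design()]; required when `locus` is a label.
#' @return character vector of allele strings.
#' @examples
#' d <- drive_preset("direct_dcd")
#' enumerate_alleles("A", d)  # "T" "R1" "R2" "E"
#' enumerate_alleles("C", d)  # "T" "G^B"
#' @export
enumerate_alleles <- function(locus, design = NULL) {
  if (is.character(locus)) {
    if (is.null(design)) stop("design required when locus is given as a label")
    if (!locus %in% design_loci(design)) stop("unknown locus label: ", locus)
    locus <- design$loci[[locus]]
  }
  alleles <- "T"
  if (locus$cuttable) {
    alleles <- c(alleles, "R1", if (locus$resistance == "both") "R2")
  }
  sort_alleles(c(alleles, locus$drive_allele))
}

# all subsets of a character vector, as comma-joined strings ("" = empty set)
.subsets <- function(x) {
  if (!length(x)) return("")
  out <- ""
  for (el in x) out <- c(out, paste0(out, ifelse(nzchar(out), ",", ""), el))
  sort(unique(out))
}

grna_set_contains <- function(set_string, label) {
  vapply(strsplit(set_string, ",", fixed = TRUE),
         function(s) label %in% s, logical(1))
}

#' Enumerate the diploid and haploid state space of a design
#'
#' Builds the canonical, deterministically ordered index of every diploid
#' genotype (per-locus unordered allele pairs) and haploid genome the
#' recursion can visit, together with their parental-deposition tags.
#'
#' A deposition tag records, for a diploid individual, whether its father and
#' mother carried a nuclease allele (Cas9 deposition markers, 0/1) and which
#' gRNAs were co-deposited by the mother (a gRNA is deposited only in complex
#' with Cas9, so a nonempty maternal gRNA set implies the maternal Cas9
#' marker is 1). Two states that differ only by swapping the parental origin
#' of the two haplotypes are identical when their tags coincide and distinct
#' otherwise. With `deposition = FALSE` all tags collapse to the single null
#' tag and the diploid count reduces to the product over loci of
#' n(n+1)/2 for per-locus allele count n.
#'
#' @param design a [drive_design()].
#' @param deposition enumerate parental-deposition tags? Enable for any
#'   simulation with a nonzero embryonic (deposition) cut-rate.
#' @return an object of class `state_space`; `x$d` and `x$h` give the diploid
#'   and haploid state counts.
#' @examples
#' nrow_states <- enumerate_states(drive_preset("spd"))$d        # 10
#' enumerate_states(drive_preset("direct_dcd"))$d                # 180
#' @export
enumerate_states <- function(design, deposition = FALSE) {
  loci <- design_loci(design)
  alleles <- lapply(loci, enumerate_alleles, design = design)
  names(alleles) <- loci
  L <- length(loci)

  # per-locus unordered pairs, canonical order (a1 <= a2)
  pairs <- lapply(alleles, function(a) {
    n <- length(a)
    i <- rep(seq_len(n), times = n)
    j <- rep(seq_len(n), each = n)
    keep <- i <= j
    list(a1 = a[i[keep]], a2 = a[j[keep]], n = sum(keep))
  })
  npair <- vapply(pairs, `[[`, integer(1), "n")

  # diploid genotypes: cross-product of per-locus pairs, first locus fastest
  grid <- do.call(expand.grid, c(lapply(npair, seq_len),
                                 list(KEEP.OUT.ATTRS = FALSE)))
  d0 <- nrow(grid)
  geno_a1 <- matrix("", d0, L, dimnames = list(NULL, loci))
  geno_a2 <- geno_a1
  for (k in seq_len(L)) {
    geno_a1[, k] <- pairs[[k]]$a1[grid[[k]]]
    geno_a2[, k] <- pairs[[k]]$a2[grid[[k]]]
  }
  geno_stride <- cumprod(c(1L, npair[-L]))
  names(geno_stride) <- loci
  geno_pair_idx <- as.matrix(grid)
  colnames(geno_pair_idx) <- loci
  pairmap <- lapply(pairs, function(p) {
    stats::setNames(seq_len(p$n), paste(p$a1, p$a2, sep = "/"))
  })

  # haploid genomes: cross-product of per-locus alleles
  nall <- vapply(alleles, length, integer(1))
  hgrid <- do.call(expand.grid, c(lapply(nall, seq_len),
                                  list(KEEP.OUT.ATTRS = FALSE)))
  h0 <- nrow(hgrid)
  hap <- matrix("", h0, L, dimnames = list(NULL, loci))
  for (k in seq_len(L)) hap[, k] <- alleles[[k]][hgrid[[k]]]
  hap_stride <- cumprod(c(1L, nall[-L]))
  names(hap_stride) <- loci

  # deposition tags
  gtargets <- grna_targets(design)
  if (deposition) {
    subsets <- .subsets(gtargets)
    ptags <- rbind(
      data.frame(cas9 = 0L, grnas = "", stringsAsFactors = FALSE),
      data.frame(cas9 = 1L, grnas = subsets, stringsAsFactors = FALSE)
    )
    gtags <- data.frame(
      cas9_pat = rep(0:1, each = nrow(ptags)),
      cas9_mat = rep(ptags$cas9, 2L),
      grnas    = rep(ptags$grnas, 2L),
      stringsAsFactors = FALSE
    )
    # put the null tag (0, 0, empty) first for readability
    ord <- order(gtags$cas9_pat, gtags$cas9_mat, gtags$grnas)
    gtags <- gtags[ord, , drop = FALSE]
    rownames(gtags) <- NULL
  } else {
    ptags <- data.frame(cas9 = 0L, grnas = "", stringsAsFactors = FALSE)
    gtags <- data.frame(cas9_pat = 0L, cas9_mat = 0L, grnas = "",
                        stringsAsFactors = FALSE)
  }
  np <- nrow(ptags)
  nt <- nrow(gtags)

  # per-genotype properties used by eligibility and metrics
  nT <- (geno_a1 == "T") + (geno_a2 == "T")
  cls1 <- matrix(allele_class(geno_a1), d0, L)
  cls2 <- matrix(allele_class(geno_a2), d0, L)
  has_N <- rowSums(cls1 == "N") + rowSums(cls2 == "N") > 0
  # genomic gRNA targeting locus l present anywhere in the genotype?
  tg1 <- matrix(allele_target(geno_a1), d0, L)
  tg2 <- matrix(allele_target(geno_a2), d0, L)
  genomic_grna <- matrix(FALSE, d0, length(loci), dimnames = list(NULL, loci))
  for (l in loci) {
    genomic_grna[, l] <- rowSums(tg1 == l, na.rm = TRUE) +
      rowSums(tg2 == l, na.rm = TRUE) > 0
  }
  drive_at <- matrix(FALSE, d0, L, dimnames = list(NULL, loci))
  for (k in seq_len(L)) {
    da <- design$loci[[k]]$drive_allele
    drive_at[, k] <- geno_a1[, k] == da | geno_a2[, k] == da
  }

  geno_key <- apply_key(loci, geno_a1, geno_a2)
  hap_key <- apply(hap, 1L, paste, collapse = "|")

  structure(list(
    design = design, deposition = deposition,
    loci = loci, alleles = alleles,
    pairs = pairs, npair = npair, geno_stride = geno_stride,
    geno_pair_idx = geno_pair_idx, pairmap = pairmap,
    d0 = d0, geno_a1 = geno_a1, geno_a2 = geno_a2, geno_key = geno_key,
    nall = nall, hap_stride = hap_stride, h0 = h0, hap = hap,
    hap_key = hap_key,
    ptags = ptags, gtags = gtags, np = np, nt = nt,
    d = d0 * nt, h = h0 * np,
    nT = nT, has_N = has_N, genomic_grna = genomic_grna, drive_at = drive_at
  ), class = "state_space")
}

apply_key <- function(loci, a1, a2) {
  key <- character(nrow(a1))
  for (k in seq_along(loci)) {
    piece <- paste0(loci[k], ":", a1[, k], "/", a2[, k])
    key <- if (k == 1L) piece else paste(key, piece, sep = "|")
  }
  key
}

#' @export
print.state_space <- function(x, ...) {
  cat("<state_space>", x$design$name,
      sprintf("- %d diploid states (%d genotypes x %d tags), %d haploid states\n",
              x$d, x$d0, x$nt, x$h))
  invisible(x)
}

# per-locus pair index (allele strings must be canonical-sorted a1 <= a2)
pair_index <- function(space, locus, a1, a2) {
  p <- space$pairs[[locus]]
  idx <- match(paste(a1, a2, sep = "/"), paste(p$a1, p$a2, sep = "/"))
  if (anyNA(idx)) stop("unknown allele pair at locus ", locus)
  idx
}

# diploid genotype index from per-locus pair indices (matrix or vector)
geno_index_from_pairs <- function(space, pair_idx) {
  if (is.null(dim(pair_idx))) pair_idx <- matrix(pair_idx, nrow = 1L)
  as.integer(1L + pair_idx %*% cbind(space$geno_stride) - sum(space$geno_stride))
}

# full diploid state index
state_index <- function(space, geno, tag) (tag - 1L) * space$d0 + geno

# full haploid state index
hap_state_index <- function(space, hapgeno, ptag) (ptag - 1L) * space$h0 + hapgeno

# tag index from components
tag_index <- function(space, cas9_pat, cas9_mat, grnas) {
  grnas <- normalize_grna_set(grnas)
  idx <- match(paste(cas9_pat, cas9_mat, grnas),
               paste(space$gtags$cas9_pat, space$gtags$cas9_mat, space$gtags$grnas))
  if (anyNA(idx)) stop("deposition tag outside the enumerated space")
  idx
}

ptag_index <- function(space, cas9, grnas) {
  grnas <- normalize_grna_set(grnas, each = length(grnas) > 1L)
  idx <- match(paste(cas9, grnas), paste(space$ptags$cas9, space$ptags$grnas))
  if (anyNA(idx)) stop("gamete deposition tag outside the enumerated space")
  idx
}

normalize_grna_set <- function(grnas, each = FALSE) {
  if (each) return(vapply(grnas, normalize_grna_set, character(1), USE.NAMES = FALSE))
  if (length(grnas) == 0L) return("")
  if (length(grnas) == 1L && grepl(",", grnas, fixed = TRUE)) {
    grnas <- strsplit(grnas, ",", fixed = TRUE)[[1]]
  }
  grnas <- grnas[nzchar(grnas)]
  if (!length(grnas)) return("")
  paste(sort(unique(grnas)), collapse = ",")
}

#' Construct a diploid genotype with a deposition tag
#'
#' Convenience constructor for the user-facing single-genotype operations
#' ([canonical_key()], [germline_row()], [deposition_row()],
#' [genotype_fitness()], [gametes_from_diploid()]). Per-locus allele pairs
#' are given as named length-2 character vectors; order within a pair is
#' irrelevant.
#'
#' @param ... named per-locus allele pairs, e.g. `A = c("T", "N^A")`.
#' @param cas9_paternal,cas9_maternal parental Cas9 deposition markers (0/1).
#' @param grnas_maternal character vector of locus labels whose gRNAs were
#'   co-deposited by the mother; nonempty requires `cas9_maternal = 1`.
#' @return an object of class `drive_genotype`.
#' @export
genotype <- function(..., cas9_paternal = 0L, cas9_maternal = 0L,
                     grnas_maternal = character()) {
  pairs <- list(...)
  if (is.null(names(pairs)) || any(!nzchar(names(pairs)))) {
    stop("per-locus pairs must be named by locus label")
  }
  if (!all(lengths(pairs) == 2L)) stop("each locus needs exactly two alleles")
  grnas <- normalize_grna_set(grnas_maternal)
  if (nzchar(grnas) && cas9_maternal != 1L) {
    stop("a deposited gRNA requires maternal Cas9 (cas9_maternal = 1)")
  }
  structure(list(pairs = pairs, cas9_paternal = as.integer(cas9_paternal),
                 cas9_maternal = as.integer(cas9_maternal), grnas_maternal = grnas),
            class = "drive_genotype")
}

#' Canonical key of a diploid genotype
#'
#' Two genotype states receive equal keys exactly when they are functionally
#' equivalent: within each locus the allele pair is unordered, and the
#' parental deposition tags are attached to parents, not to haplotypes -- so
#' a state with paternal marker 1 / maternal marker 0 differs from its mirror
#' with markers 0 / 1, while the doubly marked (or unmarked) mirrors
#' coincide.
#'
#' @param g a [genotype()].
#' @return a single character key; idempotent and order-insensitive within
#'   each locus.
#' @export
canonical_key <- function(g) {
  stopifnot(inherits(g, "drive_genotype"))
  sorted <- lapply(g$pairs, sort_alleles)
  loci <- names(sorted)
  a1 <- matrix(vapply(sorted, `[`, character(1), 1L), 1L)
  a2 <- matrix(vapply(sorted, `[`, character(1), 2L), 1L)
  paste0(apply_key(loci, a1, a2), "}",
         g$cas9_paternal, g$cas9_maternal,
         ifelse(nzchar(g$grnas_maternal), paste0("+", g$grnas_maternal), ""))
}

# resolve a drive_genotype to (geno index, tag index) in a state space
resolve_genotype <- function(space, g) {
  stopifnot(inherits(g, "drive_genotype"))
  loci <- space$loci
  if (!setequal(names(g$pairs), loci)) {
    stop("genotype loci do not match the design: expected ",
         paste(loci, collapse = ", "))
  }
  pair_idx <- vapply(loci, function(l) {
    a <- sort_alleles(g$pairs[[l]])
    pair_index(space, l, a[1], a[2])
  }, integer(1))
  geno <- geno_index_from_pairs(space, pair_idx)
  tag <- tag_index(space, g$cas9_paternal, g$cas9_maternal, g$grnas_maternal)
  c(geno = geno, tag = tag)
}

# drive_genotype from (geno, tag) indices
genotype_from_index <- function(space, geno, tag = 1L) {
  pairs <- lapply(space$loci, function(l) {
    c(space$geno_a1[geno, l], space$geno_a2[geno, l])
  })
  names(pairs) <- space$loci
  tg <- space$gtags[tag, ]
  do.call(genotype, c(pairs, list(
    cas9_paternal = tg$cas9_pat, cas9_maternal = tg$cas9_mat,
    grnas_maternal = tg$grnas)))
}

# printable label in the field's nomenclature, e.g. "ET/N^AT/G^BT}_01"
state_label <- function(space, geno, tag = 1L) {
  loci <- space$loci
  body <- vapply(seq_along(loci), function(k) {
    paste0("_", loci[k], "_", space$geno_a1[geno, loci[k]],
           space$geno_a2[geno, loci[k]])
  }, character(1))
  tg <- space$gtags[tag, ]
  paste0(paste(body, collapse = "/"), "}_", tg$cas9_pat, tg$cas9_mat,
         ifelse(nzchar(tg$grnas), paste0("+", tg$grnas), ""))
}

#' Dump the state index as a table
#'
#' One row per enumerated diploid state with its index and genotype string in
#' the field's nomenclature; intended for debugging and regression
#' inspection. Write with [utils::write.table()] for a plain TSV.
#'
#' @param space a [enumerate_states()] result.
#' @return data.frame with columns `index` and `genotype`.
#' @export
state_table <- function(space) {
  idx <- seq_len(space$d)
  tag <- (idx - 1L) %/% space$d0 + 1L
  geno <- (idx - 1L) %% space$d0 + 1L
  data.frame(
    index = idx,
    genotype = vapply(idx, function(i) state_label(space, geno[i], tag[i]),
                      character(1)),
    stringsAsFactors = FALSE
  )
}
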