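#' Declare one locus of a drive design
#'
#' A locus carries a wild-type target allele `T`, exactly one drive allele,
#' and (if cuttable) the resistance alleles that loss-of-function repair can
#' generate there. At a haplolethal or otherwise functional target gene both
#' resistance classes arise (`resistance = "both"`, split by the type-1
#' fraction beta); at a neutral insertion site every resistance mutation is
#' functionally silent and is classed type-1 (`resistance = "r1_only"`). A
#' locus that no gRNA can cut (`cuttable = FALSE`) admits no resistance
#' alleles at all.
#'
#' @param label single-letter locus label ("A", "B", ...); chain order is
#'   label order.
#' @param drive_allele the drive allele residing at this locus: `"E"`, `"N"`,
#'   or a gRNA-carrying `"G^X"` / `"N^X"` string.
#' @param cuttable can a gRNA:Cas9 complex cut the `T` allele at this locus?
#' @param resistance `"both"` (type-1 and type-2 per the beta split) or
#'   `"r1_only"` (all loss-of-function repair yields type-1, as at neutral
#'   loci).
#' @return an object of class `locus_spec`.
#' @export
locus_spec <- function(label, drive_allele, cuttable = TRUE,
                       resistance = c("both", "r1_only")) {
  resistance <- match.arg(resistance)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  cls <- allele_class(drive_allele)
  if (!cls %in% c("E", "G", "N")) {
    stop("drive_allele must be an E, G or N allele, got: ", drive_allele)
  }
  if (cls %in% c("G") && is.na(allele_target(drive_allele))) {
    stop("a G allele must carry a gRNA target annotation, e.g. \"G^A\"")
  }
  structure(
    list(label = label, drive_allele = drive_allele,
         cuttable = cuttable, resistance = resistance),
    class = "locus_spec"
  )
}

#' Assemble a drive design from locus specifications
#'
#' A design is an ordered list of loci, each holding one drive allele; gRNA
#' annotations on the drive alleles define which loci can be cut by whom.
#' Structurally impossible designs (a gRNA targeting an unknown locus, or a
#' resistance-admitting locus that is flagged never-cut) are errors;
#' chain-shape oddities are reported by [validate_design()] as warnings only.
#'
#' @param ... [locus_spec()] objects, in chain order.
#' @param name optional design name.
#' @return an object of class `drive_design` with elements `loci` (named list
#'   of locus specs) and `name`.
#' @examples
#' # the classic three-element direct daisy chain
#' drive_design(
#'   locus_spec("A", "E"),
#'   locus_spec("B", "N^A", resistance = "r1_only"),
#'   locus_spec("C", "G^B", cuttable = FALSE),
#'   name = "direct_dcd"
#' )
#' @export
drive_design <- function(..., name = "custom") {
  loci <- list(...)
  if (length(loci) == 1L && is.list(loci[[1]]) && !inherits(loci[[1]], "locus_spec")) {
    loci <- loci[[1]]
  }
  if (!all(vapply(loci, inherits, logical(1), "locus_spec"))) {
    stop("all arguments must be locus_spec objects")
  }
  labels <- vapply(loci, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate locus labels")
  names(loci) <- labels
  design <- structure(list(loci = loci, name = name), class = "drive_design")
  tgt <- grna_targets(design)
  unknown <- setdiff(tgt, labels)
  if (length(unknown)) {
    stop("gRNA targets unknown locus: ", paste(unknown, collapse = ", "))
  }
  uncut <- tgt[!vapply(loci[tgt], `[[`, logical(1), "cuttable")]
  if (length(uncut)) {
    stop("gRNA targets a locus declared never-cut: ", paste(uncut, collapse = ", "))
  }
  design
}

#' @export
print.drive_design <- function(x, ...) {
  cat("<drive_design>", x$name, "\n")
  for (l in x$loci) {
    cat(sprintf("  %s: drive %-4s cuttable=%s resistance=%s\n",
                l$label, l$drive_allele, l$cuttable, l$resistance))
  }
  invisible(x)
}

# locus labels in chain order
design_loci <- function(design) names(design$loci)

# all gRNA target labels present on any drive allele of the design
grna_targets <- function(design) {
  tg <- allele_target(vapply(design$loci, `[[`, character(1), "drive_allele"))
  sort(unique(tg[!is.na(tg)]))
}

#' Drive architecture presets
#'
#' The five named architectures (listed with their heterozygous genotype):
#' \describe{
#'   \item{`spd`}{self-perpetuating drive, `A: N^A T` -- nuclease and gRNA on
#'     one element that biases itself.}
#'   \item{`split`}{split drive, `A: G^A T / B: N T` -- the biased locus
#'     carries its own gRNA, the unlinked nuclease locus is never biased.}
#'   \item{`noble_dcd`}{`A: E T / B: N^A T / C: N^B T` -- daisy chain with a
#'     nuclease on both the B and C elements.}
#'   \item{`direct_dcd`}{`A: E T / B: N^A T / C: G^B T` -- the A-targeting
#'     gRNA rides on the nuclease element B, so an isolated B element can
#'     still cut locus A ("phantom cutting").}
#'   \item{`indirect_dcd`}{`A: G^A T / B: N T / C: G^B T` -- the A-targeting
#'     gRNA rides on A itself, so cutting at A requires both A and B
#'     elements; phantom cutting at A is impossible.}
#' }
#' In every preset the A locus is a haplolethal target gene (both resistance
#' classes arise; type-2 is dominant lethal under the default fitness), the B
#' locus is a neutral site (all resistance is type-1), and the C locus is
#' never cut.
#'
#' @param name one of `"spd"`, `"split"`, `"noble_dcd"`, `"direct_dcd"`,
#'   `"indirect_dcd"`.
#' @return a [drive_design()].
#' @export
drive_preset <- function(name) {
  switch(
    name,
    spd = drive_design(
      locus_spec("A", "N^A"),
      name = "spd"
    ),
    split = drive_design(
      locus_spec("A", "G^A"),
      locus_spec("B", "N", cuttable = FALSE),
      name = "split"
    ),
    noble_dcd = drive_design(
      locus_spec("A", "E"),
      locus_spec("B", "N^A", resistance = "r1_only"),
      locus_spec("C", "N^B", cuttable = FALSE),
      name = "noble_dcd"
    ),
    direct_dcd = drive_design(
      locus_spec("A", "E"),
      locus_spec("B", "N^A", resistance = "r1_only"),
      locus_spec("C", "G^B", cuttable = FALSE),
      name = "direct_dcd"
    ),
    indirect_dcd = drive_design(
      locus_spec("A", "G^A"),
      locus_spec("B", "N", resistance = "r1_only"),
      locus_spec("C", "G^B", cuttable = FALSE),
      name = "indirect_dcd"
    ),
    stop("unknown drive preset: ", name)
  )
}

#' Check a drive design for functional problems
#'
#' Structural impossibilities are already rejected by [drive_design()]; this
#' reports the legal-but-suspect cases as character warnings: a design with
#' gRNAs but no nuclease anywhere (inert), loci that no gRNA targets, and
#' deviations from the classic daisy-chain shape (each locus except the top
#' targeted by exactly one gRNA).
#'
#' @param design a [drive_design()].
#' @return character vector of warning messages (empty if none).
#' @export
validate_design <- function(design) {
  warnings <- character()
  drives <- vapply(design$loci, `[[`, character(1), "drive_allele")
  targets <- allele_target(drives)
  has_nuclease <- any(allele_class(drives) == "N")
  if (any(!is.na(targets)) && !has_nuclease) {
    warnings <- c(warnings, "inert: no nuclease source in the design")
  }
  labels <- design_loci(design)
  n_targeting <- vapply(labels, function(l) sum(targets == l, na.rm = TRUE), integer(1))
  multi <- labels[n_targeting > 1L]
  if (length(multi)) {
    warnings <- c(warnings,
      paste0("locus targeted by more than one gRNA: ", paste(multi, collapse = ", ")))
  }
  if (length(labels) > 1L) {
    untargeted <- labels[-length(labels)][n_targeting[-length(labels)] == 0L]
    if (length(untargeted)) {
      warnings <- c(warnings,
        paste0("non-terminal locus not targeted by any gRNA (chain broken): ",
               paste(untargeted, collapse = ", ")))
    }
  }
  warnings
}

# serialization used by the config file round-trip
design_to_list <- function(design) {
  list(
    name = design$name,
    loci = lapply(unname(design$loci), function(l) {
      list(label = l$label, drive_allele = l$drive_allele,
           cuttable = l$cuttable, resistance = l$resistance)
    })
  )
}

design_from_list <- function(x) {
  loci <- lapply(x$loci, function(l) {
    locus_spec(l$label, l$drive_allele, cuttable = isTRUE(l$cuttable),
               resistance = l$resistance)
  })
  do.call(drive_design, c(loci, list(name = x$name)))
}
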