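#' Allele notation
#'
#' Alleles are plain strings. The six classes are:
#' \describe{
#'   \item{`"T"`}{wild-type target allele, the only cuttable class;}
#'   \item{`"R1"`}{type-1 resistance: blocks re-cutting, target gene intact;}
#'   \item{`"R2"`}{type-2 resistance: blocks re-cutting, target gene disrupted;}
#'   \item{`"E"`}{drive element carrying only cargo (no nuclease, no gRNA);}
#'   \item{`"G"`}{drive element carrying a gRNA but no nuclease;}
#'   \item{`"N"`}{drive element carrying the nuclease, optionally a gRNA.}
#' }
#' A gRNA carried by a `G` or `N` allele is annotated with the locus it
#' targets after a caret, e.g. `"N^A"` (nuclease plus gRNA targeting locus A)
#' or `"G^B"` (gRNA-only element targeting locus B). `E`, `T`, `R1` and `R2`
#' never carry gRNAs.
#'
#' `allele_class()` strips the gRNA annotation; `allele_target()` returns the
#' targeted locus label or `NA` for alleles without a gRNA.
#'
#' @param allele character vector of allele strings.
#' @return `allele_class()`: character vector of classes; `allele_target()`:
#'   character vector of locus labels (`NA` where no gRNA is carried).
#' @examples
#' allele_class(c("T", "N^A", "G^B"))  # "T" "N" "G"
#' allele_target(c("T", "N^A"))        # NA  "A"
#' @export
allele_class <- function(allele) sub("\\^.*$", "", allele)

#' @rdname allele_class
#' @export
allele_target <- function(allele) {
  tgt <- rep(NA_character_, length(allele))
  has <- grepl("^[GN]\\^", allele)
  tgt[has] <- sub("^[GN]\\^", "", allele[has])
  tgt
}

# fixed canonical order of allele classes used everywhere for sorting
.allele_class_order <- c("T", "R1", "R2", "E", "G", "N")

#' Sort alleles into the package's canonical order
#'
#' The fixed order is T < R1 < R2 < E < G < N, with gRNA-target label as a
#' tie-break within a class. All genotype canonicalisation uses this order so
#' that state indices are deterministic.
#'
#' @param alleles character vector of allele strings.
#' @return the same alleles, canonically ordered.
#' @export
sort_alleles <- function(alleles) {
  cls <- match(allele_class(alleles), .allele_class_order)
  if (anyNA(cls)) {
    stop("unknown allele class in: ", paste(alleles[is.na(cls)], collapse = ", "))
  }
  tgt <- allele_target(alleles)
  tgt[is.na(tgt)] <- ""
  alleles[order(cls, tgt)]
}

is_drive_allele <- function(allele) allele_class(allele) %in% c("E", "G", "N")
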