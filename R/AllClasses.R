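#' @import methods
#' @importFrom S4Vectors isSingleString
NULL

#' Gene model with exact genomic/spliced-CDS coordinate arithmetic
#'
#' A \code{TranscriptModel} holds one protein-coding gene model: the scaffold
#' it lives on, its strand, the ordered exon intervals (1-based, inclusive,
#' ascending genomic coordinates) and the genomic span of the coding sequence.
#' All coordinate mapping between the genome and the spliced CDS (the
#' concatenated coding bases read 5' to 3' in transcript orientation, offset 1
#' being the first base of the start codon) is derived from these slots.
#'
#' Models whose spliced CDS length is not divisible by 3 are constructable but
#' carry \code{valid = FALSE} and are skipped by the pipeline.
#'
#' @slot txId transcript identifier.
#' @slot geneId gene identifier (may equal \code{txId}).
#' @slot scaffold scaffold/contig name.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot exons an \code{IRanges} of exon intervals, sorted, non-overlapping.
#' @slot cdsStart,cdsEnd genomic bounds of the CDS (cdsStart <= cdsEnd,
#'   irrespective of strand).
#' @slot proteinId optional protein identifier.
#' @slot product free-text functional annotation.
#' @slot valid logical; \code{FALSE} flags a structurally loadable but
#'   biologically invalid model (e.g. CDS length not a codon multiple).
#' @slot note reason a model was flagged invalid, otherwise \code{""}.
#' @export
setClass("TranscriptModel",
  representation(
    txId = "character", geneId = "character", scaffold = "character",
    strand = "character", exons = "IRanges",
    cdsStart = "integer", cdsEnd = "integer",
    proteinId = "character", product = "character",
    valid = "logical", note = "character"
  )
)

setValidity("TranscriptModel", function(object) {
  msg <- character()
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) == 0L)
    msg <- c(msg, "at least one exon required")
  if (length(ex) > 1L) {
    if (is.unsorted(IRanges::start(ex)))
      msg <- c(msg, "exons must be sorted by genomic start")
    if (any(IRanges::start(ex)[-1L] <= IRanges::end(ex)[-length(ex)]))
      msg <- c(msg, "exons must be non-overlapping and non-adjacent")
  }
  if (length(msg)) msg else {
    if (object@cdsStart > object@cdsEnd)
      return("cdsStart must be <= cdsEnd")
    if (object@cdsStart < min(IRanges::start(ex)) ||
        object@cdsEnd > max(IRanges::end(ex)))
      return("CDS must lie within the exon span")
    TRUE
  }
})

#' Predicted molecular consequence of one variant on one transcript
#'
#' Produced by \code{\link{predictConsequence}}. For frameshifts the report
#' carries the 1-based codon index at which the shifted frame starts, the
#' novel peptide read in the shifted frame up to (not including) the first
#' premature stop, the stop-codon type (amber TAG / ochre TAA / opal TGA),
#' the mutant protein length and the number of C-terminal residues lost
#' relative to the reference protein (negative for extensions).
#'
#' @export
setClass("ConsequenceReport",
  representation(
    snpId = "character", txId = "character",
    scaffold = "character", pos = "integer",
    kind = "character",
    refCodon = "character", altCodon = "character",
    refAA = "character", altAA = "character",
    fsCodon = "integer", novelPeptide = "character",
    stopType = "character",
    mutantLength = "integer", residuesLost = "integer",
    note = "character"
  ),
  prototype(
    refCodon = NA_character_, altCodon = NA_character_,
    refAA = NA_character_, altAA = NA_character_,
    fsCodon = NA_integer_, novelPeptide = NA_character_,
    stopType = NA_character_,
    mutantLength = NA_integer_, residuesLost = NA_integer_,
    note = ""
  )
)

.csqKinds <- c("synonymous", "missense", "stop_gained", "stop_lost",
               "inframe_indel", "frameshift", "splice_disrupting",
               "non_coding", "uncertain")

setValidity("ConsequenceReport", function(object) {
  if (!object@kind %in% .csqKinds)
    return(sprintf("kind must be one of: %s", paste(.csqKinds, collapse = ", ")))
  TRUE
})

#' Protein-level feature report
#'
#' Summary of the physicochemical characterization of a (possibly truncated)
#' protein: Guruprasad instability index with the stable/unstable call at the
#' conventional threshold of 40, Bjellqvist isoelectric point, acidic-residue
#' (D+E) fraction, and coiled-coil regions from the heptad propensity scan.
#'
#' @export
setClass("ProteinFeatureReport",
  representation(
    length = "integer", instabilityIndex = "numeric",
    stabilityClass = "character", pI = "numeric",
    acidicFraction = "numeric", coiledCoils = "data.frame",
    domains = "data.frame"
  )
)

setMethod("show", "TranscriptModel", function(object) {
  cat(sprintf("TranscriptModel %s (%s) %s:%d-%d [%s]\n",
              object@txId, object@geneId, object@scaffold,
              min(IRanges::start(object@exons)), max(IRanges::end(object@exons)),
              object@strand))
  cat(sprintf("  %d exon(s); CDS %d-%d; spliced CDS %d nt%s\n",
              length(object@exons), object@cdsStart, object@cdsEnd,
              splicedCdsLength(object),
              if (object@valid) "" else sprintf(" [INVALID: %s]", object@note)))
})

setMethod("show", "ConsequenceReport", function(object) {
  cat(sprintf("ConsequenceReport %s on %s: %s\n",
              object@snpId, object@txId, object@kind))
  if (!is.na(object@refCodon))
    cat(sprintf("  codon %s>%s (%s>%s)\n", object@refCodon, object@altCodon,
                object@refAA, object@altAA))
  if (!is.na(object@fsCodon))
    cat(sprintf("  frameshift from codon %d: +%s, stop %s, mutant %d aa, %d residue(s) lost\n",
                object@fsCodon, object@novelPeptide, object@stopType,
                object@mutantLength, object@residuesLost))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

setMethod("show", "ProteinFeatureReport", function(object) {
  cat(sprintf("ProteinFeatureReport: %d aa, instability %.2f (%s), pI %.2f, acidic %.3f\n",
              object@length, object@instabilityIndex, object@stabilityClass,
              object@pI, object@acidicFraction))
  if (nrow(object@coiledCoils))
    cat(sprintf("  %d coiled-coil region(s): %s\n", nrow(object@coiledCoils),
                paste(sprintf("%d-%d", object@coiledCoils$start,
                              object@coiledCoils$end), collapse = ", ")))
})
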