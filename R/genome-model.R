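#' @importFrom Biostrings readDNAStringSet DNAStringSet DNAString
#'   reverseComplement writeXStringSet GENETIC_CODE oligonucleotideFrequency
#'   PDict vcountPDict
#' @importFrom IRanges IRanges start end width
NULL

## ---- genome ---------------------------------------------------------------

#' Load a genome from FASTA
#'
#' Reads a multi-scaffold genome, normalizes the sequence to uppercase and
#' validates that scaffold ids are unique, sequences non-empty and the
#' alphabet restricted to A/C/G/T/N.
#'
#' @param path path to a FASTA file.
#' @return a named \code{DNAStringSet}, one entry per scaffold.
#' @export
loadGenome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate scaffold id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(x) <- ids
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(x) <- ids
  validateGenome(x)
  x
}

#' Validate an in-memory genome
#'
#' @param genome a named \code{DNAStringSet}.
#' @return the genome, invisibly, after validation.
#' @export
validateGenome <- function(genome) {
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet")
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("all scaffolds must be named")
  if (anyDuplicated(names(genome))) stop("scaffold ids must be unique")
  if (any(Biostrings::width(genome) == 0L)) stop("scaffold sequences must be non-empty")
  bad <- Biostrings::alphabetFrequency(genome, baseOnly = TRUE)
  ## 'other' column counts anything outside A/C/G/T; only N is tolerated
  letters <- Biostrings::alphabetFrequency(genome)
  allowed <- c("A", "C", "G", "T", "N")
  used <- colnames(letters)[colSums(letters) > 0]
  if (length(setdiff(used, allowed)))
    stop("genome alphabet restricted to A/C/G/T/N; found: ",
         paste(setdiff(used, allowed), collapse = ","))
  invisible(genome)
}

.scaffoldSeq <- function(genome, scaffold) {
  if (!scaffold %in% names(genome))
    stop("unknown scaffold: ", scaffold)
  genome[[scaffold]]
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.complementBases <- function(s) {
  chartr("ACGTN", "TGCAN", s)
}

## ---- transcript models ----------------------------------------------------

#' Construct a transcript model
#'
#' @param txId,geneId,scaffold,strand identifiers and orientation.
#' @param exonStarts,exonEnds integer vectors of exon bounds (1-based,
#'   inclusive, ascending genomic order).
#' @param cdsStart,cdsEnd genomic CDS bounds (start <= end on both strands).
#' @param proteinId,product optional annotation.
#' @return a \code{\linkS4class{TranscriptModel}}; models whose spliced CDS
#'   length is not a multiple of 3 are returned with \code{valid = FALSE}.
#' @export
TranscriptModel <- function(txId, scaffold, strand, exonStarts, exonEnds,
                            cdsStart, cdsEnd, geneId = txId,
                            proteinId = NA_character_, product = "") {
  o <- order(exonStarts)
  ex <- IRanges::IRanges(as.integer(exonStarts)[o], as.integer(exonEnds)[o])
  obj <- methods::new("TranscriptModel",
    txId = txId, geneId = geneId, scaffold = scaffold, strand = strand,
    exons = ex, cdsStart = as.integer(cdsStart), cdsEnd = as.integer(cdsEnd),
    proteinId = proteinId, product = product, valid = TRUE, note = "")
  n <- splicedCdsLength(obj)
  if (n %% 3L != 0L) {
    obj@valid <- FALSE
    obj@note <- sprintf("spliced CDS length %d not divisible by 3", n)
  }
  obj
}

#' @rdname TranscriptModel
#' @param x a \code{TranscriptModel}.
#' @export
txId <- function(x) x@txId

#' @rdname TranscriptModel
#' @export
txStrand <- function(x) x@strand

#' @rdname TranscriptModel
#' @export
txScaffold <- function(x) x@scaffold

#' @rdname TranscriptModel
#' @export
txExons <- function(x) x@exons

#' Genomic intervals of the coding part of each exon
#'
#' @param tx a \code{TranscriptModel}.
#' @return an \code{IRanges} in ascending genomic order.
#' @export
cdsRanges <- function(tx) {
  r <- IRanges::restrict(tx@exons, start = tx@cdsStart, end = tx@cdsEnd)
  r[IRanges::width(r) > 0L]
}

#' @rdname cdsRanges
#' @export
splicedCdsLength <- function(tx) sum(IRanges::width(cdsRanges(tx)))

#' Map a genomic coordinate to a spliced-CDS offset
#'
#' The offset counts coding bases only, 1-based from the first base of the
#' start codon, in transcript orientation (reverse order of genomic
#' coordinates for minus-strand models). Non-coding positions return
#' \code{NA} with a sub-label.
#'
#' @param tx a \code{TranscriptModel}.
#' @param genomicPos 1-based genomic coordinate on the model's scaffold.
#' @return a list with \code{offset} (integer, \code{NA} if non-coding) and
#'   \code{region}, one of \code{"cds"}, \code{"utr5"}, \code{"utr3"},
#'   \code{"intron"}, \code{"upstream"}, \code{"downstream"} (the last two
#'   strand-aware, relative to the transcript).
#' @export
genomicToSpliced <- function(tx, genomicPos) {
  p <- as.integer(genomicPos)
  if (is.na(p) || p < 1L) stop("genomic position must be a positive integer")
  cr <- cdsRanges(tx)
  hit <- which(p >= IRanges::start(cr) & p <= IRanges::end(cr))
  if (length(hit) == 1L) {
    if (tx@strand == "+") {
      off <- sum(IRanges::width(cr)[seq_len(hit - 1L)]) +
        (p - IRanges::start(cr)[hit]) + 1L
    } else {
      n <- length(cr)
      off <- if (hit == n) 0L else sum(IRanges::width(cr)[(hit + 1L):n])
      off <- off + (IRanges::end(cr)[hit] - p) + 1L
    }
    return(list(offset = as.integer(off), region = "cds"))
  }
  ex <- tx@exons
  inExon <- any(p >= IRanges::start(ex) & p <= IRanges::end(ex))
  txStart <- min(IRanges::start(ex)); txEnd <- max(IRanges::end(ex))
  region <- if (inExon) {
    beforeCds <- p < tx@cdsStart
    if (tx@strand == "+") (if (beforeCds) "utr5" else "utr3")
    else (if (beforeCds) "utr3" else "utr5")
  } else if (p >= txStart && p <= txEnd) {
    "intron"
  } else {
    beforeTx <- p < txStart
    if (tx@strand == "+") (if (beforeTx) "upstream" else "downstream")
    else (if (beforeTx) "downstream" else "upstream")
  }
  list(offset = NA_integer_, region = region)
}

#' Map a spliced-CDS offset back to its genomic coordinate
#'
#' Inverse of \code{\link{genomicToSpliced}} for coding positions.
#'
#' @param tx a \code{TranscriptModel}.
#' @param offset 1-based spliced-CDS offset.
#' @return integer genomic coordinate.
#' @export
splicedToGenomic <- function(tx, offset) {
  o <- as.integer(offset)
  n <- splicedCdsLength(tx)
  if (is.na(o) || o < 1L || o > n)
    stop(sprintf("offset must be in [1, %d]", n))
  cr <- cdsRanges(tx)
  w <- IRanges::width(cr)
  if (tx@strand == "+") {
    cum <- cumsum(w)
    i <- which(o <= cum)[1L]
    prev <- if (i == 1L) 0L else cum[i - 1L]
    IRanges::start(cr)[i] + (o - prev - 1L)
  } else {
    wRev <- rev(w)
    cum <- cumsum(wRev)
    j <- which(o <= cum)[1L]
    prev <- if (j == 1L) 0L else cum[j - 1L]
    i <- length(cr) - j + 1L
    IRanges::end(cr)[i] - (o - prev - 1L)
  }
}

#' Codon address of a spliced-CDS offset
#'
#' @param offset 1-based offset from the translation start.
#' @return list with \code{codon} (1-based codon index) and \code{within}
#'   (position within the codon, 1-3).
#' @export
codonOf <- function(offset) {
  o <- as.integer(offset)
  if (any(is.na(o)) || any(o < 1L)) stop("offset must be >= 1")
  list(codon = (o - 1L) %/% 3L + 1L, within = (o - 1L) %% 3L + 1L)
}

#' Extract the spliced CDS sequence of a model
#'
#' Concatenates coding exon bases in transcript orientation
#' (reverse-complemented for minus-strand models).
#'
#' @param tx a \code{TranscriptModel}.
#' @param genome a \code{DNAStringSet}.
#' @return uppercase nucleotide string.
#' @export
extractSplicedCds <- function(tx, genome) {
  scaf <- .scaffoldSeq(genome, tx@scaffold)
  cr <- cdsRanges(tx)
  parts <- vapply(seq_along(cr), function(i) {
    as.character(Biostrings::subseq(scaf, IRanges::start(cr)[i], IRanges::end(cr)[i]))
  }, character(1))
  s <- paste(parts, collapse = "")
  if (tx@strand == "-") s <- .revcomp(s)
  s
}

## ---- GFF3 -----------------------------------------------------------------

#' Load gene models from GFF3
#'
#' Builds one \code{TranscriptModel} per mRNA feature, using exon and CDS
#' children linked through the \code{Parent} attribute. Models whose CDS
#' falls outside the exon union are rejected with a warning; models whose
#' spliced CDS length is not a codon multiple are kept but flagged invalid.
#'
#' @param path path to a GFF3 file with gene/mRNA/exon/CDS features and
#'   ID/Parent attributes.
#' @param genome a \code{DNAStringSet}; scaffold names must resolve.
#' @return named list of \code{TranscriptModel} objects.
#' @export
loadAnnotation <- function(path, genome) {
  if (!file.exists(path)) stop("GFF3 not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  mrna <- gr[typ == "mRNA"]
  if (length(mrna) == 0L) stop("no mRNA features in ", path)
  parentOf <- function(g) vapply(g$Parent, function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  exons <- gr[typ == "exon"]; cds <- gr[typ == "CDS"]
  exPar <- parentOf(exons); cdsPar <- parentOf(cds)
  out <- list()
  for (i in seq_along(mrna)) {
    m <- mrna[i]
    id <- as.character(m$ID)
    scaf <- as.character(GenomicRanges::seqnames(m))
    if (!scaf %in% names(genome))
      stop("unknown scaffold in annotation: ", scaf)
    ex <- exons[!is.na(exPar) & exPar == id]
    cd <- cds[!is.na(cdsPar) & cdsPar == id]
    if (length(ex) == 0L && length(cd) > 0L) ex <- cd
    if (length(ex) == 0L) {
      warning("mRNA ", id, " has no exon/CDS children; skipped")
      next
    }
    if (length(cd) == 0L) cd <- ex
    exS <- GenomicRanges::start(ex); exE <- GenomicRanges::end(ex)
    cdS <- min(GenomicRanges::start(cd)); cdE <- max(GenomicRanges::end(cd))
    ## CDS must be covered by the exon union
    exIr <- IRanges::reduce(IRanges::IRanges(exS, exE))
    cdIr <- IRanges::reduce(IRanges::IRanges(GenomicRanges::start(cd),
                                             GenomicRanges::end(cd)))
    if (sum(IRanges::width(IRanges::setdiff(cdIr, exIr))) > 0L) {
      warning("mRNA ", id, " has CDS outside its exons; model rejected")
      next
    }
    gid <- parentOf(m); if (is.na(gid)) gid <- id
    prod <- if (!is.null(m$product) && !is.na(m$product)) as.character(m$product) else ""
    out[[id]] <- TranscriptModel(
      txId = id, geneId = gid, scaffold = scaf,
      strand = as.character(GenomicRanges::strand(m)),
      exonStarts = exS, exonEnds = exE,
      cdsStart = cdS, cdsEnd = cdE, product = prod)
  }
  out
}

#' Write gene models to GFF3
#'
#' @param transcripts list of \code{TranscriptModel}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAnnotation <- function(transcripts, path) {
  rows <- list()
  for (tx in transcripts) {
    ex <- tx@exons
    txStart <- min(IRanges::start(ex)); txEnd <- max(IRanges::end(ex))
    cr <- cdsRanges(tx)
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = tx@scaffold, start = txStart, end = txEnd,
      strand = tx@strand, type = "gene", ID = tx@geneId,
      Parent = NA_character_, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = tx@scaffold, start = txStart, end = txEnd,
      strand = tx@strand, type = "mRNA", ID = tx@txId,
      Parent = tx@geneId, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = tx@scaffold, start = IRanges::start(ex), end = IRanges::end(ex),
      strand = tx@strand, type = "exon", ID = NA_character_,
      Parent = tx@txId, stringsAsFactors = FALSE)
    ## GFF3 phase: bases to skip before the first complete codon of each
    ## CDS piece, accumulated in transcript (5'->3') order
    w <- IRanges::width(cr)
    cumBefore <- if (tx@strand == "+") cumsum(c(0L, w))[seq_along(w)]
                 else sum(w) - cumsum(w)
    phase <- (3L - cumBefore %% 3L) %% 3L
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = tx@scaffold, start = IRanges::start(cr), end = IRanges::end(cr),
      strand = tx@strand, type = "CDS", ID = NA_character_,
      Parent = tx@txId, phase = phase, stringsAsFactors = FALSE)
  }
  rows <- lapply(rows, function(r) {
    if (!"phase" %in% names(r)) r$phase <- NA_integer_
    r
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$seqnames,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$type <- df$type
  gr$ID <- df$ID
  gr$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  gr$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
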