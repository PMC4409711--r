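## Molecular consequence prediction on the spliced CDS: codon changes for
## SNVs, in-frame indels, and frameshifts with novel-peptide / premature-stop
## / truncation accounting.

.stopTypeOf <- function(codon) {
  switch(codon, TAG = "amber", TAA = "ochre", TGA = "opal", "none_found")
}

#' Translate a spliced CDS
#'
#' Standard genetic code; translation stops at the first stop codon. Codons
#' containing N (or other non-ACGT letters) translate to \code{"X"}.
#' A trailing partial codon is ignored and flagged.
#'
#' @param cds nucleotide string, length >= 3.
#' @return list with \code{protein} (aa string up to, not including, the first
#'   stop), \code{stopType} (\code{"amber"}, \code{"ochre"}, \code{"opal"} or
#'   \code{"none_found"}), \code{stopCodonIndex} (1-based, \code{NA} if no
#'   stop), \code{partialCodon} (logical) and \code{hasX}.
#' @export
translateCds <- function(cds) {
  n <- nchar(cds)
  if (n < 3L) stop("CDS shorter than one codon")
  nc <- n %/% 3L
  starts <- seq.int(1L, by = 3L, length.out = nc)
  codons <- substring(cds, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  stopAt <- which(aa == "*")
  stopType <- "none_found"; stopIdx <- NA_integer_
  if (length(stopAt)) {
    stopIdx <- unname(stopAt[1L])
    stopType <- .stopTypeOf(codons[stopIdx])
    aa <- aa[seq_len(stopIdx - 1L)]
  }
  list(protein = paste(aa, collapse = ""), stopType = stopType,
       stopCodonIndex = stopIdx, partialCodon = (n %% 3L) != 0L,
       hasX = any(aa == "X"))
}

#' Apply a variant to a spliced CDS string
#'
#' Alleles here are in transcript orientation and positions are spliced-CDS
#' offsets (1-based from the translation start). \code{ref} must match the
#' CDS at \code{offset}; the original string is not modified.
#'
#' @param cds nucleotide string.
#' @param offset 1-based offset of the first base of \code{ref}.
#' @param ref,alt alleles in transcript orientation (VCF-style anchored for
#'   indels, or bare: a deletion may be written ref = deleted bases,
#'   alt = "").
#' @return mutated CDS string.
#' @export
applyVariantToCds <- function(cds, offset, ref, alt) {
  o <- as.integer(offset)
  n <- nchar(cds)
  if (o < 1L || o + nchar(ref) - 1L > n)
    stop("variant does not fit inside the CDS")
  obs <- substr(cds, o, o + nchar(ref) - 1L)
  if (!identical(obs, ref))
    stop(sprintf("reference mismatch at offset %d: expected %s, observed %s",
                 o, ref, obs))
  paste0(substr(cds, 1L, o - 1L), alt,
         substr(cds, o + nchar(ref), n))
}

## Map an indel given in genomic (forward-strand, anchored) convention onto
## spliced-CDS coordinates. Returns NULL when the event is not cleanly inside
## the coding sequence.
.indelSplicedSpan <- function(tx, pos, ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr > na) {  # deletion: bases pos+1 .. pos+nd removed
    nd <- nr - na
    gFirst <- pos + 1L; gLast <- pos + nd
    m1 <- genomicToSpliced(tx, gFirst); m2 <- genomicToSpliced(tx, gLast)
    inCds <- !is.na(m1$offset) && !is.na(m2$offset)
    if (!inCds) {
      partly <- !is.na(m1$offset) || !is.na(m2$offset)
      return(list(status = if (partly) "splice" else "non_coding"))
    }
    oMin <- min(m1$offset, m2$offset); oMax <- max(m1$offset, m2$offset)
    if (oMax - oMin != nd - 1L) return(list(status = "splice"))
    delSeq <- substr(ref, na + 1L, nr)
    if (tx@strand == "-") delSeq <- .revcomp(delSeq)
    list(status = "ok", type = "deletion", oFirst = oMin, delLen = nd,
         delSeq = delSeq, firstAltered = oMin)
  } else {  # insertion between pos and pos+1
    ins <- substr(alt, nr + 1L, na)
    if (tx@strand == "+") {
      mA <- genomicToSpliced(tx, pos); mB <- genomicToSpliced(tx, pos + 1L)
      if (is.na(mA$offset) || is.na(mB$offset)) {
        partly <- !is.na(mA$offset) || !is.na(mB$offset)
        return(list(status = if (partly) "splice" else "non_coding"))
      }
      if (mB$offset - mA$offset != 1L) return(list(status = "splice"))
      list(status = "ok", type = "insertion", after = mA$offset,
           insSeq = ins, firstAltered = mA$offset + 1L)
    } else {
      mA <- genomicToSpliced(tx, pos + 1L); mB <- genomicToSpliced(tx, pos)
      if (is.na(mA$offset) || is.na(mB$offset)) {
        partly <- !is.na(mA$offset) || !is.na(mB$offset)
        return(list(status = if (partly) "splice" else "non_coding"))
      }
      if (mB$offset - mA$offset != 1L) return(list(status = "splice"))
      list(status = "ok", type = "insertion", after = mA$offset,
           insSeq = .revcomp(ins), firstAltered = mA$offset + 1L)
    }
  }
}

#' Predict the molecular consequence of a variant on a transcript
#'
#' SNVs are compared codon-by-codon (synonymous / missense / stop_gained /
#' stop_lost). CDS indels with net length a multiple of 3 are in-frame;
#' all others are frameshifts: the mutated CDS is translated from the start,
#' the frameshift start codon is the codon containing the first altered base,
#' the novel peptide runs from that codon to the residue before the first
#' premature stop, and the residues lost are counted against the reference
#' protein. Indels spanning an exon/intron boundary are called
#' \code{splice_disrupting}; non-coding positions return a
#' \code{non_coding} report rather than an error.
#'
#' @param tx a \code{TranscriptModel}.
#' @param genome \code{DNAStringSet}.
#' @param variant one-row variant table (or list) with scaffold, pos, ref,
#'   alt on the forward genomic strand (VCF-style anchored indels) and
#'   optionally snpId.
#' @return a \code{\linkS4class{ConsequenceReport}}.
#' @export
predictConsequence <- function(tx, genome, variant) {
  v <- as.list(variant)
  snp <- if (!is.null(v$snpId)) v$snpId else paste0(v$scaffold, "_", v$pos)
  pos <- as.integer(v$pos); ref <- as.character(v$ref); alt <- as.character(v$alt)
  base <- function(kind, ...) {
    methods::new("ConsequenceReport", snpId = snp, txId = txId(tx),
                 scaffold = as.character(v$scaffold), pos = pos,
                 kind = kind, ...)
  }
  if (!tx@valid)
    return(base("uncertain", note = paste("invalid model:", tx@note)))
  cls <- classifyVariant(ref, alt)
  cds <- extractSplicedCds(tx, genome)
  refTr <- translateCds(cds)
  refLen <- nchar(refTr$protein)

  if (cls %in% c("SNV", "MNV")) {
    if (cls == "MNV")
      return(base("uncertain", note = "multi-nucleotide substitution not modelled"))
    m <- genomicToSpliced(tx, pos)
    if (is.na(m$offset))
      return(base("non_coding", note = m$region))
    o <- m$offset
    refB <- if (tx@strand == "+") ref else .complementBases(ref)
    altB <- if (tx@strand == "+") alt else .complementBases(alt)
    if (substr(cds, o, o) != refB)
      stop(sprintf("reference mismatch for %s at spliced offset %d: expected %s, observed %s",
                   snp, o, refB, substr(cds, o, o)))
    ca <- codonOf(o)
    cStart <- (ca$codon - 1L) * 3L + 1L
    refCodon <- substr(cds, cStart, cStart + 2L)
    altCodon <- refCodon
    substr(altCodon, ca$within, ca$within) <- altB
    aaR <- unname(Biostrings::GENETIC_CODE[refCodon]); aaR[is.na(aaR)] <- "X"
    aaA <- unname(Biostrings::GENETIC_CODE[altCodon]); aaA[is.na(aaA)] <- "X"
    kind <- if (aaR == "X" || aaA == "X") "uncertain"
      else if (aaA == "*") "stop_gained"
      else if (aaR == "*") "stop_lost"
      else if (aaR == aaA) "synonymous" else "missense"
    mutLen <- if (kind == "stop_gained") ca$codon - 1L else refLen
    return(base(kind, refCodon = refCodon, altCodon = altCodon,
                refAA = aaR, altAA = aaA, fsCodon = NA_integer_,
                mutantLength = as.integer(mutLen),
                residuesLost = as.integer(refLen - mutLen)))
  }

  ## indel
  sp <- .indelSplicedSpan(tx, pos, ref, alt)
  if (sp$status == "non_coding") {
    reg <- genomicToSpliced(tx, .variantEventPos(data.frame(
      pos = pos, class = cls, stringsAsFactors = FALSE)))$region
    return(base("non_coding", note = reg))
  }
  if (sp$status == "splice")
    return(base("splice_disrupting",
                note = "indel spans an exon/intron boundary; spliced product undefined"))
  mutCds <- if (sp$type == "deletion") {
    applyVariantToCds(cds, sp$oFirst, sp$delSeq, "")
  } else {
    paste0(substr(cds, 1L, sp$after), sp$insSeq,
           substr(cds, sp$after + 1L, nchar(cds)))
  }
  net <- nchar(alt) - nchar(ref)
  mutTr <- translateCds(mutCds)
  mutLen <- nchar(mutTr$protein)
  if (net %% 3L == 0L) {
    return(base("inframe_indel",
                mutantLength = as.integer(mutLen),
                residuesLost = as.integer(refLen - mutLen),
                note = sprintf("net %+d nt in frame", net)))
  }
  fs <- codonOf(sp$firstAltered)$codon
  novel <- if (mutLen >= fs) substr(mutTr$protein, fs, mutLen) else ""
  base("frameshift",
       fsCodon = as.integer(fs), novelPeptide = novel,
       stopType = mutTr$stopType,
       mutantLength = as.integer(mutLen),
       residuesLost = as.integer(refLen - mutLen),
       note = if (mutTr$stopType == "none_found")
         "no stop codon found downstream in mutated CDS" else "")
}

#' Tabulate consequence reports
#'
#' One row per report, deterministically ordered by scaffold (numeric when
#' labels are numeric) then position.
#'
#' @param reports list of \code{ConsequenceReport}.
#' @return data.frame.
#' @export
consequenceTable <- function(reports) {
  if (!length(reports)) {
    return(data.frame(snpId = character(), txId = character(),
                      scaffold = character(), pos = integer(),
                      kind = character(), refCodon = character(),
                      altCodon = character(), refAA = character(),
                      altAA = character(), fsCodon = integer(),
                      novelPeptide = character(), stopType = character(),
                      mutantLength = integer(), residuesLost = integer(),
                      note = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(reports, function(r) data.frame(
    snpId = r@snpId, txId = r@txId, scaffold = r@scaffold, pos = r@pos,
    kind = r@kind, refCodon = r@refCodon, altCodon = r@altCodon,
    refAA = r@refAA, altAA = r@altAA, fsCodon = r@fsCodon,
    novelPeptide = r@novelPeptide, stopType = r@stopType,
    mutantLength = r@mutantLength, residuesLost = r@residuesLost,
    note = r@note, stringsAsFactors = FALSE)))
  key <- suppressWarnings(as.numeric(df$scaffold))
  ord <- if (all(!is.na(key))) order(key, df$pos) else order(df$scaffold, df$pos)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}
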