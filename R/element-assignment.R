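## Assign each variant to a gene element (exon / intron / promoter /
## terminator / intergenic) using asymmetric scan windows anchored on the
## coding region: promoters within `upstreamBp` (default 800 bp) 5' of the
## translation start, terminators within `downstreamBp` (default 200 bp) 3'
## of the stop, both strand-aware.

.variantEventPos <- function(variants) {
  ## representative genomic base of the event: the SNV base itself, or the
  ## first changed base after the anchor for indels
  ifelse(variants$class %in% c("SNV", "MNV"), variants$pos, variants$pos + 1L)
}

.elementForTx <- function(tx, p, upstreamBp, downstreamBp) {
  m <- genomicToSpliced(tx, p)
  if (m$region == "cds")
    return(list(element = "exon", distance = 0L, utr = FALSE))
  if (m$region %in% c("utr5", "utr3"))
    return(list(element = "exon", distance = 0L, utr = TRUE))
  if (m$region == "intron")
    return(list(element = "intron", distance = 0L, utr = FALSE))
  ## outside the transcript: distance to the strand-aware CDS boundaries
  if (tx@strand == "+") {
    dUp <- tx@cdsStart - p
    dDown <- p - tx@cdsEnd
  } else {
    dUp <- p - tx@cdsEnd
    dDown <- tx@cdsStart - p
  }
  if (dUp > 0L && dUp <= upstreamBp)
    return(list(element = "promoter", distance = dUp, utr = FALSE))
  if (dDown > 0L && dDown <= downstreamBp)
    return(list(element = "terminator", distance = dDown, utr = FALSE))
  NULL
}

#' Assign variants to gene elements
#'
#' Each variant gets exactly one primary element label. Inside a transcript
#' the label follows the position (coding exon, UTR-in-exon, intron); outside,
#' a promoter call requires the variant within \code{upstreamBp} of the
#' translation start and a terminator call within \code{downstreamBp} of the
#' stop, both measured strand-aware from the CDS boundaries. When several
#' transcripts qualify the nearest CDS boundary wins; exact ties are all
#' reported, with the first transcript by coordinate marked primary.
#'
#' @param variants variant table (\code{\link{variantTable}}).
#' @param transcripts list of \code{TranscriptModel}.
#' @param upstreamBp,downstreamBp scan windows in bp (defaults 800/200).
#' @return data.frame with one row per (variant, qualifying transcript) plus
#'   one \code{"intergenic"} row for variants hitting nothing; columns snpId,
#'   scaffold, pos, txId, element, distance, utr, primary.
#' @export
assignElements <- function(variants, transcripts, upstreamBp = 800L,
                           downstreamBp = 200L) {
  txScaf <- vapply(transcripts, txScaffold, character(1))
  txStart <- vapply(transcripts, function(t) min(IRanges::start(txExons(t))), numeric(1))
  evt <- .variantEventPos(variants)
  out <- list()
  for (i in seq_len(nrow(variants))) {
    p <- evt[i]
    cand <- which(txScaf == variants$scaffold[i])
    hits <- list()
    for (j in cand) {
      tx <- transcripts[[j]]
      if (!tx@valid) next
      h <- .elementForTx(tx, p, upstreamBp, downstreamBp)
      if (!is.null(h))
        hits[[length(hits) + 1L]] <- data.frame(
          snpId = variants$snpId[i], scaffold = variants$scaffold[i],
          pos = variants$pos[i], txId = txId(tx), element = h$element,
          distance = h$distance, utr = h$utr, txStart = txStart[j],
          stringsAsFactors = FALSE)
    }
    if (!length(hits)) {
      out[[length(out) + 1L]] <- data.frame(
        snpId = variants$snpId[i], scaffold = variants$scaffold[i],
        pos = variants$pos[i], txId = NA_character_, element = "intergenic",
        distance = NA_integer_, utr = FALSE, primary = TRUE,
        stringsAsFactors = FALSE)
      next
    }
    h <- do.call(rbind, hits)
    h <- h[order(h$distance, h$txStart), , drop = FALSE]
    h$primary <- seq_len(nrow(h)) == 1L
    h$txStart <- NULL
    out[[length(out) + 1L]] <- h
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(res) <- NULL
  res
}

#' Impacted genes from element assignments
#'
#' Unique transcripts hit in any non-intergenic element, ordered by scaffold
#' then variant position (deterministic).
#'
#' @param assignments output of \code{\link{assignElements}}.
#' @return list with \code{genes} (character vector of transcript ids) and
#'   \code{count}.
#' @export
impactedGenes <- function(assignments) {
  hit <- assignments[!is.na(assignments$txId) &
                       assignments$element != "intergenic", , drop = FALSE]
  ## order scaffolds numerically when they are numeric labels
  scafKey <- suppressWarnings(as.numeric(hit$scaffold))
  ord <- if (all(!is.na(scafKey))) order(scafKey, hit$pos)
         else order(hit$scaffold, hit$pos)
  hit <- hit[ord, , drop = FALSE]
  genes <- unique(hit$txId)
  list(genes = genes, count = length(genes))
}
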