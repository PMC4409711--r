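## Variant records and the genomic-context filters (GC window, linguistic
## complexity, k-mer uniqueness) that reduce a raw call list to credible
## homozygous mutations.

#' Classify a variant from its (anchored) alleles
#'
#' Alleles follow the VCF convention: indels carry one anchor base, so a
#' 1-nt deletion has \code{nchar(ref) == 2, nchar(alt) == 1}.
#'
#' @param ref,alt non-empty allele strings.
#' @return one of \code{"SNV"}, \code{"insertion"}, \code{"deletion"},
#'   \code{"MNV"} (balanced multi-nucleotide substitution, excluded from SNV
#'   counts).
#' @export
classifyVariant <- function(ref, alt) {
  if (!nzchar(ref) || !nzchar(alt)) stop("ref and alt must be non-empty")
  if (identical(ref, alt)) stop("ref and alt are identical: ", ref)
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == na) {
    if (nr == 1L) "SNV" else "MNV"
  } else if (nr > na) "deletion" else "insertion"
}

.contextWindow <- function(genome, scaffold, position, windowBp) {
  scaf <- .scaffoldSeq(genome, scaffold)
  len <- length(scaf)
  if (position < 1L || position > len)
    stop(sprintf("position %d off scaffold %s (length %d)", position, scaffold, len))
  half <- windowBp %/% 2L
  s <- max(1L, position - half)
  e <- min(len, s + windowBp - 1L)
  s <- max(1L, e - windowBp + 1L)
  as.character(Biostrings::subseq(scaf, s, e))
}

#' GC fraction of the window around a position
#'
#' Window of \code{windowBp} centered on the position, clipped at scaffold
#' ends; N bases are excluded from the denominator.
#'
#' @param genome \code{DNAStringSet}.
#' @param scaffold,position variant site.
#' @param windowBp window width (default 100).
#' @return GC fraction in [0,1]; \code{NA} for an all-N window.
#' @export
gcFraction <- function(genome, scaffold, position, windowBp = 100L) {
  w <- .contextWindow(genome, scaffold, position, windowBp)
  ch <- strsplit(w, "")[[1]]
  nonN <- ch != "N"
  if (!any(nonN)) return(NA_real_)
  sum(ch %in% c("G", "C")) / sum(nonN)
}

#' Linguistic complexity of the window around a position
#'
#' k-mer vocabulary richness: distinct k-mers in the window divided by the
#' maximum possible, \code{min(4^k, L - k + 1)}. A window of non-degenerate
#' sequence scores 1; homopolymers and short-period repeats score far below.
#'
#' @inheritParams gcFraction
#' @param k k-mer size (default 2, under which any non-degenerate 100-bp
#'   window attains exactly 1).
#' @return complexity in (0, 1].
#' @export
linguisticComplexity <- function(genome, scaffold, position, windowBp = 100L, k = 2L) {
  w <- .contextWindow(genome, scaffold, position, windowBp)
  L <- nchar(w)
  if (L < k) stop(sprintf("window length %d shorter than k = %d", L, k))
  kmers <- substring(w, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  length(unique(kmers)) / min(4^k, L - k + 1L)
}

#' Genome-wide k-mer uniqueness of the window around a position
#'
#' Every k-mer fully inside the window is counted genome-wide
#' (strand-symmetric: a k-mer and its reverse complement are one key) and
#' scored \code{16 / occurrences}; the site score is the mean over window
#' k-mers. A site whose every k-mer is unique scores 16; one inside an exact
#' two-copy repeat scores 8.
#'
#' @inheritParams gcFraction
#' @param kmerLen k-mer length (default 31, the scale of the short sequencing reads whose mappability the score emulates; odd, so no palindromes).
#' @return score in (0, 16].
#' @export
uniquenessScore <- function(genome, scaffold, position, windowBp = 100L,
                            kmerLen = 31L) {
  w <- .contextWindow(genome, scaffold, position, windowBp)
  L <- nchar(w)
  if (L < kmerLen) stop("window shorter than kmerLen")
  starts <- seq_len(L - kmerLen + 1L)
  kmers <- substring(w, starts, starts + kmerLen - 1L)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  if (!length(kmers)) return(NA_real_)
  uq <- unique(kmers)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(uq))
  cnt <- rowSums(Biostrings::vcountPDict(pd, genome))
  rcSet <- Biostrings::reverseComplement(Biostrings::DNAStringSet(uq))
  pdRc <- Biostrings::PDict(rcSet)
  cnt <- cnt + rowSums(Biostrings::vcountPDict(pdRc, genome))
  names(cnt) <- uq
  occ <- cnt[kmers]
  occ[occ < 1L] <- 1L  # self-hit guaranteed, guard degenerate masks
  mean(16 / occ)
}

#' Filter configuration for genomic-context filtering
#'
#' Defaults reproduce the published selection: homozygous calls with
#' complexity >= 1, uniqueness > 15.8 and GC fraction within [0.31, 0.74],
#' computed on a 100-bp window centered on the variant.
#'
#' @param gcMin,gcMax GC bounds (inclusive).
#' @param complexityMin minimal linguistic complexity.
#' @param uniquenessMin uniqueness threshold (strict: survivors score above it).
#' @param windowBp context window width.
#' @param complexityK k-mer size of the complexity scorer.
#' @param kmerLen k-mer length of the uniqueness scorer.
#' @param homozygousOnly drop heterozygous records first.
#' @return a list of class \code{"FilterConfig"}.
#' @export
filterConfig <- function(gcMin = 0.31, gcMax = 0.74, complexityMin = 1.0,
                         uniquenessMin = 15.8, windowBp = 100L,
                         complexityK = 2L, kmerLen = 31L,
                         homozygousOnly = TRUE) {
  stopifnot(gcMin >= 0, gcMin < gcMax, gcMax <= 1)
  structure(list(gcMin = gcMin, gcMax = gcMax, complexityMin = complexityMin,
                 uniquenessMin = uniquenessMin, windowBp = as.integer(windowBp),
                 complexityK = as.integer(complexityK),
                 kmerLen = as.integer(kmerLen),
                 homozygousOnly = isTRUE(homozygousOnly)),
            class = "FilterConfig")
}

#' Build a normalized variant table
#'
#' @param scaffold,pos,ref,alt vectors describing the variants; \code{pos}
#'   is the 1-based VCF-style position (anchor base for indels); alleles on
#'   the forward genomic strand.
#' @param zygosity \code{"hom"} or \code{"het"} per record.
#' @param snpId optional ids; defaults to \code{scaffold_position} where the
#'   position is the variant base itself (\code{pos} for SNVs, \code{pos + 1}
#'   for indels, whose first changed base follows the anchor).
#' @return data.frame with columns snpId, scaffold, pos, ref, alt, class,
#'   zygosity.
#' @export
variantTable <- function(scaffold, pos, ref, alt, zygosity = "hom",
                         snpId = NULL) {
  pos <- as.integer(pos)
  cls <- if (length(pos)) mapply(classifyVariant, ref, alt, USE.NAMES = FALSE)
         else character()
  evt <- ifelse(cls == "SNV" | cls == "MNV", pos, pos + 1L)
  default <- paste0(scaffold, "_", evt)
  snpId <- if (is.null(snpId)) default else ifelse(is.na(snpId), default, snpId)
  data.frame(snpId = snpId, scaffold = as.character(scaffold), pos = pos,
             ref = ref, alt = alt, class = cls,
             zygosity = rep_len(zygosity, length(pos)),
             stringsAsFactors = FALSE)
}

#' Score and filter variant records on genomic context
#'
#' A record survives iff (when requested) it is homozygous, its context
#' complexity is >= \code{complexityMin}, its uniqueness is strictly above
#' \code{uniquenessMin} and its GC fraction lies within
#' \code{[gcMin, gcMax]}. Degenerate (all-N) contexts are flagged
#' \code{"no-context"} rather than silently dropped.
#'
#' @param variants a variant table (see \code{\link{variantTable}}).
#' @param genome \code{DNAStringSet}.
#' @param config a \code{\link{filterConfig}}.
#' @return list with \code{pass} (surviving records), \code{scores}
#'   (per-record ContextScores: gc, complexity, uniqueness, pass flag and
#'   comma-joined rejection \code{reasons}).
#' @export
applyFilters <- function(variants, genome, config = filterConfig()) {
  n <- nrow(variants)
  gc <- cx <- uq <- rep(NA_real_, n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    sc <- variants$scaffold[i]; p <- variants$pos[i]
    gc[i] <- gcFraction(genome, sc, p, config$windowBp)
    cx[i] <- linguisticComplexity(genome, sc, p, config$windowBp, config$complexityK)
    uq[i] <- uniquenessScore(genome, sc, p, config$windowBp, config$kmerLen)
    fail <- character()
    if (config$homozygousOnly && !identical(variants$zygosity[i], "hom"))
      fail <- c(fail, "zygosity")
    if (is.na(gc[i]) || is.na(uq[i])) fail <- c(fail, "no-context")
    else {
      if (cx[i] < config$complexityMin) fail <- c(fail, "complexity")
      if (uq[i] <= config$uniquenessMin) fail <- c(fail, "uniqueness")
      if (gc[i] < config$gcMin || gc[i] > config$gcMax) fail <- c(fail, "gc")
    }
    reasons[i] <- paste(fail, collapse = ",")
  }
  scores <- data.frame(snpId = variants$snpId, gc = gc, complexity = cx,
                       uniqueness = uq, pass = !nzchar(reasons),
                       reasons = reasons, stringsAsFactors = FALSE)
  list(pass = variants[scores$pass, , drop = FALSE], scores = scores)
}

## ---- I/O ------------------------------------------------------------------

#' Read variants from TSV or minimal VCF
#'
#' TSV columns: snp_id, scaffold, pos, ref, alt, zygosity (header required).
#' Minimal VCF v4.2: CHROM POS ID REF ALT (+ optional FORMAT/GT column pair,
#' from which zygosity is derived; otherwise records are taken as homozygous).
#'
#' @param path input file; format inferred from the extension unless given.
#' @param format \code{"auto"}, \code{"tsv"} or \code{"vcf"}.
#' @return variant table as from \code{\link{variantTable}}.
#' @export
readVariants <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "tsv") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    names(d) <- tolower(names(d))
    variantTable(d$scaffold, d$pos, d$ref, d$alt,
                 zygosity = if ("zygosity" %in% names(d)) d$zygosity else "hom",
                 snpId = if ("snp_id" %in% names(d)) d$snp_id else NULL)
  } else {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (!length(body)) {
      return(variantTable(character(), integer(), character(), character())[0, ])
    }
    f <- strsplit(body, "\t", fixed = TRUE)
    getcol <- function(i) vapply(f, `[[`, character(1), i)
    zyg <- rep("hom", length(f))
    if (all(lengths(f) >= 10L)) {
      fmt <- strsplit(getcol(9), ":", fixed = TRUE)
      smp <- strsplit(getcol(10), ":", fixed = TRUE)
      gt <- mapply(function(a, b) {
        i <- match("GT", a); if (is.na(i)) NA_character_ else b[[i]]
      }, fmt, smp)
      al <- strsplit(gsub("\\|", "/", gt), "/", fixed = FALSE)
      zyg <- vapply(al, function(a)
        if (length(a) > 1L && length(unique(a)) == 1L) "hom" else "het",
        character(1))
      zyg[is.na(gt)] <- "hom"
    }
    id <- getcol(3)
    variantTable(getcol(1), as.integer(getcol(2)), getcol(4), getcol(5),
                 zygosity = zyg, snpId = ifelse(id == ".", NA, id))
  }
}

#' Write a variant table as minimal VCF v4.2
#'
#' @param variants variant table.
#' @param path output file.
#' @param info optional character vector of INFO strings, one per record.
#' @return \code{path}, invisibly.
#' @export
writeVariantsVcf <- function(variants, path, info = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mut2func",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (is.null(info)) info <- rep(".", nrow(variants))
  rows <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                  variants$scaffold, variants$pos, variants$snpId,
                  variants$ref, variants$alt, info)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
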