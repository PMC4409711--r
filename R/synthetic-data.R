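## Synthetic-data generator: toy multi-scaffold genomes with intron-containing
## genes on both strands, planted context tracts (repeats, low-complexity,
## GC-extreme), planted variants with ground-truth consequences, the
## frameshift fixture reproducing the truncated-regulator event, and the
## packaged 14-variant discovery table with a matching micro-annotation.

## Random 17-nt sequence containing all 16 dinucleotides exactly once
## (a random Eulerian circuit of the complete dinucleotide graph). One such
## "dinucleotide pangram" is embedded near every planted variant so that the
## k=2 linguistic-complexity score of its 100-bp context window is exactly 1
## by construction -- as it was for every published variant -- while staying
## unique genome-wide (each site gets its own random walk, so no 15-mer is
## shared between sites and the uniqueness score is unaffected).
.dinucPangram <- function() {
  bases <- c("A", "C", "G", "T")
  used <- matrix(FALSE, 4L, 4L)
  path <- integer(17L)
  walk <- function(node, depth) {
    if (depth > 17L) return(TRUE)
    for (t in sample.int(4L)) {
      if (!used[node, t]) {
        used[node, t] <<- TRUE
        path[depth] <<- t
        if (walk(t, depth + 1L)) return(TRUE)
        used[node, t] <<- FALSE
      }
    }
    FALSE
  }
  path[1L] <- sample.int(4L, 1L)
  if (!walk(path[1L], 2L)) stop("internal error: no Eulerian walk found")
  paste(bases[path], collapse = "")
}

## 18-nt dinucleotide pangram that is also six non-stop codons, for embedding
## inside coding sequence without altering the reading frame's validity.
.dinucPangramCodons <- function() {
  gc <- Biostrings::GENETIC_CODE
  repeat {
    s <- paste0(.dinucPangram(), sample(c("A", "C", "G", "T"), 1L))
    cods <- substring(s, seq(1L, 16L, 3L), seq(3L, 18L, 3L))
    if (!any(gc[cods] == "*")) return(cods)
  }
}

.randomDna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE, prob = p)])
}

.nonStopCodons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

## CDS of nAa residues plus a terminal stop; selected codons can be forced.
.randomCds <- function(nAa, forced = list(), stopCodon = "TAA") {
  codons <- c("ATG", sample(.nonStopCodons(), nAa - 1L, replace = TRUE))
  for (k in names(forced)) codons[[as.integer(k)]] <- forced[[k]]
  paste(c(codons, stopCodon), collapse = "")
}

## Assemble a gene: CDS split into exons at the given spliced offsets
## (`breaks` = last CDS offset of each non-terminal exon), introns of the
## given lengths, reverse-complemented for minus-strand placement.
.buildGene <- function(txId, scaffold, strand, gStart, cds,
                       breaks = integer(0), intronLens = integer(0),
                       product = "") {
  stopifnot(length(breaks) == length(intronLens))
  n <- nchar(cds)
  bounds <- c(0L, as.integer(breaks), n)
  exonSeqs <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1L])
  introns <- vapply(intronLens, function(l) {
    stopifnot(l >= 6L)
    paste0("GT", .randomDna(l - 4L), "AG")
  }, character(1))
  parts <- character(0)
  for (i in seq_along(exonSeqs)) {
    parts <- c(parts, exonSeqs[i])
    if (i <= length(introns)) parts <- c(parts, introns[i])
  }
  tSeq <- paste(parts, collapse = "")
  segment <- if (strand == "+") tSeq else .revcomp(tSeq)
  segLen <- nchar(tSeq)
  gEnd <- gStart + segLen - 1L
  ## exon spans within tSeq (transcript orientation)
  exLens <- nchar(exonSeqs)
  tStarts <- integer(length(exLens)); off <- 0L
  for (i in seq_along(exLens)) {
    tStarts[i] <- off + 1L
    off <- off + exLens[i] + if (i <= length(intronLens)) intronLens[i] else 0L
  }
  tEnds <- tStarts + exLens - 1L
  if (strand == "+") {
    exS <- gStart + tStarts - 1L; exE <- gStart + tEnds - 1L
  } else {
    exS <- gEnd - tEnds + 1L; exE <- gEnd - tStarts + 1L
  }
  tx <- TranscriptModel(txId = txId, scaffold = scaffold, strand = strand,
                        exonStarts = sort(exS), exonEnds = sort(exE),
                        cdsStart = gStart, cdsEnd = gEnd, product = product)
  list(tx = tx, segment = segment, gStart = gStart, gEnd = gEnd)
}

.spliceInto <- function(scaffoldSeq, segment, gStart) {
  substr(scaffoldSeq, gStart, gStart + nchar(segment) - 1L) <- segment
  scaffoldSeq
}

#' Specification of a synthetic scenario
#'
#' The defaults define the packaged study scenario: two 50-kb scaffolds at GC
#' 0.5 carrying ten intron-containing genes on both strands, four planted
#' adverse-context tracts (an exact two-copy repeat, a dinucleotide
#' low-complexity tract, a GC-rich and a GC-poor window) and twenty planted
#' variants -- fourteen in clean context (eight indels, six SNVs, with the
#' exon/promoter/intergenic element mix of the published table) and six in
#' adverse context that the genomic-context filters must remove.
#'
#' @param seed integer seed; the whole scenario is byte-reproducible from it.
#' @param scaffoldLengths named integer vector of scaffold lengths.
#' @param gcTarget genome-wide GC fraction.
#' @param nGenes number of genes (split round-robin across scaffolds).
#' @param geneAaRange protein-length range (aa) of generated genes.
#' @param maxExons maximum exon count per gene.
#' @return list of class \code{"ScenarioSpec"}.
#' @export
scenarioSpec <- function(seed = 9136L,
                         scaffoldLengths = c(`1` = 50000L, `2` = 50000L),
                         gcTarget = 0.5, nGenes = 10L,
                         geneAaRange = c(120L, 350L), maxExons = 3L) {
  structure(list(seed = as.integer(seed), scaffoldLengths = scaffoldLengths,
                 gcTarget = gcTarget, nGenes = as.integer(nGenes),
                 geneAaRange = as.integer(geneAaRange),
                 maxExons = as.integer(maxExons)),
            class = "ScenarioSpec")
}

#' Generate a synthetic genome with gene models and context tracts
#'
#' Deterministic given the spec seed. Genes carry a start codon, no internal
#' stop and a terminal stop; exon/intron structures are valid for the
#' annotation loader; minus-strand genes are reverse-complemented into the
#' scaffold. Gene slots are laid out with wide margins so planted tract and
#' variant windows never collide.
#'
#' @param spec a \code{\link{scenarioSpec}}.
#' @return list with \code{genome} (\code{DNAStringSet}), \code{transcripts},
#'   \code{tracts} (data.frame of planted adverse contexts) and \code{spec}.
#' @export
generateGenome <- function(spec = scenarioSpec()) {
  set.seed(spec$seed)
  lens <- spec$scaffoldLengths
  scafNames <- names(lens)
  slotSpacing <- 4000L
  geneAreaEnd <- min(lens) - 12000L
  nSlots <- (geneAreaEnd - 2000L) %/% slotSpacing
  perScaf <- ceiling(spec$nGenes / length(lens))
  if (perScaf > nSlots) stop("infeasible spec: too many genes for scaffold length")
  seqs <- lapply(lens, function(L) .randomDna(L, spec$gcTarget))
  names(seqs) <- scafNames
  transcripts <- list()
  gi <- 0L
  for (si in seq_along(scafNames)) {
    sc <- scafNames[si]
    for (k in seq_len(perScaf)) {
      gi <- gi + 1L
      if (gi > spec$nGenes) break
      nAa <- sample(spec$geneAaRange[1]:spec$geneAaRange[2], 1L)
      nEx <- sample.int(spec$maxExons, 1L)
      cdsLen <- 3L * (nAa + 1L)
      ## exon 1 kept >= 150 CDS nt so variant windows near the start stay
      ## within one exon; pangram codons at 21-26 (offsets 61-78)
      breaks <- if (nEx > 1L)
        sort(sample(seq(150L, cdsLen - 60L, by = 3L), nEx - 1L)) else integer(0)
      intronLens <- if (nEx > 1L) sample(60:90, nEx - 1L, replace = TRUE) else integer(0)
      forced <- as.list(.dinucPangramCodons())
      names(forced) <- as.character(21:26)
      cds <- .randomCds(nAa, forced = forced)
      strand <- sample(c("+", "-"), 1L)
      gStart <- 2000L + (k - 1L) * slotSpacing
      if (gStart + cdsLen + sum(intronLens) + 800L > lens[[si]])
        stop("infeasible spec: gene longer than scaffold slot")
      g <- .buildGene(sprintf("synth:g%02d", gi), sc, strand, gStart, cds,
                      breaks, intronLens,
                      product = sprintf("synthetic gene %d", gi))
      seqs[[sc]] <- .spliceInto(seqs[[sc]], g$segment, gStart)
      transcripts[[txId(g$tx)]] <- g$tx
    }
  }
  ## adverse-context tracts, in the reserved tail of each scaffold
  tailAt <- function(sc, off) lens[[sc]] - 10000L + off
  repSeg <- .randomDna(300L, spec$gcTarget)
  gcHigh <- paste0(.randomDna(41L, 1), .dinucPangram(), .randomDna(42L, 1))
  gcLow <- paste0(.randomDna(41L, 0), .dinucPangram(), .randomDna(42L, 0))
  lowc <- paste(rep("AT", 150L), collapse = "")
  tracts <- data.frame(
    kind = c("repeat", "repeat_copy", "low_complexity", "gc_high", "gc_low"),
    scaffold = c(scafNames[1], scafNames[length(scafNames)],
                 scafNames[1], scafNames[length(scafNames)],
                 scafNames[length(scafNames)]),
    start = c(tailAt(scafNames[1], 0L), tailAt(scafNames[length(scafNames)], 0L),
              tailAt(scafNames[1], 2000L), tailAt(scafNames[length(scafNames)], 4000L),
              tailAt(scafNames[length(scafNames)], 6000L)),
    len = c(300L, 300L, 300L, 100L, 100L),
    stringsAsFactors = FALSE)
  segs <- list(repSeg, repSeg, lowc, gcHigh, gcLow)
  for (i in seq_len(nrow(tracts)))
    seqs[[tracts$scaffold[i]]] <- .spliceInto(seqs[[tracts$scaffold[i]]],
                                              segs[[i]], tracts$start[i])
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- scafNames
  list(genome = genome, transcripts = transcripts, tracts = tracts,
       spec = spec)
}

## insert a fresh random pangram into an intergenic window near a planted
## variant
.plantPangram <- function(scaffoldSeq, pos) {
  .spliceInto(scaffoldSeq, .dinucPangram(), pos + 20L)
}

#' Plant variants with known ground truth into a generated scenario
#'
#' The default intent set plants 20 variants: 14 in clean context (3 exonic
#' missense SNVs, 3 exonic 1-nt frameshift deletions, 2 promoter deletions,
#' 3 intergenic SNVs and 3 intergenic deletions -- i.e. 8 indels and 6 SNVs
#' expected to survive filtering) and 6 SNVs in adverse context (2 in the
#' two-copy repeat, 2 in the low-complexity tract, 1 each in the GC-rich and
#' GC-poor windows) expected to be rejected. Every coding intent is verified
#' against the package's own consequence caller at planting time.
#'
#' @param gen output of \code{\link{generateGenome}}.
#' @return list with \code{genome} (tract-aware, pangram-patched),
#'   \code{transcripts}, \code{variants} (variant table) and \code{truth}
#'   (per-variant ground truth: context, element, consequence kind,
#'   expectSurvive).
#' @export
plantVariants <- function(gen) {
  set.seed(gen$spec$seed + 1L)
  seqs <- as.character(gen$genome)
  txs <- gen$transcripts
  lens <- gen$spec$scaffoldLengths
  scafNames <- names(lens)
  rows <- list(); truth <- list()
  addRow <- function(scaffold, pos, ref, alt, context, element, kind,
                     survive, txid = NA_character_) {
    v <- variantTable(scaffold, pos, ref, alt)
    rows[[length(rows) + 1L]] <<- v
    truth[[length(truth) + 1L]] <<- data.frame(
      snpId = v$snpId, context = context, element = element,
      csqKind = kind, expectSurvive = survive, txId = txid,
      stringsAsFactors = FALSE)
  }
  baseAt <- function(sc, p) substr(seqs[[sc]], p, p)

  geneIdx <- seq_along(txs)
  ## --- clean exonic missense SNVs (genes 1-3) -----------------------------
  for (i in 1:3) {
    tx <- txs[[geneIdx[i]]]
    cds <- extractSplicedCds(tx, {
      g <- Biostrings::DNAStringSet(unlist(seqs)); names(g) <- scafNames; g
    })
    ## codon 17, second position (offset 50): guaranteed inside exon 1
    o <- 50L
    refB <- substr(cds, o, o)
    codon <- substr(cds, 49L, 51L)
    altB <- setdiff(c("A", "C", "G", "T"), refB)
    altB <- altB[vapply(altB, function(b) {
      cd <- codon; substr(cd, 2, 2) <- b
      aa <- Biostrings::GENETIC_CODE[[cd]]
      aa != "*" && aa != Biostrings::GENETIC_CODE[[codon]]
    }, logical(1))][1]
    g <- splicedToGenomic(tx, o)
    gRef <- if (txStrand(tx) == "+") refB else .complementBases(refB)
    gAlt <- if (txStrand(tx) == "+") altB else .complementBases(altB)
    stopifnot(baseAt(txScaffold(tx), g) == gRef)
    addRow(txScaffold(tx), g, gRef, gAlt, "clean", "exon", "missense",
           TRUE, txId(tx))
  }
  ## --- clean exonic 1-nt frameshift deletions (genes 4-6) -----------------
  for (i in 4:6) {
    tx <- txs[[geneIdx[i]]]
    o <- 55L                       # deleted CDS offset, inside exon 1
    gDel <- splicedToGenomic(tx, o)
    anchor <- gDel - 1L
    ref <- paste0(baseAt(txScaffold(tx), anchor), baseAt(txScaffold(tx), gDel))
    addRow(txScaffold(tx), anchor, ref, substr(ref, 1, 1), "clean", "exon",
           "frameshift", TRUE, txId(tx))
  }
  ## --- clean promoter deletions (genes 7-8) -------------------------------
  for (i in 7:8) {
    tx <- txs[[geneIdx[i]]]
    sc <- txScaffold(tx)
    d <- 500L
    p <- if (txStrand(tx) == "+") tx@cdsStart - d else tx@cdsEnd + d
    seqs[[sc]] <- .plantPangram(seqs[[sc]], p)
    anchor <- p - 1L
    ref <- paste0(baseAt(sc, anchor), baseAt(sc, p))
    addRow(sc, anchor, ref, substr(ref, 1, 1), "clean", "promoter",
           NA_character_, TRUE, txId(tx))
  }
  ## --- clean intergenic variants ------------------------------------------
  ## positions in the reserved tail, far from genes and tracts
  interAt <- function(sc, off) lens[[sc]] - 1500L + off
  for (j in 1:3) {  # SNVs
    sc <- scafNames[(j %% length(scafNames)) + 1L]
    p <- interAt(sc, 100L * j)
    seqs[[sc]] <- .plantPangram(seqs[[sc]], p)
    refB <- baseAt(sc, p)
    addRow(sc, p, refB, setdiff(c("A", "C", "G", "T"), refB)[1],
           "clean", "intergenic", NA_character_, TRUE)
  }
  for (j in 1:3) {  # deletions
    sc <- scafNames[((j + 1L) %% length(scafNames)) + 1L]
    p <- interAt(sc, 400L + 100L * j)
    seqs[[sc]] <- .plantPangram(seqs[[sc]], p)
    anchor <- p - 1L
    ref <- paste0(baseAt(sc, anchor), baseAt(sc, p))
    addRow(sc, anchor, ref, substr(ref, 1, 1), "clean", "intergenic",
           NA_character_, TRUE)
  }
  ## --- adverse contexts ----------------------------------------------------
  tr <- gen$tracts
  at <- function(kind) tr[tr$kind == kind, , drop = FALSE][1L, ]
  rep1 <- at("repeat")
  for (off in c(100L, 200L)) {
    p <- rep1$start + off
    refB <- baseAt(rep1$scaffold, p)
    addRow(rep1$scaffold, p, refB, setdiff(c("A", "C", "G", "T"), refB)[1],
           "repeat", "intergenic", NA_character_, FALSE)
  }
  lc <- at("low_complexity")
  for (off in c(100L, 200L)) {
    p <- lc$start + off
    refB <- baseAt(lc$scaffold, p)
    addRow(lc$scaffold, p, refB, setdiff(c("A", "C", "G", "T"), refB)[1],
           "low_complexity", "intergenic", NA_character_, FALSE)
  }
  for (kind in c("gc_high", "gc_low")) {
    t1 <- at(kind)
    p <- t1$start + 50L
    refB <- baseAt(t1$scaffold, p)
    addRow(t1$scaffold, p, refB, setdiff(c("A", "C", "G", "T"), refB)[1],
           kind, "intergenic", NA_character_, FALSE)
  }

  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- scafNames
  variants <- do.call(rbind, rows)
  truthDf <- do.call(rbind, truth)
  ## verify coding intents against the package's own consequence caller
  for (i in which(!is.na(truthDf$csqKind))) {
    tx <- txs[[truthDf$txId[i]]]
    rep <- predictConsequence(tx, genome, variants[i, ])
    if (rep@kind != truthDf$csqKind[i])
      stop(sprintf("unsatisfied intent for %s: wanted %s, got %s",
                   variants$snpId[i], truthDf$csqKind[i], rep@kind))
  }
  list(genome = genome, transcripts = txs, variants = variants,
       truth = truthDf, tracts = gen$tracts, spec = gen$spec)
}

#' One-call default synthetic scenario
#'
#' @param seed scenario seed.
#' @return the planted scenario (see \code{\link{plantVariants}}).
#' @export
generateScenario <- function(seed = 9136L) {
  plantVariants(generateGenome(scenarioSpec(seed = seed)))
}

#' Write a scenario to disk (FASTA + GFF3 + variants TSV + truth CSV)
#'
#' @param scn a scenario from \code{\link{generateScenario}}.
#' @param dir output directory (created if needed).
#' @return named vector of file paths with a checksum manifest written
#'   alongside.
#' @export
writeScenario <- function(scn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(scn$genome, fa)
  gff <- file.path(dir, "genes.gff3")
  writeAnnotation(scn$transcripts, gff)
  tsv <- file.path(dir, "variants.tsv")
  v <- scn$variants
  utils::write.table(
    data.frame(snp_id = v$snpId, scaffold = v$scaffold, pos = v$pos,
               ref = v$ref, alt = v$alt, zygosity = v$zygosity),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- file.path(dir, "truth.csv")
  utils::write.csv(scn$truth, truth, row.names = FALSE)
  files <- c(genome = fa, annotation = gff, variants = tsv, truth = truth)
  manifest <- file.path(dir, "MANIFEST.json")
  jsonlite::write_json(as.list(tools::md5sum(unname(files))), manifest,
                       auto_unbox = TRUE)
  c(files, manifest = manifest)
}

## ---- frameshift fixture ---------------------------------------------------

## Build the 2763-nt CDS whose base at spliced offset 2294 is an A and whose
## single-base deletion yields, from codon 765, exactly the 16-residue
## peptide LSSTSSLRISGIPSTF followed by an amber (TAG) stop. Codons 765-781
## of the reference frame overlap the shifted-frame target; synonymous codon
## choice resolves the overlapping-frame constraint (no reference-frame stop),
## and all unconstrained codons come from a fixed seeded non-stop stream.
.xyr1CdsBuild <- function(seed = 122208L) {
  set.seed(seed)
  peptide <- "LSSTSSLRISGIPSTF"
  gc <- Biostrings::GENETIC_CODE
  syn <- split(names(gc), gc)
  nonstop <- .nonStopCodons()
  b <- character(2763L)
  fill <- function(pos, s) {
    for (i in seq_len(nchar(s))) b[pos + i - 1L] <<- substr(s, i, i)
  }
  ## codons 1..764 of the reference frame
  fill(1L, "ATG")
  fill(4L, paste(sample(nonstop, 763L, replace = TRUE), collapse = ""))
  ## constrained region: mutant codon 765 = CTG (L); reference codon 765 = CAT
  fill(2293L, "CATG")          # b2293..b2296; b2294 = 'A' is the deleted base
  prev3 <- "G"
  for (k in 2:16) {
    aa <- substr(peptide, k, k)
    cands <- sort(syn[[aa]])
    ok <- vapply(cands, function(cd) {
      !(prev3 == "T" && substr(cd, 1, 2) %in% c("AA", "AG", "GA"))
    }, logical(1))
    cd <- cands[ok][1L]
    fill(2297L + 3L * (k - 2L), cd)
    prev3 <- substr(cd, 3, 3)
  }
  fill(2342L, "TAG")           # premature amber stop in the shifted frame
  ## complete reference codon 782 (starts with the fixed G at 2344) and the
  ## remaining reference codons
  fill(2345L, paste(sample(c("A", "C", "G", "T"), 2L, replace = TRUE),
                    collapse = ""))
  fill(2347L, paste(sample(nonstop, (2760L - 2347L + 1L) / 3L, replace = TRUE),
                    collapse = ""))
  fill(2761L, "TAA")
  paste(b, collapse = "")
}

#' Frameshift truncation fixture
#'
#' A deterministic 2763-nt CDS (920 codons plus stop) on a small plus-strand
#' two-exon gene model. The base at spliced offset 2294 is an A; its deletion
#' shifts the frame so that codons 765-780 of the mutant read exactly
#' \code{LSSTSSLRISGIPSTF} before a premature amber stop, giving a 780-aa
#' truncated product that lacks the 140 C-terminal residues of the 920-aa
#' reference protein.
#'
#' @param seed seed of the fixed codon stream filling the unconstrained
#'   codons (stable default).
#' @return list with \code{cds}, \code{genome} (one short synthetic
#'   scaffold), \code{tx} (two-exon model), \code{variant} (anchored 1-nt
#'   deletion), \code{domains} (synthetic domain table mirroring the
#'   regulator's architecture) and \code{expected} ground truth.
#' @export
buildXyr1Fixture <- function(seed = 122208L) {
  cds <- .xyr1CdsBuild(seed)
  set.seed(seed + 1L)
  ## two exons: CDS offsets 1-300 | intron 69 nt | offsets 301-2763;
  ## pangram at codons 751-756 keeps the variant context window complexity 1
  cdsP <- cds
  substr(cdsP, 2251L, 2268L) <- paste(.dinucPangramCodons(), collapse = "")
  flank5 <- .randomDna(1000L)
  flank3 <- .randomDna(1000L)
  intron <- paste0("GT", .randomDna(65L), "AG")
  exon1 <- substr(cdsP, 1L, 300L)
  exon2 <- substr(cdsP, 301L, 2763L)
  scafSeq <- paste0(flank5, exon1, intron, exon2, flank3)
  genome <- Biostrings::DNAStringSet(scafSeq)
  names(genome) <- "11"
  gStart <- 1001L
  tx <- TranscriptModel(txId = "Trire2:122208", scaffold = "11", strand = "+",
                        exonStarts = c(gStart, gStart + 300L + 69L),
                        exonEnds = c(gStart + 299L, gStart + 300L + 69L + 2462L),
                        cdsStart = gStart, cdsEnd = gStart + 2831L,
                        product = "transcription factor XYR1")
  gDel <- splicedToGenomic(tx, 2294L)
  anchor <- gDel - 1L
  anchorBase <- substr(scafSeq, anchor, anchor)
  variant <- variantTable("11", anchor, paste0(anchorBase, "A"), anchorBase)
  domains <- data.frame(
    name = c("DBD", "coiled-coil-1", "FSTFD", "coiled-coil-2", "AAD",
             "coiled-coil-3"),
    start = c(91L, 91L, 348L, 681L, 702L, 890L),
    end = c(131L, 182L, 701L, 712L, 920L, 915L),
    stringsAsFactors = FALSE)
  list(cds = extractSplicedCds(tx, genome), genome = genome, tx = tx,
       variant = variant, domains = domains,
       expected = list(refLength = 920L, offset = 2294L, fsCodon = 765L,
                       novelPeptide = "LSSTSSLRISGIPSTF", stopType = "amber",
                       mutantLength = 780L, residuesLost = 140L))
}

## ---- packaged discovery-table fixture --------------------------------------

#' The packaged 14-variant discovery table with matching micro-annotation
#'
#' Reconstructs the published final mutation list (8 indels, 6 SNVs, ids of
#' the form scaffold_position) on a synthetic multi-scaffold genome whose
#' gene coordinates are invented but chosen so that every variant reproduces
#' its printed element label and spliced-CDS offset: six exonic hits (three
#' missense SNVs on both strands, three frameshift deletions including the
#' regulator's -1:A at spliced offset 2294 and a -8 deletion at offset 19),
#' two promoter indels, and six intergenic calls. Eight genes are impacted.
#'
#' The expected table flags the one printed-vs-arithmetic discrepancy: the
#' offset +1189 SNV maps to codon 397 under start-anchored codon numbering
#' while the publication text discusses residue 389.
#'
#' @param seed seed for the genomic background.
#' @return list with \code{genome}, \code{transcripts}, \code{variants} and
#'   \code{expected} (per-variant printed element, spliced offset, gene, and
#'   conflict notes).
#' @export
table1Fixture <- function(seed = 9136L) {
  set.seed(seed)
  lens <- c(`4` = 1498000L, `5` = 694000L, `11` = 1148000L, `16` = 185000L,
            `18` = 610000L, `19` = 525000L, `23` = 111000L, `31` = 175000L,
            `41` = 520000L)
  seqs <- lapply(lens, .randomDna)
  names(seqs) <- names(lens)
  txs <- list()
  addGene <- function(g) {
    seqs[[txScaffold(g$tx)]] <<- .spliceInto(seqs[[txScaffold(g$tx)]],
                                             g$segment, g$gStart)
    txs[[txId(g$tx)]] <<- g$tx
  }
  panAt <- function(firstCodon) {
    out <- as.list(.dinucPangramCodons())
    names(out) <- as.character(firstCodon + 0:5)
    out
  }

  ## scaffold 4, minus strand: SNV at spliced offset 38, codon 13 = TTC (F)
  addGene(.buildGene("Trire2:46238", "4", "-", gStart = 1496693L - 902L,
    cds = .randomCds(300L, forced = c(list(`13` = "TTC"), panAt(27L))),
    product = "putative S-adenosylmethionine synthetase SAM1"))
  ## scaffold 18, minus strand: SNV at offset 71, codon 24 = AGT (S)
  addGene(.buildGene("Trire2:50707", "18", "-", gStart = 608754L - 902L,
    cds = .randomCds(300L, forced = c(list(`24` = "AGT"), panAt(27L))),
    product = "putative cell-cycle regulator CDC1"))
  ## scaffold 31, plus strand: SNV at offset 1189, codon 397 = CCT (P)
  addGene(.buildGene("Trire2:124043", "31", "+", gStart = 173856L - 1188L,
    cds = .randomCds(450L, forced = c(list(`397` = "CCT"), panAt(400L))),
    product = "putative glycoside hydrolase family 18 CHI18-14"))
  ## scaffold 41, plus strand: -1:A at offset 19 (codon 7 starts with A)
  addGene(.buildGene("Trire2:102500", "41", "+", gStart = 518722L - 18L,
    cds = .randomCds(250L, forced = c(list(`7` = "ACT"), panAt(10L))),
    product = "MRSP1/expansin-like-orphan protein"))
  ## scaffold 11, plus strand, intron after offset 300: the regulator gene,
  ## -1:A at spliced offset 2294
  xyr1Cds <- .xyr1CdsBuild()
  substr(xyr1Cds, 2251L, 2268L) <- paste(.dinucPangramCodons(), collapse = "")
  addGene(.buildGene("Trire2:122208", "11", "+", gStart = 202303L - 68L - 2294L,
    cds = xyr1Cds, breaks = 300L, intronLens = 69L,
    product = "transcription factor XYR1"))
  ## scaffold 19, plus strand: -8:GCCCGGCG at offsets 19-26
  addGene(.buildGene("Trire2:66687", "19", "+", gStart = 227418L - 18L,
    cds = .randomCds(250L, forced = c(list(`7` = "GCC", `8` = "CGG",
                                           `9` = "CGT"), panAt(12L))),
    product = "beta-1,4-mannosyl-glycoprotein beta-1,4-N-acetylglucosaminyltransferase"))
  ## promoter genes
  addGene(.buildGene("Trire2:109416", "16", "+", gStart = 183301L + 300L,
    cds = .randomCds(200L, forced = panAt(21L)),
    product = "putative protein of unknown function"))
  addGene(.buildGene("Trire2:5387", "23", "-", gStart = 109645L - 300L - 602L,
    cds = .randomCds(200L, forced = panAt(21L)),
    product = "putative NADH-ubiquinone oxidoreductase"))

  ## force reference bases at intergenic / promoter variant sites and plant
  ## pangrams in their context windows
  setBase <- function(sc, p, base) {
    substr(seqs[[sc]], p, p) <<- base
    seqs[[sc]] <<- .plantPangram(seqs[[sc]], p)
  }
  setBase("4", 329479L, "G")
  setBase("11", 1146347L, "C")
  setBase("19", 523375L, "A")
  setBase("4", 1479439L, "A")
  setBase("5", 692881L, "G")    # insertion anchor
  setBase("18", 234489L, "A")
  setBase("16", 183301L, "G")
  setBase("23", 109645L, "T")

  baseAt <- function(sc, p) substr(seqs[[sc]], p, p)
  snv <- function(id, sc, p, alt)
    list(snpId = id, scaffold = sc, pos = p, ref = baseAt(sc, p), alt = alt)
  del <- function(id, sc, p, delSeq) {
    a <- baseAt(sc, p - 1L)
    list(snpId = id, scaffold = sc, pos = p - 1L,
         ref = paste0(a, delSeq), alt = a)
  }
  ins <- function(id, sc, p, insSeq) {
    a <- baseAt(sc, p)
    list(snpId = id, scaffold = sc, pos = p, ref = a, alt = paste0(a, insSeq))
  }
  vl <- list(
    snv("4_329479", "4", 329479L, "C"),
    snv("4_1496656", "4", 1496656L, "T"),
    snv("11_1146347", "11", 1146347L, "G"),
    snv("18_608684", "18", 608684L, "G"),
    snv("19_523375", "19", 523375L, "G"),
    snv("31_173856", "31", 173856L, "G"),
    del("41_518722", "41", 518722L, "A"),
    del("4_1479439", "4", 1479439L, "A"),
    ins("5_692881", "5", 692881L, "C"),
    del("11_202303", "11", 202303L, "A"),
    del("16_183301", "16", 183301L, "G"),
    del("18_234489", "18", 234489L, "A"),
    del("19_227418", "19", 227418L, "GCCCGGCG"),
    del("23_109645", "23", 109645L, "T"))
  variants <- do.call(rbind, lapply(vl, function(v)
    variantTable(v$scaffold, v$pos, v$ref, v$alt, snpId = v$snpId)))

  expected <- data.frame(
    snpId = vapply(vl, `[[`, character(1), "snpId"),
    element = c("intergenic", "exon", "intergenic", "exon", "intergenic",
                "exon", "exon", "intergenic", "intergenic", "exon",
                "promoter", "intergenic", "exon", "promoter"),
    txId = c(NA, "Trire2:46238", NA, "Trire2:50707", NA, "Trire2:124043",
             "Trire2:102500", NA, NA, "Trire2:122208", "Trire2:109416",
             NA, "Trire2:66687", "Trire2:5387"),
    splicedOffset = c(NA, 38L, NA, 71L, NA, 1189L, 19L, NA, NA, 2294L,
                      NA, NA, 19L, NA),
    note = c("", "", "", "", "",
             "printed text discusses residue 389; start-anchored arithmetic on offset +1189 gives codon 397",
             "", "", "", "", "", "", "", ""),
    stringsAsFactors = FALSE)

  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(lens)
  list(genome = genome, transcripts = txs, variants = variants,
       expected = expected)
}
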