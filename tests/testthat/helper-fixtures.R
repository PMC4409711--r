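## Session-level caches for the heavier generated fixtures, shared across
## test files, plus the property-check drivers reused by the acceptance
## suite.

.cache <- new.env(parent = emptyenv())

cachedTable1 <- function() {
  if (is.null(.cache$t1)) .cache$t1 <- table1Fixture()
  .cache$t1
}

cachedScenario <- function() {
  if (is.null(.cache$scn)) .cache$scn <- generateScenario(9136L)
  .cache$scn
}

cachedXyr1 <- function() {
  if (is.null(.cache$xyr1)) .cache$xyr1 <- buildXyr1Fixture()
  .cache$xyr1
}

## coordinate mapping vs exhaustive oracle over randomized models;
## returns the number of disagreements (0 expected)
checkMappingOracle <- function(nModels = 120L, seed = 42L) {
  set.seed(seed)
  bad <- 0L
  for (i in seq_len(nModels)) {
    m <- randomModel()
    cdsPos <- oracleCdsPositions(m$tx)
    for (g in cdsPos) {
      o <- genomicToSpliced(m$tx, g)
      if (!identical(o$region, "cds") ||
          o$offset != oracleOffsetOf(m$tx, g) ||
          splicedToGenomic(m$tx, o$offset) != g) bad <- bad + 1L
    }
    if (extractSplicedCds(m$tx, m$genome) != oracleSplicedCds(m$tx, m$scaf))
      bad <- bad + 1L
  }
  bad
}

## consequence prediction vs independent genome-level mutation + translation
## over randomized clean genes; returns number of disagreements
checkConsequenceOracle <- function(nCases = 120L, seed = 43L) {
  set.seed(seed)
  bad <- 0L
  for (i in seq_len(nCases)) {
    g <- randomCleanGene()
    cdsLen <- nchar(g$cds)
    type <- sample(c("snv", "del", "ins"), 1)
    ## pick an interior CDS offset away from boundaries
    o <- sample(seq(8L, cdsLen - 20L), 1)
    gp <- splicedToGenomic(g$tx, o)
    if (type == "snv") {
      ref <- substr(g$scaf, gp, gp)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      v <- list(scaffold = "s", pos = gp, ref = ref, alt = alt, snpId = "v")
      pos <- gp
    } else if (type == "del") {
      nd <- sample(1:6, 1)
      ## ensure the whole deleted run is coding and spliced-contiguous
      offs <- vapply(gp:(gp + nd - 1L), function(p) {
        r <- genomicToSpliced(g$tx, p); if (is.na(r$offset)) -1L else r$offset
      }, integer(1))
      if (any(offs < 0L) || (max(offs) - min(offs)) != nd - 1L) next
      anchor <- gp - 1L
      ref <- substr(g$scaf, anchor, anchor + nd)
      v <- list(scaffold = "s", pos = anchor, ref = ref,
                alt = substr(ref, 1, 1), snpId = "v")
      pos <- anchor
    } else {
      insSeq <- randomScaffoldStr(sample(1:5, 1))
      r2 <- genomicToSpliced(g$tx, gp + 1L)
      if (is.na(r2$offset) || abs(r2$offset - o) != 1L) next
      anchor <- gp
      ref <- substr(g$scaf, anchor, anchor)
      v <- list(scaffold = "s", pos = anchor, ref = ref,
                alt = paste0(ref, insSeq), snpId = "v")
      pos <- anchor
    }
    rep <- predictConsequence(g$tx, g$genome, v)
    mutCds <- oracleMutantCds(g$tx, g$scaf, pos, v$ref, v$alt)
    tr <- oracleTranslate(mutCds)
    net <- nchar(v$alt) - nchar(v$ref)
    if (type == "snv") {
      refProt <- oracleTranslate(g$cds)$protein
      okKind <- if (tr$protein == refProt && tr$stopType == "ochre")
        rep@kind == "synonymous"
      else rep@kind %in% c("missense", "stop_gained", "stop_lost")
      if (!okKind) bad <- bad + 1L
    } else if (net %% 3L == 0L) {
      if (rep@kind != "inframe_indel" ||
          rep@mutantLength != nchar(tr$protein)) bad <- bad + 1L
    } else {
      if (rep@kind != "frameshift" ||
          rep@mutantLength != nchar(tr$protein) ||
          rep@stopType != tr$stopType ||
          !identical(rep@novelPeptide,
                     substr(tr$protein, rep@fsCodon, nchar(tr$protein))))
        bad <- bad + 1L
    }
  }
  bad
}
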