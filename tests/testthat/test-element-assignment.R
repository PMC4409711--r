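## a small deterministic two-gene layout used by several cases below
.elemFixture <- function() {
  set.seed(21)
  scaf <- randomScaffoldStr(6000L)
  genome <- Biostrings::DNAStringSet(c(s = scaf))
  txp <- TranscriptModel("gPlus", "s", "+", 2001L, 2900L, 2001L, 2900L)
  txm <- TranscriptModel("gMinus", "s", "-", 4501L, 5400L, 4501L, 5400L)
  list(genome = genome, txs = list(gPlus = txp, gMinus = txm), scaf = scaf)
}

test_that("promoter and terminator windows are asymmetric and strand-aware", {
  fx <- .elemFixture()
  v <- variantTable(rep("s", 6), c(1501L, 1101L, 3000L, 3200L, 5900L, 5650L),
                    rep("A", 6), rep("G", 6),
                    snpId = sprintf("v%d", 1:6))
  v$ref <- substring(fx$scaf, v$pos, v$pos)
  v$alt <- ifelse(v$ref == "G", "C", "G")
  a <- assignElements(v, fx$txs)
  ap <- a[a$primary, ]
  ## 500 bp upstream of the plus-strand ATG -> promoter
  expect_equal(ap$element[ap$snpId == "v1"], "promoter")
  expect_equal(ap$distance[ap$snpId == "v1"], 500L)
  ## 900 bp upstream -> outside the 800-bp window
  expect_equal(ap$element[ap$snpId == "v2"], "intergenic")
  ## 100 bp downstream of the plus-strand stop -> terminator
  expect_equal(ap$element[ap$snpId == "v3"], "terminator")
  ## 300 bp downstream -> outside the 200-bp window
  expect_equal(ap$element[ap$snpId == "v4"], "intergenic")
  ## minus strand: upstream lies at higher coordinates
  expect_equal(ap$element[ap$snpId == "v5"], "promoter")
  expect_equal(ap$txId[ap$snpId == "v5"], "gMinus")
  ## enlarging the upstream window can only add promoter calls
  a2 <- assignElements(v, fx$txs, upstreamBp = 1200L)
  ap2 <- a2[a2$primary, ]
  expect_equal(ap2$element[ap2$snpId == "v2"], "promoter")
  wasProm <- ap$snpId[ap$element == "promoter"]
  expect_true(all(ap2$element[ap2$snpId %in% wasProm] == "promoter"))
})

test_that("every variant receives exactly one primary element label", {
  scn <- cachedScenario()
  a <- assignElements(scn$variants, scn$transcripts)
  prim <- a[a$primary, ]
  expect_equal(sort(prim$snpId), sort(scn$variants$snpId))
  expect_true(all(table(prim$snpId) == 1L))
  expect_true(all(prim$element %in%
    c("exon", "intron", "promoter", "terminator", "intergenic")))
})

test_that("element labels are invariant under genome mirroring", {
  ## reverse-complement the scaffold, flip strands and coordinates: labels
  ## must be unchanged
  fx <- .elemFixture()
  L <- nchar(fx$scaf)
  mirrorTx <- function(tx) {
    ex <- txExons(tx)
    TranscriptModel(txId(tx), "s",
                    if (txStrand(tx) == "+") "-" else "+",
                    rev(L - IRanges::end(ex) + 1L),
                    rev(L - IRanges::start(ex) + 1L),
                    cdsStart = L - tx@cdsEnd + 1L,
                    cdsEnd = L - tx@cdsStart + 1L)
  }
  txsM <- lapply(fx$txs, mirrorTx)
  pos <- c(1501L, 2500L, 3000L, 5000L, 5900L)
  v <- variantTable(rep("s", 5), pos,
                    substring(fx$scaf, pos, pos),
                    rep("N", 5), snpId = sprintf("v%d", 1:5))
  v$alt <- ifelse(v$ref == "A", "C", "A")
  vM <- v
  vM$pos <- L - v$pos + 1L
  a <- assignElements(v, fx$txs)
  aM <- assignElements(vM, txsM)
  expect_equal(aM[aM$primary, "element"], a[a$primary, "element"])
})

test_that("impacted genes deduplicate and count correctly", {
  fx <- .elemFixture()
  pos <- c(2100L, 2200L, 1L)  # two exon hits in one gene + one intergenic
  v <- variantTable(rep("s", 3), pos, substring(fx$scaf, pos, pos), rep("N", 3),
                    snpId = c("a", "b", "c"))
  v$alt <- ifelse(v$ref == "A", "C", "A")
  a <- assignElements(v, fx$txs)
  ig <- impactedGenes(a[a$primary, ])
  expect_equal(ig$count, 1L)
  expect_equal(ig$genes, "gPlus")
  allInter <- a[a$primary & a$element == "intergenic", ]
  expect_equal(impactedGenes(allInter)$count, 0L)
})

test_that("the packaged discovery table reproduces its printed element labels", {
  fx <- cachedTable1()
  a <- assignElements(fx$variants, fx$transcripts)
  ap <- a[a$primary, ]
  m <- merge(ap[, c("snpId", "element", "txId")],
             fx$expected[, c("snpId", "element", "txId")], by = "snpId")
  expect_equal(m$element.x, m$element.y)
  expect_equal(m$txId.x[!is.na(m$txId.y)], m$txId.y[!is.na(m$txId.y)])
  expect_equal(impactedGenes(ap)$count, 8L)
})
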