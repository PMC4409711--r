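test_that("CDS mutation is positional string surgery with reference checking", {
  fx <- cachedXyr1()
  mut <- applyVariantToCds(fx$cds, 2294L, "A", "")
  expect_equal(nchar(mut), 2762L)
  expect_equal(nchar(fx$cds), 2763L)

  cds <- "ATGTTCAAA"
  mut2 <- applyVariantToCds(cds, 5L, "T", "A")   # codon TTC -> TAC
  expect_equal(substr(mut2, 4, 6), "TAC")
  expect_error(applyVariantToCds(cds, 5L, "G", "A"), "reference mismatch")
})

test_that("translation uses the standard code and names stop types", {
  expect_equal(translateCds("ATGTAG"),
               list(protein = "M", stopType = "amber", stopCodonIndex = 2L,
                    partialCodon = FALSE, hasX = FALSE))
  tr <- translateCds("ATGAAATAA")
  expect_equal(tr$protein, "MK")
  expect_equal(tr$stopType, "ochre")
  tr2 <- translateCds("ATGAAATGA")
  expect_equal(tr2$stopType, "opal")
  tr3 <- translateCds("ATGAAAACC")
  expect_equal(tr3$stopType, "none_found")
  expect_true(is.na(tr3$stopCodonIndex))
  tr4 <- translateCds("ATGANTCCC")
  expect_equal(tr4$protein, "MXP")
  expect_true(tr4$hasX)
  expect_true(translateCds("ATGAAAC")$partialCodon)
})

test_that("SNV consequences classify codon changes on both strands", {
  fx <- cachedTable1()
  csq <- function(id) {
    v <- fx$variants[fx$variants$snpId == id, ]
    e <- fx$expected[fx$expected$snpId == id, ]
    predictConsequence(fx$transcripts[[e$txId]], fx$genome, v)
  }
  r <- csq("4_1496656")      # minus strand, TTC>TAC
  expect_equal(r@kind, "missense")
  expect_equal(r@refCodon, "TTC"); expect_equal(r@altCodon, "TAC")
  expect_equal(r@refAA, "F"); expect_equal(r@altAA, "Y")
  r2 <- csq("18_608684")     # minus strand, AGT>ACT
  expect_equal(c(r2@refAA, r2@altAA), c("S", "T"))
  r3 <- csq("31_173856")     # plus strand, CCT>GCT at offset 1189
  expect_equal(c(r3@refAA, r3@altAA), c("P", "A"))
  expect_equal(codonOf(1189L)$codon, 397L)
})

test_that("an 8-nt deletion at offset 19 shifts the frame from codon 7", {
  fx <- cachedTable1()
  v <- fx$variants[fx$variants$snpId == "19_227418", ]
  r <- predictConsequence(fx$transcripts[["Trire2:66687"]], fx$genome, v)
  expect_equal(r@kind, "frameshift")
  expect_equal(r@fsCodon, 7L)
})

test_that("in-frame and boundary-spanning indels are called as such", {
  fx <- cachedXyr1()
  scaf <- as.character(fx$genome[[1]])
  ## 3-nt codon-aligned deletion: remove CDS offsets 10-12 (genomic 1010-1012)
  anchor <- 1009L
  ref <- substr(scaf, anchor, anchor + 3L)
  v <- variantTable("11", anchor, ref, substr(ref, 1, 1))
  r <- predictConsequence(fx$tx, fx$genome, v)
  expect_equal(r@kind, "inframe_indel")
  expect_equal(r@residuesLost, 1L)
  ## deletion spanning the exon1/intron boundary (offsets 299-300 + intron)
  anchor2 <- 1298L
  ref2 <- substr(scaf, anchor2, anchor2 + 4L)
  v2 <- variantTable("11", anchor2, ref2, substr(ref2, 1, 1))
  r2 <- predictConsequence(fx$tx, fx$genome, v2)
  expect_equal(r2@kind, "splice_disrupting")
  ## intronic SNV is non-coding, not an error
  v3 <- variantTable("11", 1320L, substr(scaf, 1320, 1320),
                     setdiff(c("A", "C", "G", "T"),
                             substr(scaf, 1320, 1320))[1])
  r3 <- predictConsequence(fx$tx, fx$genome, v3)
  expect_equal(r3@kind, "non_coding")
})

test_that("frameshift accounting matches the independent mutate-and-translate oracle", {
  expect_equal(checkConsequenceOracle(nCases = 130L), 0L)
})

test_that("synonymous calls never change the translated protein", {
  set.seed(99)
  gc <- Biostrings::GENETIC_CODE
  found <- 0L
  for (i in 1:400) {
    g <- randomCleanGene(withIntron = FALSE)
    o <- sample(seq(4L, nchar(g$cds) - 4L), 1)
    gp <- splicedToGenomic(g$tx, o)
    ref <- substr(g$scaf, gp, gp)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      r <- predictConsequence(g$tx, g$genome,
                              list(scaffold = "s", pos = gp, ref = ref,
                                   alt = alt, snpId = "v"))
      if (r@kind == "synonymous") {
        found <- found + 1L
        mutCds <- oracleMutantCds(g$tx, g$scaf, gp, ref, alt)
        expect_equal(oracleTranslate(mutCds)$protein,
                     oracleTranslate(g$cds)$protein)
      }
    }
    if (found >= 25L) break
  }
  expect_gte(found, 25L)
})

test_that("residue accounting closes whenever a stop is found", {
  set.seed(123)
  for (i in 1:40) {
    g <- randomCleanGene()
    o <- sample(seq(8L, nchar(g$cds) - 30L), 1)
    gp <- splicedToGenomic(g$tx, o)
    m <- genomicToSpliced(g$tx, gp - 1L)
    if (is.na(m$offset) || abs(m$offset - o) != 1L) next
    ref <- substr(g$scaf, gp - 1L, gp)
    r <- predictConsequence(g$tx, g$genome,
                            list(scaffold = "s", pos = gp - 1L, ref = ref,
                                 alt = substr(ref, 1, 1), snpId = "v"))
    if (r@kind == "frameshift" && r@stopType != "none_found")
      expect_equal(r@residuesLost + r@mutantLength,
                   nchar(oracleTranslate(g$cds)$protein))
  }
})

test_that("consequence tables are deterministically ordered and complete", {
  fx <- cachedTable1()
  reports <- list()
  for (i in seq_len(nrow(fx$expected))) {
    e <- fx$expected[i, ]
    if (is.na(e$txId) || e$element != "exon") next
    v <- fx$variants[fx$variants$snpId == e$snpId, ]
    reports[[length(reports) + 1L]] <-
      predictConsequence(fx$transcripts[[e$txId]], fx$genome, v)
  }
  tab <- consequenceTable(reports)
  expect_equal(nrow(tab), 6L)
  expect_equal(sum(tab$kind == "missense"), 3L)
  expect_equal(sum(tab$kind == "frameshift"), 3L)
  key <- order(as.numeric(tab$scaffold), tab$pos)
  expect_equal(key, seq_len(nrow(tab)))
  expect_equal(nrow(consequenceTable(list())), 0L)
})
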