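test_that("FASTA loading round-trips, normalizes case and rejects duplicates", {
  d <- withr::local_tempdir()
  fa <- file.path(d, "g.fa")
  writeLines(c(">s1", "ACGTACGTAA", ">s2", "GGCCGGCC"), fa)
  g <- loadGenome(fa)
  expect_equal(names(g), c("s1", "s2"))
  expect_equal(unname(Biostrings::width(g)), c(10L, 8L))

  writeLines(c(">lc", "acgtn"), fa)
  expect_equal(as.character(loadGenome(fa)[["lc"]]), "ACGTN")

  writeLines(c(">a", "ACGT", ">a", "GGCC"), fa)
  expect_error(loadGenome(fa), "duplicate")
})

test_that("GFF3 annotation round-trips through export and import", {
  set.seed(7)
  scn <- generateGenome(scenarioSpec(seed = 11L, nGenes = 4L))
  d <- withr::local_tempdir()
  fa <- file.path(d, "g.fa"); gff <- file.path(d, "a.gff3")
  Biostrings::writeXStringSet(scn$genome, fa)
  writeAnnotation(scn$transcripts, gff)
  g2 <- loadGenome(fa)
  txs2 <- loadAnnotation(gff, g2)
  expect_setequal(names(txs2), names(scn$transcripts))
  for (id in names(scn$transcripts)) {
    a <- scn$transcripts[[id]]; b <- txs2[[id]]
    expect_equal(txStrand(b), txStrand(a))
    expect_equal(IRanges::start(txExons(b)), IRanges::start(txExons(a)))
    expect_equal(IRanges::end(txExons(b)), IRanges::end(txExons(a)))
    expect_equal(extractSplicedCds(b, g2), extractSplicedCds(a, scn$genome))
  }
})

test_that("annotation loader rejects CDS outside exons and unknown scaffolds", {
  d <- withr::local_tempdir()
  gff <- file.path(d, "bad.gff3")
  writeLines(c(
    "##gff-version 3",
    "s1\t.\tgene\t10\t100\t.\t+\t.\tID=g1",
    "s1\t.\tmRNA\t10\t100\t.\t+\t.\tID=m1;Parent=g1",
    "s1\t.\texon\t10\t60\t.\t+\t.\tParent=m1",
    "s1\t.\tCDS\t10\t100\t.\t+\t.\tParent=m1"), gff)
  genome <- Biostrings::DNAStringSet(c(s1 = strrep("ACGT", 50)))
  expect_warning(txs <- loadAnnotation(gff, genome), "outside")
  expect_length(txs, 0L)

  writeLines(c(
    "##gff-version 3",
    "sX\t.\tmRNA\t10\t60\t.\t+\t.\tID=m1",
    "sX\t.\texon\t10\t60\t.\t+\t.\tParent=m1",
    "sX\t.\tCDS\t10\t60\t.\t+\t.\tParent=m1"), gff)
  expect_error(loadAnnotation(gff, genome), "unknown scaffold")
})

test_that("models with CDS length not divisible by 3 are flagged invalid", {
  tx <- TranscriptModel("t", "s", "+", 101L, 110L, 101L, 110L)
  expect_false(tx@valid)
  expect_match(tx@note, "divisible")
  tx2 <- TranscriptModel("t", "s", "+", 101L, 112L, 101L, 112L)
  expect_true(tx2@valid)
})

test_that("genomic to spliced mapping handles simple plus-strand models", {
  tx <- TranscriptModel("t", "s", "+", 101L, 400L, 101L, 400L)
  expect_equal(genomicToSpliced(tx, 101L)$offset, 1L)
  expect_equal(genomicToSpliced(tx, 138L)$offset, 38L)
  expect_equal(genomicToSpliced(tx, 50L)$region, "upstream")
  expect_equal(genomicToSpliced(tx, 450L)$region, "downstream")
  expect_error(genomicToSpliced(tx, 0L), "positive")
})

test_that("intron and UTR positions are labelled as non-coding", {
  ## exons 101-160 / 221-280; CDS 131-250 (UTRs at both ends)
  tx <- TranscriptModel("t", "s", "+", c(101L, 221L), c(160L, 280L),
                        cdsStart = 131L, cdsEnd = 250L)
  expect_equal(genomicToSpliced(tx, 110L)$region, "utr5")
  expect_equal(genomicToSpliced(tx, 260L)$region, "utr3")
  expect_equal(genomicToSpliced(tx, 180L)$region, "intron")
  expect_equal(genomicToSpliced(tx, 131L)$offset, 1L)
  expect_equal(genomicToSpliced(tx, 221L)$offset, 31L)
  ## same geometry on the minus strand flips the UTR labels
  txm <- TranscriptModel("t", "s", "-", c(101L, 221L), c(160L, 280L),
                         cdsStart = 131L, cdsEnd = 250L)
  expect_equal(genomicToSpliced(txm, 110L)$region, "utr3")
  expect_equal(genomicToSpliced(txm, 260L)$region, "utr5")
  expect_equal(genomicToSpliced(txm, 250L)$offset, 1L)
})

test_that("codon addressing follows start-anchored arithmetic", {
  expect_equal(codonOf(38L), list(codon = 13L, within = 2L))
  expect_equal(codonOf(71L), list(codon = 24L, within = 2L))
  expect_equal(codonOf(2294L), list(codon = 765L, within = 2L))
  expect_equal(codonOf(1L), list(codon = 1L, within = 1L))
  k <- 1:200
  expect_true(all(codonOf(3L * k)$within == 3L))
  expect_error(codonOf(0L), ">= 1")
})

test_that("coordinate mapping and CDS extraction agree with the exhaustive oracle", {
  expect_equal(checkMappingOracle(nModels = 120L), 0L)
})

test_that("minus-strand extraction reverse-complements the genomic span", {
  scaf <- "TTTTTCATTTTT"  # revcomp of central CAT -> ATG on minus strand
  genome <- Biostrings::DNAStringSet(c(s = scaf))
  tx <- TranscriptModel("t", "s", "-", 6L, 8L, 6L, 8L)
  expect_equal(extractSplicedCds(tx, genome), "ATG")
})
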