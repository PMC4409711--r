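test_that("variant classification follows allele-length rules", {
  expect_equal(classifyVariant("A", "T"), "SNV")
  expect_equal(classifyVariant("TGCCCGGCG", "T"), "deletion")  # -8 nt
  expect_equal(nchar("TGCCCGGCG") - nchar("T"), 8L)
  expect_equal(classifyVariant("T", "TC"), "insertion")
  expect_equal(classifyVariant("AT", "GC"), "MNV")
  expect_error(classifyVariant("A", "A"), "identical")
  expect_error(classifyVariant("", "A"), "non-empty")
})

test_that("GC fraction counts G+C over the non-N window", {
  g <- Biostrings::DNAStringSet(c(s = "AGGCCA"))
  expect_equal(gcFraction(g, "s", 4L, windowBp = 4L), 1.0)   # window GGCC
  g2 <- Biostrings::DNAStringSet(c(s = "GAATTG"))
  expect_equal(gcFraction(g2, "s", 4L, windowBp = 4L), 0.0)  # window AATT
  g3 <- Biostrings::DNAStringSet(c(s = "TGATCT"))
  expect_equal(gcFraction(g3, "s", 4L, windowBp = 4L), 0.5)  # window GATC
  g4 <- Biostrings::DNAStringSet(c(s = "NNNN"))
  expect_true(is.na(gcFraction(g4, "s", 2L, windowBp = 4L)))
})

test_that("linguistic complexity is k-mer vocabulary richness", {
  g <- Biostrings::DNAStringSet(c(s = strrep("A", 100)))
  expect_equal(linguisticComplexity(g, "s", 50L, windowBp = 100L, k = 4L),
               1 / 97)
  ## 100-nt prefix of a de Bruijn order-4 sequence: all 97 4-mers distinct
  db <- substr(deBruijnDna(4L), 1, 100)
  gdb <- Biostrings::DNAStringSet(c(s = db))
  expect_equal(linguisticComplexity(gdb, "s", 50L, windowBp = 100L, k = 4L), 1)
  g3 <- Biostrings::DNAStringSet(c(s = "ACG"))
  expect_error(linguisticComplexity(g3, "s", 2L, windowBp = 3L, k = 4L),
               "shorter")
})

test_that("uniqueness scores unique sites 16 and two-copy repeats 8", {
  set.seed(5)
  uniq <- randomScaffoldStr(600L)
  g <- Biostrings::DNAStringSet(c(s = uniq))
  expect_equal(uniquenessScore(g, "s", 300L, windowBp = 100L, kmerLen = 15L),
               16.0)
  block <- randomScaffoldStr(250L)
  rep2 <- paste0(randomScaffoldStr(200L), block, randomScaffoldStr(200L),
                 block, randomScaffoldStr(200L))
  g2 <- Biostrings::DNAStringSet(c(s = rep2))
  ## site at the center of the first copy: every window k-mer occurs twice
  expect_equal(uniquenessScore(g2, "s", 325L, windowBp = 100L, kmerLen = 15L),
               8.0)
  expect_error(uniquenessScore(g, "s", 700L, windowBp = 100L), "off scaffold")
})

test_that("a GC-extreme but complex, unique context is rejected for gc alone", {
  set.seed(8)
  pan <- mut2func:::.dinucPangram()
  gcp <- sum(strsplit(pan, "")[[1]] %in% c("G", "C"))
  ## 100-nt window with exactly 80 G/C, all dinucleotides present, no repeats
  gcPart <- paste(sample(c("G", "C"), 80L - gcp, replace = TRUE), collapse = "")
  atPart <- paste(sample(c("A", "T"), 20L - (17L - gcp), replace = TRUE),
                  collapse = "")
  win <- paste0(pan, gcPart, atPart)
  expect_equal(nchar(win), 100L)
  scaf <- paste0(randomScaffoldStr(200L), win, randomScaffoldStr(200L))
  g <- Biostrings::DNAStringSet(c(s = scaf))
  v <- variantTable("s", 250L, substr(scaf, 250, 250),
                    setdiff(c("A", "C", "G", "T"), substr(scaf, 250, 250))[1])
  fr <- applyFilters(v, g, filterConfig(kmerLen = 15L))
  expect_false(fr$scores$pass)
  expect_equal(fr$scores$reasons, "gc")
  expect_gt(fr$scores$gc, 0.74)
})

test_that("clean contexts survive and planted adverse contexts are rejected", {
  scn <- cachedScenario()
  fr <- applyFilters(scn$variants, scn$genome, filterConfig())
  m <- merge(fr$scores, scn$truth, by = "snpId")
  expect_equal(m$pass, m$expectSurvive)
  expect_equal(sum(fr$scores$pass), 14L)
  expect_true(all(grepl("uniqueness",
                        m$reasons[m$context == "repeat"])))
  expect_true(all(grepl("complexity",
                        m$reasons[m$context == "low_complexity"])))
  expect_true(all(grepl("gc", m$reasons[m$context %in% c("gc_high", "gc_low")])))
})

test_that("heterozygous records are dropped only when homozygousOnly is set", {
  scn <- cachedScenario()
  v <- scn$variants
  v$zygosity[1] <- "het"
  fr <- applyFilters(v, scn$genome, filterConfig())
  expect_true(grepl("zygosity", fr$scores$reasons[1]))
  fr2 <- applyFilters(v, scn$genome, filterConfig(homozygousOnly = FALSE))
  expect_true(fr2$scores$pass[1])
})

test_that("relaxing any single threshold never shrinks the surviving set", {
  scn <- cachedScenario()
  base <- applyFilters(scn$variants, scn$genome, filterConfig())
  baseSet <- base$pass$snpId
  relaxed <- list(
    filterConfig(gcMin = 0.05), filterConfig(gcMax = 0.95),
    filterConfig(complexityMin = 0.1), filterConfig(uniquenessMin = 4))
  for (cfg in relaxed) {
    r <- applyFilters(scn$variants, scn$genome, cfg)
    expect_true(all(baseSet %in% r$pass$snpId))
  }
})

test_that("filtering is order-independent", {
  scn <- cachedScenario()
  set.seed(1)
  perm <- sample(nrow(scn$variants))
  a <- applyFilters(scn$variants, scn$genome, filterConfig())
  b <- applyFilters(scn$variants[perm, ], scn$genome, filterConfig())
  expect_setequal(a$pass$snpId, b$pass$snpId)
  expect_equal(b$scores$snpId, scn$variants$snpId[perm])
})

test_that("variant TSV and minimal VCF readers agree", {
  scn <- cachedScenario()
  d <- withr::local_tempdir()
  files <- writeScenario(scn, d)
  vt <- readVariants(files[["variants"]])
  expect_equal(vt$snpId, scn$variants$snpId)
  expect_equal(vt$class, scn$variants$class)
  vcf <- file.path(d, "v.vcf")
  writeVariantsVcf(scn$variants, vcf)
  vv <- readVariants(vcf)
  expect_equal(vv$snpId, scn$variants$snpId)
  expect_equal(vv$pos, scn$variants$pos)
  expect_equal(vv$ref, scn$variants$ref)
})
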