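## Independent brute-force oracles and small fixture builders used by the
## property tests. These deliberately re-derive coordinate arithmetic and
## translation by exhaustive per-base walks, independent of the package's
## interval-based implementation.

.cmp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracleRevcomp <- function(s) {
  paste(rev(.cmp[strsplit(s, "")[[1]]]), collapse = "")
}

## genomic positions of all CDS bases, in transcript (5'->3') order
oracleCdsPositions <- function(tx) {
  cr <- cdsRanges(tx)
  pos <- unlist(lapply(seq_along(cr), function(i)
    seq(IRanges::start(cr)[i], IRanges::end(cr)[i])))
  if (txStrand(tx) == "-") pos <- rev(pos)
  pos
}

oracleSplicedCds <- function(tx, scafStr) {
  pos <- oracleCdsPositions(tx)
  ch <- substring(scafStr, pos, pos)
  if (txStrand(tx) == "-") ch <- unname(.cmp[ch])
  paste(ch, collapse = "")
}

oracleOffsetOf <- function(tx, genomicPos) {
  match(genomicPos, oracleCdsPositions(tx))
}

oracleTranslate <- function(cds) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(cds) %/% 3L
  aa <- character(0)
  stopType <- "none_found"
  for (i in seq_len(n)) {
    cod <- substr(cds, 3L * i - 2L, 3L * i)
    a <- gc[cod]
    if (is.na(a)) a <- "X"
    if (a == "*") {
      stopType <- c(TAG = "amber", TAA = "ochre", TGA = "opal")[[cod]]
      break
    }
    aa <- c(aa, a)
  }
  list(protein = paste(aa, collapse = ""), stopType = stopType)
}

## mutate the scaffold itself, shift exon bounds past the edit, and rebuild
## the spliced CDS -- the "independent route" for consequence checks
oracleMutantCds <- function(tx, scafStr, pos, ref, alt) {
  stopifnot(substr(scafStr, pos, pos + nchar(ref) - 1L) == ref)
  newScaf <- paste0(substr(scafStr, 1L, pos - 1L), alt,
                    substr(scafStr, pos + nchar(ref), nchar(scafStr)))
  net <- nchar(alt) - nchar(ref)
  ex <- txExons(tx)
  sh <- function(x) ifelse(x > pos, x + net, x)
  tx2 <- TranscriptModel(txId(tx), txScaffold(tx), txStrand(tx),
                         sh(IRanges::start(ex)), sh(IRanges::end(ex)),
                         sh(tx@cdsStart), sh(tx@cdsEnd))
  oracleSplicedCds(tx2, newScaf)
}

randomScaffoldStr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## random multi-exon model embedded in a random scaffold; CDS = exon union
randomModel <- function(scafLen = 2500L, nExons = sample(1:5, 1),
                        codonMultiple = FALSE) {
  lens <- sample(30:120, nExons, replace = TRUE)
  if (codonMultiple) {
    extra <- (3L - sum(lens) %% 3L) %% 3L
    lens[nExons] <- lens[nExons] + extra
  }
  gaps <- if (nExons > 1) sample(20:80, nExons - 1, replace = TRUE) else integer(0)
  start <- sample(100:300, 1)
  starts <- start + cumsum(c(0L, lens[-nExons] + gaps))
  ends <- starts + lens - 1L
  strand <- sample(c("+", "-"), 1)
  tx <- TranscriptModel("tx1", "s", strand, starts, ends,
                        cdsStart = starts[1], cdsEnd = ends[nExons])
  scaf <- randomScaffoldStr(max(ends) + 200L)
  genome <- Biostrings::DNAStringSet(scaf)
  names(genome) <- "s"
  list(tx = tx, scaf = scaf, genome = genome)
}

## gene with a clean ORF (ATG, no internal stop, terminal stop) for
## consequence property tests; intron optional, both strands
randomCleanGene <- function(nAa = sample(40:120, 1),
                            withIntron = sample(c(TRUE, FALSE), 1)) {
  gc <- Biostrings::GENETIC_CODE
  nonstop <- names(gc)[gc != "*"]
  cds <- paste(c("ATG", sample(nonstop, nAa - 1, replace = TRUE), "TAA"),
               collapse = "")
  n <- nchar(cds)
  strand <- sample(c("+", "-"), 1)
  flank <- 150L
  if (withIntron) {
    brk <- sample(seq(30L, n - 30L), 1)
    intron <- paste0("GT", randomScaffoldStr(60L), "AG")
    tSeq <- paste0(substr(cds, 1, brk), intron, substr(cds, brk + 1L, n))
    seg <- if (strand == "+") tSeq else oracleRevcomp(tSeq)
    scaf <- paste0(randomScaffoldStr(flank), seg, randomScaffoldStr(flank))
    gStart <- flank + 1L
    gEnd <- flank + nchar(tSeq)
    if (strand == "+") {
      exS <- c(gStart, gStart + brk + 64L)
      exE <- c(gStart + brk - 1L, gEnd)
    } else {
      exS <- c(gStart, gEnd - brk + 1L)
      exE <- c(gEnd - brk - 64L, gEnd)
    }
  } else {
    seg <- if (strand == "+") cds else oracleRevcomp(cds)
    scaf <- paste0(randomScaffoldStr(flank), seg, randomScaffoldStr(flank))
    gStart <- flank + 1L; gEnd <- flank + n
    exS <- gStart; exE <- gEnd
  }
  tx <- TranscriptModel("g1", "s", strand, exS, exE,
                        cdsStart = gStart, cdsEnd = gEnd)
  genome <- Biostrings::DNAStringSet(scaf)
  names(genome) <- "s"
  list(tx = tx, scaf = scaf, genome = genome, cds = cds)
}

## de Bruijn sequence over ACGT of order n (classic Lyndon-word algorithm);
## a 100-nt prefix has all 97 of its 4-mers distinct for n = 4
deBruijnDna <- function(n) {
  k <- 4L
  a <- integer(k * n + 1L)
  out <- integer(0)
  dbrec <- function(t, p) {
    if (t > n) {
      if (n %% p == 0L) out <<- c(out, a[2:(p + 1L)])
    } else {
      a[t + 1L] <<- a[t - p + 1L]
      dbrec(t + 1L, p)
      j <- a[t - p + 1L] + 1L
      while (j <= k - 1L) {
        a[t + 1L] <<- j
        dbrec(t + 1L, t)
        j <- j + 1L
      }
    }
  }
  dbrec(1L, 1L)
  cyc <- c(out, out[seq_len(n - 1L)])
  paste(c("A", "C", "G", "T")[cyc + 1L], collapse = "")
}

## exhaustive permutation oracle for the randomization test (small n)
exhaustivePermutationP <- function(sampleCq, controlCq, eTarget, eRef) {
  poolT <- c(sampleCq$target, controlCq$target)
  poolR <- c(sampleCq$reference, controlCq$reference)
  ns <- nrow(sampleCq); n <- length(poolT)
  obs <- abs((mean(controlCq$target) - mean(sampleCq$target)) * log(eTarget) -
             (mean(controlCq$reference) - mean(sampleCq$reference)) * log(eRef))
  combs <- utils::combn(n, ns)
  disp <- apply(combs, 2, function(ix) {
    mST <- mean(poolT[ix]); mSR <- mean(poolR[ix])
    mCT <- mean(poolT[-ix]); mCR <- mean(poolR[-ix])
    abs((mCT - mST) * log(eTarget) - (mCR - mSR) * log(eRef))
  })
  mean(disp >= obs - 1e-12)
}
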