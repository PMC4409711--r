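## Orchestration: filter -> element assignment -> consequence prediction ->
## protein features of truncated products, with deterministic report output.

#' Run the mutation-to-function pipeline
#'
#' Stages: (1) genomic-context filtering (optional), (2) gene-element
#' assignment with the asymmetric promoter/terminator windows, (3)
#' consequence prediction for variants whose primary element is a coding
#' exon, (4) protein feature and domain-loss reports for frameshift /
#' premature-stop products.
#'
#' @param genome \code{DNAStringSet} or path to a FASTA file.
#' @param transcripts list of \code{TranscriptModel} or path to a GFF3 file.
#' @param variants variant table or path to a TSV/VCF file.
#' @param filter a \code{\link{filterConfig}}, or \code{NULL} to skip the
#'   context-filter stage (e.g. for an already-final variant list).
#' @param upstreamBp,downstreamBp element-assignment windows.
#' @param domains optional named list: transcript id -> domain data.frame
#'   (name/start/end) for truncation reporting.
#' @return list with elements \code{variants}, \code{scores},
#'   \code{filtered}, \code{assignments}, \code{consequences} (list of
#'   \code{ConsequenceReport}), \code{consequenceTable},
#'   \code{proteinFeatures}, \code{summary}.
#' @export
runPipeline <- function(genome, transcripts, variants,
                        filter = filterConfig(), upstreamBp = 800L,
                        downstreamBp = 200L, domains = NULL) {
  if (is.character(genome)) genome <- loadGenome(genome)
  if (is.character(transcripts)) transcripts <- loadAnnotation(transcripts, genome)
  if (is.character(variants)) variants <- readVariants(variants)

  if (nrow(variants) == 0L) {
    empty <- consequenceTable(list())
    return(list(variants = variants, scores = NULL, filtered = variants,
                assignments = NULL, consequences = list(),
                consequenceTable = empty, proteinFeatures = list(),
                summary = list(nVariants = 0L, nFiltered = 0L,
                               byClass = table(character()),
                               byElement = table(character()),
                               impactedGenes = character(),
                               nImpactedGenes = 0L,
                               frameshifts = empty[0, ])))
  }

  scores <- NULL
  filtered <- variants
  if (!is.null(filter)) {
    fr <- applyFilters(variants, genome, filter)
    scores <- fr$scores
    filtered <- fr$pass
  }

  assignments <- assignElements(filtered, transcripts,
                                upstreamBp = upstreamBp,
                                downstreamBp = downstreamBp)
  primary <- assignments[assignments$primary, , drop = FALSE]

  reports <- list()
  for (i in seq_len(nrow(primary))) {
    a <- primary[i, ]
    if (is.na(a$txId) || a$element != "exon" || a$utr) next
    tx <- transcripts[[a$txId]]
    v <- filtered[filtered$snpId == a$snpId, , drop = FALSE][1, ]
    reports[[length(reports) + 1L]] <- predictConsequence(tx, genome, v)
  }
  csqTab <- consequenceTable(reports)

  features <- list()
  for (r in reports) {
    if (!r@kind %in% c("frameshift", "stop_gained")) next
    tx <- transcripts[[r@txId]]
    cds <- extractSplicedCds(tx, genome)
    refProt <- translateCds(cds)$protein
    mutProt <- substr(refProt, 1L, r@mutantLength)
    if (r@kind == "frameshift" && !is.na(r@fsCodon) && nzchar(r@novelPeptide))
      mutProt <- paste0(substr(refProt, 1L, r@fsCodon - 1L), r@novelPeptide)
    dom <- if (!is.null(domains)) domains[[r@txId]] else NULL
    feat <- list(
      snpId = r@snpId, txId = r@txId,
      reference = proteinFeatureReport(refProt, domains = dom),
      mutant = proteinFeatureReport(mutProt, domains = NULL))
    if (!is.null(dom))
      feat$domainStatus <- truncationReport(dom, nchar(refProt), nchar(mutProt))
    features[[r@txId]] <- feat
  }

  ig <- impactedGenes(primary)
  fsTab <- csqTab[csqTab$kind == "frameshift", , drop = FALSE]
  summary <- list(
    nVariants = nrow(variants),
    nFiltered = nrow(filtered),
    byClass = table(filtered$class),
    byElement = table(primary$element),
    impactedGenes = ig$genes,
    nImpactedGenes = ig$count,
    frameshifts = fsTab)

  list(variants = variants, scores = scores, filtered = filtered,
       assignments = assignments, consequences = reports,
       consequenceTable = csqTab, proteinFeatures = features,
       summary = summary)
}

#' Write pipeline reports to a directory
#'
#' Emits an annotated minimal VCF (INFO keys ELEMENT/TXID/DIST and, for
#' coding variants, CSQ_KIND/FS_CODON/NOVEL_PEP/STOP_TYPE/MUT_LEN/LOST_AA),
#' TSV tables of context scores, element assignments and consequences, a
#' JSON summary, and a checksum manifest. Output is deterministic: two runs
#' on identical inputs produce byte-identical files.
#'
#' @param results output of \code{\link{runPipeline}}.
#' @param outdir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
writeReports <- function(results, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wt <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[name]] <<- p
  }
  if (!is.null(results$scores)) wt(results$scores, "context_scores.tsv")
  if (!is.null(results$assignments)) wt(results$assignments, "elements.tsv")
  wt(results$consequenceTable, "consequences.tsv")

  ## annotated VCF for the surviving variants
  v <- results$filtered
  if (!is.null(v) && nrow(v)) {
    a <- results$assignments
    ap <- a[a$primary, , drop = FALSE]
    info <- vapply(seq_len(nrow(v)), function(i) {
      row <- ap[ap$snpId == v$snpId[i], , drop = FALSE]
      s <- if (nrow(row)) sprintf("ELEMENT=%s;TXID=%s;DIST=%s",
                                  row$element[1],
                                  ifelse(is.na(row$txId[1]), ".", row$txId[1]),
                                  ifelse(is.na(row$distance[1]), ".", row$distance[1]))
           else "."
      cs <- results$consequenceTable
      cr <- cs[cs$snpId == v$snpId[i], , drop = FALSE]
      if (nrow(cr))
        s <- paste0(s, sprintf(";CSQ_KIND=%s;FS_CODON=%s;NOVEL_PEP=%s;STOP_TYPE=%s;MUT_LEN=%s;LOST_AA=%s",
                               cr$kind[1],
                               ifelse(is.na(cr$fsCodon[1]), ".", cr$fsCodon[1]),
                               ifelse(is.na(cr$novelPeptide[1]) | !nzchar(cr$novelPeptide[1]),
                                      ".", cr$novelPeptide[1]),
                               ifelse(is.na(cr$stopType[1]), ".", cr$stopType[1]),
                               ifelse(is.na(cr$mutantLength[1]), ".", cr$mutantLength[1]),
                               ifelse(is.na(cr$residuesLost[1]), ".", cr$residuesLost[1])))
      s
    }, character(1))
    p <- file.path(outdir, "annotated.vcf")
    writeVariantsVcf(v, p, info = info)
    files[["annotated.vcf"]] <- p
  }

  s <- results$summary
  p <- file.path(outdir, "summary.json")
  jsonlite::write_json(list(
    nVariants = s$nVariants, nFiltered = s$nFiltered,
    byClass = as.list(s$byClass), byElement = as.list(s$byElement),
    impactedGenes = s$impactedGenes, nImpactedGenes = s$nImpactedGenes,
    frameshifts = s$frameshifts), p, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  files[["summary.json"]] <- p

  manifest <- file.path(outdir, "MANIFEST.json")
  jsonlite::write_json(as.list(tools::md5sum(unname(unlist(files)))),
                       manifest, auto_unbox = TRUE)
  files[["MANIFEST.json"]] <- manifest
  invisible(unlist(files))
}
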