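# End-to-end orchestration on simulated data: simulate -> build reference
# -> QC -> map -> quantify -> classify -> DE -> enrichment -> clustering
# -> qPCR concordance, with a ledger/summary report and optional TSV/JSON
# export. Thresholds default to the published analysis values.

#' Run the full DGE tag-profiling pipeline on simulated data
#'
#' Executes every stage in dependency order under a single master seed
#' and returns a result bundle whose report tables (QC ledgers, stage
#' summary, DE summaries, enrichment heads) are recomputed from the run's
#' own data. Deterministic: the same config yields an identical bundle.
#'
#' @param config a [simConfig()].
#' @param outDir optional directory; when given, stage outputs are
#'   written as TSV/JSON.
#' @param maxQ,maxP,minLfc DEG thresholds (defaults 0.001, 0.0005, 1).
#' @param enrichMaxQ enrichment significance threshold (default 0.05).
#' @param minTags detection threshold (default 1).
#' @param fdrMethod FDR method for DE and enrichment.
#' @param nQpcrGenes size of the qPCR validation panel drawn from called
#'   DEGs.
#' @return A list with elements `config`, `provenance`, `transcriptome`,
#'   `truth`, `refdb`, `qc` (per stage: ledger, spectrum), `mapping`
#'   (per stage summary), `expression` (SummarizedExperiment),
#'   `stageSummary`, `de` (per comparison: table and summary),
#'   `enrichment` (per comparison), `clustering`, `qpcr`.
#' @export
runPipeline <- function(config = simConfig(), outDir = NULL,
                        maxQ = 0.001, maxP = 0.0005, minLfc = 1,
                        enrichMaxQ = 0.05, minTags = 1, fdrMethod = "BH",
                        nQpcrGenes = 13) {
  st <- config$stages

  tx <- simulateTranscriptome(config)
  truth <- simulateStageProfiles(config, names(tx))
  db <- scanCatgTags(tx)

  qc <- list()
  maps <- list()
  assignments <- list()
  cleanTotals <- numeric()
  for (i in seq_along(st)) {
    s <- st[i]
    sim <- simulateTagLibrary(tx, truth$tpm[, s], config, stage = s,
                              seed = config$seed + 100L + i)
    fl <- filterRawTags(sim$library, adaptorSeqs = config$adaptorSeq)
    qc[[s]] <- list(ledger = fl$ledger, spectrum = copySpectrum(fl$clean),
                    lowCopyFraction = lowCopyFraction(fl$clean))
    mp <- mapTags(fl$clean, db)
    maps[[s]] <- mp$summary
    assignments[[s]] <- mp$assignments
    cleanTotals[s] <- tagTotal(fl$clean)
  }

  se <- quantifyExpression(assignments, cleanTotals, names(tx))
  stageSummary <- classifyStages(se, st, minTags = minTags)

  comparisons <- list(c(st[1], st[2]), c(st[2], st[3]))
  de <- lapply(comparisons, function(cc) {
    tab <- callDEGs(se, cc[1], cc[2], maxQ = maxQ, maxP = maxP,
                    minLfc = minLfc, fdrMethod = fdrMethod)
    list(table = tab,
         summary = degSummary(tab, stageSummary$atLeastOne))
  })
  names(de) <- vapply(comparisons, function(cc) paste0(cc[1], "vs", cc[2]),
                      character(1))

  anno <- simulateAnnotations(
    names(tx), unique(unlist(lapply(truth$deLabels, function(l)
      names(l)[l]))), config)
  enrichment <- lapply(de, function(d) {
    degs <- d$table$gene_id[d$table$call != "unchanged"]
    if (!length(degs)) return(NULL)
    enrichTerms(degs, anno, fdrMethod = fdrMethod, maxQ = enrichMaxQ)
  })

  clustering <- NULL
  cm <- selectClusterGenes(de[[1]]$table, de[[2]]$table, se,
                           maxQ = maxQ, minLfc = minLfc, minTags = minTags)
  if (nrow(cm) >= 2L) clustering <- c(hierarchicalCluster(cm),
                                      list(matrix = cm))

  qpcr <- NULL
  deGenes <- unique(c(de[[1]]$table$gene_id[de[[1]]$table$call != "unchanged"],
                      de[[2]]$table$gene_id[de[[2]]$table$call != "unchanged"]))
  panel <- deGenes[truth$tpm[deGenes, st[1]] > 0 &
                     truth$tpm[deGenes, st[3]] > 0]
  if (length(panel)) {
    panel <- head(sort(panel), nQpcrGenes)
    simq <- simulateQpcr(truth$tpm, panel, config, calibrator = st[1],
                         test = st[3])
    ratios <- vapply(panel, function(g)
      ddctRatio(simq$ct, g, c("actin", "rRNA18S", "GAPDH"),
                calibrator = st[1], test = st[3])$ratio, numeric(1))
    tpmObs <- exprTpm(se)
    dgeLr <- setNames(log2((tpmObs[panel, st[3]] + 0.001) /
                             (tpmObs[panel, st[1]] + 0.001)), panel)
    qpcr <- c(signConcordance(ratios, dgeLr),
              list(ratios = ratios, trueRatio = simq$trueRatio))
  }

  bundle <- list(
    config = config,
    provenance = list(seed = config$seed,
                      package = as.character(packageVersion("tagDGE")),
                      thresholds = list(maxQ = maxQ, maxP = maxP,
                                        minLfc = minLfc,
                                        enrichMaxQ = enrichMaxQ,
                                        minTags = minTags,
                                        fdrMethod = fdrMethod)),
    transcriptome = tx, truth = truth, refdb = db, qc = qc,
    mapping = maps, expression = se, stageSummary = stageSummary,
    de = de, enrichment = enrichment, clustering = clustering,
    qpcr = qpcr)

  if (!is.null(outDir)) .writeBundle(bundle, outDir)
  bundle
}

.writeBundle <- function(bundle, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outDir, ...)
  writeTagDB(bundle$refdb, p("refdb.tsv"))
  for (s in names(bundle$qc)) {
    write.table(bundle$qc[[s]]$ledger, p(sprintf("ledger_%s.tsv", s)),
                sep = "\t", quote = FALSE)
    write.table(bundle$qc[[s]]$spectrum, p(sprintf("spectrum_%s.tsv", s)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  expr <- data.frame(gene_id = rownames(exprCounts(bundle$expression)),
                     exprCounts(bundle$expression),
                     exprTpm(bundle$expression), check.names = FALSE)
  names(expr) <- c("gene_id",
                   paste0("count_", colnames(bundle$expression)),
                   paste0("tpm_", colnames(bundle$expression)))
  write.table(expr, p("expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (cc in names(bundle$de))
    write.table(bundle$de[[cc]]$table, p(sprintf("de_%s.tsv", cc)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  for (cc in names(bundle$enrichment))
    if (!is.null(bundle$enrichment[[cc]]))
      write.table(bundle$enrichment[[cc]],
                  p(sprintf("enrichment_%s.tsv", cc)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$clustering))
    writeCdtGtr(bundle$clustering, p("cluster"))
  jsonlite::write_json(
    list(provenance = bundle$provenance,
         mapping = bundle$mapping,
         stageSummary = bundle$stageSummary[
           c("nReferenceGenes", "detected", "pctDetectedOfReference",
             "specific", "pctSpecificOfStage", "allStages", "atLeastOne",
             "pctAtLeastOneOfReference")],
         deSummary = lapply(bundle$de, `[[`, "summary")),
    p("report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
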