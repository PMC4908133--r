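# 2^-ddCt relative quantification from Ct tables with multiple reference
# genes, and sign concordance with DGE log ratios.

.meanCt <- function(ct, sample, gene) {
  v <- ct$ct[ct$sample == sample & ct$gene_id == gene]
  if (!length(v)) return(c(mean = NA_real_, se = NA_real_, n = 0))
  c(mean = mean(v), se = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
    n = length(v))
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt(sample) = mean Ct(target) - mean over reference genes of their
#' replicate-mean Cts`; the ratio is `2^-(dCt(test) - dCt(calibrator))`,
#' assuming perfect doubling per cycle. Multiple reference genes are
#' combined by the arithmetic mean of their Cts (the geometric mean of
#' their linear quantities). Replicate standard errors are propagated in
#' quadrature onto the ddCt scale.
#'
#' @param ct data.frame with columns `sample`, `gene_id`, `replicate`,
#'   `ct`.
#' @param targetGene target gene id.
#' @param referenceGenes character vector of reference (housekeeping)
#'   gene ids, all measured in both samples.
#' @param calibrator,test sample labels.
#' @return A list: `ratio` (fold, test vs calibrator), `log2_ratio`
#'   (`-ddCt`), `ddct`, `se_ddct`.
#' @examples
#' ct <- data.frame(
#'   sample = rep(c("test", "cal"), each = 2),
#'   gene_id = rep(c("tgt", "ref"), 2),
#'   replicate = 1,
#'   ct = c(20, 18, 22, 18))
#' ddctRatio(ct, "tgt", "ref", calibrator = "cal", test = "test")$ratio
#' @export
ddctRatio <- function(ct, targetGene, referenceGenes,
                      calibrator = "MP", test = "PT") {
  stopifnot(all(c("sample", "gene_id", "ct") %in% names(ct)))
  dct <- function(sample) {
    tg <- .meanCt(ct, sample, targetGene)
    if (tg[["n"]] == 0)
      stop(sprintf("target '%s' not measured in sample '%s'",
                   targetGene, sample))
    refs <- vapply(referenceGenes, function(g) {
      r <- .meanCt(ct, sample, g)
      if (r[["n"]] == 0)
        stop(sprintf("reference '%s' missing in sample '%s'", g, sample))
      r[c("mean", "se")]
    }, numeric(2))
    c(dct = tg[["mean"]] - mean(refs["mean", ]),
      se = sqrt(tg[["se"]]^2 + sum(refs["se", ]^2) /
                  length(referenceGenes)^2))
  }
  a <- dct(test)
  b <- dct(calibrator)
  ddct <- a[["dct"]] - b[["dct"]]
  list(ratio = 2^(-ddct), log2_ratio = -ddct, ddct = ddct,
       se_ddct = sqrt(a[["se"]]^2 + b[["se"]]^2))
}

#' qPCR vs DGE sign concordance
#'
#' Per-gene agreement of the direction of change between qPCR
#' (`log2` of the 2^-ddCt ratio) and the DGE log2 ratio for the same
#' comparison orientation, plus the overall agreeing fraction.
#'
#' @param qpcrRatios named numeric vector of qPCR fold ratios (test vs
#'   calibrator), names are gene ids.
#' @param dgeLog2 named numeric vector of DGE log2 ratios for the same
#'   genes and orientation.
#' @param genes genes to compare; default the intersection of names.
#' @return A list: `perGene` (data.frame `gene_id`, `qpcr_log2`,
#'   `dge_log2`, `agree`) and `fraction`.
#' @export
signConcordance <- function(qpcrRatios, dgeLog2,
                            genes = intersect(names(qpcrRatios),
                                              names(dgeLog2))) {
  if (!length(genes)) stop("no shared genes to compare")
  ql <- log2(qpcrRatios[genes])
  dl <- dgeLog2[genes]
  agree <- sign(ql) == sign(dl)
  list(perGene = data.frame(gene_id = genes, qpcr_log2 = unname(ql),
                            dge_log2 = unname(dl), agree = unname(agree),
                            stringsAsFactors = FALSE),
       fraction = mean(agree))
}

#' Read a Ct table TSV
#'
#' Columns `sample`, `gene_id`, `replicate`, `ct`.
#'
#' @param path TSV path.
#' @return data.frame for [ddctRatio()].
#' @export
readCtTable <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene_id", "replicate", "ct")
  if (!all(need %in% names(x)))
    stop("Ct TSV needs columns sample, gene_id, replicate, ct")
  if (any(x$ct <= 0)) stop("Ct values must be positive")
  x[need]
}
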