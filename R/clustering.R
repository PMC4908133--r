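# Three-stage DEG intersection selection and hierarchical clustering of
# expression ratios, with Eisen Cluster-compatible CDT/GTR export.

#' Select the clustering gene set
#'
#' Genes expressed in all three stages that pass `q <= maxQ` and
#' `|log2 ratio| >= minLfc` in both comparisons, ordered by gene id.
#' The clustered matrix holds the two log2 ratios per gene by default,
#' or log2 TPM per stage with `what = "tpm"`.
#'
#' @param deA,deB DE tables from [callDEGs()] for the two successive
#'   comparisons.
#' @param se expression `SummarizedExperiment`.
#' @param maxQ,minLfc selection thresholds (defaults 0.001 and 1).
#' @param what `"ratio"` (default) or `"tpm"`.
#' @param minTags detection threshold per stage.
#' @param pseudoTpm pseudo-TPM for `what = "tpm"`.
#' @return Numeric matrix (genes x columns) ready for
#'   [hierarchicalCluster()]; zero rows (with a warning) when no gene
#'   qualifies.
#' @export
selectClusterGenes <- function(deA, deB, se, maxQ = 0.001, minLfc = 1,
                               what = c("ratio", "tpm"), minTags = 1,
                               pseudoTpm = 0.001) {
  what <- match.arg(what)
  cnt <- exprCounts(se)
  allStages <- rownames(cnt)[rowSums(cnt >= minTags) == ncol(cnt)]
  pass <- function(de) de$gene_id[de$q <= maxQ & abs(de$log2_ratio) >= minLfc]
  genes <- sort(Reduce(intersect, list(allStages, pass(deA), pass(deB))))
  if (!length(genes)) {
    warning("no genes satisfy the clustering selection")
    return(matrix(numeric(), 0, 2,
                  dimnames = list(NULL, c(unique(deA$comparison),
                                          unique(deB$comparison)))))
  }
  if (what == "ratio") {
    m <- cbind(setNames(deA$log2_ratio, deA$gene_id)[genes],
               setNames(deB$log2_ratio, deB$gene_id)[genes])
    colnames(m) <- c(unique(deA$comparison), unique(deB$comparison))
  } else {
    m <- log2(exprTpm(se)[genes, , drop = FALSE] + pseudoTpm)
  }
  rownames(m) <- genes
  m
}

#' Pearson distance matrix
#'
#' `1 - r` with `r` the centred Pearson correlation between gene
#' profiles. Zero-variance profiles, whose correlation is undefined, get
#' distance 1 to every other gene (and 0 to themselves).
#'
#' @param x numeric matrix, genes in rows.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
pearsonDistance <- function(x) {
  r <- suppressWarnings(cor(t(x)))
  r[!is.finite(r)] <- 0
  d <- 1 - r
  diag(d) <- 0
  d
}

#' Average-linkage hierarchical clustering with Pearson distance
#'
#' The historical defaults of the Eisen Cluster program: distance
#' `1 - r` and average (UPGMA) linkage. Deterministic for a fixed input
#' order.
#'
#' @param x numeric matrix (genes x conditions), >= 2 rows.
#' @return A list: `hclust` (the tree), `order` (leaf order), `ordered`
#'   (the input matrix in leaf order), `distance` (the distance matrix).
#' @export
hierarchicalCluster <- function(x) {
  if (nrow(x) < 2L) stop("need at least 2 genes to cluster")
  d <- pearsonDistance(x)
  hc <- hclust(as.dist(d), method = "average")
  list(hclust = hc, order = hc$order,
       ordered = x[hc$order, , drop = FALSE], distance = d)
}

#' Write Eisen Cluster CDT + GTR files
#'
#' Tab-delimited files consumable by Java TreeView: the CDT carries the
#' reordered data matrix with `GENE<i>X` identifiers, the GTR the gene
#' tree with `NODE<i>X` joins and node similarity `1 - height`.
#'
#' @param clust result of [hierarchicalCluster()].
#' @param prefix output path prefix; writes `<prefix>.cdt` and
#'   `<prefix>.gtr`.
#' @return The two paths, invisibly.
#' @export
writeCdtGtr <- function(clust, prefix) {
  hc <- clust$hclust
  x <- clust$ordered
  ng <- length(hc$order)
  geneId <- paste0("GENE", seq_len(ng) - 1L, "X")
  names(geneId) <- hc$labels[hc$order]

  idOf <- function(j) {
    # hclust merge coding: negative = leaf index, positive = earlier node
    vapply(j, function(jj) {
      if (jj < 0)
        paste0("GENE", match(hc$labels[-jj], hc$labels[hc$order]) - 1L,
               "X")
      else paste0("NODE", jj - 1L, "X")
    }, character(1))
  }
  gtr <- data.frame(
    node = paste0("NODE", seq_len(nrow(hc$merge)) - 1L, "X"),
    left = idOf(hc$merge[, 1L]),
    right = idOf(hc$merge[, 2L]),
    similarity = 1 - hc$height)
  write.table(gtr, paste0(prefix, ".gtr"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  cdt <- data.frame(GID = geneId[rownames(x)], UNIQID = rownames(x),
                    NAME = rownames(x), GWEIGHT = 1,
                    x, check.names = FALSE)
  con <- file(paste0(prefix, ".cdt"), "w")
  on.exit(close(con))
  writeLines(paste(c("GID", "UNIQID", "NAME", "GWEIGHT", colnames(x)),
                   collapse = "\t"), con)
  writeLines(paste(c("EWEIGHT", "", "", "", rep("1", ncol(x))),
                   collapse = "\t"), con)
  write.table(cdt, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(paste0(prefix, c(".cdt", ".gtr")))
}
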