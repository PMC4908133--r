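# Mismatch-tolerant tag-to-gene mapping, TPM quantification, stage
# classification, saturation and fold-change-distribution analyses.
#
# Matching policy: an exact hit beats any 1-mismatch hit; ambiguity
# (>= 2 distinct genes) is evaluated only within the winning class, and
# ambiguous tags are excluded from quantification.

# distinct gene set / strand lookup per reference tag sequence
.refIndex <- function(db) {
  tg <- refTags(db)
  genes <- lapply(split(tg$gene_id, tg$tag_seq), unique)
  list(
    seqs = names(genes),  # split() order: lookups index genes by position
    genes = genes,
    # sense-first strand per (tag, gene): TRUE if any sense occurrence
    senseByTagGene = tapply(tg$strand == "sense",
                            paste(tg$tag_seq, tg$gene_id, sep = "\r"), any)
  )
}

# all 63 Hamming-1 neighbours of each tag (3 alternatives x 21 positions)
.mismatchNeighbours <- function(tags) {
  n <- length(tags)
  if (!n) return(list(variant = character(), origin = integer()))
  bases <- c("A", "C", "G", "T")
  variant <- vector("list", 21L)
  for (pos in 1:21) {
    cur <- substr(tags, pos, pos)
    reps <- lapply(bases, function(b) {
      v <- tags
      substr(v, pos, pos) <- b
      v[cur != b]
    })
    keepOrigin <- lapply(bases, function(b) which(substr(tags, pos, pos) != b))
    variant[[pos]] <- list(v = unlist(reps), o = unlist(keepOrigin))
  }
  list(variant = unlist(lapply(variant, `[[`, "v")),
       origin = unlist(lapply(variant, `[[`, "o")))
}

#' Map clean tags to the virtual tag reference
#'
#' Assigns each distinct clean tag to the reference with at most one
#' mismatch. Exact matches take priority; within the best class a tag
#' hitting two or more distinct genes is excluded as multi-gene, a tag
#' hitting exactly one gene is assigned with the strand of the matched
#' virtual tag (sense wins a within-gene strand tie), and unmatched tags
#' are `unknown`.
#'
#' @param clean a clean [TagLibrary-class].
#' @param db a [ReferenceTagDB-class].
#' @return A list with `assignments` (data.frame: `tag_seq`, `count`,
#'   `match_class`, `strand`, `gene_id` (NA unless uniquely assigned),
#'   `n_genes`, `excluded_multi_gene`) and `summary` (see
#'   [mappingSummary()]).
#' @export
mapTags <- function(clean, db) {
  stopifnot(is(clean, "TagLibrary"), is(db, "ReferenceTagDB"))
  if (nrow(refTags(db)) == 0L) stop("empty reference tag database")
  idx <- .refIndex(db)
  tags <- clean@tags
  cnt <- clean@counts
  n <- length(tags)

  matchClass <- rep("unknown", n)
  geneSets <- vector("list", n)

  exact <- match(tags, idx$seqs)
  hitE <- !is.na(exact)
  matchClass[hitE] <- "exact"
  geneSets[hitE] <- idx$genes[exact[hitE]]

  todo <- which(!hitE)
  if (length(todo)) {
    nb <- .mismatchNeighbours(tags[todo])
    m <- match(nb$variant, idx$seqs)
    hit <- !is.na(m)
    if (any(hit)) {
      hitGenes <- idx$genes[m[hit]]
      origin <- nb$origin[hit]
      byOrigin <- split(hitGenes, origin)
      for (o in names(byOrigin)) {
        i <- todo[as.integer(o)]
        matchClass[i] <- "one_mismatch"
        geneSets[[i]] <- unique(unlist(byOrigin[[o]]))
      }
    }
  }

  nGenes <- vapply(geneSets, function(g) if (is.null(g)) 0L else length(g),
                   integer(1))
  excluded <- nGenes >= 2L
  geneId <- rep(NA_character_, n)
  geneId[nGenes == 1L] <- vapply(geneSets[nGenes == 1L], `[[`, "", 1L)

  strand <- rep("none", n)
  assigned <- which(nGenes == 1L)
  if (length(assigned)) {
    # strand of the matched virtual tag; for exact matches look the tag
    # itself up, for 1-mismatch matches any matched neighbour determines
    # the gene, so recover strand from the reference (sense-first tie)
    strand[assigned] <- "sense"
    keyE <- paste(tags[assigned], geneId[assigned], sep = "\r")
    kn <- idx$senseByTagGene[keyE]
    isExact <- matchClass[assigned] == "exact"
    strand[assigned[isExact & !is.na(kn) & !kn]] <- "antisense"
    mm <- assigned[!isExact]
    if (length(mm)) {
      tg <- refTags(db)
      for (i in mm) {
        cand <- tg[tg$gene_id == geneId[i] &
                     .hamming1(tg$tag_seq, tags[i]), , drop = FALSE]
        strand[i] <- if (any(cand$strand == "sense")) "sense" else "antisense"
      }
    }
  }

  assignments <- data.frame(
    tag_seq = tags, count = cnt, match_class = matchClass,
    strand = strand, gene_id = geneId, n_genes = nGenes,
    excluded_multi_gene = excluded, stringsAsFactors = FALSE)
  list(assignments = assignments,
       summary = mappingSummary(assignments, clean@stage))
}

# vectorised Hamming-distance<=1 test of many 21-mers against one 21-mer
.hamming1 <- function(refs, tag) {
  if (!length(refs)) return(logical(0))
  t0 <- charToRaw(tag)
  vapply(refs, function(r) sum(charToRaw(r) != t0) <= 1L, logical(1),
         USE.NAMES = FALSE)
}

#' Mapping class summary for one library
#'
#' Partitions a library's distinct and total tag counts into all-mapping
#' (any reference hit), unambiguous-mapping (single-gene hit) and unknown,
#' and reports sense/antisense tallies: distinct assigned tags per strand,
#' and the gene-level ("transcript") sense:antisense ratio, where a gene is
#' called on a strand if any uniquely assigned tag hits it on that strand.
#'
#' @param assignments assignment table from [mapTags()].
#' @param stage stage label carried into the output.
#' @return A list of summary tallies.
#' @export
mappingSummary <- function(assignments, stage = "library") {
  a <- assignments
  cls <- function(sel) c(distinct = sum(sel), total = sum(a$count[sel]))
  anyHit <- a$match_class != "unknown"
  uniq <- !is.na(a$gene_id)
  senseGenes <- unique(a$gene_id[uniq & a$strand == "sense"])
  antiGenes <- unique(a$gene_id[uniq & a$strand == "antisense"])
  list(
    stage = stage,
    clean = cls(rep(TRUE, nrow(a))),
    all_mapping = cls(anyHit),
    unambiguous_mapping = cls(uniq),
    excluded_multi_gene = cls(a$excluded_multi_gene),
    unknown = cls(!anyHit),
    sense_distinct_tags = sum(uniq & a$strand == "sense"),
    antisense_distinct_tags = sum(uniq & a$strand == "antisense"),
    sense_transcripts = length(senseGenes),
    antisense_transcripts = length(antiGenes),
    sense_antisense_transcript_ratio =
      if (length(antiGenes)) length(senseGenes) / length(antiGenes) else NA_real_
  )
}

#' Quantify gene expression from tag assignments
#'
#' Sums the copy numbers of each gene's uniquely assigned tags (both
#' strands pooled into the gene count; per-strand tallies kept in
#' `rowData`) and normalises to transcripts per million clean tags.
#'
#' @param assignmentsList named list (stage -> assignment table from
#'   [mapTags()]).
#' @param cleanTotals named numeric vector of clean library totals per
#'   stage (denominator of TPM).
#' @param geneIds character vector of all reference gene ids (rows of the
#'   result).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assays
#'   `counts` and `tpm`, `colData` column `cleanTotal`, and per-strand
#'   count assays `countsSense` and `countsAntisense`.
#' @export
quantifyExpression <- function(assignmentsList, cleanTotals, geneIds) {
  stages <- names(assignmentsList)
  if (is.null(stages) || any(!stages %in% names(cleanTotals)))
    stop("assignmentsList and cleanTotals must share stage names")
  if (any(cleanTotals[stages] <= 0)) stop("stage with zero clean tags")
  tally <- function(a, strand = NULL) {
    sel <- !is.na(a$gene_id)
    if (!is.null(strand)) sel <- sel & a$strand == strand
    v <- tapply(a$count[sel], a$gene_id[sel], sum)
    out <- setNames(numeric(length(geneIds)), geneIds)
    out[names(v)] <- v
    out
  }
  asMat <- function(x) matrix(x, nrow = length(geneIds),
                              dimnames = list(geneIds, stages))
  counts <- asMat(vapply(assignmentsList, tally,
                         numeric(length(geneIds))))
  cS <- asMat(vapply(assignmentsList, tally, numeric(length(geneIds)),
                     strand = "sense"))
  cA <- asMat(vapply(assignmentsList, tally, numeric(length(geneIds)),
                     strand = "antisense"))
  tpm <- sweep(counts, 2, cleanTotals[stages], "/") * 1e6
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, tpm = tpm,
                  countsSense = cS, countsAntisense = cA),
    colData = S4Vectors::DataFrame(cleanTotal = cleanTotals[stages],
                                   row.names = stages))
}

#' Expression TPM / count accessors
#'
#' @param se expression `SummarizedExperiment` from [quantifyExpression()].
#' @return Numeric matrix genes x stages.
#' @export
exprTpm <- function(se) SummarizedExperiment::assay(se, "tpm")

#' @rdname exprTpm
#' @export
exprCounts <- function(se) SummarizedExperiment::assay(se, "counts")

#' Stage detection and specificity summary
#'
#' Classifies genes as detected per stage (count >= `minTags`), specific
#' to one stage, detected in all stages or in at least one, with the
#' published denominators: detection percentages against the reference
#' gene universe, specificity percentages against the respective stage's
#' detected genes (both rounded to 2 decimals).
#'
#' @param se expression `SummarizedExperiment` from [quantifyExpression()].
#' @param stages stage labels, in developmental order.
#' @param minTags detection threshold on the unambiguous tag count.
#' @return A list with `detected`, `specific`, `allStages`, `atLeastOne`
#'   counts, matching percentage vectors, and the gene id sets.
#' @export
classifyStages <- function(se, stages = colnames(se), minTags = 1) {
  cnt <- exprCounts(se)[, stages, drop = FALSE]
  det <- cnt >= minTags
  nRef <- nrow(cnt)
  nDetStage <- colSums(det)
  nStagesPerGene <- rowSums(det)
  specific <- vapply(stages, function(s)
    sum(det[, s] & nStagesPerGene == 1L), numeric(1))
  allThree <- sum(nStagesPerGene == length(stages))
  atLeastOne <- sum(nStagesPerGene >= 1L)
  list(
    stages = stages,
    nReferenceGenes = nRef,
    detected = nDetStage,
    pctDetectedOfReference = stagePercent(nDetStage, nRef),
    specific = specific,
    pctSpecificOfStage = stagePercent(specific, nDetStage),
    allStages = allThree,
    pctAllStagesOfReference = stagePercent(allThree, nRef),
    atLeastOne = atLeastOne,
    pctAtLeastOneOfReference = stagePercent(atLeastOne, nRef),
    detectedGenes = lapply(stages, function(s) rownames(cnt)[det[, s]]),
    expressedGenes = rownames(cnt)[nStagesPerGene >= 1L]
  )
}

#' Percentage with 2-decimal rounding
#'
#' The reporting convention of the stage-summary tables: counts over a
#' stated denominator, times 100, rounded to two decimals.
#'
#' @param count numerator count(s).
#' @param denominator denominator count(s).
#' @return Numeric percentage(s), rounded to 2 decimals.
#' @examples
#' stagePercent(13017, 41404)  # 31.44
#' @export
stagePercent <- function(count, denominator) {
  round(100 * count / denominator, 2)
}

#' Saturation analysis by subsampling
#'
#' Subsamples the clean tag multiset without replacement at a grid of
#' depths (nested within each replicate, so both curves are monotone) and
#' reports the replicate-averaged number of distinct tags and, when
#' assignments are supplied, distinct detected genes.
#'
#' @param clean a clean [TagLibrary-class].
#' @param depths increasing vector of subsampling depths (<= library
#'   total).
#' @param assignments optional assignment table from [mapTags()] used to
#'   count detected genes.
#' @param nReps number of replicates.
#' @param seed RNG seed.
#' @return data.frame `depth`, `meanDistinctTags`, `meanDetectedGenes`
#'   (NA without assignments).
#' @export
saturationCurve <- function(clean, depths, assignments = NULL, nReps = 5,
                            seed = 1) {
  stopifnot(is(clean, "TagLibrary"))
  total <- tagTotal(clean)
  if (any(depths > total)) stop("depth exceeds library total")
  depths <- sort(depths)
  tagGene <- NULL
  if (!is.null(assignments))
    tagGene <- setNames(assignments$gene_id, assignments$tag_seq)
  pool <- rep.int(seq_along(clean@tags), clean@counts)
  resT <- matrix(0, length(depths), nReps)
  resG <- matrix(NA_real_, length(depths), nReps)
  withSeed(seed, {
    for (r in seq_len(nReps)) {
      perm <- sample(pool)
      for (d in seq_along(depths)) {
        idx <- unique(perm[seq_len(depths[d])])
        resT[d, r] <- length(idx)
        if (!is.null(tagGene)) {
          g <- tagGene[clean@tags[idx]]
          resG[d, r] <- length(unique(g[!is.na(g)]))
        }
      }
    }
  })
  data.frame(depth = depths,
             meanDistinctTags = rowMeans(resT),
             meanDetectedGenes = rowMeans(resG))
}

#' Expected distinct tags under subsampling
#'
#' Closed-form expectation of the saturation curve: for a library with
#' copy numbers c_i summing to T, the expected number of distinct tags in
#' a without-replacement draw of depth d is
#' sum_i (1 - C(T - c_i, d) / C(T, d)), evaluated with log binomial
#' coefficients.
#'
#' @param clean a [TagLibrary-class].
#' @param depths subsampling depths.
#' @return Numeric vector of expectations, one per depth.
#' @export
expectedDistinctTags <- function(clean, depths) {
  total <- tagTotal(clean)
  vapply(depths, function(d) {
    lq <- lchoose(total - clean@counts, d) - lchoose(total, d)
    sum(1 - exp(lq))
  }, numeric(1))
}

#' Fold-change distribution between two stages
#'
#' Bins genes detected in either stage by the magnitude of their TPM fold
#' change (pseudo-TPM added on both sides, as for the DE log ratio) into
#' `<2`, `2-5` and `>=5` fold.
#'
#' @param se expression `SummarizedExperiment`.
#' @param stageA,stageB stage labels (direction does not matter; the fold
#'   change is the larger-over-smaller ratio).
#' @param pseudoTpm pseudo-TPM added to both stages before the ratio.
#' @return data.frame `bin`, `n`, `fraction` (fractions sum to 1).
#' @export
foldChangeDistribution <- function(se, stageA, stageB, pseudoTpm = 0.001) {
  tpm <- exprTpm(se)
  cnt <- exprCounts(se)
  sel <- cnt[, stageA] >= 1 | cnt[, stageB] >= 1
  a <- tpm[sel, stageA] + pseudoTpm
  b <- tpm[sel, stageB] + pseudoTpm
  fold <- pmax(a, b) / pmin(a, b)
  n <- c(sum(fold < 2), sum(fold >= 2 & fold < 5), sum(fold >= 5))
  data.frame(bin = c("<2", "2-5", ">=5"), n = n,
             fraction = if (sum(n)) n / sum(n) else rep(0, 3))
}
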