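# Audic-Claverie exact test for tag counts between two pooled libraries,
# FDR control, and threshold-based DEG calling.
#
# Conditional model: given x tags in library 1 (total N1), the count y in
# library 2 (total N2) under equal underlying rates follows
#   p(y|x) = (N2/N1)^y * (x+y)! / (x! y! (1 + N2/N1)^(x+y+1)),
# a negative-binomial law with size x+1 and success probability
# N1/(N1+N2). Tails are evaluated through the regularized incomplete
# beta function, which is this distribution's exact cumulative sum.

.checkAc <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop("negative counts")
  if (any(x != round(x)) || any(y != round(y)))
    stop("counts must be integers")
  if (any(N1 < 1) || any(N2 < 1)) stop("library totals must be >= 1")
}

#' Audic-Claverie conditional probability
#'
#' Probability of observing `y` tags for a gene in a library of total `N2`
#' given `x` tags in a library of total `N1`, under the null of equal
#' underlying expression. Computed in log space, stable for counts up to
#' millions.
#'
#' @param x,y tag counts in the two libraries (vectorised).
#' @param N1,N2 clean totals of the two libraries.
#' @return Probability in (0, 1\].
#' @examples
#' acProbability(0, 0, 1e6, 1e6)  # 0.5
#' @export
acProbability <- function(x, y, N1, N2) {
  .checkAc(x, y, N1, N2)
  r <- N2 / N1
  lp <- y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(r)
  exp(lp)
}

# P(Y <= y | x): regularized incomplete beta I_p(x+1, y+1), p = N1/(N1+N2)
.acLowerTail <- function(x, y, N1, N2) {
  pbeta(N1 / (N1 + N2), x + 1, y + 1)
}

# P(Y >= y | x) = I_q(y, x+1) for y >= 1, else 1
.acUpperTail <- function(x, y, N1, N2) {
  ifelse(y < 1, 1, pbeta(N2 / (N1 + N2), pmax(y, 1), x + 1))
}

#' Two-sided Audic-Claverie p-value
#'
#' Doubles the smaller of the two conditional tails,
#' `p = min(1, 2 min(P(Y <= y | x), P(Y >= y | x)))`. A one-sided value
#' (the smaller tail alone) is available via `sided = 1`.
#'
#' @inheritParams acProbability
#' @param sided 2 (default, doubled-tail) or 1.
#' @return p-value in (0, 1\].
#' @examples
#' acTwoSidedP(0, 0, 1e6, 1e6)  # 1
#' @export
acTwoSidedP <- function(x, y, N1, N2, sided = 2) {
  .checkAc(x, y, N1, N2)
  lo <- .acLowerTail(x, y, N1, N2)
  hi <- .acUpperTail(x, y, N1, N2)
  m <- pmin(lo, hi)
  if (sided == 1) return(m)
  pmin(1, 2 * m)
}

#' Step-up FDR adjustment
#'
#' Benjamini-Hochberg (default) or Benjamini-Yekutieli adjusted values,
#' via the standard step-up procedure.
#'
#' @param p p-values in \[0, 1\].
#' @param method `"BH"` or `"BY"`.
#' @return q-values, same length as `p`.
#' @export
fdrAdjust <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  p.adjust(p, method = method)
}

#' Call differentially expressed genes between two stages
#'
#' Tests every gene detected in either stage with the Audic-Claverie
#' two-sided test on raw unambiguous tag counts, adjusts across all
#' tested genes, and calls a gene up (higher in `stageB`, the later
#' stage) or down when all three thresholds hold conjunctively:
#' `q <= maxQ`, `p < maxP` and `|log2 ratio| >= minLfc`. The log ratio is
#' computed on TPM with a pseudo-TPM so stage-exclusive genes get large
#' finite ratios; the test itself uses raw counts.
#'
#' @param se expression `SummarizedExperiment` from [quantifyExpression()].
#' @param stageA,stageB earlier and later stage labels.
#' @param maxQ,maxP,minLfc calling thresholds (defaults 0.001, 0.0005, 1).
#' @param pseudoTpm pseudo-TPM for the log ratio (default 0.001).
#' @param fdrMethod FDR method passed to [fdrAdjust()].
#' @return data.frame: `gene_id`, `comparison`, `x`, `y`, `tpm1`, `tpm2`,
#'   `log2_ratio`, `p`, `q`, `call`.
#' @export
callDEGs <- function(se, stageA, stageB, maxQ = 0.001, maxP = 0.0005,
                     minLfc = 1, pseudoTpm = 0.001, fdrMethod = "BH") {
  if (!all(c(stageA, stageB) %in% colnames(se)))
    stop(sprintf("unknown stage label: %s",
                 paste(setdiff(c(stageA, stageB), colnames(se)),
                       collapse = ", ")))
  cnt <- exprCounts(se)
  tpm <- exprTpm(se)
  tot <- SummarizedExperiment::colData(se)$cleanTotal
  names(tot) <- colnames(se)
  sel <- cnt[, stageA] >= 1 | cnt[, stageB] >= 1
  x <- cnt[sel, stageA]
  y <- cnt[sel, stageB]
  p <- acTwoSidedP(x, y, tot[stageA], tot[stageB])
  q <- fdrAdjust(p, fdrMethod)
  lr <- log2((tpm[sel, stageB] + pseudoTpm) / (tpm[sel, stageA] + pseudoTpm))
  call <- rep("unchanged", sum(sel))
  sig <- q <= maxQ & p < maxP & abs(lr) >= minLfc
  call[sig & lr > 0] <- "up"
  call[sig & lr < 0] <- "down"
  data.frame(
    gene_id = rownames(cnt)[sel],
    comparison = paste0(stageA, "vs", stageB),
    x = unname(x), y = unname(y),
    tpm1 = unname(tpm[sel, stageA]), tpm2 = unname(tpm[sel, stageB]),
    log2_ratio = unname(lr), p = unname(p), q = unname(q), call = call,
    stringsAsFactors = FALSE)
}

#' Summarise a DEG call table
#'
#' Up/down counts with percentages of the total expressed-gene universe,
#' rounded to 2 decimals as in published stage summaries.
#'
#' @param deres DE table from [callDEGs()].
#' @param nExpressed denominator: number of genes expressed in at least
#'   one stage.
#' @return A list with `up`, `down`, `total`, `pctUp`, `pctDown`.
#' @export
degSummary <- function(deres, nExpressed) {
  up <- sum(deres$call == "up")
  down <- sum(deres$call == "down")
  list(up = up, down = down, total = up + down,
       pctUp = stagePercent(up, nExpressed),
       pctDown = stagePercent(down, nExpressed))
}
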