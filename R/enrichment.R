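# Hypergeometric term enrichment of DEG sets against an annotated
# background, with step-up multiple-testing correction.

#' Exact hypergeometric upper tail
#'
#' `P(X >= k)` for X hypergeometric: drawing `n` genes from a background
#' of `N` of which `K` carry the term,
#' `p = sum_{i=k}^{min(n,K)} C(K,i) C(N-K, n-i) / C(N,n)`,
#' evaluated as a log-space sum of log binomial coefficients.
#'
#' @param k observed overlap (set members carrying the term).
#' @param n set size (genes drawn).
#' @param K term size in the background.
#' @param N background size.
#' @return Upper-tail probability in (0, 1\]; exactly 1 when `k = 0`.
#' @examples
#' hypergeomUpperTail(13, 620, 85, 22673)  # 5.13e-07
#' @export
hypergeomUpperTail <- function(k, n, K, N) {
  if (length(k) > 1L || length(n) > 1L || length(K) > 1L || length(N) > 1L)
    return(mapply(hypergeomUpperTail, k, n, K, N))
  if (k < 0 || n < 0 || K < 0 || N < 0 || k > n || n > N || K > N)
    stop("violated bounds: need 0 <= k <= n <= N and 0 <= K <= N")
  if (k == 0) return(1)
  hi <- min(n, K)
  if (k > hi) return(0)
  i <- k:hi
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lt)
  min(1, exp(m + log(sum(exp(lt - m)))))
}

#' Term enrichment of a gene set
#'
#' One upper-tail hypergeometric test per term against the annotated
#' background, corrected across all tested terms. The effective set size
#' `n` is the number of query genes carrying any annotation, matching the
#' "DEGs with pathway annotation" convention; optionally the full
#' reference universe can serve as background via `background=`.
#'
#' @param genes character vector of query (e.g. DEG) gene ids.
#' @param annotations data.frame with columns `gene_id`, `term_id`,
#'   `term_name` (see [readAnnotations()]).
#' @param background gene universe; default all annotated genes.
#' @param minOverlap only terms with at least this many query genes are
#'   tested (default 1).
#' @param fdrMethod correction method for [fdrAdjust()].
#' @param maxQ significance threshold on the corrected value.
#' @return data.frame sorted by `p`: `term_id`, `term_name`, `k`,
#'   `k_pct` (of `n`), `K`, `K_pct` (of `N`), `n`, `N`, `p`, `q`,
#'   `significant`.
#' @export
enrichTerms <- function(genes, annotations, background = NULL,
                        minOverlap = 1, fdrMethod = "BH", maxQ = 0.05) {
  if (!length(genes)) stop("empty query gene set")
  if (is.null(background)) background <- unique(annotations$gene_id)
  if (!length(background)) stop("empty background")
  anno <- annotations[annotations$gene_id %in% background, , drop = FALSE]
  N <- length(unique(background))
  inSet <- unique(genes[genes %in% background &
                          genes %in% anno$gene_id])
  n <- length(inSet)
  byTerm <- split(anno$gene_id, anno$term_id)
  termName <- tapply(anno$term_name, anno$term_id, `[`, 1L)
  rows <- lapply(names(byTerm), function(t) {
    tg <- unique(byTerm[[t]])
    K <- length(tg)
    k <- sum(inSet %in% tg)
    if (k < minOverlap) return(NULL)
    data.frame(term_id = t, term_name = unname(termName[t]),
               k = k, K = K, n = n, N = N,
               p = hypergeomUpperTail(k, n, K, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), k_pct = numeric(), K = integer(),
                      K_pct = numeric(), n = integer(), N = integer(),
                      p = numeric(), q = numeric(),
                      significant = logical()))
  }
  res <- do.call(rbind, rows)
  res$q <- fdrAdjust(res$p, fdrMethod)
  res$significant <- res$q < maxQ
  res$k_pct <- round(100 * res$k / max(res$n, 1L), 2)
  res$K_pct <- round(100 * res$K / res$N, 2)
  res <- res[order(res$p, res$term_id), ]
  rownames(res) <- NULL
  res[, c("term_id", "term_name", "k", "k_pct", "K", "K_pct", "n", "N",
          "p", "q", "significant")]
}

#' Read a gene-to-term annotation TSV
#'
#' Expects columns `gene_id`, `term_id`, `term_name` (tab separated, with
#' header).
#'
#' @param path TSV path.
#' @return data.frame usable by [enrichTerms()].
#' @export
readAnnotations <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "term_id", "term_name")
  if (!all(need %in% names(x)))
    stop("annotation TSV needs columns gene_id, term_id, term_name")
  x[need]
}

#' Functional category tally of DEG sets
#'
#' Counts genes per category for each direction-labelled DEG set; a gene
#' carrying several categories counts once in each, so per-set category
#' percentages may sum above 100.
#'
#' @param degSets named list of gene id vectors (e.g.
#'   `MPvsHP_up`, `MPvsHP_down`, ...).
#' @param categoryMap data.frame with columns `gene_id`, `category`.
#' @return data.frame `set`, `category`, `n`, `pct` (of the set's
#'   categorised genes, 2 decimals).
#' @export
functionalCategoryTally <- function(degSets, categoryMap) {
  cats <- sort(unique(categoryMap$category))
  out <- lapply(names(degSets), function(nm) {
    g <- degSets[[nm]]
    sub <- categoryMap[categoryMap$gene_id %in% g, , drop = FALSE]
    denom <- length(unique(sub$gene_id))
    if (!denom) return(NULL)
    n <- vapply(cats, function(cc)
      length(unique(sub$gene_id[sub$category == cc])), numeric(1))
    data.frame(set = nm, category = cats, n = n,
               pct = round(100 * n / denom, 2), stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(set = character(), category = character(),
                      n = numeric(), pct = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
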