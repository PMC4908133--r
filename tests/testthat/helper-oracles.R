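# Independent oracles, written against the definitions rather than the
# package's code paths.

# regex scan for CATG + 17 bases, both strands, via explicit reverse
# complement
oracleRevcomp <- function(s) {
  comp <- chartr("ACGTN", "TGCAN", s)
  vapply(strsplit(comp, ""), function(ch)
    paste(rev(ch), collapse = ""), character(1))
}

oracleCatgTags <- function(seqs) {
  scan1 <- function(s, gene, strand) {
    out <- list()
    start <- 1L
    repeat {
      p <- regexpr("CATG", substr(s, start, nchar(s)), fixed = TRUE)
      if (p == -1L) break
      pos <- start + as.integer(p) - 1L
      if (pos + 20L <= nchar(s)) {
        tag <- substr(s, pos, pos + 20L)
        if (!grepl("N", tag, fixed = TRUE))
          out[[length(out) + 1L]] <-
            data.frame(tag_seq = tag, gene_id = gene, strand = strand,
                       offset = pos - 1L, stringsAsFactors = FALSE)
      }
      start <- pos + 1L
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  res <- list()
  for (g in names(seqs)) {
    res[[length(res) + 1L]] <- scan1(seqs[[g]], g, "sense")
    res[[length(res) + 1L]] <- scan1(oracleRevcomp(seqs[[g]]), g,
                                     "antisense")
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res)) do.call(rbind, res) else NULL
}

# naive dictionary filter, one pass per rule
oracleFilter <- function(tags, counts, adaptors = character()) {
  keepN <- !grepl("[^ACGT]", tags)
  keepA <- !(tags %in% adaptors)
  keep <- keepN & keepA
  keep2 <- keep & counts >= 2
  list(tags = tags[keep2], counts = counts[keep2],
       nN = c(sum(!keepN), sum(counts[!keepN])),
       nA = c(sum(keepN & !keepA), sum(counts[keepN & !keepA])),
       nS = c(sum(keep & counts < 2), sum(counts[keep & counts < 2])))
}

# O(tags x reftags) Hamming scan assignment
oracleAssign <- function(tags, refTagSeq, refGene) {
  hd <- function(a, b) sum(charToRaw(a) != charToRaw(b))
  t(vapply(tags, function(tg) {
    d <- vapply(refTagSeq, hd, numeric(1), a = tg)
    best <- min(d)
    if (best > 1) return(c(class = "unknown", genes = ""))
    g <- sort(unique(refGene[d == best]))
    c(class = if (best == 0) "exact" else "one_mismatch",
      genes = paste(g, collapse = ","))
  }, character(2)))
}

# Audic-Claverie conditional probability and tails by explicit
# log-sum-exp summation
oracleAcLogProb <- function(x, y, N1, N2) {
  y * (log(N2) - log(N1)) + lgamma(x + y + 1) - lgamma(x + 1) -
    lgamma(y + 1) - (x + y + 1) * log1p(N2 / N1)
}

oracleAcTwoSided <- function(x, y, N1, N2, span = 4000) {
  logsumexp <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
  lower <- exp(logsumexp(oracleAcLogProb(x, 0:y, N1, N2)))
  # upper tail summed until the term underflows relative to the running sum
  yy <- y:(y + span)
  upper <- exp(logsumexp(oracleAcLogProb(x, yy, N1, N2)))
  min(1, 2 * min(lower, upper))
}

# textbook step-up BH, independent loop
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# hypergeometric upper tail by direct pmf summation (dhyper is the
# independent distribution routine)
oracleHyper <- function(k, n, K, N) {
  if (k == 0) return(1)
  i <- k:min(n, K)
  sum(stats::dhyper(i, K, N - K, n))
}

# naive O(n^3) average-linkage agglomeration on a distance matrix,
# returns sorted merge heights
oracleAverageLinkHeights <- function(d) {
  n <- nrow(d)
  active <- as.list(seq_len(n))
  D <- d
  heights <- numeric(0)
  while (length(active) > 1L) {
    m <- length(active)
    best <- c(Inf, 0, 0)
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      dd <- mean(d[active[[i]], active[[j]]])
      if (dd < best[1]) best <- c(dd, i, j)
    }
    heights <- c(heights, best[1])
    merged <- c(active[[best[2]]], active[[best[3]]])
    active <- active[-c(best[2], best[3])]
    active[[length(active) + 1L]] <- merged
  }
  sort(heights)
}

# small deterministic three-stage expression fixture
toyExpression <- function() {
  counts <- rbind(
    gA = c(MP = 10, HP = 0, PT = 0),
    gB = c(MP = 40, HP = 50, PT = 60),
    gC = c(MP = 0, HP = 30, PT = 20),
    gD = c(MP = 0, HP = 0, PT = 0))
  assignments <- lapply(colnames(counts), function(s) {
    sel <- counts[, s] > 0
    data.frame(tag_seq = paste0("CATG", strrep("A", 16),
                                LETTERS[seq_len(sum(sel))]),
               count = counts[sel, s], match_class = "exact",
               strand = "sense", gene_id = rownames(counts)[sel],
               n_genes = 1L, excluded_multi_gene = FALSE,
               stringsAsFactors = FALSE)
  })
  names(assignments) <- colnames(counts)
  quantifyExpression(assignments,
                     c(MP = 1e6, HP = 1e6, PT = 1e6),
                     rownames(counts))
}
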