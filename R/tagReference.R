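# Virtual tag reference construction: every CATG+17-nt 21-mer on both
# strands of a transcript set, the in-silico image of NlaIII DGE tags.

.checkDnaAlphabet <- function(seqs) {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    nm <- names(seqs)[which(bad)[1L]]
    stop(sprintf("non-DNA characters in record '%s'", nm))
  }
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# all CATG anchor positions with >= 17 following bases; 1-based starts
.catgSites <- function(seq) {
  hit <- gregexpr("CATG", seq, fixed = TRUE)[[1L]]
  if (hit[1L] == -1L) return(integer(0))
  hit[hit + 20L <= nchar(seq)]
}

#' Read transcript sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that uppercases
#' sequences and keeps only the first whitespace-delimited token of each
#' header as the gene identifier.
#'
#' @param path FASTA file (gzip transparent).
#' @return A named [Biostrings::DNAStringSet].
#' @export
readTranscripts <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Build the virtual CATG+17-nt tag reference
#'
#' Scans every transcript for `CATG` anchors with at least 17 following
#' bases and emits the 21-mer at each site, on the sense strand and on the
#' reverse complement (antisense) strand. 21-mers containing `N` are
#' skipped (they can never match a clean tag) but tallied. A tag sequence
#' is flagged ambiguous when it occurs in two or more distinct genes,
#' pooling both strands; multiple sites within one gene do not make a tag
#' ambiguous.
#'
#' @param transcripts named character vector or [Biostrings::DNAStringSet]
#'   of transcript sequences; names are gene identifiers.
#' @return A [ReferenceTagDB-class].
#' @examples
#' db <- scanCatgTags(c(g1 = paste0("AACATG", strrep("A", 17), "GG")))
#' refTags(db)
#' @export
scanCatgTags <- function(transcripts) {
  if (is(transcripts, "DNAStringSet")) {
    seqs <- as.character(transcripts)
  } else {
    seqs <- setNames(toupper(as.character(transcripts)), names(transcripts))
  }
  if (length(seqs) == 0L) stop("empty reference")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("transcripts must have unique gene_id names")
  if (any(nchar(seqs) < 1L)) stop("zero-length transcript sequence")
  .checkDnaAlphabet(seqs)

  scanOne <- function(seq) {
    p <- .catgSites(seq)
    if (!length(p)) return(NULL)
    list(offset = p - 1L, tag = substring(seq, p, p + 20L))
  }

  rows <- vector("list", 2L * length(seqs))
  rc <- .revcomp(seqs)
  k <- 0L
  genesWithCatg <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    s <- scanOne(seqs[[i]])
    if (!is.null(s)) {
      genesWithCatg[i] <- TRUE
      k <- k + 1L
      rows[[k]] <- data.frame(tag_seq = s$tag, gene_id = names(seqs)[i],
                              strand = "sense", offset = s$offset,
                              stringsAsFactors = FALSE)
    }
    a <- scanOne(rc[[i]])
    if (!is.null(a)) {
      k <- k + 1L
      rows[[k]] <- data.frame(tag_seq = a$tag, gene_id = names(seqs)[i],
                              strand = "antisense", offset = a$offset,
                              stringsAsFactors = FALSE)
    }
  }
  tg <- if (k) do.call(rbind, rows[seq_len(k)]) else
    data.frame(tag_seq = character(), gene_id = character(),
               strand = character(), offset = integer(),
               stringsAsFactors = FALSE)

  hasN <- grepl("N", tg$tag_seq, fixed = TRUE)
  nDropped <- sum(hasN)
  tg <- tg[!hasN, , drop = FALSE]

  # ambiguity across the union of both strands of all genes
  nGenesPerTag <- tapply(tg$gene_id, tg$tag_seq,
                         function(g) length(unique(g)))
  tg$ambiguous <- as.vector(nGenesPerTag[tg$tag_seq] >= 2L)
  rownames(tg) <- NULL

  new("ReferenceTagDB", tags = tg,
      nGenesTotal = length(seqs),
      nGenesWithCatg = sum(genesWithCatg),
      nTagsDroppedN = as.integer(nDropped))
}

#' Summarise a tag reference database
#'
#' Reports the fraction of genes carrying a CATG site and the unambiguous
#' tag fraction, with denominators stated explicitly. The unambiguous
#' fraction is reported both against all virtual tag records and against
#' distinct tag sequences, since either denominator is defensible.
#'
#' @param db a [ReferenceTagDB-class].
#' @return A list: `nGenesTotal`, `nGenesWithCatg`, `pctGenesWithCatg`
#'   (1 decimal), `nTagsTotal`, `nTagsUnambiguous`, `nTagSeqsDistinct`,
#'   `nTagSeqsUnambiguous`, `pctUnambiguousOfTags` and
#'   `pctUnambiguousOfDistinct` (1 decimal), `nTagsDroppedN`.
#' @export
referenceSummary <- function(db) {
  stopifnot(is(db, "ReferenceTagDB"))
  tg <- db@tags
  nTags <- nrow(tg)
  nUnamb <- sum(!tg$ambiguous)
  seqAmb <- tapply(tg$ambiguous, tg$tag_seq, any)
  list(
    nGenesTotal = db@nGenesTotal,
    nGenesWithCatg = db@nGenesWithCatg,
    pctGenesWithCatg = round(100 * db@nGenesWithCatg /
                               max(db@nGenesTotal, 1L), 1),
    nTagsTotal = nTags,
    nTagsUnambiguous = nUnamb,
    nTagSeqsDistinct = length(seqAmb),
    nTagSeqsUnambiguous = sum(!seqAmb),
    pctUnambiguousOfTags = round(100 * nUnamb / max(nTags, 1L), 1),
    pctUnambiguousOfDistinct = round(100 * sum(!seqAmb) /
                                       max(length(seqAmb), 1L), 1),
    nTagsDroppedN = db@nTagsDroppedN
  )
}

#' Write / read a tag reference database as TSV
#'
#' The TSV carries the per-tag table; a JSON sidecar (`<path>.json`)
#' carries the summary counts so the database round-trips exactly.
#'
#' @param db a [ReferenceTagDB-class].
#' @param path output TSV path.
#' @return `writeTagDB` returns `path` invisibly; `readTagDB` returns the
#'   reconstructed [ReferenceTagDB-class].
#' @export
writeTagDB <- function(db, path) {
  write.table(db@tags, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(nGenesTotal = db@nGenesTotal,
               nGenesWithCatg = db@nGenesWithCatg,
               nTagsDroppedN = db@nTagsDroppedN)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeTagDB
#' @export
readTagDB <- function(path) {
  tg <- read.delim(path, stringsAsFactors = FALSE)
  tg$ambiguous <- as.logical(tg$ambiguous)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("ReferenceTagDB", tags = tg,
      nGenesTotal = as.integer(meta$nGenesTotal),
      nGenesWithCatg = as.integer(meta$nGenesWithCatg),
      nTagsDroppedN = as.integer(meta$nTagsDroppedN))
}
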