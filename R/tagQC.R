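# Raw library filtering with an exact accounting ledger, plus the
# copy-number spectrum. The ledger classes are disjoint and sum exactly:
# raw - N - adaptors - singletons = clean, for distinct and total alike.

#' Filter a raw tag library into a clean library
#'
#' Removal order is fixed: (1) tags containing any character outside
#' A/C/G/T (including N), (2) tags exactly equal to a supplied adaptor
#' sequence, (3) tags whose copy number after the first two removals is
#' below 2 (singletons). The returned ledger satisfies, for both distinct
#' and total counts,
#' `raw - tags_containing_N - adaptors - copy_lt_2 = clean` exactly.
#'
#' @param raw a [TagLibrary-class] of raw tags.
#' @param adaptorSeqs character vector of adaptor sequences matched by
#'   exact full-length equality (default empty).
#' @return A list with `clean` (a [TagLibrary-class]) and `ledger`
#'   (data.frame with rownames `raw`, `tags_containing_N`, `adaptors`,
#'   `copy_lt_2`, `clean` and columns `distinct`, `total`).
#' @examples
#' raw <- TagLibrary(c(CATGAAAAAAAAAAAAAAAAA = 3,
#'                     CATGCCCCCCCCCCCCCCCCN = 5,
#'                     CATGGGGGGGGGGGGGGGGGG = 1), stage = "MP")
#' filterRawTags(raw)$ledger
#' @export
filterRawTags <- function(raw, adaptorSeqs = character()) {
  stopifnot(is(raw, "TagLibrary"))
  if (tagDistinct(raw) == 0L) stop("raw library is empty")
  tags <- raw@tags
  cnt <- raw@counts

  isN <- grepl("[^ACGT]", tags)
  isAd <- !isN & tags %in% adaptorSeqs
  keep <- !isN & !isAd
  isSingle <- keep & cnt < 2

  cleanIdx <- keep & !isSingle
  ledger <- data.frame(
    distinct = c(length(tags), sum(isN), sum(isAd), sum(isSingle),
                 sum(cleanIdx)),
    total = c(sum(cnt), sum(cnt[isN]), sum(cnt[isAd]), sum(cnt[isSingle]),
              sum(cnt[cleanIdx])),
    row.names = c("raw", "tags_containing_N", "adaptors", "copy_lt_2",
                  "clean")
  )
  clean <- new("TagLibrary", stage = raw@stage,
               tags = tags[cleanIdx], counts = cnt[cleanIdx])
  list(clean = clean, ledger = ledger)
}

#' Table-1-style ledger arithmetic from printed class tallies
#'
#' Given the raw, N-containing, adaptor and singleton tallies of a library
#' (as a published ledger prints them), returns the implied clean-library
#' distinct and total counts by the exact conservation identity.
#'
#' @param raw,tagsContainingN,adaptors,copyLt2 length-2 numeric vectors
#'   `c(distinct, total)`.
#' @return Named numeric vector `c(distinct, total)` of the clean library.
#' @examples
#' ledgerClean(c(346420, 4746710), c(39861, 57487), c(0, 0),
#'             c(180056, 180056))
#' @export
ledgerClean <- function(raw, tagsContainingN, adaptors, copyLt2) {
  out <- raw - tagsContainingN - adaptors - copyLt2
  names(out) <- c("distinct", "total")
  if (any(out < 0)) stop("inconsistent ledger: negative clean counts")
  out
}

#' Copy-number spectrum of a clean library
#'
#' Counts distinct tags and their summed copies at the conventional
#' thresholds: the first row is inclusive (copy number >= 2, i.e. the
#' whole clean library); the remaining rows are strict (> 5, > 10, > 20,
#' > 50, > 100).
#'
#' @param clean a clean [TagLibrary-class] (no singletons).
#' @return data.frame with columns `threshold`, `distinct`, `total`.
#' @export
copySpectrum <- function(clean) {
  stopifnot(is(clean, "TagLibrary"))
  if (length(clean@counts) && min(clean@counts) < 2)
    stop("library contains copy-number-1 tags; filter first")
  cuts <- c(5, 10, 20, 50, 100)
  cnt <- clean@counts
  rows <- rbind(
    c(distinct = length(cnt), total = sum(cnt)),
    t(vapply(cuts, function(th) {
      sel <- cnt > th
      c(distinct = sum(sel), total = sum(cnt[sel]))
    }, numeric(2)))
  )
  data.frame(threshold = c(">=2", paste0(">", cuts)),
             distinct = rows[, "distinct"], total = rows[, "total"])
}

#' Low-copy dominance of a clean library
#'
#' Fraction of distinct clean tags with copy number below `maxCopy`
#' (default 20), the statistic behind the observation that most distinct
#' tags are low copy.
#'
#' @param clean a clean [TagLibrary-class].
#' @param maxCopy exclusive upper copy-number bound.
#' @return A single fraction in \[0, 1\].
#' @export
lowCopyFraction <- function(clean, maxCopy = 20) {
  stopifnot(is(clean, "TagLibrary"))
  if (!length(clean@counts)) return(NA_real_)
  mean(clean@counts < maxCopy)
}

#' Read a tag-count TSV into a TagLibrary
#'
#' Expects two columns, `tag_seq` and `count` (header optional when the
#' first field is a valid 21-mer).
#'
#' @param path TSV path.
#' @param stage stage label.
#' @return A [TagLibrary-class].
#' @export
readTagCounts <- function(path, stage = "library") {
  x <- read.delim(path, stringsAsFactors = FALSE,
                  header = !grepl("^[ACGTN]{21}\t",
                                  readLines(path, n = 1L)))
  names(x)[1:2] <- c("tag_seq", "count")
  TagLibrary(setNames(as.numeric(x$count), x$tag_seq), stage = stage)
}

#' Write a TagLibrary as a two-column TSV
#'
#' @param lib a [TagLibrary-class].
#' @param path output path.
#' @export
writeTagCounts <- function(lib, path) {
  write.table(data.frame(tag_seq = lib@tags, count = lib@counts),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract CATG-anchored tags from FASTQ reads
#'
#' Takes the 21-mer starting at the first occurrence of `CATG` in each
#' read. Reads without a CATG anchor, or whose anchor leaves fewer than 17
#' following bases, are tallied as the diagnostic class `no_anchor` and
#' excluded before the raw tally (quality strings are ignored; the tag
#' protocol does no quality trimming).
#'
#' @param path FASTQ file (gzip transparent).
#' @param stage stage label.
#' @return A [TagLibrary-class] with attribute `noAnchor` giving the
#'   number of anchorless reads.
#' @export
tagsFromFastq <- function(path, stage = "library") {
  reads <- toupper(as.character(
    Biostrings::readDNAStringSet(path, format = "fastq")))
  pos <- regexpr("CATG", reads, fixed = TRUE)
  ok <- pos != -1L & pos + 20L <= nchar(reads)
  tags <- substring(reads[ok], pos[ok], pos[ok] + 20L)
  tab <- table(tags)
  lib <- TagLibrary(setNames(as.numeric(tab), names(tab)), stage = stage)
  attr(lib, "noAnchor") <- sum(!ok)
  lib
}
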