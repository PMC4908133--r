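#' @import methods
#' @importFrom stats p.adjust pbeta cor sd setNames rmultinom rbinom rnorm
#'   rlnorm runif hclust as.dist quantile
#' @importFrom utils read.delim write.table head packageVersion
NULL

#' Virtual CATG tag reference database
#'
#' Holds every CATG+17-nt virtual tag that can be extracted from a transcript
#' set, on both strands, together with per-tag ambiguity (whether the same
#' 21-mer occurs in two or more distinct genes) and summary bookkeeping.
#' Create with [scanCatgTags()].
#'
#' @slot tags data.frame with columns `tag_seq` (21-nt string starting
#'   `CATG`), `gene_id`, `strand` (`"sense"`/`"antisense"`), `offset`
#'   (0-based position of the C of CATG on the coordinate system of the
#'   stated strand) and `ambiguous` (logical).
#' @slot nGenesTotal number of transcripts scanned.
#' @slot nGenesWithCatg number of transcripts contributing at least one
#'   valid sense tag site.
#' @slot nTagsDroppedN number of candidate 21-mers skipped because they
#'   contained an N.
#'
#' @seealso [referenceSummary()], [writeTagDB()]
#' @export
setClass("ReferenceTagDB",
  representation(
    tags = "data.frame",
    nGenesTotal = "integer",
    nGenesWithCatg = "integer",
    nTagsDroppedN = "integer"
  )
)

setValidity("ReferenceTagDB", function(object) {
  tg <- object@tags
  need <- c("tag_seq", "gene_id", "strand", "offset", "ambiguous")
  if (!all(need %in% names(tg)))
    return(paste("tags must have columns:", paste(need, collapse = ", ")))
  if (nrow(tg)) {
    if (any(nchar(tg$tag_seq) != 21L))
      return("all tag_seq must be 21 nt")
    if (any(substr(tg$tag_seq, 1L, 4L) != "CATG"))
      return("all tag_seq must begin with CATG")
    if (!all(tg$strand %in% c("sense", "antisense")))
      return("strand must be 'sense' or 'antisense'")
  }
  if (object@nGenesWithCatg > object@nGenesTotal)
    return("nGenesWithCatg cannot exceed nGenesTotal")
  TRUE
})

#' A stage's tag library
#'
#' A multiset of 21-nt tags with copy numbers, labelled with the
#' developmental stage it profiles (e.g. MP, HP, PT). Construct with
#' [TagLibrary()], [readTagCounts()] or [tagsFromFastq()].
#'
#' @slot stage single stage label.
#' @slot tags character vector of distinct 21-nt tag sequences.
#' @slot counts numeric vector of positive integer copy numbers, parallel
#'   to `tags`.
#'
#' @export
setClass("TagLibrary",
  representation(stage = "character", tags = "character", counts = "numeric")
)

setValidity("TagLibrary", function(object) {
  if (length(object@stage) != 1L) return("stage must be a single label")
  if (length(object@tags) != length(object@counts))
    return("tags and counts must be parallel")
  bad <- which(nchar(object@tags) != 21L)
  if (length(bad))
    return(sprintf("tag of wrong length (not 21 nt): '%s'",
                   object@tags[bad[1L]]))
  if (anyDuplicated(object@tags)) return("tag sequences must be distinct")
  if (length(object@counts) && any(object@counts < 1 |
                                   object@counts != round(object@counts)))
    return("counts must be positive integers")
  TRUE
})

#' Construct a TagLibrary
#'
#' @param counts named numeric vector (names are 21-nt tag sequences,
#'   values positive integer copy numbers) or unnamed vector accompanied
#'   by `tags`.
#' @param stage stage label, e.g. `"MP"`.
#' @param tags optional character vector of tag sequences if `counts` is
#'   unnamed.
#' @return A [TagLibrary-class] object.
#' @examples
#' lib <- TagLibrary(c(CATGAAAAAAAAAAAAAAAAA = 5), stage = "MP")
#' tagTotal(lib)
#' @export
TagLibrary <- function(counts, stage = "library", tags = names(counts)) {
  if (is.null(tags)) stop("tag sequences required (names of counts or tags=)")
  new("TagLibrary", stage = as.character(stage),
      tags = as.character(tags), counts = as.numeric(counts))
}

#' @describeIn TagLibrary total tag count (sum of copy numbers).
#' @param x a `TagLibrary`.
#' @export
tagTotal <- function(x) sum(x@counts)

#' @describeIn TagLibrary number of distinct tag sequences.
#' @export
tagDistinct <- function(x) length(x@tags)

#' @describeIn TagLibrary named copy-number vector.
#' @export
tagCounts <- function(x) setNames(x@counts, x@tags)

#' @describeIn TagLibrary stage label.
#' @export
stageLabel <- function(x) x@stage

setMethod("show", "TagLibrary", function(object) {
  cat(sprintf("TagLibrary '%s': %d distinct / %.0f total tags\n",
              object@stage, tagDistinct(object), tagTotal(object)))
})

setMethod("show", "ReferenceTagDB", function(object) {
  cat(sprintf(
    "ReferenceTagDB: %d virtual tags (%d unambiguous) from %d/%d genes with a CATG site\n",
    nrow(object@tags), sum(!object@tags$ambiguous),
    object@nGenesWithCatg, object@nGenesTotal))
})

#' @describeIn ReferenceTagDB the virtual tag table.
#' @param x a `ReferenceTagDB`.
#' @export
refTags <- function(x) x@tags

#' @describeIn ReferenceTagDB number of genes scanned.
#' @export
nRefGenes <- function(x) x@nGenesTotal
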