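mkTags <- function(n, prefix = "CATG") {
  vapply(seq_len(n), function(i)
    paste0(prefix, paste(sample(c("A", "C", "G", "T"), 21 - nchar(prefix),
                                replace = TRUE), collapse = "")),
    character(1))
}

test_that("toy library filters by the N -> adaptor -> singleton order", {
  raw <- TagLibrary(c(3, 5, 1), stage = "x",
                    tags = c(paste0("CATG", strrep("A", 17)),
                             paste0("CATG", strrep("C", 16), "N"),
                             paste0("CATG", strrep("G", 17))))
  res <- filterRawTags(raw)
  expect_equal(tagCounts(res$clean),
               setNames(3, paste0("CATG", strrep("A", 17))))
  expect_equal(unname(unlist(res$ledger["tags_containing_N", ])), c(1, 5))
  expect_equal(unname(unlist(res$ledger["copy_lt_2", ])), c(1, 1))
  expect_equal(unname(unlist(res$ledger["clean", ])), c(1, 3))
})

test_that("adaptor reads are removed by exact equality before the singleton pass", {
  ad <- "TCGTATGCCGTCTTCTGCTTG"
  raw <- TagLibrary(c(10, 2), stage = "x",
                    tags = c(ad, paste0("CATG", strrep("T", 17))))
  res <- filterRawTags(raw, adaptorSeqs = ad)
  expect_equal(unname(unlist(res$ledger["adaptors", ])), c(1, 10))
  expect_equal(tagDistinct(res$clean), 1L)
})

test_that("wrong-length tags are rejected naming the read", {
  expect_error(TagLibrary(c(2), tags = "CATGAAA"), "CATGAAA")
})

test_that("ledger conservation holds on fuzzed libraries and matches the naive filter", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(50:300, 1)
    tags <- unique(mkTags(n))
    # inject N tags and singletons
    iN <- sample(seq_along(tags), length(tags) %/% 10)
    substr(tags[iN], 10, 10) <- "N"
    tags <- tags[!duplicated(tags)]
    counts <- sample(1:50, length(tags), replace = TRUE)
    raw <- TagLibrary(counts, tags = tags, stage = "fuzz")
    res <- filterRawTags(raw)
    lg <- res$ledger
    expect_equal(lg["raw", "distinct"] - lg["tags_containing_N", "distinct"] -
                   lg["adaptors", "distinct"] - lg["copy_lt_2", "distinct"],
                 lg["clean", "distinct"])
    expect_equal(lg["raw", "total"] - lg["tags_containing_N", "total"] -
                   lg["adaptors", "total"] - lg["copy_lt_2", "total"],
                 lg["clean", "total"])
    expect_equal(lg["copy_lt_2", "distinct"], lg["copy_lt_2", "total"])
    orc <- oracleFilter(tags, counts)
    expect_equal(sort(tagCounts(res$clean)[orc$tags]),
                 sort(setNames(orc$counts, orc$tags)))
    expect_equal(unname(unlist(lg["tags_containing_N", ])), unname(orc$nN))
  }
})

test_that("filtering is idempotent", {
  set.seed(11)
  tags <- unique(mkTags(100))
  raw <- TagLibrary(sample(1:20, length(tags), replace = TRUE),
                    tags = tags, stage = "x")
  clean <- filterRawTags(raw)$clean
  again <- filterRawTags(clean)
  expect_equal(tagCounts(again$clean), tagCounts(clean))
  expect_equal(sum(again$ledger[c("tags_containing_N", "adaptors",
                                  "copy_lt_2"), "total"]), 0)
})

test_that("simulated library (seed 7) satisfies the ledger and clean totals match the naive recount", {
  cfg <- simConfig(nGenes = 150, depth = 2e5, seed = 7)
  tx <- simulateTranscriptome(cfg)
  tr <- simulateStageProfiles(cfg, names(tx))
  sim <- simulateTagLibrary(tx, tr$tpm[, "MP"], cfg, "MP", seed = 7)
  res <- filterRawTags(sim$library)
  orc <- oracleFilter(sim$library@tags, sim$library@counts)
  expect_equal(tagTotal(res$clean), sum(orc$counts))
  expect_equal(tagDistinct(res$clean), length(orc$tags))
})

test_that("copy spectrum uses >=2 then strict thresholds and matches brute force", {
  clean <- TagLibrary(c(2, 6, 101), stage = "x",
                      tags = mkTags(3))
  sp <- copySpectrum(clean)
  expect_equal(sp$distinct, c(3, 2, 1, 1, 1, 1))
  expect_equal(sp$total, c(109, 107, 101, 101, 101, 101))

  set.seed(7)
  tags <- unique(mkTags(400))
  counts <- sample(2:300, length(tags), replace = TRUE)
  lib <- TagLibrary(counts, tags = tags, stage = "x")
  sp <- copySpectrum(lib)
  for (i in seq_along(sp$threshold)) {
    th <- sp$threshold[i]
    sel <- if (th == ">=2") counts >= 2 else
      counts > as.numeric(sub(">", "", th))
    expect_equal(sp$distinct[i], sum(sel))
    expect_equal(sp$total[i], sum(counts[sel]))
  }
  expect_true(all(diff(sp$distinct) <= 0))
  expect_true(all(diff(sp$total) <= 0))
  expect_error(copySpectrum(TagLibrary(c(1), tags = mkTags(1))),
               "copy-number-1")
  expect_true(lowCopyFraction(lib) >= 0 && lowCopyFraction(lib) <= 1)
})

test_that("FASTQ reads are anchored at the first CATG and anchorless reads are counted", {
  reads <- c(paste0("TT", "CATG", strrep("A", 17), "GGG"),  # anchored
             paste0("CATG", strrep("C", 17)),               # exact 21
             strrep("T", 30),                               # no anchor
             paste0(strrep("G", 20), "CATG", "AAAA"))       # < 17 after
  fq <- tempfile(fileext = ".fq")
  writeLines(unlist(lapply(seq_along(reads), function(i)
    c(paste0("@r", i), reads[i], "+",
      strrep("I", nchar(reads[i]))))), fq)
  lib <- tagsFromFastq(fq, stage = "MP")
  expect_equal(sort(lib@tags),
               sort(c(paste0("CATG", strrep("A", 17)),
                      paste0("CATG", strrep("C", 17)))))
  expect_equal(attr(lib, "noAnchor"), 2L)
})

test_that("tag-count TSV round-trips a library", {
  tags <- c(paste0("CATG", strrep("A", 17)), paste0("CATG", strrep("G", 17)))
  lib <- TagLibrary(c(5, 9), tags = tags, stage = "HP")
  f <- tempfile(fileext = ".tsv")
  writeTagCounts(lib, f)
  lib2 <- readTagCounts(f, stage = "HP")
  expect_equal(tagCounts(lib2), tagCounts(lib))
})
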