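# A tiny reference where tags are controllable: each gene is a CATG site
# plus a designed 17-mer.
mkRef <- function(suffixes) {
  seqs <- setNames(paste0("CATG", suffixes), names(suffixes))
  scanCatgTags(seqs)
}

test_that("exact unique hits, multi-gene exclusion and unknowns partition the library", {
  db <- mkRef(c(gA = strrep("A", 17), gB = strrep("C", 17)))
  tagA <- paste0("CATG", strrep("A", 17))
  # one mismatch from both gA (pos 5) and gB? construct a tag at distance
  # 1 from gA only, and one unmatched
  near <- paste0("CATG", "T", strrep("A", 16))
  far <- paste0("CATG", paste(rep(c("G", "T"), length.out = 17),
                              collapse = ""))
  lib <- TagLibrary(c(10, 5, 2), tags = c(tagA, near, far), stage = "x")
  res <- mapTags(lib, db)
  a <- res$assignments
  expect_equal(a$match_class, c("exact", "one_mismatch", "unknown"))
  expect_equal(a$gene_id[1:2], c("gA", "gA"))
  expect_equal(a$strand[1:2], c("sense", "sense"))
  s <- res$summary
  expect_equal(unname(s$all_mapping["distinct"] + s$unknown["distinct"]),
               tagDistinct(lib))
  expect_equal(unname(s$all_mapping["total"] + s$unknown["total"]),
               tagTotal(lib))
})

test_that("a tag at distance 1 from two genes is excluded and counted to none", {
  db <- mkRef(c(gA = paste0("A", strrep("G", 16)),
                gB = paste0("C", strrep("G", 16))))
  probe <- paste0("CATG", "T", strrep("G", 16))  # distance 1 from both
  lib <- TagLibrary(c(7), tags = probe, stage = "x")
  a <- mapTags(lib, db)$assignments
  expect_true(a$excluded_multi_gene)
  expect_equal(a$n_genes, 2L)
  expect_true(is.na(a$gene_id))
})

test_that("an exact single-gene hit beats 1-mismatch hits to other genes", {
  db <- mkRef(c(gA = strrep("A", 17),
                gB = paste0("T", strrep("A", 16))))  # distance 1 from gA tag
  tagA <- paste0("CATG", strrep("A", 17))
  a <- mapTags(TagLibrary(c(3), tags = tagA, stage = "x"), db)$assignments
  expect_equal(a$match_class, "exact")
  expect_equal(a$gene_id, "gA")
  expect_false(a$excluded_multi_gene)
})

test_that("assignments equal the brute-force Hamming oracle on a simulated library", {
  cfg <- simConfig(nGenes = 300, depth = 3e4, seed = 7)
  tx <- simulateTranscriptome(cfg)
  tr <- simulateStageProfiles(cfg, names(tx))
  sim <- simulateTagLibrary(tx, tr$tpm[, "MP"], cfg, "MP", seed = 7)
  clean <- filterRawTags(sim$library)$clean
  db <- scanCatgTags(tx)
  a <- mapTags(clean, db)$assignments

  tg <- refTags(db)
  orc <- oracleAssign(clean@tags, tg$tag_seq, tg$gene_id)
  expect_equal(a$match_class, unname(orc[, "class"]))
  orcGenes <- orc[, "genes"]
  expect_equal(ifelse(a$n_genes == 1L, a$gene_id, NA_character_),
               unname(ifelse(orc[, "class"] != "unknown" &
                               !grepl(",", orcGenes), orcGenes, NA)))
  multi <- orc[, "class"] != "unknown" & grepl(",", orcGenes)
  expect_equal(a$excluded_multi_gene, unname(multi))

  # partition property on distinct and total counts
  s <- mapTags(clean, db)$summary
  expect_equal(unname(s$unambiguous_mapping["distinct"] +
                        s$excluded_multi_gene["distinct"] +
                        s$unknown["distinct"]),
               tagDistinct(clean))
  expect_equal(unname(s$unambiguous_mapping["total"] +
                        s$excluded_multi_gene["total"] +
                        s$unknown["total"]),
               tagTotal(clean))
})

test_that("error-free, antisense-free libraries map all-sense and all-exact", {
  cfg <- simConfig(nGenes = 100, depth = 2e4, perBaseError = 0,
                   nReadRate = 0, singletonNoiseRate = 0,
                   antisenseFraction = 0, seed = 9)
  tx <- simulateTranscriptome(cfg)
  tr <- simulateStageProfiles(cfg, names(tx))
  sim <- simulateTagLibrary(tx, tr$tpm[, "MP"], cfg, "MP", seed = 9)
  clean <- filterRawTags(sim$library)$clean
  a <- mapTags(clean, scanCatgTags(tx))$assignments
  expect_true(all(a$match_class == "exact"))
  expect_true(all(a$strand[!is.na(a$gene_id)] == "sense"))
})

test_that("singly-errored tags of unambiguous origin are recovered as one-mismatch", {
  # a well-separated reference: tags differ in >= 3 positions
  suff <- c(gA = strrep("A", 17), gB = strrep("C", 17),
            gC = strrep("G", 17), gD = strrep("T", 17))
  db <- mkRef(suff)
  set.seed(2)
  tags <- paste0("CATG", suff)
  errTags <- vapply(rep(tags, 5), function(t) {
    p <- sample(5:21, 1)
    substr(t, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(t, p, p)), 1)
    t
  }, character(1))
  errTags <- unique(errTags)
  lib <- TagLibrary(rep(2, length(errTags)), tags = errTags, stage = "x")
  a <- mapTags(lib, db)$assignments
  expect_gte(mean(a$match_class == "one_mismatch" & !is.na(a$gene_id)), 0.9)
})

test_that("quantification sums uniquely assigned copies and flags detection", {
  se <- toyExpression()
  expect_equal(unname(exprCounts(se)["gB", ]), c(40, 50, 60))
  expect_equal(unname(exprTpm(se)["gB", "MP"]), 40)  # 40 / 1e6 * 1e6
  expect_equal(unname(exprCounts(se)["gD", ]), c(0, 0, 0))
  expect_error(quantifyExpression(list(MP = data.frame()),
                                  c(MP = 0), "g"),
               "zero clean tags")
})

test_that("stage classification reproduces the toy and published percentage conventions", {
  se <- toyExpression()
  cls <- classifyStages(se, c("MP", "HP", "PT"))
  expect_equal(unname(cls$detected), c(2, 2, 2))
  expect_equal(unname(cls$specific), c(1, 0, 0))  # gA is MP-only
  expect_equal(cls$allStages, 1)                  # gB
  expect_equal(cls$atLeastOne, 3)
  expect_equal(stagePercent(11751, 41404), 28.38)
  expect_equal(stagePercent(13017, 41404), 31.44)
})

test_that("saturation curve hits the trivial endpoints and the closed-form expectation", {
  set.seed(5)
  tags <- unique(vapply(1:200, function(i)
    paste0("CATG", paste(sample(c("A", "C", "G", "T"), 17, TRUE),
                         collapse = "")), character(1)))
  counts <- sample(2:40, length(tags), replace = TRUE)
  lib <- TagLibrary(counts, tags = tags, stage = "x")
  total <- tagTotal(lib)
  sat <- saturationCurve(lib, c(1, round(total / 3), total), nReps = 30,
                         seed = 4)
  expect_equal(sat$meanDistinctTags[1], 1)
  expect_equal(sat$meanDistinctTags[3], tagDistinct(lib))
  expect_true(all(diff(sat$meanDistinctTags) >= 0))
  # middle depth vs expectation within 3 SE of the replicate mean
  mid <- round(total / 3)
  expv <- expectedDistinctTags(lib, mid)
  reps <- vapply(1:30, function(r)
    saturationCurve(lib, mid, nReps = 1, seed = 100 + r)$meanDistinctTags,
    numeric(1))
  se3 <- 3 * sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - expv), max(se3, 1e-9))
  expect_error(saturationCurve(lib, total + 1), "exceeds")
})

test_that("fold-change distribution bins TPM ratios with fractions summing to one", {
  counts <- rbind(g1 = c(A = 10, B = 10), g2 = c(A = 10, B = 30),
                  g3 = c(A = 10, B = 100))
  mk <- function(s) data.frame(
    tag_seq = paste0("CATG", strrep("A", 16), c("A", "C", "G")),
    count = counts[, s], match_class = "exact", strand = "sense",
    gene_id = rownames(counts), n_genes = 1L,
    excluded_multi_gene = FALSE, stringsAsFactors = FALSE)
  se <- quantifyExpression(list(A = mk("A"), B = mk("B")),
                           c(A = 1e6, B = 1e6), rownames(counts))
  fd <- foldChangeDistribution(se, "A", "B")
  expect_equal(fd$fraction, rep(1 / 3, 3))
  fdSame <- foldChangeDistribution(se, "A", "A")
  expect_equal(fdSame$fraction, c(1, 0, 0))
  expect_equal(sum(fd$fraction), 1)
})
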