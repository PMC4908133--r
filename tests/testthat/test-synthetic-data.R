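test_that("config validation rejects impossible settings", {
  expect_error(simConfig(perBaseError = 1.5), "rates")
  expect_error(simConfig(depth = 0), "depth")
  expect_error(simConfig(lengthRange = c(10, 50)), "infeasible")
  expect_error(simConfig(specificFraction = c(MP = 0.5, HP = 0.3,
                                              PT = 0.3)), "exceed")
})

test_that("transcriptome honours the CATG fraction and is seed-reproducible", {
  cfg <- simConfig(nGenes = 500, catgFraction = 0.9, seed = 1)
  tx <- simulateTranscriptome(cfg)
  seqs <- as.character(tx)
  hasSite <- vapply(seqs, function(s)
    grepl("CATG.{17}", s), logical(1))
  expect_gte(sum(hasSite), 435)
  expect_lte(sum(hasSite), 465)
  cfgAll <- simConfig(nGenes = 100, catgFraction = 1, seed = 4)
  expect_true(all(grepl("CATG.{17}",
                        as.character(simulateTranscriptome(cfgAll)))))
  tx2 <- simulateTranscriptome(cfg)
  expect_identical(as.character(tx), as.character(tx2))
})

test_that("stage profiles: column sums, specificity zeros and planted effect sizes", {
  cfg <- simConfig(nGenes = 1000, seed = 11)
  tr <- simulateStageProfiles(cfg, seed = 11)
  expect_equal(unname(colSums(tr$tpm)), rep(1e6, 3), tolerance = 1e-6)
  expect_equal(length(tr$specific$MP), 150)  # 0.15 * 1000, deterministic
  for (s in c("MP", "HP", "PT"))
    expect_true(all(tr$tpm[tr$specific[[s]],
                           setdiff(colnames(tr$tpm), s)] == 0))
  # planted genes carry |log2 effect| >= 1 in their comparison's truth
  for (cc in names(tr$planted)) {
    planted <- tr$planted[[cc]]$gene_id
    expect_true(all(abs(tr$log2Truth[[cc]][planted]) >= 1))
  }
  # all-zero DE and specificity yields identical stage columns
  cfg0 <- simConfig(nGenes = 200, deFraction = 0, deBothFraction = 0,
                    specificFraction = c(MP = 0, HP = 0, PT = 0),
                    seed = 3)
  tr0 <- simulateStageProfiles(cfg0, seed = 3)
  expect_equal(tr0$tpm[, 1], tr0$tpm[, 2])
  expect_equal(tr0$tpm[, 2], tr0$tpm[, 3])
})

test_that("noise-free libraries contain only sense reference tags of expressed genes", {
  cfg <- simConfig(nGenes = 100, depth = 1e4, perBaseError = 0,
                   nReadRate = 0, singletonNoiseRate = 0,
                   antisenseFraction = 0, seed = 21)
  tx <- simulateTranscriptome(cfg)
  tr <- simulateStageProfiles(cfg, names(tx))
  sim <- simulateTagLibrary(tx, tr$tpm[, "MP"], cfg, "MP", seed = 21)
  db <- scanCatgTags(tx)
  senseTags <- refTags(db)$tag_seq[refTags(db)$strand == "sense"]
  expect_true(all(sim$library@tags %in% senseTags))
  expect_true(all(sim$provenance$class == "perfect"))
})

test_that("the errored-read fraction matches the binomial closed form within 3 SE", {
  cfg <- simConfig(nGenes = 200, depth = 1e5, perBaseError = 0.005,
                   nReadRate = 0, singletonNoiseRate = 0,
                   adaptorRate = 0, seed = 8)
  tx <- simulateTranscriptome(cfg)
  tr <- simulateStageProfiles(cfg, names(tx))
  sim <- simulateTagLibrary(tx, tr$tpm[, "MP"], cfg, "MP", seed = 8)
  prov <- sim$provenance
  nErr <- sum(prov$count[prov$class == "errored"])
  nTot <- sum(prov$count)
  pExp <- 1 - (1 - 0.005)^21
  se3 <- 3 * sqrt(pExp * (1 - pExp) / nTot)
  expect_lt(abs(nErr / nTot - pExp), se3)
})

test_that("libraries, annotations and Ct tables are bit-reproducible under a fixed seed", {
  cfg <- simConfig(nGenes = 80, depth = 5e3, seed = 14)
  tx <- simulateTranscriptome(cfg)
  tr <- simulateStageProfiles(cfg, names(tx))
  a <- simulateTagLibrary(tx, tr$tpm[, "HP"], cfg, "HP", seed = 14)
  b <- simulateTagLibrary(tx, tr$tpm[, "HP"], cfg, "HP", seed = 14)
  expect_identical(tagCounts(a$library), tagCounts(b$library))
  g <- names(tx)
  expect_identical(simulateAnnotations(g, g[1:10], cfg, seed = 5),
                   simulateAnnotations(g, g[1:10], cfg, seed = 5))
  tpm <- tr$tpm[rowSums(tr$tpm == 0) == 0, ][1:3, c("MP", "PT")]
  expect_identical(simulateQpcr(tr$tpm, rownames(tpm), cfg, seed = 6)$ct,
                   simulateQpcr(tr$tpm, rownames(tpm), cfg, seed = 6)$ct)
})

test_that("planted annotation term over-samples DE genes near its expected overlap", {
  cfg <- simConfig(nGenes = 1000, plantedOddsRatio = 8, seed = 17)
  genes <- sprintf("gene_%04d", 1:1000)
  de <- genes[1:100]
  # expected planted-term DE members: K * w_de / (w_de + w_bg) with
  # weights 8 * 100 vs 1 * 900
  K <- round(mean(cfg$termSizeRange))
  pDe <- 8 * 100 / (8 * 100 + 900)  # per-draw odds before depletion
  reps <- vapply(1:30, function(r) {
    anno <- simulateAnnotations(genes, de, cfg, seed = 1000 + r)
    sum(anno$gene_id[anno$term_id == "term_planted"] %in% de)
  }, numeric(1))
  # weighted sampling without replacement depletes the DE pool, so the
  # realised mean sits at or below the per-draw expectation but far above
  # the uniform one
  expect_lte(mean(reps), K * pDe + 3)
  expect_gt(mean(reps), 2 * K * 100 / 1000)
  # odds ratio 1 plants nothing special
  cfg1 <- simConfig(nGenes = 1000, plantedOddsRatio = 1, seed = 17)
  reps1 <- vapply(1:30, function(r) {
    anno <- simulateAnnotations(genes, de, cfg1, seed = 2000 + r)
    sum(anno$gene_id[anno$term_id == "term_planted"] %in% de)
  }, numeric(1))
  expect_lt(mean(reps1), K * 100 / 1000 + 3 * sd(reps1) / sqrt(30))
})
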