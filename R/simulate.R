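# Synthetic-data generators with ground truth: transcriptomes with a
# controlled CATG-site fraction, three-stage expression profiles with
# planted stage-specific and differentially expressed genes, raw tag
# libraries with sequencing noise classes, term annotations with a
# planted enriched term, and Ct tables.
#
# The generators emit reads from the 3'-most CATG site of each gene (the
# NlaIII DGE chemistry), while the reference scanner indexes all sites;
# that asymmetry is deliberate.

#' Simulation configuration
#'
#' Parameters of the synthetic three-stage DGE study. Defaults emulate
#' the magnitudes of a pooled-library pollen tag-profiling experiment:
#' ~90% of genes carrying a CATG site, libraries dominated by low-copy
#' tags, ~1% of reads carrying an N, no adaptor contamination, a few
#' percent of singleton noise tags, a minority antisense-transcribed
#' read fraction, and stage-specific plus >= 2-fold differentially
#' expressed gene subsets.
#'
#' @param nGenes number of transcripts.
#' @param lengthRange transcript length range in nt (min must allow a
#'   21-nt tag).
#' @param catgFraction target fraction of genes with a valid sense CATG
#'   site.
#' @param specificFraction named fractions (stages) of genes expressed in
#'   exactly that stage.
#' @param deFraction fraction of genes planted as differentially
#'   expressed, per comparison.
#' @param deBothFraction fraction of genes planted as differentially
#'   expressed in both successive comparisons (the highly dynamic genes
#'   that drive the clustering stage).
#' @param log2EffectRange magnitude range of planted log2 effects.
#' @param tpmSdLog log-normal sdlog of baseline expression.
#' @param depth total raw tags per stage library.
#' @param perBaseError per-base substitution error rate of a read.
#' @param nReadRate fraction of reads carrying an N.
#' @param adaptorRate fraction of adaptor reads.
#' @param adaptorSeq 21-nt adaptor sequence emitted for adaptor reads.
#' @param singletonNoiseRate fraction of reads that are unique random
#'   noise tags.
#' @param antisenseFraction probability that a read of a gene is drawn
#'   from its antisense strand.
#' @param stages stage labels, in developmental order.
#' @param nTerms,termSizeRange background annotation terms and their size
#'   range.
#' @param plantedOddsRatio over-sampling odds of DE genes in the planted
#'   term.
#' @param ctBaseline,ctNoiseSd,qpcrReplicates Ct-table generation
#'   parameters.
#' @param seed master RNG seed; all generators derive from it.
#' @return A classed list of validated parameters.
#' @export
simConfig <- function(nGenes = 1000,
                      lengthRange = c(200, 800),
                      catgFraction = 0.9,
                      specificFraction = c(MP = 0.15, HP = 0.03, PT = 0.07),
                      deFraction = 0.10,
                      deBothFraction = 0.02,
                      log2EffectRange = c(1.5, 3),
                      tpmSdLog = 1.2,
                      depth = 5e5,
                      perBaseError = 0.005,
                      nReadRate = 0.012,
                      adaptorRate = 0,
                      adaptorSeq = "TCGTATGCCGTCTTCTGCTTG",
                      singletonNoiseRate = 0.035,
                      antisenseFraction = 0.15,
                      stages = c("MP", "HP", "PT"),
                      nTerms = 50,
                      termSizeRange = c(20, 100),
                      plantedOddsRatio = 8,
                      ctBaseline = 30,
                      ctNoiseSd = 0.1,
                      qpcrReplicates = 3,
                      seed = 42) {
  rates <- c(catgFraction, specificFraction, deFraction, perBaseError,
             nReadRate, adaptorRate, singletonNoiseRate, antisenseFraction)
  if (any(rates < 0 | rates > 1)) stop("all rates must be in [0, 1]")
  if (depth < 1) stop("depth must be >= 1")
  if (lengthRange[1] < 21 && catgFraction > 0)
    stop("infeasible length/fraction combination: minimum length < 21")
  if (sum(specificFraction) + 2 * deFraction + deBothFraction > 1)
    stop("specific and DE fractions exceed the gene set")
  if (nchar(adaptorSeq) != 21L) stop("adaptorSeq must be 21 nt")
  structure(as.list(environment()), class = "SimConfig")
}

#' Simulate a transcriptome with a controlled CATG-site fraction
#'
#' Sequences are i.i.d. uniform over A/C/G/T; exactly
#' `round(catgFraction * nGenes)` genes are guaranteed a sense CATG site
#' with >= 17 following bases (planted when the random draw lacks one),
#' and the remaining genes are scrubbed of such sites.
#'
#' @param config a [simConfig()].
#' @param seed RNG seed; defaults to the config's.
#' @return Named [Biostrings::DNAStringSet] (`gene_0001`, ...).
#' @export
simulateTranscriptome <- function(config, seed = config$seed) {
  n <- config$nGenes
  withSeed(seed, {
    lens <- sample(config$lengthRange[1]:config$lengthRange[2], n,
                   replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), character(1))
    nWith <- round(config$catgFraction * n)
    withSite <- sample.int(n, nWith)
    hasSite <- logical(n)
    hasSite[withSite] <- TRUE
    for (i in seq_len(n)) {
      if (hasSite[i]) {
        if (!length(.catgSites(seqs[i]))) {
          p <- sample.int(lens[i] - 20L, 1L)
          substr(seqs[i], p, p + 3L) <- "CATG"
        }
      } else {
        for (pass in 1:10) {
          p <- .catgSites(seqs[i])
          if (!length(p)) break
          substr(seqs[i], p[1L], p[1L]) <-
            sample(c("A", "G", "T"), 1L)
        }
        if (length(.catgSites(seqs[i])))
          stop("failed to scrub CATG sites; widen lengthRange")
      }
    }
    names(seqs) <- sprintf("gene_%04d", seq_len(n))
    Biostrings::DNAStringSet(seqs)
  })
}

#' Simulate three-stage expression profiles with ground truth
#'
#' Baseline abundances are log-normal; disjoint gene subsets are made
#' stage-specific (TPM 0 outside their stage) or differentially expressed
#' in one of the two successive comparisons with a signed log2 effect
#' drawn from `log2EffectRange`; each stage column is then normalised to
#' one million TPM. Truth labels are recomputed from the final matrix so
#' they remain consistent after normalisation.
#'
#' @param config a [simConfig()].
#' @param geneIds gene identifiers (default `gene_0001` style).
#' @param seed RNG seed.
#' @param pseudoTpm pseudo-TPM used for the truth log ratios.
#' @return A list: `tpm` (genes x stages, columns sum to 1e6),
#'   `specific` (named list of gene id vectors per stage), `planted`
#'   (per comparison: gene ids and signed planted effects), `deLabels`
#'   (per comparison: logical vector over genes, TRUE when the truth
#'   |log2 ratio| >= 1), `log2Truth` (per comparison numeric vector).
#' @export
simulateStageProfiles <- function(config,
                                  geneIds = sprintf("gene_%04d",
                                                    seq_len(config$nGenes)),
                                  seed = config$seed + 1L,
                                  pseudoTpm = 0.001) {
  n <- length(geneIds)
  st <- config$stages
  stopifnot(length(st) == 3L)
  withSeed(seed, {
    base <- rlnorm(n, meanlog = 0, sdlog = config$tpmSdLog)
    tpm <- matrix(base, n, 3, dimnames = list(geneIds, st))

    perm <- sample.int(n)
    nSpec <- round(config$specificFraction[st] * n)
    nDe <- round(config$deFraction * n)
    take <- function(k) {
      out <- perm[seq_len(k)]
      perm <<- perm[-seq_len(k)]
      out
    }
    specific <- lapply(st, function(s) take(nSpec[[s]]))
    names(specific) <- st
    for (s in st) tpm[specific[[s]], setdiff(st, s)] <- 0

    plantEffect <- function(idx) {
      sgn <- sample(c(-1, 1), length(idx), replace = TRUE)
      sgn * runif(length(idx), config$log2EffectRange[1],
                  config$log2EffectRange[2])
    }
    dePg <- take(nDe)
    effPg <- plantEffect(dePg)
    tpm[dePg, st[2]] <- tpm[dePg, st[1]] * 2^effPg
    tpm[dePg, st[3]] <- tpm[dePg, st[2]]
    dePtg <- take(nDe)
    effPtg <- plantEffect(dePtg)
    tpm[dePtg, st[3]] <- tpm[dePtg, st[2]] * 2^effPtg
    # highly dynamic genes: independent effects in both comparisons
    deBoth <- take(round(config$deBothFraction * n))
    effB1 <- plantEffect(deBoth)
    effB2 <- plantEffect(deBoth)
    tpm[deBoth, st[2]] <- tpm[deBoth, st[1]] * 2^effB1
    tpm[deBoth, st[3]] <- tpm[deBoth, st[2]] * 2^effB2
    dePg <- c(dePg, deBoth)
    effPg <- c(effPg, effB1)
    dePtg <- c(dePtg, deBoth)
    effPtg <- c(effPtg, effB2)

    tpm <- sweep(tpm, 2, colSums(tpm), "/") * 1e6

    lr <- function(a, b) log2((tpm[, b] + pseudoTpm) /
                                (tpm[, a] + pseudoTpm))
    log2Truth <- list(lr(st[1], st[2]), lr(st[2], st[3]))
    names(log2Truth) <- c(paste0(st[1], "vs", st[2]),
                          paste0(st[2], "vs", st[3]))
    deLabels <- lapply(log2Truth, function(v) abs(v) >= 1)
    list(
      tpm = tpm,
      specific = lapply(specific, function(i) geneIds[i]),
      planted = setNames(list(
        data.frame(gene_id = geneIds[dePg], effect = effPg,
                   stringsAsFactors = FALSE),
        data.frame(gene_id = geneIds[dePtg], effect = effPtg,
                   stringsAsFactors = FALSE)), names(log2Truth)),
      deLabels = deLabels,
      log2Truth = log2Truth)
  })
}

# 3'-most valid CATG tag per strand for every gene; NA when absent
.threePrimeTags <- function(transcriptome) {
  seqs <- as.character(transcriptome)
  rc <- .revcomp(seqs)
  last <- function(s) {
    p <- .catgSites(s)
    if (!length(p)) NA_character_ else substr(s, max(p), max(p) + 20L)
  }
  data.frame(gene_id = names(seqs),
             sense = vapply(seqs, last, character(1), USE.NAMES = FALSE),
             antisense = vapply(rc, last, character(1), USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

# mutate k random positions of each read (k >= 1), never to the same base
.mutateReads <- function(reads, kPerRead) {
  bases <- c("A", "C", "G", "T")
  for (round in seq_len(max(kPerRead))) {
    act <- which(kPerRead >= round)
    if (!length(act)) break
    pos <- sample.int(21L, length(act), replace = TRUE)
    cur <- substr(reads[act], pos, pos)
    alt <- vapply(cur, function(b) sample(setdiff(bases, b), 1L),
                  character(1), USE.NAMES = FALSE)
    substr(reads[act], pos, pos) <- alt
  }
  reads
}

#' Simulate a raw tag library for one stage
#'
#' Reads are multinomial over expressed genes proportionally to their
#' TPM; each gene emits its 3'-most sense CATG tag, or (with probability
#' `antisenseFraction`, when the gene has one) its 3'-most antisense tag.
#' Independent per-base substitution errors, N-carrying reads, adaptor
#' reads and unique random singleton noise tags are then injected at the
#' configured rates. Expressed genes without a CATG site are excluded
#' from sampling and reported.
#'
#' @param transcriptome [Biostrings::DNAStringSet] from
#'   [simulateTranscriptome()].
#' @param tpm named numeric vector of the stage's true TPM.
#' @param config a [simConfig()].
#' @param stage stage label.
#' @param seed RNG seed.
#' @return A list: `library` (raw [TagLibrary-class]), `provenance`
#'   (data.frame `tag_seq`, `count`, `gene_id`, `strand`, `class` with
#'   class in perfect/errored/n_read/adaptor/noise), `skippedGenes`
#'   (expressed genes without a CATG site).
#' @export
simulateTagLibrary <- function(transcriptome, tpm, config, stage = "MP",
                               seed = config$seed + 100L) {
  tags3p <- .threePrimeTags(transcriptome)
  tpm <- tpm[tags3p$gene_id]
  expressed <- tpm > 0
  skipped <- tags3p$gene_id[expressed & is.na(tags3p$sense)]
  ok <- expressed & !is.na(tags3p$sense)

  withSeed(seed, {
    depth <- config$depth
    classN <- rmultinom(1, depth, c(adaptor = config$adaptorRate,
                                    noise = config$singletonNoiseRate,
                                    gene = 1 - config$adaptorRate -
                                      config$singletonNoiseRate))[, 1]
    geneReads <- rmultinom(1, classN[["gene"]], tpm[ok])[, 1]
    gid <- tags3p$gene_id[ok]
    hasAnti <- !is.na(tags3p$antisense[ok])
    nAnti <- ifelse(hasAnti,
                    rbinom(sum(ok), geneReads, config$antisenseFraction), 0L)
    nSense <- geneReads - nAnti

    src <- rbind(
      data.frame(tag_seq = tags3p$sense[ok], count = nSense, gene_id = gid,
                 strand = "sense", stringsAsFactors = FALSE),
      data.frame(tag_seq = tags3p$antisense[ok], count = nAnti,
                 gene_id = gid, strand = "antisense",
                 stringsAsFactors = FALSE))
    src <- src[src$count > 0, , drop = FALSE]

    # per-base substitution errors: split each source row into perfect
    # reads and reads carrying >= 1 error
    pErr <- 1 - (1 - config$perBaseError)^21
    nErr <- rbinom(nrow(src), src$count, pErr)
    prov <- data.frame(src, class = "perfect", stringsAsFactors = FALSE)
    prov$count <- src$count - nErr
    errRows <- NULL
    tot <- sum(nErr)
    if (tot > 0 && config$perBaseError > 0) {
      reads <- rep.int(src$tag_seq, nErr)
      origin <- rep.int(seq_len(nrow(src)), nErr)
      kProb <- stats::dbinom(1:21, 21, config$perBaseError)
      k <- sample.int(21L, tot, replace = TRUE, prob = kProb)
      reads <- .mutateReads(reads, k)
      agg <- stats::aggregate(
        list(count = rep.int(1L, tot)),
        by = list(tag_seq = reads, gene_id = src$gene_id[origin],
                  strand = src$strand[origin]), FUN = sum)
      errRows <- data.frame(agg[c("tag_seq", "count", "gene_id", "strand")],
                            class = "errored", stringsAsFactors = FALSE)
    }
    pool <- rbind(prov[prov$count > 0, , drop = FALSE], errRows)

    # N-carrying reads: one random position replaced by N
    nN <- rbinom(nrow(pool), pool$count, config$nReadRate)
    totN <- sum(nN)
    nRows <- NULL
    if (totN > 0) {
      reads <- rep.int(pool$tag_seq, nN)
      origin <- rep.int(seq_len(nrow(pool)), nN)
      pos <- sample.int(21L, totN, replace = TRUE)
      substr(reads, pos, pos) <- "N"
      agg <- stats::aggregate(
        list(count = rep.int(1L, totN)),
        by = list(tag_seq = reads, gene_id = pool$gene_id[origin],
                  strand = pool$strand[origin]), FUN = sum)
      nRows <- data.frame(agg[c("tag_seq", "count", "gene_id", "strand")],
                          class = "n_read", stringsAsFactors = FALSE)
      pool$count <- pool$count - nN
      pool <- pool[pool$count > 0, , drop = FALSE]
    }

    extra <- NULL
    if (classN[["adaptor"]] > 0)
      extra <- data.frame(tag_seq = config$adaptorSeq,
                          count = classN[["adaptor"]],
                          gene_id = NA_character_, strand = "none",
                          class = "adaptor", stringsAsFactors = FALSE)
    if (classN[["noise"]] > 0) {
      noise <- unique(vapply(seq_len(classN[["noise"]]), function(i)
        paste(sample(c("A", "C", "G", "T"), 21L, replace = TRUE),
              collapse = ""), character(1)))
      extra <- rbind(extra, data.frame(
        tag_seq = noise, count = 1L, gene_id = NA_character_,
        strand = "none", class = "noise", stringsAsFactors = FALSE))
    }

    provenance <- rbind(pool, nRows, extra)
    cnt <- tapply(provenance$count, provenance$tag_seq, sum)
    lib <- TagLibrary(setNames(as.numeric(cnt), names(cnt)), stage = stage)
    list(library = lib, provenance = provenance, skippedGenes = skipped)
  })
}

#' Simulate gene-to-term annotations with a planted enriched term
#'
#' Background terms sample genes uniformly; the planted term
#' (`term_planted`) over-samples the supplied DE genes with the
#' configured odds ratio, so it should surface as the top enrichment of
#' the DE set.
#'
#' @param geneIds all gene ids.
#' @param deGenes gene ids of the truly differential set.
#' @param config a [simConfig()].
#' @param seed RNG seed.
#' @return data.frame `gene_id`, `term_id`, `term_name`; attribute
#'   `planted` names the planted term id.
#' @export
simulateAnnotations <- function(geneIds, deGenes, config,
                                seed = config$seed + 200L) {
  withSeed(seed, {
    sizes <- pmin(sample(config$termSizeRange[1]:config$termSizeRange[2],
                         config$nTerms, replace = TRUE),
                  length(geneIds))
    rows <- lapply(seq_len(config$nTerms), function(i)
      data.frame(gene_id = sample(geneIds, sizes[i]),
                 term_id = sprintf("term_%03d", i),
                 term_name = sprintf("background term %d", i),
                 stringsAsFactors = FALSE))
    w <- ifelse(geneIds %in% deGenes, config$plantedOddsRatio, 1)
    kP <- min(round(mean(config$termSizeRange)), length(geneIds))
    planted <- data.frame(
      gene_id = sample(geneIds, kP, prob = w),
      term_id = "term_planted", term_name = "planted enriched term",
      stringsAsFactors = FALSE)
    out <- rbind(do.call(rbind, rows), planted)
    attr(out, "planted") <- "term_planted"
    out
  })
}

#' Simulate a qRT-PCR Ct table from true abundances
#'
#' `Ct = baseline - log2(quantity) + N(0, sd)`, with reference genes held
#' at a constant quantity in both samples (up to noise).
#'
#' @param tpm genes x stages truth TPM matrix.
#' @param genes target gene ids (must be nonzero in both samples).
#' @param config a [simConfig()].
#' @param calibrator,test sample (stage) labels.
#' @param referenceGenes labels for the simulated reference genes.
#' @param seed RNG seed.
#' @return A list: `ct` (data.frame `sample`, `gene_id`, `replicate`,
#'   `ct`), `trueRatio` (named vector, test over calibrator).
#' @export
simulateQpcr <- function(tpm, genes, config, calibrator = "MP",
                         test = "PT",
                         referenceGenes = c("actin", "rRNA18S", "GAPDH"),
                         seed = config$seed + 300L) {
  q <- tpm[genes, c(calibrator, test), drop = FALSE]
  if (any(q == 0)) stop("qPCR genes must be expressed in both samples")
  withSeed(seed, {
    reps <- config$qpcrReplicates
    mk <- function(sample, gene, quantity) {
      data.frame(sample = sample, gene_id = gene,
                 replicate = seq_len(reps),
                 ct = config$ctBaseline - log2(quantity) +
                   rnorm(reps, 0, config$ctNoiseSd),
                 stringsAsFactors = FALSE)
    }
    ct <- do.call(rbind, c(
      lapply(genes, function(g) rbind(mk(calibrator, g, q[g, calibrator]),
                                      mk(test, g, q[g, test]))),
      lapply(referenceGenes, function(g) rbind(mk(calibrator, g, 1000),
                                               mk(test, g, 1000)))))
    list(ct = ct, trueRatio = setNames(q[, test] / q[, calibrator], genes))
  })
}
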