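---
title: "Methods: DGE tag profiling from virtual tags to validated calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DGE tag profiling from virtual tags to validated calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagDGE)
```

## The measurement model

NlaIII-anchored digital gene expression represents each transcript by
21-nt tags: a `CATG` restriction site plus the 17 following bases. The
library preparation cuts at the 3'-most site, so a transcript
contributes essentially one biological tag, and tag copy number is a
digital count of transcript abundance. Three pooled libraries — mature
pollen (MP), hydrated pollen (HP) and pollen tubes (PT) — are compared
to characterise pollen germination (MP to HP) and pollen tube growth
(HP to PT).

`tagDGE` separates this model into a reference layer (which tags
*could* exist), a library layer (which tags *were* observed), and
inference layers (quantification, testing, enrichment, clustering,
qPCR validation). A synthetic-data generator with complete ground truth
drives validation of every layer.

## Virtual tag reference

`scanCatgTags()` indexes **all** CATG+17-nt sites of every transcript,
not only the 3'-most one: sequencing errors, incomplete digestion and
isoform variation make interior tags observable, and restricting the
reference would silently discard them. The 3'-bias of the chemistry
lives in the simulator instead, which emits only 3'-most tags. Both
strands are scanned — `CATG` is its own reverse complement, so every
site also defines an antisense tag — which is what makes antisense
transcription detectable downstream.

A tag sequence is *ambiguous* when it occurs in two or more distinct
genes (either strand). Two occurrences within one gene do not make a
tag ambiguous: the exclusion rule downstream targets tags that cannot
be attributed to a single gene, and a within-gene repeat still has one
gene target. 21-mers containing `N` are skipped (they can never match a
clean tag) but tallied for diagnostics. Offsets are 0-based on the
coordinate system of the reported strand, so every tag is recoverable
by slicing, and the whole database round-trips through its TSV
serialisation.

The reference summary reports the unambiguous fraction against two
denominators — all virtual tag records and distinct tag sequences —
because published summaries of this quantity are not always explicit
about which universe they use.

## Library QC and the accounting ledger

`filterRawTags()` removes, in order: (1) tags containing any character
outside A/C/G/T, (2) tags equal to a supplied adaptor sequence (exact
full-length equality; the default adaptor list is empty), (3) tags
whose copy number *after* the first two removals is below 2. The order
matters: it makes the singleton class well defined and the four classes
disjoint, so the ledger identity

raw − N − adaptors − singletons = clean

holds exactly for distinct and total counts alike. This identity is
fuzz-tested, and `ledgerClean()` exposes the arithmetic directly so a
printed ledger can be checked without the raw reads. Copy-number
spectra use an inclusive first threshold (>= 2, the clean library
itself) and strict thresholds above (> 5, > 10, > 20, > 50, > 100); the
published tables write the first row differently from the rest, which
is the reading adopted here.

FASTQ input takes the 21-mer at the *first* `CATG` of each read; reads
without an anchor (or with fewer than 17 following bases) are counted
as a `no_anchor` diagnostic class before the raw tally. This makes
FASTQ support deterministic even though the tag protocol itself starts
from tags, not reads.

## Tag-to-gene mapping

`mapTags()` matches each distinct clean tag against the reference with
at most one mismatch. Exact matches take absolute priority; ambiguity
is evaluated only within the winning class. The interaction of the
mismatch allowance with multi-gene exclusion is not standardised, and
best-class-first is the convention adopted: a tag exactly matching one
gene is assigned to it even if it is also one mismatch away from
others. Within the best class, a tag hitting two or more genes is
excluded from quantification; a tag hitting exactly one gene is
assigned with the strand of the matched virtual tag (sense wins a
within-gene strand tie, so a tag matching both strands of one gene
still counts to that gene). Everything else is `unknown` — this class
also absorbs what a genome-level mapping step would catch, since no
genome aligner is in scope.

The mismatch search enumerates the 63 Hamming-1 neighbours of each
unmatched tag and looks them up in a hash of reference tag sequences,
which is exact and fast at desk scale; tests compare it against a
brute-force all-pairs Hamming scan.

Gene counts sum the copies of uniquely assigned tags, both strands
pooled (per-strand tallies are kept separately for the antisense
statistics, which are reported both as distinct-tag counts and as
gene-level sense:antisense calls). TPM is count / clean-library total ×
10^6. Detection is >= 1 unambiguous tag by default; the threshold is a
parameter (`minTags`) because published analyses leave it implicit.
Stage-summary percentages follow the published conventions: detection
against the reference-gene universe, specificity against the
respective stage's detected genes, DEG fractions against the
expressed-in-at-least-one-stage universe, all rounded to 2 decimals.
(The published text and table disagree on one detection percentage —
25.6 vs 28.38 for the same 11,751/41,404 ratio; the table's arithmetic
is the one that checks out and is the convention implemented.)

Saturation analysis subsamples the clean multiset without replacement
on a depth grid, nested within each replicate so both curves are
monotone by construction; the closed-form expectation
`sum_i (1 − C(T−c_i, d)/C(T, d))` serves as the oracle.

## Differential expression

The Audic–Claverie conditional probability

p(y|x) = (N2/N1)^y (x+y)! / ( x! y! (1+N2/N1)^(x+y+1) )

is evaluated in log space. Algebraically this is a negative-binomial
law with size x+1 and success probability N1/(N1+N2), so the
cumulative sums are evaluated exactly through the regularized
incomplete beta function — stable at counts up to millions, O(1) per
gene. The two-sided p doubles the smaller tail and caps at 1; the
sidedness convention is documented and switchable because the source
analyses do not state it. Note that while p(y|x) itself is symmetric
in (x, y) at equal depths, the doubled-tail p is only asymptotically
so — the two tails condition on different observed counts. Tests validate both the pointwise
probabilities and the tails against an independent log-sum-exp
summation oracle at 1e-10 relative tolerance, and the null calibration
of the doubled-tail p (super-uniform at alpha = 0.05) on 10,000
simulated null genes.

Calling uses the published conjunction: FDR <= 0.001 (Benjamini–
Hochberg step-up by default), P < 0.0005, and |log2 ratio| >= 1. The
P-threshold is largely redundant next to the FDR threshold but is
applied as printed. BH is the default despite the Benjamini–Yekutieli
citation in the source analyses: reconstructing the published rank-1
pathway Q-value from the printed p-values and m = 186 tested pathways
matches BH (within rounding) and not BY, so BH is what that pipeline
actually ran; BY remains available. The log ratio is computed on TPM
with a pseudo-TPM of 0.001 so stage-exclusive genes get large finite
ratios — the test itself uses raw counts and needs no pseudo-count.
Genes with zero counts in both libraries are not tested (undefined
contrast).

## Enrichment

`hypergeomUpperTail()` computes P(X >= k) — including the observed
overlap, the convention verified against the published tables — by
log-space summation of log binomial coefficients, exact to well beyond
six significant digits. The background defaults to genes carrying any
annotation (the "22,673" convention) rather than the full reference;
both choices are available, and the effective DEG-set size n counts
only annotated query genes. Correction is BH across the tested terms
of one ontology and comparison.

## Clustering

The clustering set is the intersection: expressed in all three stages,
and passing FDR <= 0.001 with |log2 ratio| >= 1 in *both* successive
comparisons. The clustered quantity defaults to the two log2 ratios
per gene (matching the red/green up-down encoding of the published
figure); per-stage log2 TPM is the alternative. With two-column ratio
profiles, centred Pearson correlation is degenerate (±1), so the
dendrogram effectively separates concordant from discordant dynamic
patterns — exactly the published use. Distance is 1 − Pearson with
average linkage, the historical defaults of the Eisen Cluster program
the source analyses name without settings; zero-variance profiles get
distance 1 to all others. Merge heights are validated against a naive
O(n^3) agglomerative oracle, and CDT/GTR export follows the TreeView
format (node similarity recorded as 1 − height).

## qRT-PCR concordance

2^−ΔΔCt with amplification efficiency fixed at 2. Multiple reference
genes are combined by the arithmetic mean of their replicate-mean Cts —
equivalent to the geometric mean of their linear quantities, the
standard multi-reference rule; per-reference normalisation can be had
by calling with a single reference. Replicate SEs are propagated in
quadrature onto the ΔΔCt scale. Validation is sign concordance between
the qPCR log ratio and the DGE log ratio for the same orientation.

## The synthetic-data generator

The generator defines the study conditions under which everything is
tested. Defaults: 1,000 genes of 200–800 nt with a 90% CATG-site
fraction; three stage libraries of 5×10^5 raw tags; log-normal
baseline abundances (sdlog 1.2, a realistic bulk-transcriptome
spread); stage-specific fractions 15% / 3% / 7% (MP / HP / PT,
mirroring the published ordering MP > PT > HP); 10% of genes planted
differentially expressed per comparison plus 2% in both comparisons
(the highly dynamic genes that populate the clustering intersection);
signed log2 effects uniform on [1.5, 3] — the lower bound sits clear of
the |log2 ratio| >= 1 calling threshold so planted effects survive the
per-stage renormalisation shift (bounded well below 0.5 in log2 at
these fractions); per-base error rate
0.005; 1.2% N-reads; no adaptor reads (matching the published zero
adaptor tally, with the rate available); 3.5% unique singleton noise
tags; 15% antisense read fraction. Stage columns are renormalised to
10^6 TPM, and truth DE labels are recomputed from the final matrix so
labels and matrix never disagree.

Reads are multinomial over expressed genes proportional to TPM — with
one pooled library per stage no overdispersion parameter is
identifiable, so a negative-binomial layer would be pure convention;
this is a stated limitation. Each gene emits its 3'-most sense tag
(or its 3'-most antisense tag with the antisense probability), errors
mutate 1+ positions per affected read with binomial multiplicity,
N-reads replace one position with N, and noise tags are unique random
21-mers. Per-read provenance (source gene, strand, noise class) is
retained, which is what makes parameter-recovery testing possible.

What the generator does not emulate: 3'-bias gradients within
transcripts, PCR duplication, quality-score structure, incomplete
digestion, and biological replicate variance. Passing tests therefore
demonstrate correctness of the analysis machinery under the stated
sampling model, not robustness to every artefact of real libraries.

## Numerical and design choices

* Log-space evaluation throughout (lgamma/lchoose, log-sum-exp with
  max-shift) keeps p-values exact at library totals of millions.
* Deterministic ordering: clustering input sorted by gene id;
  reference and assignment tables keep input order; all generators are
  bit-reproducible under a master seed with documented per-module
  offsets.
* Degenerate inputs: empty references, zero-clean-tag stages and
  wrong-length tags raise named errors; empty DEG sets propagate as
  empty outputs with warnings rather than failures.
* Problem sizes in the test suite (a few hundred genes, 10^4–10^5-tag
  libraries for unit oracles; the 1,000-gene / 5×10^5-tag default for
  end-to-end recovery; 10,000 null genes for calibration) were chosen
  so the brute-force oracles remain exact cross-checks at full
  coverage.
* The package is an analysis library: `runPipeline()` plus the
  exported per-stage functions are the orchestration surface, and all
  outputs are plain TSV/JSON for diff-ability.

## Known limitations

Published full-scale results that depend on the deposited sequencing
data and the *Populus trichocarpa* reference (total detected-gene
counts, global mapping rates, the 4.2:1 sense:antisense ratio) are not
reproducible at desk scale and are out of numeric scope; the
worked-example arithmetic (ledgers, percentage conventions, enrichment
contingencies) and the property-based validation above are what the
package asserts. Genome-level tag mapping, GO DAG propagation, qPCR
efficiency correction and replicate-aware dispersion modelling are
deliberately out of scope.
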