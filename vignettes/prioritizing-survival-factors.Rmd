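---
title: "Prioritizing stromal survival factors for bone-marrow plasma cells"
author: "marrowNiche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing stromal survival factors for bone-marrow plasma cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marrowNiche)
```

# The scientific problem

Antibody-secreting cells (ASC) circulating in blood after vaccination die
within days unless they reach the bone marrow, where a subset matures into
long-lived plasma cells (LLPC) supported by the local microniche —
principally the secreted products of mesenchymal stromal cells (MSC),
the cytokine APRIL, and hypoxia. Which individual secretome proteins drive
this support is hard to establish by perturbation alone: the secretome
contains hundreds of proteins, and survival assays are slow and noisy.

`marrowNiche` implements an integrated prioritization that triangulates
three independent data types:

1. **Secretome proteomics.** Protein identification lists from several
   secretome fractions, some of which support ASC survival (bioactive) and
   some of which do not (inactive controls). Set algebra — union of
   bioactive fractions, subtraction of the serum background, subtraction of
   a non-marrow control secretome, intersection of the two experiments —
   funnels these lists down to a candidate protein set.
2. **Interactome context.** Each candidate is expanded to its first
   neighbors in a confidence-weighted protein–protein interaction (PPI)
   network, on the premise that a survival factor acts through receptors and
   signaling partners expressed by the plasma cells.
3. **Maturation transcriptomics.** Genes differentially expressed (DE)
   between blood ASC and bone-marrow LLPC mark the maturation program.
   Candidates are ranked by how many of their interaction partners are
   differentially expressed, so a protein whose neighborhood is saturated
   with maturation genes rises to the top.

Pre-ranked gene-set enrichment (GSEA) over the contrast t-statistic
summarizes which transcriptional programs the prioritized interactions
touch, and Elispot survival statistics quantify the functional readout that
motivates the whole exercise.

# Pipeline stages and their models

## Target-decoy PSM filtering (`filterPsms`)

Peptide-spectrum matches are filtered at 1% FDR by the concatenated
target-decoy method. At score threshold $s$ the false-discovery proportion
is estimated as $\widehat{FDR}(s) = \#\{decoys \ge s\}/\#\{targets \ge s\}$;
the q-value of a match is the minimum estimate over all thresholds that
admit it. Peptides shorter than 7 residues are removed first, proteins
inherit their best peptide score, and the same q-value procedure is applied
again at the protein level. Decoys sort before targets at tied scores (the
conservative direction), and a `(\#decoys + 1)` numerator is available via
`conservative = TRUE`. The estimator is unbiased only when the decoy
database matches the target database in size, so decoy hits track incorrect
target hits; the synthetic PSM generator follows that condition by default.

## The secretome funnel (`unionActive`, `subtractBackground`, `differentialProteome`, `intersectExperiments`)

Pure set algebra over normalized gene symbols (uppercase, optional isoform
suffix stripping, optional raw-to-symbol mapping). Provenance — which
fraction contributed each retained protein — is carried through to the
final report. Replicate runs of a fraction are merged by union before
entering the funnel.

## PPI expansion (`loadNetwork`, `expandSeeds`)

Networks load from HIPPIE-style six-column TSV or generic three-column edge
lists; duplicate edges keep the maximum confidence, self-loops are dropped,
and a confidence floor is available (default 0: all edges, since no
published threshold governs this step — treat it as a reproducibility
knob). Expansion is strictly first-neighbor: no diffusion, no multi-hop.
Partner sets may include other seeds (default) or exclude them
(`includeSeedPartners = FALSE`); both conventions are defensible and the
flag records which one a result used. Seeds absent from the network are
reported, never silently dropped.

## Differential-expression core (`runDegAnalysis`)

* **TMM normalization** (`tmmFactors`): trimmed mean of M-values with 30%
  log-ratio and 5% abundance trims, inverse asymptotic-variance weights,
  and the upper-quartile rule for picking the reference sample. Factors are
  normalized to geometric mean 1. This is the classical count-normalization
  estimator; the unit tests pin it to the edgeR implementation at 1e-10.
* **log2 CPM** (`cpmLog2`): $\log_2((c + 0.5) / (\text{effective library
  size}/10^6))$, effective size = raw total × TMM factor.
* **Abundance filter** (`abundanceFilter`): genes with mean log2 CPM below
  3 are removed (boundary inclusive). The function also emits the per-gene
  (mean, CV) table used to choose that threshold by eye.
* **Variance attribution** (`pcva`): samples are projected onto principal
  components after per-gene standardization; the score variance of the
  first three PCs is attributed to each design factor by the R² of a
  one-way fit, averaged with PC-variance weights. Because the factors are
  fitted one at a time, contributions only partition exactly when the
  design factors are mutually orthogonal; the residual is reported as 100
  minus their sum and can drift in confounded designs.
* **Batch adjustment** (`adjustBatchEffects`): per gene, an additive
  two-factor fit (population + batch); the estimated batch component is
  centered and subtracted so population effects and grand means are
  untouched. Aliased designs error rather than silently absorbing biology.
* **Testing** (`perGeneAnova`, `contrastTstat`): fixed-effects one-way
  ANOVA across populations plus a pooled-variance two-group t for the
  blood-ASC-vs-LLPC contrast (Welch by flag). When testing a
  batch-adjusted matrix, the residual degrees of freedom spent by the batch
  fit (`nBatches - 1`) are subtracted from the error df — without this the
  error variance is underestimated by $(N-K)/(N-K-B+1)$ and the realized
  FDR exceeds its nominal level.
* **FDR** (`bhFdr`, `callDegs`): Benjamini–Hochberg step-up q-values
  (via `stats::p.adjust`), DEG called at q ≤ 0.05.

Whether the contrast should be computed on batch-adjusted or raw log-CPM is
genuinely open; the default adjusts first (matching the stated order of the
original workflow), and `adjust_batch = FALSE` runs the raw path.

## Candidate ranking (`rankCandidates`)

Per seed: total partners, DEG-overlapping partners. The sort key is
(DEG partners ↓, total partners ↓, symbol ↑) — the published analysis does
not state a tie rule, so this three-level key is the documented contract,
and it makes the table a deterministic, permutation-invariant total order.
The "more than 45 DEG partners" mark is a reporting flag, not a filter.

## Pre-ranked GSEA (`gseaPreranked`)

Genes are sorted by the contrast t (ties broken by symbol). The running sum
gains $|t|^p / \sum_{S}|t|^p$ at members ($p = 1$ by default; $p = 0$ gives
the unweighted Kolmogorov–Smirnov form) and loses $1/(N - |S|)$ at
non-members; ES is the signed maximum deviation, with exact peak–trough
ties resolved toward the positive sign under a 1e-9 tolerance so the
answer does not depend on floating-point accumulation order. Because the
input is a pre-ranked list, the null must be gene-label permutation —
phenotype permutation is impossible without per-sample data. NES divides ES
by the mean magnitude of same-sign permutation ES values; FDR q pools null
and observed NES two-sidedly in the standard way. "Enriched for high or
low expression" is read as two-sided: both signs are tested and the
direction is reported.

## Set-level summarization (`standardizeSlsm`, `genesetPc1`, `wardCluster`)

Group means per gene are z-standardized across groups (sample-SD
convention: two groups give ±1/√2) so abundant genes do not dominate; each
significant set is summarized by the first principal component of its
standardized rows (sign oriented along the set's mean profile; a singleton
set returns its own row), and set profiles are clustered with Ward's
variance criterion (`ward.D2` on Euclidean distance), serializable to
Newick.

## Elispot survival statistics (`normalizeSurvival`, `compareMedia`, `anovaConditions`)

Per-day well means are normalized to the maximum of the day-1–3 means
(tie → earliest day; a zero reference is an error, not a silent NaN).
Condition comparisons fit ordinary least squares of percent on day plus a
media indicator — wells are averaged before modeling because the survival
curves are plotted per day; day is continuous by default and an optional
`log1p` response is available, with raw percent the default since the
original analysis does not state a transform. Multi-condition comparisons
use fixed-effects ANOVA (day + condition when day-matched) with BH
adjustment over pairwise contrasts.

# The synthetic study

`simulateStudy()` generates every input with planted ground truth
(`SyntheticTruth`), which is what makes each stage testable without any
external download. Defaults define the reference study:

| component | default | rationale |
|---|---|---|
| PPI network | 500 nodes, 2000 edges, preferential attachment (bias 1), confidence U(0.5, 1) | sparse hub-rich graph, the regime of curated interactomes |
| planted factors | 5 hubs of degree ≥ 15 | a handful of well-connected secretome proteins |
| counts | 2000 genes, 8 vs 4 samples, NB with variance μ + 0.1μ², library sizes log-uniform in [5×10⁵, 2×10⁶] | a small two-population bulk RNA-seq study with realistic library-size spread to exercise TMM |
| planted DE | factor neighbors at probability 0.5, background 0.05, |log2 FC| = 1.5 | ties the interactome hubs to the transcriptome; ~8–10% DE overall |
| batch | 2 batches, per-gene shifts N(0, 1) shared within batch, assigned round-robin within population | strong batch structure (dominates the leading PCs) that is never confounded with population |
| fractions | 3 bioactive + 2 inactive + serum background; dropout 0, contaminant rate 0.1 | abundant factors are detected in every bioactive fraction, as the top real secretome proteins are; dropout is a knob, not the default condition |
| gene sets | 25 sets of 20–80 genes, 5 enriched at factor 5, direction-coherent | a running-sum statistic cannot see sign-mixed enrichment, and real pathways move coherently; the non-DE remainder is drawn from non-DE genes so the planted DE content is exact |
| PSM table | 1000 true + 1000 null targets + 1000 decoys, score shift 3 SD | matched decoy/target database sizes, the estimator's validity condition |
| Elispot | days {1, 2, 3, 5, 7, 14}, 6 wells/day, 100 max spots, Poisson | chosen by a one-time calibration: with fewer wells the media-regression p-values sit at the edge of uniformity, with many more spots the linear model's lack of fit to exponential decay makes the test conservative, and a shorter window makes the shared normalization anticonservative |

A note on the batch model: the shifts are drawn per gene and shared by all
samples of a batch. A batch shift that were literally identical across
genes would be a library-size change, which TMM/CPM absorbs before the
batch stage ever sees it; per-gene shifts are what make the batch
contribution to PC variance a tunable quantity.

All randomness flows from one integer master seed through a documented
splitting scheme, so reruns of any module are reproducible and two studies
with the same seed are byte-identical.

**What the generator does not emulate:** gene–gene correlation beyond the
planted structure, gene-specific dispersions, isoform ambiguity, protein
groups and shared peptides, mapping loss between proteome and transcriptome
identifiers, multi-hop network signal, and non-exponential survival
kinetics. Tests passing on this study therefore demonstrate algorithmic
correctness and statistical calibration under the stated model — not
robustness to every pathology of real data.

# Numerical choices and degenerate inputs

* TMM: the "no co-expressed genes with the reference" condition errors with
  the offending sample named; identical libraries return exactly 1.
* ES ties: positive sign preferred at 1e-9 tolerance (documented above);
  the ES of a set covering the whole universe is 1 by convention.
* Constant genes: standardization steps drop or zero them with a warning
  rather than producing NaN rows.
* `perGeneAnova` with zero within- and between-group variance returns F = 0,
  p = 1; zero within with positive between returns F = ∞, p = 0.
* Empty seed sets, empty DEG sets and a zero FDR threshold degrade the
  pipeline to empty-but-well-formed outputs with warnings, never to errors
  halfway through a run.
* Problem sizes in the test-suite calibration loops (50 simulations of the
  2000 × 12 study for DEG FDR; 50 GSEA null studies at 300 genes × 15 sets ×
  200 permutations; 200 Elispot null pairs; 20 full pipeline runs for
  recovery) were chosen so the whole suite completes in about a minute on
  one CPU while keeping Monte-Carlo error well below the tolerances being
  checked.

# Known limitations

* Protein inference is best-peptide only; parsimony grouping and rescoring
  of search results are out of scope (the package consumes scored PSMs).
* PCVA's one-way attribution is not a strict variance partition under
  confounded designs (see above); it is a diagnostic, not an estimator.
* The GSEA FDR is the standard pooled-NES procedure; it is conservative
  under the global null and is not guaranteed monotone in NES.
* The Elispot regression treats per-day means as independent observations;
  the shared normalization reference induces mild within-series correlation
  that the model ignores (quantified by the calibration results above).
* Survival modeling is fixed-effects only; per-experiment random effects
  would require raw multi-experiment well data the package does not model.
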