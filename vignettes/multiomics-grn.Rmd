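---
title: "Multi-omics gene regulatory networks: model, assumptions and design"
author: "multiGRN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics gene regulatory networks: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

multiGRN models how transcription factors (TFs) regulate target genes (TGs)
by fusing four data layers — TF ChIP-seq binding, protein–protein
interactions (PPI), co-expression, and chromosome conformation (Hi-C) — into
a weighted TF×gene regulatory network, and then uses that network two ways:

1. **Expression prediction.** Network edge weights become regression
   features in an elastic-net model of per-gene log10 FPKM, fitted under a
   resampling protocol; the averaged coefficients are interpretable per-TF
   effect estimates (positive = activator, negative = repressor).
2. **Rare-variant association.** The effect estimates re-weight per-variant
   TF-binding disruption z-scores into "merge scores", which serve as kernel
   weights in a SKAT variance-component test of rare variants against gene
   expression.

Everything runs on synthetic fixtures generated in-package, so the full
pipeline is testable end to end without any download.

# Regulatory geometry

Coordinates are held in `GRanges` (1-based, closed intervals); GTF and BED
input conversion is handled by rtracklayer on read.

For each protein-coding gene we take the **longest transcript** (maximal
span; ties broken by the lexicographically smallest transcript id, so the
choice is reproducible) and define:

* the **candidate window**: 50 kb upstream of the TSS to 50 kb downstream of
  the gene-body 3' end, strand-aware, clipped at the chromosome start;
* the **CTCF-bounded window**: the candidate window truncated at the most
  distant CTCF peak midpoint on each side of the gene body. CTCF acts as an
  insulator, so peaks beyond it are unlikely to regulate the gene. We measure
  "most distant" by peak midpoint and cut at the midpoint itself — the
  boundary peak's proximal half remains inside the window. Peaks whose
  midpoint falls inside the gene body are ignored, so the window never
  shrinks into the body. A flank without any CTCF peak keeps the candidate
  boundary.
* the **promoter**: the 5 kb immediately upstream of the TSS;
* **introns**: per transcript, the span minus the union of its exons, then
  unioned across transcripts. Because the subtraction is per transcript, a
  merged intron may overlap another transcript's exon; that is intentional
  and mirrors subtracting exons from "the respective transcript lengths".

Peaks overlapping (≥ 1 bp) the bounded window are partitioned into
promoter / intronic / distal classes with precedence
promoter > intronic > distal for multi-overlap peaks (the promoter class is
the most specific claim about mechanism, so it wins).

# Binding evidence

Three exchangeable definitions of TF→gene binding feed the network prior:

* **Positional**: any ChIP-seq peak inside the bounded window (binary).
* **Motif-confirmed** (`scanPWM`): log-odds PWM scanning of the sequence
  under peaks at p ≤ 0.01. Scores are `log2((p + 1e-3 pseudocount,
  renormalized) / background)` summed over positions; both strands are
  scanned; the per-position p-value is **exact**, computed by dynamic
  programming over the score distribution discretized at 1e-3 bits. The
  discretization is part of the score definition (observed scores use the
  same integer table), so the DP null is exact for the reported score, and
  is verified in tests against exhaustive enumeration of all k-mers for
  motifs up to 6 bp. Windows containing N are skipped; palindromic hits on
  both strands at one start position are deduplicated to the best strand.
* **Affinity** (`affinityScore`): a distance-decay aggregate
  `sum_i a_i exp(-|center_i - TSS| / d0)` with d0 = 5000 bp, where `a_i` is a
  per-site strength (normalized peak signal, or a PWM posterior). This is a
  self-contained affinity contract in the TRAP/TEPIC tradition rather than a
  wrapper around an external energy-model implementation; it keeps the stage
  dependency-free and directly testable (translation invariance, strict
  monotonicity in added sites).

# The network model

PANDA-style message passing fuses three z-score-normalized networks: the
motif prior W (TF×gene), PPI P (TF×TF, 0/1 with unit diagonal) and
co-expression C (gene×gene Pearson correlation, passed unthresholded). Each
iteration computes a responsibility `R = T(P, W)` and availability
`A = T(W, C)` with the continuous Tanimoto kernel

```
T(x, y) = (x . y) / sqrt(||x||^2 + ||y||^2 - |x . y|)
```

and moves `W <- (1 - u) W + u (R + A) / 2` with update rate u = 0.1. P and C
are moved toward the cooperativity/co-regulation implied by the current W at
the same rate, with the diagonal replaced by an inflated off-diagonal row sd
(factor `num * exp(2 u step)`) so self-similarity cannot dominate. Iteration
stops when the Hamming distance `mean(|W_t - W_{t-1}|)` drops below 0.001
(data-dependent iteration count; 200-iteration cap with a warning). The
update equations are pinned by an oracle test against an independent
naive-loop implementation (agreement to 1e-10 on random 5×8 networks); the
algorithm is deterministic.

# Hi-C edge weighting

Promoter-contact records (KR-normalized counts between a TF peak and a gene
promoter, consumed pre-normalized as sparse triplets) re-weight motif edges.
Per TF–gene pair the mean contact count over *all* of the TF's peaks in the
gene's region is taken (peaks without a recorded contact contribute 0), the
means are scaled globally by `0.99 * x / max(x)`, and the edge weight is
`1 + scaled`. The scaler is deliberately *not* a generic min–max: anchoring
zero at zero makes "no contacts ⇒ weight exactly 1" hold even when the
smallest observed mean is positive, and the maximal pair lands exactly at
1.99. Two schemes apply the weights to a binary motif prior:

* **DP** (distal-preserving): every motif edge is multiplied by its weight —
  contact-free edges are effectively down-weighted relative to contacted
  ones.
* **UP** (up-weighting): DP, then promoter-based pairs (TF has ≥ 1
  promoter-category peak for the gene) whose weight is exactly 1.0 — pairs
  invisible to low-resolution Hi-C — are boosted to the maximum 2.0. Only
  zero-contact promoter pairs are boosted; promoter pairs with recorded
  contacts keep their DP weight.

# Expression models and effect estimates

Gene×TF edge weights are the design matrix, per-gene log10 FPKM the
response. Each resampling iteration draws a seeded 80/20 train/test split,
standardizes features column-wise on the training set, selects the penalty
strength by 20-fold inner cross-validation (minimizing MSE over a 50-point
log-spaced grid on [1e-4, 10] — the grid is a package choice), and reports
test-set MSE and Pearson correlation. The elastic-net mixing ratio defaults
to 0.5. Coefficients are reported on the standardized scale so that per-TF
averages are comparable across TFs — which the downstream quintile binning
requires. A constant prediction has an undefined correlation; it is reported
as 0 with a warning. Twenty iterations with seeds `base_seed + 0..19` give
per-TF averaged effects; model pairs are compared by two-sided Wilcoxon
rank-sum tests on the PCC and MSE lists (exact null when the combined n ≤ 20
and there are no ties). TFs are then sorted by averaged effect and split
into 5 contiguous bins whose sizes differ by at most one (remainder assigned
from bin 1 upward); tied values never straddle a boundary — ties collapse
into the lower bin.

# Rare-variant scoring and SKAT

Variants are filtered to MAF strictly below 1%, and binding z-scores to
p ≤ 1e-4. For a variant v, TF t and gene g, the effect-scaled z-score is the
TF's averaged effect times the mean z over the TF's significantly perturbed
peaks in the gene's region; the merge score averages that over TFs. Setting
every effect to 1 gives the aggregate (binding-only) z-score. Both score
sets are scaled genome-wide into [-1, 1] by `x / max(|x|)` (a per-gene
option exists; genome-wide is the default because a single kernel-weight
scale keeps genes comparable).

The SKAT statistic is `Q = r' G diag(w)^2 G' r / sigma^2` with residuals r
from an OLS null model (intercept + covariates). Weights enter squared, so
their sign cannot affect the test — a property asserted in the suite. The
p-value uses the Liu three-moment approximation to the
mixture-of-chi-squares null, with mixture eigenvalues computed exactly from
the covariate-projected kernel (an m×m eigenproblem, m = number of
variants). The three-moment route is dependency-free and calibrated at desk
scale: the suite checks an empirical type-I error within [0.03, 0.07] at
nominal 0.05 over 1000 null replicates. Missing dosages are imputed to the
column mean (twice the allele frequency). The significance threshold
defaults to Bonferroni 0.05 / genes tested and is a parameter.

# The synthetic study

`simConfig()` fixes the study conditions: 200 genes in co-regulation modules
of 20, 20 TFs (40% activators with planted effects in [0.4, 1.2], 30%
repressors in [-1.0, -0.3], the rest near zero), 50 expression samples, 300
genotyped individuals, 8 rare variants per gene, 60 kb gene spacing, 30%
binding-site dropout, Hi-C decay length 20 kb, expression noise sd 0.5.
These are desk-scale surrogates of a mammalian cell-line study: enough genes
for stable elastic-net fits, enough individuals for rare-variant kernel
tests with moderate power, and modules large enough to give the
co-expression network block structure.

The generator plants a ground truth the pipeline should recover:

* each module's genes share regulator TFs, so true binding is
  block-structured and co-expression is informative about it;
* observed peaks cover each true site with probability 0.7 — the cis
  evidence has gaps that only trans information can fill, which is exactly
  why PANDA-refined features outperform affinity-only features in the
  directional acceptance check;
* expression couples sample-varying TF activity through the planted effects
  plus a module-level factor plus Gaussian noise; a held-out response vector
  (an independent instance) is the regression target;
* Hi-C contacts are Poisson draws with mean `30 exp(-d / 20 kb)`;
* rare variants (MAF ~ 0.01·Beta(1.2, 4), floored at one expected carrier)
  sit inside and outside binding sites; in causal genes, variants in
  large-effect TF sites disrupt binding (|z| ≈ 5) *and* shift the phenotype
  proportionally to the planted effect, while decoy variants in
  near-zero-effect TF sites disrupt binding equally strongly but leave the
  phenotype alone. The decoys are the contrast that lets effect-weighted
  (merge-score) kernels beat binding-only (aggregate-z) kernels.

One RNG stream per component (annotation/effects/regulation/genotypes)
derives from the master seed, so regenerating one layer never perturbs the
others, and everything is bitwise reproducible under a fixed seed.

What the generator does **not** emulate: linkage disequilibrium (variants
are independent), read-level noise, multi-chromosome genomes, alternative
TSS usage, peak-calling artefacts, population structure, and realistic
co-expression beyond block structure. Passing tests therefore demonstrate
internal correctness and the qualitative behaviour of the method under its
own assumptions — not performance on real cohort data.

# Problem sizes and runtime choices

The test suite runs the shared acceptance study once at the default scale
(200 genes, 20 TFs, 20 elastic-net iterations, ~1 minute), the SKAT
calibration at 1000 replicates of a 300×10 design, and all oracle
equivalence checks at small sizes (5×8 PANDA networks, 12-individual SKAT,
motifs ≤ 6 bp, n = 3+3 Wilcoxon). The staged pipeline tests use 30 genes / 6
TFs to keep file-based round trips fast. These sizes are the package's
choices for a responsive developer loop; all statistical checks are fixed
before execution and none is tuned to its observed outcome.

# Known limitations

* The PANDA update equations follow the published message-passing scheme;
  other implementations differ in normalization details, so absolute edge
  weights are not comparable across implementations (orderings generally
  are).
* The Liu three-moment p-value is slightly conservative in the extreme tail;
  for genome-wide thresholds far beyond 1e-6 an exact Davies-type
  integration would be preferable.
* Affinity scores use peak signal or PWM posteriors, not trained energy
  models (PSEMs); the exponential-decay contract is shared, the per-site
  strengths are not.
* `fitENet` requires ≥ 25 genes and ≥ 2 feature columns; smaller problems
  are out of contract.
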