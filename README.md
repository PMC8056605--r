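# multiGRN

Multi-omics gene regulatory networks for expression prediction and
rare-variant association.

## The problem

How much of a gene's expression can be explained by *which* transcription
factors (TFs) bind near it — and can a map of TF influence make rare
non-coding variants easier to interpret? multiGRN is for regulatory
genomicists who have (or simulate) TF ChIP-seq peaks, CTCF boundaries,
protein–protein interactions (PPI), co-expression, Hi-C promoter contacts
and genotypes, and want one coherent pipeline from binding-site geometry to
network inference, expression modelling and kernel-based rare-variant
testing.

## The model

For each protein-coding target gene *g*, binding evidence is collected in a
CTCF-bounded cis-regulatory window (50 kb around the gene, truncated at the
most distant flanking CTCF peak midpoints). Three layers are fused by
PANDA-style message passing into edge weights *W<sub>t,g</sub>*: a motif
prior (binary peak overlap, motif-confirmed hits at p ≤ 0.01, or
distance-decay affinities Σ<sub>i</sub> a<sub>i</sub>·e^(−d<sub>i</sub>/5000)),
a TF×TF PPI network, and a gene×gene Pearson co-expression network, iterated
with Tanimoto-similarity updates (update rate 0.1, Hamming tolerance 0.001).

Hi-C promoter contacts optionally re-weight motif edges as

> C<sub>t,g</sub> = 1 + scaled( mean over the TF's peaks of KR-normalized
> contacts with the promoter ),  scaled(x) = 0.99·x/max(x)

so contact-free pairs get exactly 1 and the strongest pair 1.99; the "UP"
scheme additionally boosts zero-contact promoter pairs to 2.0.

Edge weights predict per-gene log10 FPKM through elastic-net regression
(mixing ratio 0.5, 80/20 split, 20-fold inner CV, 20 seeded iterations).
Averaging each TF's standardized coefficient over iterations gives its
effect estimate β̄<sub>t</sub> (activator > 0, repressor < 0), binned into
quintiles. Finally, per-variant binding-disruption z-scores (p ≤ 1e-4, MAF
< 1%) are combined into merge scores

> Z<sub>v,t,g</sub> = β̄<sub>t</sub> · mean(z over the TF's perturbed peaks),
> S<sub>v,g</sub> = mean over TFs of Z<sub>v,t,g</sub>

scaled to [−1, 1] and used as kernel weights in a SKAT test
(Q = r′G·diag(w)²·G′r/σ̂², Liu three-moment p-value) of rare variants
against expression.

A first-class synthetic-data module generates every input with planted
ground truth (TF effects, binding maps, causal variants), so the whole
pipeline runs and validates offline.

## Worked example

```r
library(multiGRN)

cfg <- simConfig(seed = 11)                 # 200 genes, 20 TFs, 50 samples
sim <- simulateAnnotation(cfg, with_sequence = FALSE)
reg <- simulateRegulation(cfg, sim)
rw  <- regulatoryWindows(sim$annotation, reg$ctcf)

tf_tab <- positionalTFBS(reg$peaks, rw)
tfs    <- sort(unique(tf_tab$tf))
motif  <- motifAdjacency(unique(tf_tab[, c("tf", "gene_id")]),
                         tfs, colnames(reg$expression))
nets   <- alignNetworks(motif, ppiNetwork(reg$ppi, tfs),
                        coexpressionNetwork(reg$expression))
fit <- pandaFit(nets$motif, nets$ppi, nets$coexpr)
fit
#> PandaResult: 20 TFs x 200 genes; 27 iterations; converged

X  <- t(pandaW(fit))                        # gene x TF features
y  <- reg$truth$response[rownames(X)]       # held-out log-expression
rf <- repeatFit(X, y, iterations = 20, base_seed = 1)
median(sapply(rf$perf, `[[`, "pcc"))
#> [1] 0.734  (median MSE 0.571)

eff <- quintileBins(averageEffects(rf$fits))
head(data.frame(beta = round(effectBeta(eff), 4), bin = effectBins(eff),
                planted = round(reg$truth$beta, 2)), 3)
#>        beta bin planted
#> TF01 0.2167   5    1.06
#> TF02 -0.0068  3    0.97
#> TF03 0.3015   5    1.17
```

The fitted network explains a substantial share of held-out expression
(median test-set Pearson correlation 0.73 across 20 resampling iterations),
and the strongest planted activators land in quintile bin 5 with positive
averaged coefficients. Downstream, `mergeScoreTable()` + `skatByGene()`
carry the effect estimates into rare-variant tests; `runPipeline()` (or the
thin CLI at `inst/scripts/grnexpress.R`) drives the same stages through
TSV/BED/GTF artifacts with a manifest.

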