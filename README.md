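# immuneLayers

Layered analysis of immune gene expression for bulk RNA-seq
experiments on replicated host individuals — built for the kind of
study where an early-branching animal (the motivating system is a
sponge) is challenged with an immune elicitor such as bacterial
lipopolysaccharide (LPS) and sampled at two timepoints, with clone
pieces of the same individual at both timepoints within a treatment.

The package partitions immune gene regulation into three layers and
implements the inference for each:

* **Constitutive expression** — genes detected (raw count > 0) in
  every sample; a high-expression tier is flagged at mean
  TMM-normalized TPM > 10, and the median expression of constitutive
  immune genes is compared with all other constitutive genes.
* **Individual-specific expression** — genes detected in only some
  samples, tracking the individual rather than treatment or timepoint.
  Individuality is quantified on the presence/absence matrix with
  Jaccard distances, a mutual-nearest-neighbour clone-pairing score and
  a label-permutation p-value.
* **Induced response** — per-timepoint LPS-vs-control contrasts with a
  negative-binomial Wald test (method-of-moments dispersions with
  decile-trend shrinkage), significant at FDR < 0.005 and
  |log2 fold change| >= 2; shared fractions and direction consistency
  across timepoints; and a split of DEGs into *consistent* vs
  *variable* by replicate support within expression-pattern clusters
  (Euclidean/complete tree cut at 40% of maximum height; a DEG is
  consistent when more than half of the treatment replicates carry its
  regulation, variable otherwise).

Upstream of the expression analysis, a rule engine classifies
transcripts into pattern-recognition-receptor families from Pfam
domain architectures: TLR-like (TIR + Ig-like + transmembrane),
TIR-only, bona fide NLR (NACHT + LRR), NACHT-only, GPCR with/without a
GPS motif next to 7TM evidence, SRCR, and C-type lectin domain genes,
with a fixed configurable precedence and an e-value filter.

A synthetic-data generator plants all of this structure —
negative-binomial counts over the clone design, exact-zero structural
absences, per-individual carriage, responder penetrance per gene, an
immune median boost — and returns a truth table, so every stage is
validated by recovery rather than by fiat.

## Worked example

```r
library(immuneLayers)

cfg <- SimulationConfig(nGenes = 3000, seed = 11)
report <- runPipeline(simConfig = cfg, outdir = "run1", nPermutations = 199)
report
```

```
immuneLayers pipeline run — 3000 genes x 23 samples
  layers (expressed genes): constitutive 45.3%, individual-specific 54.7%
  PRR tally: TLR_like=25 TIR_only=25 NLR_bona_fide=25 NACHT_only=25 GPCR_GPS_7TM=25 GPCR_7TM=25 SRCR=25 CTLD=25 none=0
  constitutive immune vs other median ratio: 1.413
  t1h: 221 DEGs (112 up / 109 down), 90% consistent
  t6h: 217 DEGs (107 up / 110 down), 87% consistent
  timepoint overlap: up 0.82, down 0.56, 0 conflicts
  individuality: pairing score 1.00, p = 0.005
  outputs: run1
```

Reading the output: the planted 40/45/15 layer split appears as ~45%
constitutive among expressed genes (sampling zeros only ever demote
constitutive genes); all 200 planted receptor genes (25 per family)
are recovered by the domain screen; the constitutive immune median
sits near the planted 1.35x boost; the ~200 planted LPS-responsive
genes dominate the DEG lists with no cross-timepoint direction
conflict; and the clone-pairing score of 1.0 with the minimum
permutation p-value shows samples pairing by individual, not
timepoint. Every printed number is also written as a tab-separated or
JSON file under `run1/`.

A thin command-line wrapper with `simulate`, `screen`, `normalize`,
`layers`, `detest`, `partition` and `run-all` subcommands is installed
at `inst/scripts/immunelayers.R`.

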