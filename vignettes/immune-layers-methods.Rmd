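---
title: "Layered immune gene expression analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layered immune gene expression analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immuneLayers)
```

# Scope and model

`immuneLayers` analyses bulk RNA-seq experiments in which replicated
individuals of a host organism — the motivating system is a sponge
challenged with bacterial lipopolysaccharide (LPS) — are sampled at two
timepoints under a treatment and a control. Immune gene regulation is
described in three layers:

1. **Constitutive expression** — a gene is detected (raw expected count
   > 0) in *every* sample, regardless of treatment or timepoint.
2. **Individual-specific expression** — detected in some samples only,
   tracking the individual rather than the condition: both clone pieces
   of an individual share the gene's presence or absence.
3. **Induced response** — differential expression between treatment and
   control at each timepoint, further split into *consistent* and
   *variable* genes by how many treatment replicates carry the
   regulation.

Around these layers the package places a domain-architecture screen
that classifies transcripts into pattern-recognition-receptor (PRR)
families from Pfam annotations, and a synthetic-data generator that
plants all of the above so each inference step can be validated against
a known truth table.

## Experimental design assumptions

The design emulated (and expected in real inputs) is 2 treatments x
2 timepoints x n individuals per treatment, with the *same* individual
sampled at both timepoints within a treatment (clones) but never in
both treatments. Dropout cells are allowed — the default configuration
drops one LPS individual at 6 h, giving 23 samples for n = 6, matching
the replication structure of the motivating experiment (5 LPS
replicates at 6 h). Because treatment arms contain disjoint individuals,
differential expression uses unpaired two-group contrasts per timepoint;
there is no individual blocking across treatment.

# The PRR domain screen

Transcripts are classified from Pfam domain content plus two per-
transcript predictions (transmembrane segment, signal peptide):

| family | rule |
|---|---|
| TLR_like | TIR (PF01582) + >= 1 Ig-like (PF00047) + TM segment |
| TIR_only | TIR without the complete TLR architecture |
| NLR_bona_fide | NACHT (PF05729) + >= 1 LRR (PF13516) |
| NACHT_only | NACHT without LRR |
| GPCR_GPS_7TM | 7TM evidence + GPS motif (PF01825) |
| GPCR_7TM | 7TM evidence alone |
| SRCR | PF00530 or PF15494 |
| CTLD | PF00059 |

Design choices a user should know:

* **TIR accession.** The TIR rule uses PF01582; the screen treats any
  other spelling of that accession in inputs as a distinct (ignored)
  accession — unknown accessions are never an error.
* **"7TM" has no single Pfam accession.** The default evidence set is
  the GPCR family accessions {PF00001, PF00002, PF00003, PF10320,
  PF10328}; it is a slot of `ReceptorRuleset` and fully overridable.
* **Precedence.** Real architectures can satisfy several rules; a fixed
  precedence (TLR_like > TIR_only > NLR_bona_fide > NACHT_only >
  GPCR_GPS_7TM > GPCR_7TM > SRCR > CTLD) makes the call single-valued
  and is configurable. Tallies are therefore non-overlapping by
  construction.
* **E-value filter.** Hits with e-value > 1e-5 are dropped before rule
  evaluation (overridable), mirroring the common homology-search
  threshold.
* **Cytokine receptors are out of scope** for the rule engine: they
  lack a shared diagnostic domain and require cross-species proteome
  mapping; a precomputed boolean column can carry them instead.
* Whether a complete TLR-like call should require the transmembrane
  segment is genuinely open; the default requires it
  (`tlrRequiresTM = TRUE`) because a receptor without membrane anchoring
  is at best an incomplete model, and the flag relaxes it.

The test suite checks the engine against a brute-force rule evaluator
that scores every family definition independently on randomized
annotation tables, and against planted architectures round-tripped
through the generator.

# Normalization

Within-sample abundance is TPM from counts and effective lengths;
between-sample scaling uses the trimmed mean of M-values (TMM) computed
on **counts** and then applied to the TPM matrix — the convention of the
assembly-pipeline scripts this workflow mirrors; computing TMM on TPM
directly is rejected as nonstandard. Details that matter numerically:

* Reference sample: the column whose 75th-percentile count fraction is
  closest to the mean of those fractions.
* Genes zero in either the sample or the reference are excluded from
  M/A; no pseudocounts enter the TMM computation.
* Double trim of 30% on M and 5% on A; precision weights from the
  delta method (an unweighted mean is available via
  `weighted = FALSE`). Factors are rescaled to geometric mean 1.
* Degenerate inputs: fewer than 10 genes surviving the trim triggers a
  warning and an untrimmed fallback; a sample sharing no positive genes
  with the reference is an error. Note the factor of a sample is exactly
  invariant to globally rescaling that sample's library only in
  unweighted mode — precision weights depend on library size, so the
  weighted factor is invariant to first order.

# Expression layers

Presence is `count > 0` on the **raw** expected-count matrix — the
constitutive definition is stated on observed detection, and normalized
values would let scaling decisions change presence. Fractional expected
counts below 1 still count as present; tools that assign ambiguous
reads can legitimately produce them, and zero remains the only
unambiguous absence.

The high-expression tier of constitutive genes uses the across-sample
*mean* TMM-TPM against a threshold of 10 by default (`highRule = "all"`
switches to requiring every sample above threshold). The
immune-vs-other comparison reports the ratio of median per-gene mean
TMM-TPM between constitutive immune genes and all other constitutive
genes; immune flags are an input.

## Individuality of repertoires

If carriage of individual-specific genes is a property of the
individual, samples should pair by individual rather than timepoint.
This is quantified on the presence/absence matrix restricted to
individual-specific genes: Jaccard distance between sample presence
vectors (the natural metric for binary repertoires), average-linkage
clustering for display, and a **pairing score** — the fraction of
two-sample individuals whose clone pair are mutual nearest neighbours.
Significance comes from permuting individual labels over samples:
`p = (1 + #{permuted score >= observed}) / (1 + n_permutations)`,
bounded in (0, 1] and reproducible under a fixed seed. When all
presence vectors are identical the score is undefined; the result is
flagged as a tie with p = 1. The mutual-nearest-neighbour score is this
package's quantification of a qualitative clustering observation; it is
deliberately simple and label-permutation-exact.

# Differential expression

The induced layer is tested per timepoint with an in-package
negative-binomial Wald test; no external DE engine is wrapped, and no
numerical equivalence with any published engine is claimed. The
thresholds — FDR < 0.005 and |log2FC| >= 2 — are the contribution this
stage embodies; the engine is a documented, desk-scale NB test:

* Effective size factors = library size x TMM factor, rescaled to
  geometric mean 1; counts are scaled before group means.
* Dispersion per gene: method-of-moments on pooled within-group
  residuals, `(s2 - mu) / mu^2` clamped at zero, shrunk 50/50 toward
  the 10%-trimmed mean raw dispersion of the gene's expression decile,
  floored at 1e-8. The 50/50 weight is a deliberate, simple compromise
  between per-gene noise and trend bias at n = 6 per group.
* log2FC between group means with pseudocount 0.5 (so zeros stay
  finite); SE by the delta method from the NB variance; two-sided
  p-value from the normal reference; Benjamini-Hochberg within the
  contrast.
* Independent filtering (all-zero genes plus the lowest base-mean
  decile) is applied before BH by default and reported via a message,
  since it changes the BH denominator.

Calibration at the study's group sizes is part of the test suite: on
null simulations (2000 genes, 6 vs 6, dispersion 0.1, log-normal
means) at most 5 genes are called in >= 95% of 50 seeded replicates,
and planted |log2FC| = 3 effects at mu = 100 are detected with power
>= 0.9.

# Consistent vs variable DEGs

DEG profiles (median-centered log2(TMM-TPM + 1) over the contrast's
samples) are clustered with Euclidean distance and complete linkage,
and the tree is cut at 40% of the maximum merge height — the
conventions of the clustering script family this stage mirrors, both
configurable. Replicate support operationalizes "regulated in a
replicate", which the source analyses leave informal: treatment
replicate r supports a DEG when
`log2((x_r + 1) / (control geometric mean + 1))` has the DE direction's
sign and magnitude >= 1 (half the DEG fold-change threshold). The
geometric mean is taken over raw control values, so any zero control
replicate drives it to zero; the +1 inside the ratio keeps it defined.

Labels: a support count is **consistent** when strictly greater than
half the number of treatment replicates, **variable** otherwise. This
single rule reproduces both stated conventions — "variable when
regulated in only 2 of the 5/6 replicates" and "consistent when more
than half" — and settles the gap case explicitly: with 6 replicates a
support of 3 is *variable* (more than half is not met), with 5
replicates a support of 3 is *consistent*. By default clusters are
labeled from their median member support and genes inherit the cluster
label (the cluster-based reading of the source analysis);
`mode = "gene"` labels each gene from its own support.

# The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions: 6 individuals per treatment, 2 timepoints, one LPS
individual missing at 6 h (23 samples), 20,000 genes split 40% / 45% /
15% into constitutive / individual-specific / silent, NB dispersion
0.2, log-normal baseline means (meanlog = log 50, sdlog = 1), 200
LPS-responsive genes at |log2FC| = 3 with 60% down-regulation
(reflecting the predominance of down-regulation in the motivating
response), responder penetrance 1, a 1.35x multiplicative boost on
constitutive immune gene means (10% of genes flagged immune), and
log-normal gene lengths (median 1.5 kb). Where the emulated study
fixes a value (design shape, thresholds, the ~35% immune median
excess, the share of down-regulation), the default encodes it; the
remaining distributional choices (log-normal means and lengths,
dispersion 0.2, presence probability 0.5) are one-time realism choices
typical of bulk RNA-seq, not fits.

Structural decisions:

* **Structural zeros are exact zeros**, matching the presence/absence
  reading of repertoire heatmaps; sampling zeros arise only from NB
  draws at positive means.
* **Constitutive means are floored at mu = 20** so the
  expressed-in-all-samples rule is recoverable from counts: at the
  floor, dispersion 0.2 and 23 samples, the expected fraction of
  constitutive genes hit by a sampling zero is under 1%, and every
  such error converts constitutive to individual-specific, never the
  reverse.
* **Carriage is decided per individual**, shared by both clones, and
  the carrier set is a non-empty *proper* subset of individuals — a
  gene carried by everyone would be constitutive by definition.
* **Responder penetrance is per gene** (scalar or vector), so one
  simulation can mix fully penetrant and minority-responder genes;
  responder sets are drawn from LPS individuals only, and responsive
  genes are drawn from the constitutive layer so the response is
  observable.
* **Dispersion 0 selects exact Poisson sampling**, used by tests that
  need the small-noise limit.
* **Seeding**: one config seed drives the count stage; derived stages
  use documented offsets (annotations: seed + 1; permutation tests in
  the pipeline: seed + 2), keeping a full run reproducible from a
  single integer.

What the generator does *not* emulate — and what passing tests
therefore do not show about real data: assembly artifacts (several
fragments per gene), length-dependent quantification bias, correlated
gene modules, library-composition shifts beyond what TMM absorbs,
microbiome-derived reads, and any real distributional form of
expression (log-normal + NB is an assumption of convenience). Headline
dataset numbers of the motivating study (absolute DEG counts, the
38%/62% PRR split, the 28,466 constitutive genes) depend on its raw
data and annotation databases and are deliberately not reproduction
targets; the package validates *properties* (recovery, calibration,
determinism) instead.

# Problem sizes and determinism

The shipped tests run the full stack at desk scale: 20,000 genes x 23
samples for layer recovery, 50 x 2,000-gene null replicates for DE
calibration, 100 null repetitions of the individuality permutation
test, and two full pipeline runs for byte-determinism (MD5 digests of
every stage file). These sizes make the whole suite run in a few
minutes on one CPU while keeping binomial noise on the asserted
fractions well inside the asserted bands. `runPipeline()` is
single-threaded by design; no result depends on parallelism.

# Worked example

```{r example, eval = FALSE}
cfg <- SimulationConfig(nGenes = 3000, seed = 11)
report <- runPipeline(simConfig = cfg, outdir = "run1")
report
```

Every number the report prints is written to a plain tab-separated or
JSON file under the output directory, so each stage can be re-examined
or re-run independently.
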