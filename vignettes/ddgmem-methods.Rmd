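---
title: "Methods: curation, features and the ddG training protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation, features and the ddG training protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddgmem)
```

# The model and its assumptions

`ddgmem` predicts the change in binding free energy of a protein–protein
complex caused by a single amino-acid substitution, from sequence alone.
The thermodynamic backbone is standard: a dissociation constant K_D maps
to a binding free energy ΔG = RT·ln(K_D), and the mutational effect is
ΔΔG = ΔG_mutant − ΔG_wild-type, positive when the mutation destabilizes
the complex. The statistical model is a gradient-boosted ensemble of
regression trees over descriptors computed from the two chains' sequences
and their PSI-BLAST profiles. The central assumptions are:

* **Sequence sufficiency.** No structural information is used. The
  evolutionary profile of each chain (its PSSM) and the local sequence
  context of the mutated site are assumed to carry enough signal about
  the interface. This is the operative assumption for membrane protein
  complexes, where 3D structures are rare.
* **Single, dimeric mutations.** The curation pipeline retains only
  two-chain complexes with one substitution; multi-mutations and
  higher-order assemblies are out of scope.
* **One consensus value per mutation.** Replicate measurements are either
  reconciled (mean) or discarded (high variance, sign conflicts); the
  model never sees contradictory labels for the same (complex, mutation)
  key.

# Curation: decisions behind each stage

The pipeline runs ten stages in a fixed order; every removal is recorded
with a machine-readable reason, and the report is checked for
conservation (records in − removed = out, stages chain without gaps).

* **ΔΔG recomputation.** When both ΔG values are present or derivable
  from K_D pairs, the difference always replaces a stated ΔΔG: published
  tables are known to contain transcription discrepancies, and the
  difference is the definition. A record with only a stated ΔΔG keeps it.
* **Gas constant and temperature.** R = 1.987e-3 kcal/(mol·K) and
  T = 298.15 K by default. Source tables rarely state the assay
  temperature; 25 °C is the conventional reference, and both values are
  configurable through `curationConfig()`.
* **Replicate filter.** Groups sharing (complex, mutated partner,
  mutation) are removed whole when the ΔΔG sample standard deviation
  (n−1 denominator) exceeds 1.0 kcal/mol. The estimator choice matters
  only for tiny groups; the sample form is the conservative one (larger
  SD, more removals flagged for review). Singletons get SD 0 — nothing
  to disagree with.
* **Sign conflicts.** The codified rules: (i) a pair with opposite signs,
  both |ΔΔG| > 0.5 kcal/mol, is removed whole; (ii) groups of 3–4 with
  mixed signs and any |ΔΔG| > 0.5 are removed whole; (iii) in groups of
  five or more, one or two values deviating from the group median by more
  than 0.5 kcal/mol are removed individually and the remainder is kept
  for averaging. "Deviates significantly" is operationalized as distance
  from the median because the median is the robust center under exactly
  the contamination being removed. These rules reproduce the documented
  behavior for every group size, but other operationalizations exist; the
  cutoff is a config parameter.
* **Duplicate merging.** The arithmetic mean; after merging, the
  per-replicate K_D/ΔG fields are cleared so a re-run cannot overwrite
  the consensus — this is what makes the pipeline idempotent, which the
  tests assert.
* **Pseudonyms.** Complexes without an identifier get one derived from a
  32-bit FNV-1a hash of the sorted partner-identifier pair: deterministic
  across reruns, shared by records of the same complex, and collision-safe
  at the scale of affinity databases (thousands of complexes).
* **Renumbering.** Mutation positions are translated from structure to
  sequence coordinates via caller-supplied maps (identity when absent),
  then the stated wild-type residue is checked against the sequence.
  Records renumbered once are marked, so re-curation validates without
  double-translating.

# Features

All matrices use the alphabetical one-letter residue order
(ACDEFGHIKLMNPQRSTVWY) internally; file parsers re-map from whatever
order the file declares, so feature order never depends on the file
dialect.

* **Normalization.** PSSM log-odds pass through the logistic function
  f(x) = 1/(1+e^−x) before any descriptor is computed, bounding every
  entry in (0,1). The lag descriptors are computed on these normalized
  scores — the natural reading, since normalization is introduced before
  the sequence-order terms and keeps their squared differences on one
  scale (on raw integer scores a single saturated pair could dominate a
  whole lag block).
* **Averaged PSSM** (20 values per chain) is the column mean — length
  independent by construction. **Row-PSSM** (20) is the normalized row at
  the mutation site. **Pseudo-PSSM** lag blocks
  φ_j^φ = (1/(L−φ))·Σ(P_i,j − P_i+φ,j)² need L > φ; shorter sequences are
  an error, not a silent zero.
* **The ONLY_10_PLUS set** (the default model input) is: averaged PSSM of
  the mutating and interacting chains, the lag-10 pseudo-PSSM block of
  both chains, and the Row-PSSM — exactly 100 features. The lag-10-only
  reading (rather than all lags 1..10) is what makes the count come out
  at 100 = 20·5, which is the set's defining property; the cumulative
  reading would give 460. The "mutating" chain is the one carrying the
  substitution, the "interacting" chain is its partner.
* **Physicochemical set**: AAIndex1 attribute differences (mutant −
  wild-type, one per complete scale), the ten neighboring-residue codes
  (five before and five after the site, 0 for positions off either
  terminus — termini are real data, not errors), five residue-category
  transition labels (chemical 7 classes, size 5, polarity 4, hydrogen
  bonding 4, hydrophobicity 3; the label encodes the ordered class pair),
  and the mutation-type label — a fixed bijection from the 380 ordered
  residue pairs onto 0..379. The mutation-type label sits in this group
  as the residue-identity descriptor; it is categorical by nature, and
  tree ensembles split on it directly.
* **Evolutionary set**: AAIndex2 substitution scores, both averaged
  PSSMs, Row-PSSM, and the lag blocks φ = 1..10 for both chains. The lag
  blocks enter without repeating the 20 column averages (which are
  already their own group) — the package documents its own exact counts
  rather than forcing agreement with any externally printed total.
* **Database features** (combined set only): pH as a number (7.0 when
  absent) and integer-coded functional/structural membrane-protein
  classes against vocabularies frozen at fit time, with 0 reserved for
  classes unseen at training.

# Training protocol

* **Cross-validation.** k-fold (5 or 10) with pooled out-of-fold
  predictions: every sample is predicted exactly once by a model that
  never saw it, and the Pearson correlation (PCC) and RMSE are computed
  on the pooled vector. Pooled rather than fold-averaged PCC because it
  stays well-defined for small folds and weights every sample equally.
  Constant responses raise an explicit error (PCC is undefined).
* **Hyperparameter search.** Uniform draws with replacement from a
  discrete dictionary (`defaultHyperSpace()`: boosting rounds 100–500,
  depth 3–8, learning rate 0.01–0.2, row/column subsampling 0.6–1.0,
  min child weight, L1/L2 weights), each draw scored by cross-validation.
  Argmax by PCC, ties broken by lower RMSE then earlier draw — total
  order, hence reproducible.
* **Determinism.** Every random stream (splits, draws, per-fold fits) is
  seeded from the master seed through a label-keyed hash, so runs are
  bitwise reproducible end to end, which the acceptance checks assert via
  artifact comparison.
* **Importance.** Gain importance accumulated over every fold model of
  repeated 10-fold cross-validation, averaged and normalized to sum to 1;
  features never split on get exactly 0.
* **Persistence.** A model artifact embeds the serialized ensemble, the
  feature-set spec, the hyperparameters and a fingerprint of the ordered
  feature names; both loading and prediction verify the fingerprint, so a
  vector assembled under a different spec is refused rather than silently
  mis-ordered.

# What the synthetic generators emulate — and what they do not

The fixture module exists so that every pipeline stage is exercised
without downloading the affinity database, AAIndex release, or running
PSI-BLAST.

* `syntheticPSSM()` draws integer log-odds from a rounded Gaussian
  (mean −2, SD 4) clamped to [−16, 13] — the range and discreteness of
  real PSI-BLAST ASCII output — and up-weights the true-residue column to
  mimic conservation. The writer emits the PSI-BLAST ASCII dialect
  (NCBI column order, percentage block, trailing statistics) so the
  parser is tested against the layout it will meet in the field.
* `plantedDataset()` builds records whose ΔΔG is a linear function of
  five named ONLY_10_PLUS features plus Gaussian noise, with the features
  computed by the package's own extraction code — the planted map is
  exactly learnable and ground truth stays analytic. Defaults: n = 800
  records, chain lengths 30–60, three Row-PSSM features at |weight|
  2 kcal/mol and two lag-10 features at |weight| 6 kcal/mol, noise SD
  0.3 kcal/mol. The weights were fixed from the measured spreads of the
  feature families under the synthetic PSSM model (Row-PSSM SD ≈ 0.38,
  lag-10 SD ≈ 0.06), giving a planted signal SD ≈ 1.4 kcal/mol — the
  few-kcal/mol spread real single-mutation data shows — and a noise
  ceiling PCC ≈ 0.97. A linear map was chosen because tree ensembles
  approximate it well while keeping recovery tests closed-form.
* `messyAffinityTable()` plants one defect class per curation stage
  (constructed to be orthogonal: e.g. the opposite-sign pair ±0.7 kcal/mol
  has sample SD 0.99, below the replicate cutoff, so it survives to the
  sign-conflict stage), and returns the expected stage-by-stage report.

What passing these tests shows: the arithmetic, accounting, determinism
and learnability of the pipeline are correct. What it does not show:
accuracy on real membrane-protein data. Synthetic PSSMs have no
phylogenetic column correlations, the planted ΔΔG map is linear in five
features while real effects are diffuse and epistatic, and the real ΔΔG
distribution is strongly enriched near zero (alanine scanning dominates
real tables; the generator does not reproduce that point mass). Real-data
performance must be established with the externally distributed affinity
tables and UniRef50 PSSMs.

# Problem sizes and tolerances

The test suite and the acceptance script run the planted benchmark at
n = 800 with 10-fold cross-validation, the importance average over 3
repeats of 10-fold refits, the lag-descriptor oracle over 100 random
matrices at tolerance 1e−12 (observed agreement is at machine epsilon),
and the curation equality check over 20 random defect plans — sizes
chosen to give stable statistics in about two minutes on a single CPU.
The closed-form ΔG/ΔΔG identities are checked to 1e−9 kcal/mol over 1000
random K_D pairs.

# Known limitations

* The sign-conflict tie-break is one defensible codification of an
  under-documented convention; record-for-record agreement with any
  specific historical curation script is not guaranteed, which is why the
  report exposes per-stage diffs instead of asserting a single terminal
  count.
* AAIndex2 matrices with gap/ambiguity rows are used after dropping those
  rows; a matrix that still cannot resolve all 400 ordered pairs is
  excluded as a whole rather than imputed.
* PSSM generation is external by design (PSI-BLAST, 3 iterations,
  E-value 0.001, UniRef50); the package parses and consumes profiles but
  does not embed a sequence-database search.
* The predictor inherits the training distribution's biases: mutations at
  positions with shallow profiles (few homologs) carry little signal, and
  nothing in the model detects that a query is out of distribution.
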