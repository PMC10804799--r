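---
title: "Multitask modelling of GPCR ligand potency: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitask modelling of GPCR ligand potency: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

G protein-coupled receptors (GPCRs) are the largest family of drug
targets, yet roughly a hundred human GPCRs are *orphans*: no endogenous
ligand is known and few or no ligand potencies have been measured.
Per-receptor (single-task) QSAR models cannot be trained for them.
`gpcrmtl` implements a multitask alternative: one regression model is
trained on the pooled ligand-potency records of *all* receptors, with
receptor identity carried by features derived from a multiple sequence
alignment. Because the receptor enters the model only through its
aligned sequence, the model can extrapolate to receptors unseen in
training — the orphan setting — and the reliability of such transfers
can be gated by protein-feature similarity.

# Data model

The atomic observation is one bioactivity record: a receptor, a ligand
(SMILES), an interaction mode (agonist or antagonist), and an EC50 in
nanomolar. The modelling label is `log10(EC50 / nM)`; base 10 is the
standard potency convention at nanomolar scale (a pEC50 up to sign and
offset). Records lacking a recognizable mode or a positive numeric EC50
are dropped and counted; mode strings are normalized case-insensitively
with whitespace stripped, and anything other than the two modes is
rejected. Duplicate (receptor, ligand, mode) measurements are kept as
independent records by default — repeated assays are informative about
noise — with an optional median-collapse.

Receptors with fewer than 8 records in total (both modes combined) are
held out entirely as an orphan test set; the count is across modes
because a receptor's data volume, not its per-mode split, determines
whether a per-receptor model is trainable. The remaining records are
split 0.8/0.2 into training and validation *within* each
(receptor, mode) group, then merged, so every receptor and mode is
represented in both partitions. Groups of fewer than five records put
`ceiling(0.8 n)` in training; a singleton group trains. The split is a
seeded draw and reproduces byte-identically.

# Feature encoding

Each record becomes one row of a block design matrix
`[protein | descriptors | fingerprint | mode]`:

* **Protein block** (width = alignment width `L`). Every aligned
  residue is mapped to an integer side-chain property class: 0 for the
  gap dash, 1 for special side chains (C, G, P, A), 2 for hydrophobic
  (V, I, L, M, F, Y, W), 3 for polar uncharged (S, T, N, Q), 4 for
  charged (D, E, R, H, K). Codes are fed to the learners as plain
  integers, exactly as this ordinal encoding implies; tree learners
  split them freely and the network standardizes them. Ambiguous
  letters (B, J, O, U, X, Z) are an error by default — data hygiene —
  with an opt-in mapping to the gap code.
* **Descriptor block** (width `D`, provider-dependent). The default
  provider computes OpenBabel's numeric 2-D physicochemical properties
  (hydrogen-bond acceptors and donors, logP, molar refractivity,
  molecular weight, fluorine count, topological polar surface area,
  `D = 8`); a precomputed table (e.g. a PaDEL export with `D = 1444`)
  can be supplied instead and is looked up by ligand id. Non-finite
  descriptor values are imputed with training-column medians, frozen at
  assembly and reused at prediction.
* **Fingerprint block** (width `F`, default 1024). Extended-connectivity
  (circular) fingerprints with maximum environment diameter 6
  (radius 3), computed by OpenBabel as 4096-bit ECFP6 and folded to
  `F` bits by OR over index modulo `F`. Unparsable SMILES exclude the
  record with a logged reason rather than silently contributing a zero
  vector.
* **Mode flag** (width 1): agonist = 1, antagonist = 0. The numeric
  convention is arbitrary and recorded in the column provenance.

With the reference block sizes (`L = 2554`, `D = 1444`, `F = 1024`) the
row is 5,023-dimensional. Column provenance (block and within-block
index) travels with the matrix so that downstream stages — feature
selection, probes, similarity — can always recover which columns are
alignment positions.

# The regression engine

The core fit is a stacked ensemble, `stack_ensemble()`, over five base
learner families: two gradient-boosted tree configurations (depth-6 /
learning-rate 0.1 and depth-4 / learning-rate 0.05), a random forest,
extremely randomized trees, and a single-hidden-layer feed-forward
network that standardizes inputs internally. Each base learner is
cross-fitted (5-fold) to produce out-of-fold predictions; a combiner
then chooses non-negative weights summing to one by greedy forward
selection with replacement, minimizing out-of-fold mean squared error.
Because each single base model is in the greedy pool, the combined
out-of-fold MSE can never exceed the best single learner's. Base models
with non-zero weight are refit on all training rows. All learner
randomness descends from one seed, so a fit is exactly reproducible; a
soft wall-clock budget skips remaining learners gracefully when
exceeded (at least one always trains).

Single-task models (`train_single_task()`) fit this stack per
(receptor, mode) group — or per receptor with modes pooled — and skip
groups with fewer than 4 training records, the smallest size for which
an internal cross-fit is meaningful. Multitask models
(`train_multitask()`) fit one stack on everything, with a mode filter
selecting the agonist-only, antagonist-only or merged task.

Evaluation reports MSE and Pearson correlation per receptor (or
receptor-by-mode) and overall; a group whose labels or predictions are
constant gets an explicitly undefined correlation (`NA` with a flag),
never a silent zero. Model families are compared with a two-sided
Mann-Whitney U test over per-receptor metrics, computed by exhaustive
enumeration of group assignments when the pooled sample is small
(n ≤ 12, exact even under ties) and by the tie-corrected,
continuity-corrected normal approximation otherwise.

# Feature selection

Candidate features (protein and descriptor columns; the fingerprint
block and mode flag are protected and always kept) are ranked by
minimum-redundancy–maximum-relevance in the MID (difference) form: the
first pick maximizes mutual information with the label, each later pick
maximizes relevance minus mean pairwise mutual information with the
already-selected set. Mutual information is the plug-in estimate on
discretized data: protein codes are already categorical; continuous
columns and the label are cut into five equal-frequency bins (the bin
count is configurable; five is a robust default for ~2,000 records).
Ties break toward the lowest column index, and a zero-relevance column
(e.g. a constant) is never ranked before an informative one. The
quotient (MIQ) form is available behind a switch; MID is the default as
the numerically stabler of the two.

The feature budget m is chosen from a validation-MSE curve over a
budget grid: the chosen m is the smallest for which the next budget's
relative improvement falls below 5%. "Improvement" is plain relative
change, not a significance test — the stopping rule is deliberately
simple and monotone in the curve. The retained-feature count is
reported as m plus the protected fingerprint width (the mode flag is
appended but not counted), so the reference configuration m = 200 with
F = 1024 reports 1,224 features.

# Interpretation probes

To localize which protein regions a trained multitask model relies on,
the alignment columns are divided into seven contiguous segments of
near-equal size — first `L mod 7` segments one column longer — echoing
the seven-transmembrane architecture. Probes are run only on receptors
the model predicts well (validation correlation strictly above 0.95),
because error inflation is only interpretable against a good baseline:

* **Truncation**: all (retained) protein columns of one segment are set
  to 0, the gap code, in the validation rows; the model is re-evaluated
  without refitting.
* **Permutation**: each protein column in the segment is shuffled
  across rows, preserving its marginal code frequencies while
  destroying the receptor–column association. Shuffling is the default
  reading of "randomized encoding" because it is standard permutation
  importance; drawing uniform random codes 0–4 is available behind a
  flag. Shuffles are seeded and repetitions can be averaged.

Segmentation is over alignment columns of the full protein block (not
per-receptor ungapped positions), so segments mean the same thing for
every receptor. For feature-selected models only the retained columns
within a segment are probed; a segment that retained no columns is
reported with fold change 1 and flagged. The per-segment result is the
per-receptor MSE fold change over the unperturbed baseline, which is
recomputed on the identical record set.

# Applicability domain

Transfer to an orphan receptor is only credible if its protein features
resemble some training receptor. The similarity is a gap-aware Tanimoto
over property-code vectors: a position counts toward the intersection
only when both receptors carry the *same non-zero* code; each vector's
set size is its non-gap position count; positions gapped in both
vectors contribute nowhere. This reading makes the measure symmetric,
bounded in [0, 1], and equal to 1 on self-comparison of any non-empty
vector — properties required for its use as a percentage similarity.
(Requiring code equality rather than mere joint coverage is the
stricter of the two readings; the alternative is exposed in the
configuration for comparison.) The domain gate takes each orphan's
maximum similarity to the training receptors, over the full protein
block or the selected protein positions, and retains the orphan only if
it is *strictly greater* than the threshold — receptors at or below the
threshold are excluded, so 5% and 9% operating points behave as
permissive and strict gates.

# The synthetic benchmark generator

Real GPCR bioactivity corpora are large, heterogeneous and have no
ground truth, so every pipeline stage is verified against a generator
whose answers are known exactly (`synth_config()`,
`generate_synthetic_dataset()`).

**Receptors.** Four families of six receptors each are derived from
family ancestors (uniform codes 1–4, 10% of positions gapped) by 5%
per-position mutation, giving recognizable families: within-family
similarity exceeds between-family similarity, which the
applicability-domain statistics must recover. Twenty *informative
positions* are planted inside segment 1 of 7 (the N-terminal part of a
210-column alignment; 210 is divisible by 7 so probe segments are
exactly equal). Each informative position has a preferred code and an
effect weight drawn from U(0.9, 1.1).

**Why the informative codes are assigned by balanced stratification.**
Protein features are constant within a receptor, so any
family-identifying column is a potential proxy for family-mean potency.
If informative codes were drawn independently, sampling noise would
make realized family means differ, and proxy columns anywhere in the
alignment would genuinely predict the label — feature selection and
probes would then correctly, but unhelpfully, point at proxies. The
generator therefore assigns preferred codes by stratified balanced
draw: within each family (and separately within its regular and
low-data/orphan members), exactly half the receptors — the configurable
match rate — carry the preferred code. Family membership is thereby
orthogonal to the planted signal, and the planted positions are the
*only* cross-receptor carriers of it. One consequence: with the
mutation rate set to zero, family members are identical only outside
the informative positions.

**Records.** Each record draws a fresh synthetic ligand: 64 Bernoulli
fingerprint bits (density 0.2) of which 10 are active with weights
U(0.4, 0.8), and an 8-column descriptor block in which 3 columns are
noisy multiples of the weighted active-bit sum (recoverable by feature
selection) and 5 are pure noise. The noiseless label is the sum of the
planted position effects, the active-bit effects, ten sparse
position-by-bit interaction terms (U(0.2, 0.5)), and a +0.5 agonist
offset; Gaussian noise with standard deviation 0.2 log10 units — the
optimistic end of inter-assay EC50 reproducibility — is added, and the
EC50 is emitted as `10^label` nM so the loader's log-transform
round-trips. Ligand signal and noise are calibrated so that a
well-fitted receptor can exceed the 0.95 validation-correlation probe
filter, as the probe design requires.

**Record counts** are skewed as in real collections: 80 records for
each regular receptor, 12 for six low-data receptors (above the orphan
threshold, but far too few for a good per-receptor model — the
multitask-benefit comparison arm), and 5 for three orphan-like
receptors (isolated exactly by the orphan threshold of 8). The default
totals 2,007 records over 33 receptors. All randomness flows from one
master seed through named child seeds (informative positions,
alignment, ligands, modes, noise), so stages are individually
reproducible.

**What the generator does not emulate.** Synthetic ligands are feature
vectors, not molecules — chemistry featurization is tested separately
on a fixed list of real SMILES — and the generator makes no attempt to
match GPCRdb's empirical EC50 distribution, assay heterogeneity,
activity-cliff structure, or real GPCR phylogeny. Passing the recovery
tests therefore demonstrates that the machinery is correct, not that
comparable accuracy will be achieved on real data.

# Benchmark properties and problem sizes

`run_benchmark_seed()` executes the full study design on one seed:
train the merged multitask model, probe it, and train merged-mode
single-task models for the low-data receptors. Across five seeds the
package's acceptance properties are: the multitask model beats the
single-task models on mean per-receptor low-data validation MSE in at
least 4 of 5 seeds; the planted segment attains the maximum permutation
fold change in at least 4 of 5; and the mRMR ranking recovers at least
80% of the planted positions among its top 40 candidates on average.
The benchmark sizes (about 2,000 records, 283 features, five base
learners, 5-fold cross-fitting) were chosen so a full five-seed
replicate completes in minutes on a single CPU while leaving the
planted effects clearly above estimation noise.

# Numerical and design notes

* The equal-frequency discretizer collapses to fewer bins when a column
  has few distinct values; a constant column has zero relevance by
  construction and is ranked last.
* Greedy ensemble weighting stops when no candidate addition improves
  the out-of-fold MSE; with a 25-round cap, weights are multiples of
  small reciprocals, never negative, and sum to one.
* The feed-forward net guards against zero-variance columns by unit
  scale substitution; label standardization is undone at prediction.
* Orphan receptors never contribute to training, to fold assignment, or
  to descriptor imputation medians.
* `stratified_split` sends `round(0.8 n)` to training for groups of at
  least five and `ceiling(0.8 n)` below that, so no non-empty group
  ever loses all training records.
* Exact Mann-Whitney enumeration costs `choose(nA + nB, nA)` table
  evaluations; the default exactness cutoff of 12 keeps this under a
  thousand.

# Known limitations

* The protein encoding is ordinal over an unordered five-class
  alphabet; trees handle this natively, but the network sees arbitrary
  order. A one-hot switch exists for sensitivity analysis.
* OpenBabel's ECFP bit assignment differs from other toolkits'
  implementations of the same fingerprint family; fingerprints are
  deterministic and canonical within a toolkit, but bit-level
  compatibility across toolkits is not provided.
* The default descriptor provider has 8 columns — sufficient for the
  pipeline's mechanics and the synthetic benchmark, far fewer than a
  full QSAR descriptor battery; supply a precomputed table for serious
  chemical modelling.
* Multitask transfer is only as good as the alignment: receptors whose
  alignment rows are mostly gaps will have near-empty protein feature
  sets and correspondingly low similarity to everything, and should be
  gated out by the applicability domain.
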