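# gpcrmtl

Multitask stacked-ensemble modelling of GPCR ligand potency (EC50),
with feature selection, protein-region interpretation probes, and a
similarity-gated applicability domain for orphan receptors.

## The problem

G protein-coupled receptors (GPCRs) are the largest family of drug
targets, but many are *orphans* with few or no measured ligand
activities, so ordinary per-receptor QSAR models cannot be trained for
them. `gpcrmtl` trains **one** regression model over the pooled records
of many receptors. Receptor identity enters only through features
derived from a multiple sequence alignment, so the model transfers to
receptors unseen in training, and the trustworthiness of such a
transfer can be quantified by protein-feature similarity.

Each record (receptor *r*, ligand with SMILES *s*, mode *m* ∈
{agonist, antagonist}, EC50 in nM) is encoded as one row

```
x = [ protein codes (L) | descriptors (D) | ECFP bits (F) | mode flag ]
y = log10(EC50 / nM)
```

where the protein block maps each aligned residue to a side-chain
property class (0 gap; 1 = C,G,P,A; 2 = V,I,L,M,F,Y,W; 3 = S,T,N,Q;
4 = D,E,R,H,K), the fingerprint block is a folded extended-connectivity
fingerprint of diameter 6, and the reference block sizes
(L = 2554, D = 1444, F = 1024) give a 5,023-dimensional design.

The regression engine is a stacked ensemble of five base learners (two
gradient-boosting configurations, random forest, extremely randomized
trees, a feed-forward net), cross-fitted out of fold and combined by
greedy non-negative weighting; performance is reported as MSE and
Pearson CC per receptor:

```
MSE = (1/n) Σᵢ (Yᵢ − yᵢ)²
CC  = Σᵢ(Yᵢ − Ȳ)(yᵢ − ȳ) / sqrt( Σᵢ(Yᵢ − Ȳ)² · Σᵢ(yᵢ − ȳ)² )
```

Around the core model the package provides:

* **mRMR feature selection** (MID criterion, discretized mutual
  information) with a protected fingerprint block and a ≤5%-improvement
  budget rule;
* **truncation / permutation probes** over seven equal alignment
  segments, measuring which protein regions a trained model relies on;
* a **gap-aware Tanimoto similarity** between receptors'
  property-code vectors,
  `Ts(X, Y) = |X ∩ Y| / (|X| + |Y| − |X ∩ Y|)`, where a position is in
  the intersection only when both codes are equal and non-gap, used to
  gate orphan predictions (applicability domain);
* a **synthetic-data generator** with planted ground truth (informative
  alignment positions concentrated in one segment, active fingerprint
  bits, interactions, mode offset) so every stage is verifiable end to
  end;
* a thin **command-line interface**
  (`inst/cli/gpcrmtl.R`: `simulate | encode | select | train | probe |
  ad | evaluate | report`) driven by a YAML run configuration.

## Worked example

Generate a synthetic benchmark, train the merged multitask model, and
evaluate it per receptor:

```r
library(gpcrmtl)

ds    <- generate_synthetic_dataset(seed = 1)
parts <- split_orphan_receptors(ds$records, threshold = 8)
split <- stratified_split(parts$modelled, ratio = 0.8, seed = 1,
                          orphan_test = parts$orphan)
fm    <- assemble_synth(ds)

mtl <- train_multitask(fm, split, mode_filter = "merged", seed = 1)
print(mtl)
#> Multitask EC50 model (mode filter: merged )
#> Stacked ensemble regressor (1596 training records, 283 features, 5-fold OOF)
#>   combiner weights:
#>     gbdt_a                       0.000
#>     gbdt_b                       1.000
#>     random_forest                0.000
#>     extremely_randomized_trees   0.000
#>     feedforward_net              0.000
#>   out-of-fold MSE: 0.0964

evaluate_model(mtl, fm, split, "validation")
#> Evaluation over 396 records: MSE 0.0778, CC 0.9964
#> 30 groups; per-group summary of MSE:
#>     Min.  1st Qu.   Median     Mean  3rd Qu.     Max.
#> 0.005912 0.052446 0.074027 0.073235 0.101284 0.147643
```

The validation MSE of 0.078 approaches the generator's noise floor
(noise SD 0.2, irreducible MSE 0.04), and the pooled validation CC of
0.996 says the model recovers almost all planted signal. Receptors the model
predicts well (CC > 0.95) can then be probed for which alignment
segments matter:

```r
ev  <- evaluate_model(mtl, fm, split, "validation")
rec <- select_probe_receptors(ev)                 # CC > 0.95
seg <- segment_protein_columns(L = 210, k = 7)
pr  <- permutation_test(mtl, fm, split, seg, rec, seed = 1)
summarize_probe(pr)[, c("segment", "mean_fold_change")]
#>   segment mean_fold_change
#> 1       1       217.416432
#> 2       2         1.509864
#> 3       3         3.144102
#> 4       4         1.625907
#> 5       5         4.893053
#> 6       6         1.490320
#> 7       7         1.226241
```

Segment 1 — where the generator plants its informative positions —
shows a two-orders-of-magnitude MSE inflation under permutation while
the other segments stay near 1: the probe localizes the planted
region.

The same stages run from the shell:

```sh
Rscript inst/cli/gpcrmtl.R simulate --out run1 --seed 1
Rscript inst/cli/gpcrmtl.R encode   --out run1
Rscript inst/cli/gpcrmtl.R train    --out run1 --task mtl-ag-atg
Rscript inst/cli/gpcrmtl.R evaluate --out run1
Rscript inst/cli/gpcrmtl.R report   --out run1
```

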