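# hippcat

Rate-coded simulations of how the hippocampal circuit supports rapid
category learning, and how its two pathways divide that labour.

The hippocampus both stores distinct episodes and extracts regularities
across them. `hippcat` implements a neural-circuit account of how it
manages both during category learning: a five-layer network (Input,
superficial/deep entorhinal cortex `EC_in`/`EC_out`, and subfields DG,
CA3, CA1) trained as an autoencoder with theta-phase Contrastive
Hebbian Learning. The **trisynaptic pathway** (EC_in → DG → CA3 → CA1)
is sparse and fast-learning — its pattern-separated, attractor-bound
codes store exemplar-specific details. The **monosynaptic pathway**
(EC_in → CA1) is dense and 10× slower — its overlapping codes
accumulate the shared structure that defines categories. Lesioning
either pathway (and probing the behaviour of the remaining one)
dissociates recognition of unique exemplar features from categorization
and generalization.

Activity is a rate code in [0, 1] with set-point k-winner-take-all
inhibition per layer: inhibition settles between the k-th and (k+1)-th
largest drives, and activation is a logistic function of
(drive − inhibition). Learning contrasts unit coactivities between
free (minus) and target-clamped (plus) phases,
`Δw = ε (x⁺y⁺ − x⁻y⁻)`, with the two theta minus phases (trough:
EC-driven CA1; peak: CA3-driven CA1) letting the two pathways learn
independently; sparse-pathway projections add CPCA Hebbian
self-organization (`Δw = ε y (x − w)`) that builds the CA3
auto-associator.

Three task generators reproduce classic category-learning paradigms:

* **satellites** — 3 categories × 5 exemplars over 27 binary features
  (shared + unique features; 140 trials),
* **weather** — the probabilistic Weather Prediction Task (4 cards, 14
  combinations, stopping rule after ≥25 trials with 5 consecutive
  sum-squared errors < 1.2),
* **typicality** — two intermixed categories over 10 binary features
  with a graded typicality continuum (100 trials).

## A worked example

```r
library(hippcat)

sat <- build_satellite_dataset(seed = 1)
sat
#> <hippcat_dataset> satellites: 15 training items over 27 input units
#>   probe sets: unique_feature, categorization, generalization

net <- build_task_network(sat, seed = 42, condition = "intact")
fit <- train(net, sat, seed = 43)                 # 140 trials
scores <- run_test_battery(fit$network, sat, trial = 140)
aggregate(cbind(score, chance) ~ kind, scores, mean)
#>             kind     score    chance
#> 1 categorization 0.5739209 0.3333333
#> 2 generalization 0.8179142 0.3333333
#> 3 unique_feature 0.5316391 0.2500000
```

After training, this network fills in the category-prototypical feature
for novel satellites far above the 1/3 chance level (generalization
0.82), and recognizes unique exemplar features and the category of
single-feature cues above their chance levels.  The pathway
dissociations emerge across conditions and seeds: rerun with
`condition = "MSP-only"` and the network generalizes just as well but
recognizes unique features exactly at chance; with
`condition = "TSP-only"` the profile reverses.

Full experiments (many seeded networks × lesion conditions, score
tables, learning curves, similarity matrices, JSON manifest):

```r
res <- run_experiment("satellites", n_networks = 100, seed = 1,
                      rsa = TRUE, out_dir = "runs/satellites")
res$aggregate
condition_contrasts(res$scores, "generalization")
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/hippcat run --sim weather --n-networks 100 --seed 1 --out runs/wea
Rscript inst/cli/hippcat make-dataset --sim typicality --seed 1 --out typ.tsv
```

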