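# ptmnet

Post-translational modifications (PTMs) carry disease-relevant signal,
but curated PTM–disease catalogues are sparse and overlap only
partially with the proteins measured in clinical expression panels.
`ptmnet` is an R package for proteomics researchers that closes the
loop between the two data types in two stages:

1. **PTM potentiality scores.** From a binary protein × disease
   association matrix *A* and protein sequences, a layer-attention
   graph convolutional network (GCN) over the heterogeneous network

   *A*<sub>H</sub> = [ D<sub>p</sub><sup>-1/2</sup> S<sub>P</sub> D<sub>p</sub><sup>-1/2</sup>, A ; Aᵀ, D<sub>d</sub><sup>-1/2</sup> S<sub>D</sub> D<sub>d</sub><sup>-1/2</sup> ]

   — where S<sub>P</sub> fuses Smith–Waterman sequence similarity with
   the Gaussian interaction profile (GIP) kernel and S<sub>D</sub> is
   the disease GIP kernel — learns per-layer embeddings combined by a
   trained attention vector and decoded bilinearly,
   *A′* = sigmoid(H<sub>p</sub> W′ H<sub>d</sub>ᵀ), under a
   class-weighted cross-entropy.  Each entry *a′₍ᵢⱼ₎* ∈ (0,1) scores
   how plausible an undiscovered protein–disease PTM association is.

2. **Score-weighted subtype classification.** For proteins shared
   between the catalogue and a sample × protein expression matrix, each
   abundance value *p* is re-weighted as
   *p′ = 2 · p · a · exp(δ·|p|)* — amplified when its potentiality
   score *a* exceeds 0.5, attenuated below — before transductive GCN
   classification over a thresholded cosine-similarity sample graph.
   Cross-validated screening then identifies which shared proteins
   actually improve prediction (candidate PTM biomarkers), ranked by
   the number of folds in which they help.

A seeded synthetic-data generator (block-structured associations,
motif-sharing sequences, expression cohorts with planted subtype
signal) makes the whole pipeline testable end to end without any
external download.

## Worked example

```r
library(ptmnet)

spec <- synthetic_spec(n_proteins = 40, n_diseases = 16, n_blocks = 4,
                       n_samples = 120, n_expr_proteins = 60,
                       n_shared = 12, n_shared_informative = 6, seed = 42)
study <- simulate_ptm_study(spec)

## Stage 1: potentiality scores from the heterogeneous network
ssp <- sequence_similarity(study$sequences)
sgp <- gip_kernel(study$assoc)
sgd <- gip_kernel(t(study$assoc))
sp  <- fuse_similarity(ssp, sgp)
net <- build_input_graph(build_hetero_network(study$assoc, sp, sgd), psi = 6)
fit <- lagcn(net, study$assoc, epochs = 300, seed = 42)
fit
#> Layer-attention GCN link predictor (40 proteins x 16 diseases)
#>   k = 64, L = 3, preset 'grid' (lr 0.01, 300 steps), psi = 6
#>   final loss 0.38337; attention theta: 0.662, 0.258, 0.030
rank_auc(fit$scores[study$assoc == 1], fit$scores[study$assoc == 0])
#> [1] 0.978
```

Known pairs average a score of 0.92 against 0.11 for unknown pairs:
the network reproduces the catalogue and spreads scores to related
pairs.  (Held-out performance is measured properly with
`kfold_link_auc()`, which masks test associations before similarity
computation and training.)

```r
## Stage 2: weight the expression panel and classify subtypes
cv_plain    <- fwgcn_cv(study$expr, k = 5, seed = 42)
weighted    <- feature_weight(study$expr, study$truth$scores, delta = 0.01)
cv_weighted <- fwgcn_cv(weighted, k = 5, seed = 42)
c(unweighted = cv_plain$mean_acc, weighted = cv_weighted$mean_acc)
#> unweighted   weighted
#>      0.783      0.875
unlist(classification_metrics(study$expr$labels, cv_weighted$prob))
#>       acc        f1       auc
#> 0.8750000 0.8760331 0.9416667
```

Weighting the 12 shared proteins by their scores lifts 5-fold accuracy
from 0.783 to 0.875 on this fixture.  The screen ranks shared proteins
by how often their individual weighting improves a fold:

```r
screen_biomarkers(study$expr, study$truth$scores, k = 5, seed = 42,
                  hidden = 32, epochs = 150)
#> Biomarker screen over 5 folds: 12 shared protein(s), 11 with count > 0
#>   protein count mean_improvement
#> 1  PROT33     4       0.05000000
#> 2  PROT27     4       0.03333333
#> 3  PROT23     3       0.05000000
#> 4   PROT4     3       0.03333333
#> 5  PROT21     3       0.03333333
#> 6   PROT9     3       0.02500000
```

Five of the six planted informative proteins (`PROT4, PROT9, PROT21,
PROT23, PROT27`) sit in the top six.

A command-line surface wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/ptmnet.R", package="ptmnet"))') \
    simulate --out-dir demo --seed 4
```

with subcommands `simulate`, `predict-ptm`, `classify`, `screen` and
`evaluate`.  See the vignette `vignettes/ptmnet-methods.Rmd` for the
model, its defaults, and the design decisions.

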