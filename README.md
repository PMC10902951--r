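# pathsurvnet

Pathway-masked multitask deep survival networks with uncertainty-aware
integrated-gradients gene ranking, in pure R.

## The problem

Predicting a cancer patient's outcome from gene expression is a censored
survival problem with far more genes than patients (p of order 10^3–10^4,
n of order 10^2). Dense models memorize; and even when a model predicts
well, clinicians need to know *which genes* drive the prediction, with some
notion of how trustworthy each attribution is. `pathsurvnet` is for
biostatisticians and computational biologists who want a single framework
that (i) regularizes a deep survival model with prior pathway structure and
with auxiliary self-supervised tasks, and (ii) ranks genes by an
attribution score that is explicitly discounted by its own estimation
uncertainty.

## The model

The network is a multitask autoencoder over expression profiles
`x ∈ R^p`:

- **Sparse pathway layer.** A binary biadjacency matrix `A ∈ {0,1}^{q×p}`
  (pathway × gene membership, from a GMT file) gates the first layer:
  `h_1 = ReLU((W ∘ Aᵀ)ᵀ x + b)`. Only gene–pathway edges carry weights;
  masked weights are structurally inert.
- **Encoder / decoder.** `h_1 → 1000 → 500 → z` (ReLU, dropout after the
  hidden layers), with a mirrored decoder and linear output giving a
  reconstruction `x'`; the reconstruction loss is
  `L_D = (1/n) Σ_i ‖x_i − x'_i‖²`.
- **Deep embedded clustering.** Soft assignments of embeddings `z_i` to
  cluster centers `μ_j` under a Student-t kernel,
  `t_ij ∝ (1 + ‖z_i − μ_j‖²)^{-1}`, sharpened into a target distribution
  `s_ij ∝ t_ij²/Σ_i t_ij`; the clustering loss is `L_C = KL(S‖T)`. The
  number of clusters k ∈ [2,4] is picked by silhouette on k-means; labels
  and centers are refreshed every epoch.
- **Risk head.** A linear unit on `z` produces the log-hazard `h_θ(x)`,
  trained with the negative Cox partial likelihood
  `L_P = −Σ_{i: event} [h_i − log Σ_{j: T_j ≥ T_i} exp(h_j)]`
  (Breslow ties).
- **Total loss.** `γ L_D + β L_C + L_P` with defaults `γ = 1`, `β = 10`,
  optimized full-batch with Adam and L2 weight decay.

Gene importance uses **integrated gradients** of the risk output along the
straight path from a baseline (the cohort mean, i.e. zero in standardized
units), with the path integral approximated by Gauss–Legendre quadrature.
The attribution is repeated T times under Monte-Carlo dropout; for each
gene the dispersion across runs gives an uncertainty
`U_i = sd(IG_i) / |mean(IG_i)|`, which after `log(1+U)` and min–max
normalization discounts the final importance
`V_i = (1 − U'_i) · IG_i`. Genes are ranked by `|V|`.

Everything is validated offline against a synthetic-cohort generator with
planted prognostic genes, pathway-aligned co-expression modules, latent
patient clusters, exponential proportional-hazards event times, and
calibrated uniform censoring.

## Worked example

```r
library(pathsurvnet)

# simulate a cohort: 260 patients, 300 genes in 20 pathways,
# 12 planted prognostic genes, 60% censoring
spec <- synthetic_spec(n_samples = 260, n_genes = 300, n_pathways = 20,
                       pathway_size = 15, planted_genes = 12,
                       effect_size = 0.5, target_censoring = 0.6, seed = 42)
sim <- simulate_cohort(spec)
pathways <- simulate_pathways(spec)
sim$cohort
#> cohort_dataset: 260 samples x 300 genes, 102 events (60.8% censored)

mask <- build_pathway_mask(pathways, colnames(sim$cohort$expression))
mask
#> pathway_mask: 20 pathways x 300 genes, density 0.050, 0 gene(s) dropped

# hold out 60 patients for evaluation
set.seed(1)
idx <- sample(260)
train_set <- subset_cohort(sim$cohort, idx[1:200])
test_set  <- subset_cohort(sim$cohort, idx[201:260])

cfg <- network_config(n_hidden1 = 48, n_hidden2 = 24, n_embedding = 8,
                      learning_rate = 1e-3, max_epochs = 200,
                      dropout_rate = 0.1, weight_decay = 1e-3, seed = 42)
fit <- train(train_set, mask, cfg)
fit$model
#> survnet_model: 300 genes -> 20 pathways -> 48 -> 24 -> 8 embedding; k = 2

evaluate_model(fit$model, test_set)
#> evaluation_report: C-index 0.722, |log10(P)| 2.074, mean td-AUC 0.740 (groups 30/30)

att <- attribute_genes(fit$model, train_set,
                       attribution_config(n_quadrature = 16, n_mc_runs = 20,
                                          seed = 42))
print(att, n = 5)
#> attribution_result: 300 genes, 20 MC runs; top 5:
#>    gene    mean_IG          U       U_adj          V unstable_flag rank
#> 1 g0079 -0.3290374 0.09765439 0.001507019 -0.3285415         FALSE    1
#> 2 g0146 -0.3193594 0.09514579 0.001161019 -0.3189886         FALSE    2
#> 3 g0077  0.2818757 0.10731144 0.002831631  0.2810776         FALSE    3
#> 4 g0010  0.2377673 0.10710160 0.002802972  0.2371008         FALSE    4
#> 5 g0239  0.2332156 0.10301232 0.002243373  0.2326924         FALSE    5
```

The held-out C-index of 0.722 means 72% of comparable patient pairs are
risk-ordered correctly; `|log10(P)| = 2.07` says the median risk split
separates survival at p ≈ 0.009. In the ranking, `g0010` is one of the
planted prognostic genes; most other top hits are co-expressed members of
the pathways carrying the planted signal — with module-structured
expression, attribution mass spreads over a prognostic module rather than
singling out individual genes:

```r
prognostic_pw <- which(sapply(pathways$members,
                              function(m) any(m %in% sim$truth$planted_genes)))
in_prog <- sapply(head(att$table$gene, 12), function(g)
  any(sapply(pathways$members[prognostic_pw], function(m) g %in% m)))
sum(in_prog)
#> [1] 6
```

Six of the top twelve genes sit in the three signal-carrying pathways
(chance expectation: 1.8).

## Command line

A thin wrapper over the same functions
(`inst/scripts/pathsurvnet`):

```sh
pathsurvnet simulate  --config cfg.yaml --out data/
pathsurvnet train     --expr data/expression.tsv --surv data/survival.tsv \
                      --gmt data/pathways.gmt --config cfg.yaml \
                      --out model.ckpt --ablation none
pathsurvnet interpret --model model.ckpt --expr data/expression.tsv \
                      --config cfg.yaml --out importance.tsv
pathsurvnet evaluate  --model model.ckpt --expr data/expression.tsv \
                      --surv data/survival.tsv --out report.json
pathsurvnet pipeline  --config cfg.yaml --out run/   # all of the above
```

Or without installing the wrapper:
`Rscript -e 'pathsurvnet::cli_main()' pipeline --config cfg.yaml --out run/`.

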