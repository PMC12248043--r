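# grnvae

Joint inference of per-cell **transcription factor (TF) activities** and
**weighted gene regulatory networks (GRNs)** from single-cell RNA-seq,
using a variational autoencoder whose final decoder layer *is* the GRN.

## Who this is for

Single-cell analysts who want more than a per-regulon enrichment score:
a latent, probabilistic TF-activity embedding that respects a curated
TF→target prior while remaining free to discover new regulation, plus
cell-type-specific weighted networks for downstream comparison,
enrichment, and co-regulation analysis.

## The model

For a log-normalized expression vector $x$ of one cell:

$$\mu, \sigma = q_\phi(z \mid x), \qquad z = \mu + \sigma \odot \epsilon,
\qquad \epsilon \sim \mathcal N(0, I)$$

$$e_{\mathrm{dec}} = p_\theta(e_{TF} \mid z), \qquad
\hat e_{TF} = (1-\alpha)\, e_{TF}^{\mathrm{ULM}} + \alpha\, e_{\mathrm{dec}},
\qquad \hat x = W_{\mathrm{GRN}} \cdot \hat e_{TF}$$

- The encoder (1–3 ReLU layers) and decoder (1–2 ReLU layers plus a
  linear TF head) are ordinary MLPs; the **final linear map
  $W_{\mathrm{GRN}}$ (TF × gene) is the interpretable, trainable GRN**,
  initialized from a signed prior network (entries −1/0/+1).
- $e_{TF}^{\mathrm{ULM}}$ anchors the latent TF axes: per cell, each TF's
  activity is the slope *t*-statistic of regressing the cell's expression
  vector on the TF's signed prior target vector (the classic univariate
  linear model regulon scorer). The anchor weight follows the schedule
  $\alpha(t+1)=\min(\alpha_{\max}, \alpha(t)+\Delta\alpha)$, moving from
  prior-driven to data-driven inference.
- The prior is enforced early and relaxed late by a decreasing logistic
  mask $m(t) = 1/(1+\exp((t-T/2)/(T/20)))$ applied once per epoch:
  $W \leftarrow m(t) W_{\mathrm{prior}} + (1-m(t)) W$.
- Loss: $\mathcal L = \underbrace{\|x-\hat x\|^2 +
  \mathrm{KL}(q_\phi \,\|\, \mathcal N(0,I))}_{\text{ELBO penalties}} +
  \gamma \|W_{\mathrm{GRN}}\|_1$, with $\gamma$ ramped linearly over
  epochs; Adam, 85/15 train/validation split, plateau learning-rate
  decay, best-validation checkpointing.
- Phase three fine-tunes the model per cell type at reduced learning
  rate, yielding one weighted GRN and activity matrix per cell type.

Everything (forward pass, analytic backprop, Adam) is implemented in
plain R matrix algebra — no deep-learning runtime needed — and is exactly
reproducible under a seed.

## Worked example

Ground truth is known here because the data come from the package's own
generator: 1000 cells in 3 types, 15 TFs with 15 targets each, and a
prior with 20% of true edges dropped and as many false edges added.

```r
library(grnvae)

ds    <- simulate_dataset(sim_config(n_cells = 1000, n_genes = 150,
                                     n_tfs = 15, n_cell_types = 3,
                                     edges_per_tf = 15, seed = 7))
prior <- corrupt_prior(ds, drop_frac = 0.2, seed = 8)

fl <- filter_dataset(ds$expr, prior)   # standard gene/cell/TF filters
ln <- lognormalize(fl$expr)

tm <- fit(ln, fl$prior,
          model_cfg = model_config(latent_dim = 16,
                                   encoder_widths = c(128, 64),
                                   decoder_widths = 64,
                                   epochs = 100, seed = 7),
          train_cfg = train_config(max_epochs = 100, seed = 7))
acts <- infer_activities(tm, ln)

ev <- evaluate_grn(tm$grn, gold_edges(ds))
labs <- ds$labels[match(acts$cell_ids, ds$expr$cell_ids)]
evaluate_clustering(acts, labs, resolutions = c(0.2, 0.6, 1))
head(differential_tf_activity(acts, labs), 3)
```

Output (as printed by this code):

```
edge recovery  AUROC 0.928 (prior 0.912)  AUPRC 0.799 (chance 0.118)

  resolution n_clusters       ari       nmi  macro_f1       auc
1        0.2          3 0.9790917 0.9604227 0.9929990 0.9955030
2        0.6          5 0.7538678 0.8118335 0.9929974 0.9972169
3        1.0          9 0.4435560 0.6632768 0.9939985 0.9981766

    tf cell_type      lfc mean_diff             p         p_adj
1 TF07     type1 1.433525 0.9735679 7.896337e-145 7.605743e-144
2 TF10     type1 1.396282 0.7586356 1.014099e-144 7.605743e-144
3 TF01     type1 1.230777 0.8165497 2.396014e-141 1.198007e-140
```

Reading it: ranking learned |W| recovers the true edges at AUROC 0.93 —
*better than the corrupted prior itself scores* (0.912), i.e. training
both prunes false prior edges and rediscovers dropped ones. At Leiden
resolution 0.2 the TF embedding clusters reproduce the three simulated
cell types almost exactly (ARI 0.98), and the top differentially active
TFs in `type1` are exactly its simulated signature TFs, with positive
log2 fold changes.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "grnvae", package = "grnvae"))')
$CLI simulate   --out sim --cells 1000 --genes 150 --tfs 15 --seed 7
$CLI preprocess --expr sim --prior sim/true_grn.tsv --out pre
$CLI train      --expr pre --prior pre/prior_filtered.tsv --out model.rds
$CLI activities --model model.rds --expr pre --out acts.csv
$CLI grn        --model model.rds --out grn.tsv
```

Subcommands also cover ULM scoring, fine-tuning, differential activity,
gene-set enrichment, and the benchmark battery (`bench-grn`,
`bench-cluster`, `bench-dropout`, `bench-subsets`, `bench-knockdown`);
see `?grnvae_cli`.

## Scope notes

The package ships its own ground-truth generator rather than external
benchmark datasets; real-data workflows (TFLink-style priors, Perturb-seq
groups, GMT gene sets) are supported through the standard file formats
shown above. See `vignettes/methods.Rmd` for modeling assumptions,
parameter guidance, and known limitations.
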