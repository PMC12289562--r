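# emrfuse

Multimodal fusion of structured EMR data and clinical text for diagnosis,
with a seeded synthetic-cohort generator so the whole pipeline is testable
without access to any clinical data.

## The problem

Spirometry is the reference standard for diagnosing chronic obstructive
pulmonary disease (COPD), but it is frequently unavailable in primary-care
and resource-constrained settings, and some patients cannot perform the
maneuver. Routine electronic medical records, however, already contain two
complementary kinds of evidence: structured fields (demographics, a fever
indicator, C-reactive protein, blood-gas and hematology panels) and free-text
units (the pulmonary CT report and the medical-history narrative). `emrfuse`
implements a diagnosis classifier that fuses the two modalities, for
methodologists who want a fully reproducible, dependency-light reference
implementation of this family of models in R.

## The model

Let a patient contribute categorical fields with cardinalities `c_i`,
standardized continuous values `x_j`, and a token sequence `T`.

* **Offset categorical embedding.** One shared table `E` with `sum(c_i + 1)`
  rows (one reserved unknown slot per field). Field `i`, category `x_i` maps
  to row `x_i + phi_i` with the prefix-sum offset
  `phi_i = sum_{j<i} (c_j + 1)`, so distinct (field, category) pairs never
  collide.
* **Parametric numerical embedding.** `x_j -> w_j * x_j + b_j` with learnable
  `w_j, b_j` of the fusion width `d`.
* **Text encoder.** A frozen backbone maps `T` to hidden states
  `H in R^{l x d_bert}`; a trainable projection
  `LayerNorm(GELU(W_p H + b_p))` aligns them to width `d`. The packaged
  backbone is a seeded, randomly initialized single-block transformer
  (`d_bert = 32`), the deterministic test stand-in for a pretrained
  bidirectional encoder.
* **Gated cross-attention (GCA).** Queries from the normalized structured
  tokens, keys/values from the normalized text tokens,
  `Softmax(Q K' / sqrt(d_k)) V`, gated elementwise by
  `sigmoid(W_g [X ; pool(H)])`.
* **Residual fusion block.** `X_out = X + FFN(LN(X)) + lambda * GCA(X, H)`
  with a learnable scalar fusion coefficient `lambda` per block; a residual
  self-attention sublayer over the structured tokens lets the prepended
  classification token aggregate the tabular evidence.
* **Contrastive alignment.** Both pooled vectors pass through one shared
  projection head into `Z`; a symmetric InfoNCE loss with cosine similarity
  and learnable temperature `tau` pulls matched structured/text pairs
  together. Total objective:
  `L = alpha * L_task + beta * L_cont + gamma * L_reg`.

Everything trains on a small reverse-mode autodiff engine built into the
package (gradient-checked against finite differences in the test suite) — no
external deep-learning runtime.

## Worked example

```r
library(emrfuse)

# a synthetic cohort with a strong planted cross-modal signal
cohort <- generate_cohort(strong_signal_config(n_patients = 400, seed = 7))
cohort
#> <emr_cohort> 400 patients, 11 structured fields, 2 text units

summary <- cohort_summary(cohort)
c(summary$n, summary$n_female, summary$n_male)
#> [1] 400 180 220

# what any model could at best achieve on this cohort
latent_oracle(cohort)$expected_accuracy
#> [1] 0.9475156

# 2-fold cross-validated training of the fusion model (small test settings)
mcfg <- model_config(d = 32, d_bert = 32, d_z = 16, ffn_mult = 2, l_max = 48,
                     beta = 1, gamma = 1e-4, max_epochs = 15, patience = 4)
res <- cross_validate(cohort, mcfg, K = 2, seed = 7)
subset(res$report, fold == "mean")
#>   variant fold accuracy precision   recall specificity        f1
#> 3    full mean   0.7975 0.8471019 0.766055   0.8351648 0.8044135
```

The report carries one row per fold plus two averaged rows: `mean` is the
mean over folds (the headline convention) and `pooled` recomputes every
metric from the pooled confusion counts; the two differ slightly by design
and both are reported. The 0.7975 here is a deliberately tiny training run
(400 patients, 15 epochs); the acceptance suite trains the same model at
n = 1400 and reaches beyond 0.92 of the Bayes oracle's 0.94 bound.
`single_modality_baselines()` and `run_ablation()` quantify how much comes
from each modality and each architectural component.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "emrfuse", package = "emrfuse"))')
Rscript "$CLI" simulate --config config.json --seed 1 --out out/
Rscript "$CLI" train    --config config.json --seed 1 --out out/ --cohort out/cohort.csv
Rscript "$CLI" ablate   --config config.json --seed 1 --out out/ --cohort out/cohort.csv
```

`config.json` holds `generator`, `model`, `training` and `ablation` sections;
every omitted entry falls back to the documented defaults.

## Package layout

* `R/autodiff.R` — tape-based reverse-mode autodiff on dense matrices.
* `R/schema.R` — cohort schema, validation, winsorization, clinically-aware
  imputation (afebrile CRP baseline 3.5 mg/L), z-scoring, one-hot encoding.
* `R/synthetic.R` — seeded synthetic cohort generator with plantable
  structured, text and interaction label signals; Bayes oracle.
* `R/encoders.R` — categorical/numerical embedders, tiny text backbone,
  projection layer.
* `R/fusion.R` — gated cross-attention, fusion blocks, forward pass.
* `R/objectives.R` — shared projection head, symmetric InfoNCE, joint loss.
* `R/train.R` — stratified K-fold harness, Adam training with early
  stopping, baselines and ablations.
* `vignettes/methods.Rmd` — the model, its assumptions, and every design
  decision with its rationale.
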