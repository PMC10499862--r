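# bflex

Sequence-based prediction of protein Cα B factors with an
encoder → bidirectional LSTM → decoder regressor, plus the
interpretability analyses that ask *how far* — along the chain and through
Euclidean space — the information shaping a residue's flexibility reaches.

## Who this is for

Structural bioinformaticians and protein biophysicists who want (a) a
self-contained, CPU-scale implementation of per-residue B-factor
regression from sequence-level features, (b) the companion analyses for
probing a trained model (window-size sweeps, cutoff-radius masking,
per-atom marginal contributions, the normalized neighbor-count
statistic), and (c) a synthetic Cα-chain generator with a *known*
packing → flexibility law, so the whole pipeline is testable without
downloading a single structure.

## The model

Deposited B factors are not comparable across structures, so everything
is per-protein Z-scored (population SD, divisor N):

    B̂ᵢ = (Bᵢ − μ_B) / σ_B        and per axis   X̂ᵢ = (Xᵢ − μ_X) / σ_X

Each residue becomes a 28-slot vector — 21 amino-acid one-hot slots
(canonical 20 + a catch-all), 3 secondary-structure slots (sheet, helix,
coil), 3 Z-scored coordinates, and a chain start/end flag — and the
regressor maps the N×28 matrix to N predictions:

    Eᵢ = f_enc(Iᵢ),   L = f_lstm(E),   B̂ᵖᵢ = f_dec(Lᵢ)

trained on the per-protein mean squared error
MSE = Σᵢ (B̂ᵖᵢ − B̂ᵉᵢ)² / N. The bidirectional recurrence lets residue i
draw on every other residue in both directions; disabling it
(`use_lstm = FALSE`) yields the feedforward ablation that sees each
residue in isolation. Accuracy is the Pearson correlation (PCC) between
predicted and actual profiles, averaged unweighted over proteins.

Input structures are curated with four filters: any Cα B factor > 80 Å²,
any B factor ≤ 0, an all-constant B profile, or length > 500 residues
rejects the protein (all violated rules are reported). Secondary
structure is assigned from Cα geometry alone (P-SEA-style distance
windows), so the pipeline works identically on deposited and synthetic
traces.

## Worked example

Train on synthetic chains whose B factors follow a known caging law
(contact count within r\* = 8 Å, Z-scored, negated, plus noise), then ask
the trained model which cutoff radius it has learned:

```r
library(bflex)

cfg <- synthetic_config()                      # 60-160 residues, r* = 8 A
ds  <- generate_dataset(cfg, 240, seed = 5)
enc <- encode_dataset(ds$records)              # N x 28 features + Z-scored targets
ids <- vapply(enc, `[[`, character(1), "protein_id")
sp  <- split_dataset(ids, c(0.84, 0.08, 0.08), seed = 2)
pick <- function(e, s) e[ids %in% s]

fit <- train_model(model_config(),
                   train_config(max_epochs = 80, batch_size = 16,
                                early_stop_patience = 15),
                   pick(enc, sp$train), pick(enc, sp$validation))
evaluate_dataset(fit$model, pick(enc, sp$test))$average_pcc
#> [1] 0.8041156

ws_grid <- seq(0, 40, 4)
sweeps  <- lapply(pick(enc, sp$test),
                  function(e) window_sweep(fit$model, e, ws_grid))
pccn_vs_rcut(sweeps, pick(ds$records, sp$test),
             rcut_grid = seq(4, 20, 2), ws_grid = ws_grid)$peak_rcut
#> [1] 10
```

The held-out average PCC of **0.80** says the model recovers most of the
synthetic flexibility signal (the noise ceiling is ≈0.96); the
curve-correlation peak at **10 Å** is the model's own estimate of the
radius of influence, landing next to the generative 8 Å. Retraining the
PS-only feedforward ablation the same way scores 0.46 — sequence identity
alone, without recurrence, is the weakest configuration, matching the
qualitative ablation ordering. See `vignettes/bfactor-prediction.Rmd` for
the full methods account.

A command-line interface wraps the same functions
(`inst/cli/bflex.R`): `simulate`, `curate`, `encode`, `train`, `predict`,
`evaluate`, `analyze-window`, `analyze-rcut`, `summarize-groups`, each
echoing its fully resolved configuration before any work.

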