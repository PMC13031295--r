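# solvachrom

Solvent-aware 3D neural models for chromophore optical properties in R.

## The problem

The absorption maximum λ_abs, emission maximum λ_ems and photoluminescence
quantum yield (PLQY) of a dye depend on both its 3D conformation and its
solvent environment. Quantum-chemical prediction (TD-DFT) is accurate enough
to be useful but costs CPU-hours per molecule; 2D graph neural networks are
fast but blind to the geometric effects (torsional twists, bond-length
alternation, solvent-equilibrated relaxation) that control excited states.
`solvachrom` is for computational chemists and method developers who want a
fully inspectable, desk-scale implementation of the solvent-aware 3D
modelling recipe:

* a **directed edge-message-passing encoder (D-MPNN)** embeds the solvent
  from its 2D graph, pretrained inside a dual-encoder 2D baseline
  (chromophore MPNN ⊕ solvent MPNN → regression head);
* an **SE(3)-invariant global-attention backbone** encodes the chromophore
  conformer: per-pair distances expanded in a Gaussian radial basis
  `G_ijk = exp(−(d_ij − μ_k)² / 2σ²)` enter the attention scores as learned
  biases together with graph features (shortest-path buckets), and a
  coordinate-free **virtual node** carries the molecule-level representation;
* an **equivariant coordinate head** predicts a displacement
  `Δr_i = Σ_j c_ij (r_i − r_j)/d_ij` with invariant scalar weights `c_ij`,
  so refined geometries transform covariantly by construction;
* solvent **fusion** happens either by projecting the solvent embedding onto
  the atom-feature width and summing it into the virtual node before the
  first attention block (`VIRTUAL_NODE`), or by concatenation at the
  regression head (`HEAD_CONCAT`); `NONE` is the solvent-blind ablation;
* training minimises a **joint objective** on conformation pairs
  `L = w_prop · maskedL1(ŷ, y) + w_coord · meanKabschDist(r̂, r_ref)`,
  where a low-cost input geometry (force-field or semi-empirical level) is
  refined toward the high-accuracy reference and masked slots of the target
  vector (λ_abs, λ_ems, log₁₀ PLQY) contribute no gradient;
* evaluation uses **Bemis-Murcko scaffold splits** (80/10/10 and k-fold
  cross-validation) grouped at the chromophore level, so no framework leaks
  between training and test.

Everything — forward passes, backpropagation, Adam, the two-phase schedule
(head-only with frozen encoders, then a joint finetune) — is implemented in
the package (R with an RcppArmadillo core for the attention backbone), with
a pure-R reference implementation cross-checked in the test suite.

Because real measured datasets and the quantum-chemistry pipeline that
produces multi-fidelity conformers are outside the package's scope, it ships
a first-class **synthetic data generator**: donor/acceptor-substituted
diaryl polyenes with idealized geometries, a closed-form solvatochromic
ground truth, a geometry-fidelity noise ladder (`RDKIT`, `XTB`, `DFT_VAC`,
`DFT_IMP`), solvent-equilibrated reference geometries and configurable
missing-label patterns. See the methods vignette
(`vignettes/solvent-aware-3d-models.Rmd`) for the model, assumptions and
design decisions.

## Worked example

```r
library(solvachrom)

## a seeded synthetic benchmark: 40 chromophores x 9 solvents
fix <- make_fixture_dataset(fixture_spec(n_chromophores = 40, seed = 11))
fix$dataset
#> <sc_dataset> 360 records, 40 chromophores, 9 solvents
#>   observed: lambda_abs 343, lambda_ems 232, log_plqy 172

## curation (topology checks, duplicates, conflicting labels)
curate(fix$dataset)$report
#> <curation report> inspected 360, removed 0, retained 360

## fit a solvent-aware model: scaffold split, solvent-encoder pretraining,
## two-phase training, held-out evaluation
fit <- solvachrom(fix$dataset,
                  config = model_config(
                    fusion = "VIRTUAL_NODE",
                    backbone = backbone_config(width = 64, layers = 2,
                                               heads = 8, K = 32),
                    solvent_width = 32, solvent_depth = 2,
                    pair = pair_training_config("XTB", "DFT_IMP")),
                  schedule = train_schedule(phase1_epochs = 15,
                                            phase2_epochs = 8, seed = 3),
                  pretrain_epochs = 8, seed = 3)
print(fit)
#> Solvent-aware chromophore property model
#>   fusion: VIRTUAL_NODE; input fidelity: XTB; targets: lambda_abs
#>   records: TEST 36, TRAIN 288, VAL 36
#>   held-out test metrics:
#>     lambda_abs MAE 16.45  RMSE 17.84  R2 0.615  (n = 35)
```

The held-out MAE is in nm on scaffolds never seen in training; at this toy
size (288 training records, 23 epochs) the model has learned the main
conjugation-length and solvent trends but not converged — the acceptance
script below runs the full-size benchmark (2000 pairs), where the same
architecture reaches a single-digit MAE and beats the solvent-blind
ablation by a wide margin. `summary(fit)`, `plot(fit)`, `predict(fit,
newdata)`, `coef(fit)` and `residuals(fit)` behave as for other R model
objects.

A thin command-line interface wraps the same functions
(`inst/cli/solvachrom`): subcommands `make-fixtures`, `curate`, `split`,
`pretrain-solvent`, `train`, `evaluate`, `crossval`, `benchmark-grid`.

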