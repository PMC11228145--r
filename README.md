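# glucotab

Group-informed attentive tabular modelling of blood-glucose progression.

Routine physical-examination tables hold 37 laboratory indicators
organised in six clinical panels — liver function (B1–B8), kidney function
(C1–C3), lipid profile (D1–D4), hepatitis-B markers (E1–E5), complete
blood count (F1–F12) and white-cell differential (G1–G5) — plus age and
gender.  `glucotab` predicts fasting blood glucose y from such tables for
biostatisticians and clinical-ML practitioners who need three things at
once: imputation that respects whole-panel missingness, predictions robust
to small indicator fluctuations, and panel-level interpretability.

The pipeline:

1. **Cluster-informed stepwise imputation** — DBSCAN on the 19
   near-complete attributes (A, F, G); per-patient cluster-mean auxiliary
   features for the 20 skippable-panel attributes (m = 20); then
   gradient-boosted regressors fill B1, …, E5 one column at a time, each
   completed column feeding the next model.
2. **Dual-layer augmentation** — every training patient gets two copies
   with n = 10 random indicators shifted by Δ_f drawn uniformly from
   (−ε_f, ε_f), ε_f = column mean ⁄ 20; and an all-feature clustering
   appends 12 group-mean columns for the liver-function and lipid panels.
3. **A group-masked attentive network** — at each decision step i an
   attentive transformer produces sparse unit attention
   q[i] = sparsemax(P[i−1] ⊙ scores), the prior
   P[i] = Π_{j≤i}(γ·1 − q[j]) discourages re-selecting attended units,
   and the feature mask M[i] = q[i]·G gives every indicator of one panel
   the same attention value.  GLU feature transformers with ghost batch
   norm process the masked input; rectified decision outputs sum into the
   prediction; per-step masks and the step-strength-weighted aggregate
   M_agg expose feature importance.  Fitting minimises
   MSE + λ_sparse · Σ(−q log q) with Adam and peak-validation selection.

Evaluation reports MAE = (1/n)Σ|y−ŷ|, MSE = (1/n)Σ(y−ŷ)², RMSE = √MSE, a
four-way ablation (−Imp, −AugS, −AugF, −GM) and a robustness protocol
that perturbs 10 random continuous test features and reports metric
deltas.

A synthetic-cohort generator (latent patient clusters, grouped-panel
missingness, target driven by the B and D panels) makes every stage
testable without any external download.

## Worked example

```r
library(glucotab)

sim <- simulate_table(simulation_config(n_patients = 3000, seed = 1))
sim$table
#> <clinical_table> 3000 patients x 39 attributes; 20424 missing cells; target attached

res <- run_pipeline(sim$table,
                    pipeline_config(tabnet = tabnet_config(max_epochs = 40,
                                                           patience = 12),
                                    seed = 1))
res$metrics
#> MSE 14.1882  MAE 3.0423  RMSE 3.7667  (n = 300)

# variance of the test target is ~41, so the model explains ~2/3 of it
# under the desk-scale training budget

ui <- res$importance$unit_importance
round(sort(ui, decreasing = TRUE)[1:4], 3)
#>     B     D D_grp    E3
#> 0.788 0.174 0.018 0.006
```

The importance mass sits on the liver-function (B) and lipid (D) units —
exactly the panels the synthetic target is driven by.

A thin command-line wrapper covers the same stages:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "glucotab.R", package = "glucotab"))')" \
    simulate --n 2000 --seed 1 --out cohort.csv
Rscript .../glucotab.R impute --in cohort.csv --out completed.csv
Rscript .../glucotab.R train --in cohort.csv --epochs 40 --out-dir run/
Rscript .../glucotab.R ablation --in cohort.csv --epochs 40 --out-dir ablation/
```

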