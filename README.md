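# srnet — survival recurrent networks for discrete-time survival prediction

`srnet` is an R implementation of a *survival recurrent network* (SRN): a
discrete-time survival model in which an LSTM-based network is retrained
sequentially at yearly time points, receives each patient's constant
clinical features plus two time-dependent "life value" features (the phase
and the prior survival probability), and handles censored patients through
fractional rank-score targets instead of discarding them. Once trained, the
network takes only the first-visit data and rolls its own predictions
forward, year by year, to a 5-year survival trajectory.

The package is aimed at biostatisticians and methods researchers who want a
fully inspectable, dependency-light reference implementation of this model
family, together with the complete study machinery around it:

* a **synthetic multi-cohort gastric-cancer generator** with a known
  discrete-time logistic hazard (planted prognostic effects, a planted
  temporal ramp, planted subtype-by-treatment interactions), so every
  component can be validated against ground truth;
* the **preprocessing pipeline**: one-hot encoding, standard scaling,
  ×10³ integer quantization, k-nearest-neighbour imputation fitted on
  training rows only;
* the **evaluation suite**: time-dependent ROC/AUC, concordance index,
  Kaplan–Meier calibration with Greenwood intervals, decision-curve net
  benefit, Mann–Whitney comparison of AUC distributions;
* the **counterfactual treatment recommender**: apply every adjuvant
  option to every patient, stratify into five prognosis subgroups, and
  mine the clinical factors associated with each response pattern.

## The model in brief

For yearly intervals t = 1..5, the network outputs a conditional survival
probability f_t(X) = σ(W_t·X_t); cumulative survival is S(t) = ∏ f_k.
Patients dying in year t contribute targets (1, …, 1, 0); patients censored
at month m of year t contribute the rank score **R = (r + 0.5)/(K + 1)**,
where K is the number of that year's deaths cohort-wide and r the number at
months ≤ m, so 0 < R < 1 always. Between years the prior survival feature
is updated by the residual rule

    S[t+1] = S[t] + α · (Y − Ŷ)(1 − Ŷ)Ŷ,

at inference replaced by the model's own f_t (no outcome exists at
prediction time). The architecture: 49 input nodes (47 encoded clinical
features + 2 life values), a learned 47×32 scaled-embedding block, two
LSTM layers whose recurrence runs over the yearly phases, two dense ReLU
layers, softmax output; Gaussian dropout in training, deterministic
inference. Training is minibatch Adam with gradient clipping, up to 7
epochs per phase with validation-loss epoch selection.

Everything is base R + the `survival`, `jsonlite` and `yaml` packages; the
network, backpropagation-through-time and optimizer are part of the
package source.

## Worked example

```r
library(srnet)

spec   <- gastric_cohort_spec(seed = 1)        # 1,186 patients, 3 cohorts
cohort <- generate_cohort(spec)

split  <- split_cohort(cohort, 0.8, seed = 1, stratify = "cohort")
nrow(split$train); nrow(split$test)
#> [1] 950
#> [1] 236

enc  <- encode_features(split$train, schema = spec$schema)
encv <- encode_features(split$test, encoder = enc$encoder)
# a few lab values are missing: impute with training-row donors only
x_tr <- round(knn_impute(enc$x))
x_te <- round(knn_impute(encv$x, reference = x_tr))

model <- init_srn(srn_config(seed = 7))
model
#> <srn_model> input 49 nodes (47 features + 2 life values); embedding 47x32;
#> LSTM 64 -> LSTM 32 -> dense 16 -> dense 8 -> softmax 2; untrained

model <- train_sequential(
  model,
  srn_data(x_tr, split$train$survival_months, split$train$event),
  srn_data(x_te, split$test$survival_months,  split$test$event))
round(model$val_auc, 3)
#> year1 year2 year3 year4 year5
#> 0.565 0.719 0.758 0.788 0.815
```

The validation AUC rises across the years: in the synthetic cohorts (as in
the clinical setting they emulate) first-year mortality is the least
tumour-determined, while recurrent disease and adverse pathology kill
mostly in years 2–5, so discrimination improves as the horizon extends.

Counterfactual treatment query for one cohort:

```r
model$encoder <- enc$encoder
grid <- counterfactual_predict(model, cohort)   # "other" arm < 5%, dropped
grid
#> <srn_cf_grid> 1186 patients x 3 options (XP, XP+RT+XP, FU/LV/RT)
table(assign_subgroups(grid))
#>   I  II III  IV   V
#> 372 146 333  20 315
```

`assign_subgroups()` labels each patient I–V (good under every option,
chemotherapy-responsive variants, poor under every option), and
`factor_association()` reports which clinical factors — microsatellite
instability and papillary histology, in the planted design — distinguish
the XP-favorable patients.

## Documentation

The methods vignette (`vignettes/srn-methods.Rmd`) documents the model and
its assumptions, the synthetic study design and every planted effect, the
numerical choices, and the known limitations — in particular the
train/inference asymmetry of the life-value feedback and what it does to
calibration in the highest-risk deciles.
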