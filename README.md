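# adrnet

Antidepressant treatment response prediction from longitudinal clinical
cohorts.

Treating major depressive disorder is slow feedback control: an
antidepressant — often a combination of two — is prescribed, and its effect
on the patient's Hamilton Depression Rating score (HAM-D 17) only shows
weeks later. `adrnet` is for methods researchers and biostatisticians who
want a complete, testable implementation of a neural treatment-response
model and the pipeline around it: given a patient's tabular covariates
(demographic, neuroimaging, genetic-variant and DNA-methylation blocks),
their current HAM-D score, the prescribed drug set and the time to the next
visit, the model predicts the next-visit HAM-D score. From that one-step
predictor the package derives remission classification, exhaustive
prescription ranking, and patient-similarity retrieval.

## The model

One example is a pair of consecutive visits. The patient branch embeds

    X_P = [V_demo; V_bio; V_gene; V_methyl; H; dT]        (length 189 by default)

through a single nonlinear layer, `V_P = relu(X_P W_P + b_P)`, giving a
d-dimensional patient representation. Each antidepressant owns a row of an
embedding matrix `E_A`; a prescription is represented additively as the sum
of its drugs' rows, `V_A`. A linear head predicts

    Yhat = [V_P; V_A] . W + b,

trained by minibatch Adam on mean squared error with dropout on `V_P` and
an L2 penalty on the weight matrices. Additivity of `V_A` is what lets a
model trained on observed prescriptions score all `n + n(n-1)/2` candidate
regimens (105 for 14 drugs).

Around the model: random-donor imputation of missing covariates, a
missingness filter (drop features absent in >30% of patients), a nested
5-subset / 10-fold cross-validated elastic-net protocol that keeps the 10
most-positive and 10 most-negative averaged coefficients per covariate
block, two evaluation tasks (one-step regression; remission classification
via an autoregressive rollout of the predictor along each patient's visit
sequence), a generic-regressor baseline harness, and a seeded synthetic
cohort generator so everything runs without protected clinical data.

## Worked example

```r
library(adrnet)

sim      <- generate_cohort(sim_config(n_patients = 121, seed = 1))
feats    <- impute_missing(sim$features, seed = 1)
examples <- build_pairs(sim$visits)                  # 363 one-step examples
split    <- split_dataset(examples, test_fraction = 0.1, seed = 1)

fit <- adrnet(split$train, feats, sim$vocabulary, seed = 1)
fit
#> Antidepressant-response prediction network
#>   patient layer: 189 -> 32 (relu), drug embedding: 14 x 8
#>   trained 300 epochs on 327 examples; final training MSE 3.3737

evaluate_model(fit, split$test, feats, visits = sim$visits)
#> Task 1 (one-step regression, n=36): RMSE 1.3864, R-squared 0.9601
#> Task 2 (remission rollout, n=121): sens 0.8000 spec 0.9906 prec 0.9231 F1 0.8571 acc 0.9669
```

Task 1 says held-out next-visit scores are predicted to within ~1.4 HAM-D
points, explaining 96% of their variance on this synthetic cohort. Task 2
chains the predictor along each patient's own visit sequence and applies
the half-score remission rule to the final predicted score; the confusion
metrics compare those rolled-out labels with the observed ones.

Ranking all 105 candidate prescriptions for one held-out patient at a
4-week horizon:

```r
rank_prescriptions(fit, feats, patient_id = split$test$patient_id[1],
                   hamd_now = 22, interval = 4)[1:5, ]
#>              prescription predicted_hamd rank
#> 1 CITALOPRAM;ESCITALOPRAM          18.14    1
#> 2   CITALOPRAM;PAROXETINE          18.17    2
#> 3    BUPROPION;CITALOPRAM          18.33    3
#> 4 ESCITALOPRAM;PAROXETINE          18.47    4
#> 5  CITALOPRAM;MIRTAZAPINE          18.57    5
```

Rank 1 is the candidate with the lowest predicted next-visit score. (These
are synthetic-cohort numbers; the drug effects are planted by the
simulator, not clinical findings.)

`run_pipeline()` wires simulate → select → train → evaluate → rank into one
call and writes every artifact plus a manifest (seed, config hash) to a run
directory; `inst/cli/adrnet.R` exposes the same stages as shell
subcommands. The methods vignette
(`vignettes/antidepressant-response.Rmd`) documents the model, the
selection protocol, the generator's assumptions and the numerical choices.

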