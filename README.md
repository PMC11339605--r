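# grouprisk

Group-level disease-rate estimation from genetic and non-genetic risk
scores, for biostatisticians and genetic epidemiologists who need the
*case rate of a group* (a recruitment centre, a region, a prospective
cohort) rather than the risk of a named individual.

## The problem and the model

Averaging individual logistic-regression predictions within a group is
the obvious group-rate estimator, and it can fail badly even when the
individual-level model discriminates well. Selection into the analyzed
sample (participation, survival, ascertainment) that varies between
groups can reverse the sign of an association between the individual
level and the level of group means — Simpson's paradox. A genuinely
high-risk group whose high-liability members were preferentially lost
shows a *low* mean polygenic risk score (PRS), and the averaged
predictions rank the groups backwards.

The package's core is the Mundlak (within-between) logistic regression

```
logit(p_gn) = β₀ + Σⱼ βⱼ (x_gnj − x̄_gj) + Σⱼ γⱼ x̄_gj ,
```

which adds each covariate's group mean as a predictor: `β` carries the
within-group effect, `γ` the between-group effect, and the group-mean
columns act as proxies for unobserved group-level structure. Because the
group means are computed from covariates alone, a fitted model can
predict the case rate of a *new* group with no observed outcomes —
unlike a random-intercept model. Around this sit: a synthetic cohort
generator with liability-threshold disease (`D = 1{L > T}`,
`T = Φ⁻¹(1−K)`), group structure and liability-dependent participation
bias; Monte Carlo permutation tests with Benjamini–Hochberg FDR control;
liability-threshold case probabilities
`1 − Φ((T − prs)/√(1−V))`; an individual- versus group-level correlation
scan; leave-one-group-out cross-validation (LOCOCV); Wilson score
intervals computed as a fixed point; and DeLong-variance AUC intervals.

## Worked example

Build a synthetic cohort at a 3.21% incidence rate, rebuild its group
labels from a hidden variable that weights PRS *negatively* and the
non-genetic score positively (the regime that creates Simpson's
paradox), and compare group-rate prediction for a PRS-only GLM versus a
PRS-only Mundlak GLM:

```r
library(grouprisk)

coh <- generate_base_cohort(
  cohort_config(n_groups = 21, group_sizes = 2000, prevalence = 0.0321,
                seed = 7)
)
mean(coh$outcome)
#> [1] 0.0316

ex <- run_structured_permutation_experiment(coh, alpha1 = -0.5,
                                            alpha2 = 0.5, seed = 7)
ex
#> Structured-permutation experiment (alpha1 = -0.5, alpha2 = 0.5, 21 groups, n = 42000)
#> LOCOCV correlation, GLM:      -0.9285
#> LOCOCV correlation, Mundlak:  0.9241
```

The GLM's out-of-sample group-rate predictions are strongly
*anti*-correlated with the observed rates — it predicts low rates for
the highest-rate groups — while the Mundlak model, using the identical
single covariate, recovers the ranking (correlation 0.92). The per-group
table shows why:

```r
head(ex$rates, 4)
#>   group    n observed_rate glm_predicted_rate mundlak_predicted_rate
#> 1     1 2000        0.0130             0.0497                 0.0163
#> 2     2 2000        0.0205             0.0428                 0.0188
#> 3     3 2000        0.0200             0.0407                 0.0206
#> 4     4 2000        0.0250             0.0381                 0.0221
```

Group 1 has the *highest* mean PRS but the *lowest* case rate, so the
GLM over-predicts it; the Mundlak fit resolves this with
opposite-signed within and between coefficients:

```r
grouped <- assign_quantile_groups(
  coh, structured_permutation_config(-0.5, 0.5, 21, seed = 7)
)
fit_mundlak(grouped, "prs")
#> Logistic fit (42000 observations, logLik -5546.21, converged in 7 iterations)
#>             estimate     se
#> (Intercept)  -3.6779 0.0342
#> prs_within    0.7363 0.0315
#> prs_between  -0.7975 0.0713
```

Within a group, one PRS standard deviation raises the log-odds of
disease by 0.74; *between* groups, a higher mean PRS marks a
lower-risk group (γ = −0.80) — the sign reversal, estimated rather
than hidden.

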