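# dyadstress

Dyadic state-space modelling of subjective stress and hair cortisol.

## What this package is for

Subjective stress questionnaires and physiological stress markers rarely
correlate cross-sectionally, partly because of method variance and partly
because hair cortisol concentration (HCC) is a *retrospective* marker: a
3-cm hair segment integrates cortisol secreted over the preceding ~3
months. `dyadstress` implements, for ambulatory couple studies, the full
analysis chain that makes this temporal structure visible:

* **Scoring** of a 30-item weekly hassle scale (WHS: number of hassles
  `WHS_n`, mean occurrence `WHS_occur`, mean stressfulness `WHS_intens`),
  the 10-item Perceived Stress Scale (PSS, sum 0–40 with reverse-coded
  items) and the 12-item TICS chronic-stress screening scale (sum 0–48),
  each available as self-report and vicarious partner-report, plus hair
  cortisol preprocessing (triplicates per 1-cm segment, replicate CVs,
  raw-scale segment averaging, natural log).
* **Psychometrics**: McDonald's omega from a one-factor minimum-residual
  fit, occasion-pair retest correlations pooled per time lag by
  random-effects meta-analysis on the Fisher-z scale, and the correlation
  matrix of time-averaged measures with HCC.
* **A Bayesian dyadic state-space (dynamic factor) model**: per informant
  perspective, latent stress follows a random walk with individual drift,

      S[i,p,t] = S[i,p,t-1] + delta[i,p] + xi[i,p,t]
      Q[i,j,p,t] = lambda[j,p] * S[i,p,t] + eps[i,j,p,t]

  with the self/partner innovation pairs coupled through a 2x2 covariance
  (correlation `r_xi`, transient agreement) and the drift pairs through a
  hierarchical bivariate normal (correlation `r_delta`, agreement about
  trends). Mixed sampling frequencies (weekly WHS, monthly PSS, one TICS)
  enter as scheduled likelihood contributions. Fitting is by a blocked
  Gibbs sampler written for this model (drifts drawn from their
  state-marginal posterior, states by FFBS, partially collapsed Metropolis
  moves for the variance components), with JAGS available as an
  alternative backend and split-chain Gelman-Rubin diagnostics throughout.
* **A lag scan**: standardized log-HCC is sequentially regressed on the
  latent state at each week within every posterior draw, yielding the
  profile of coefficients `alpha_t` and implied correlations `r_t` whose
  peak locates the delay at which subjective stress best predicts HCC.
* **A synthetic-data generator** reproducing the whole study design (37
  couples, 12 weeks, both informants, ordinal items, triplicate assays)
  with known ground truth, so every stage is testable end to end.

## Worked example

```r
library(dyadstress)

params <- true_parameters(seed = 42)      # 37 couples, 12 weeks, known truth
study  <- simulate_study(params)
scores <- score_panel(study$panel)
hcc    <- preprocess_hcc(study$hair)

spec <- state_space_spec(n_iter = 4000)   # quick run; default is 20,000
std  <- standardize_measures(scores, c("WHS_occur", "PSS", "TICS"))
fit  <- fit_state_space(std, spec, seed = 3)

standardized_loadings(fit)[, 1:5]
#>   instrument informant loading loading_median lower
#> 1  WHS_occur      self   0.884          0.884 0.850
#> 2  WHS_occur   partner   0.940          0.940 0.916
#> 3        PSS      self   0.373          0.375 0.259
#> 4        PSS   partner   0.544          0.544 0.446
#> 5       TICS      self   0.279          0.280 0.124
#> 6       TICS   partner   0.391          0.392 0.253

informant_coupling(fit)[1:2, ]
#>   quantity estimate  lower upper
#> 1     r_xi    0.618  0.367 0.809
#> 2  r_delta    0.345 -0.240 0.726

prof <- lag_profile(fit, setNames(hcc$log_hcc, hcc$participant_id))
attr(prof, "peak")
#>   informant peak_occasion alpha     r variance_explained_pct
#> 1      self             8 0.507 0.465                   21.6
#> 2   partner            10 0.222 0.251                    6.3
```

Reading the output: the weekly hassle scale is by far the purest indicator
of latent stress (standardized loadings near 0.9, against 0.4–0.55 for the
PSS and TICS); transient stress fluctuations are visible to both
informants (`r_xi`, true value 0.70), while systematic trends agree less
(`r_delta`, true value 0.34); and the self-report latent series predicts
log-HCC best around week 8 of 12 — weeks before hair sampling — exactly
the retrospective pattern the marker should show. The
`variance_explained_pct` column is the regression R² at the peak occasion,
in percent.

`run_pipeline(pipeline_config(preset = "fast"))` chains all stages
(simulate, score, psychometrics, fit, lag scan) into a run directory with
CSV outputs and a manifest; `inst/scripts/dyadstress` exposes the same
stages as a command line
(`dyadstress simulate|score|psychometrics|fit|lagscan|run`).

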