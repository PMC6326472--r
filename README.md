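# riversel

Discrete-choice modelling of riverine stopover habitat selection by
migratory waterbirds (the motivating system is whooping-crane roost
choice on braided Great Plains rivers), with penalized regression spline
smooths, AIC multimodel inference, relative-selection-ratio response
functions and calibration-slope validation — exercised end to end on a
seeded synthetic river landscape, so every stage is testable without any
field data.

## The model

Each stopover is one choice from a choice set: the used location plus 20
available locations sampled within a 32-km river reach (16 km up- and
downstream).  The multinomial weight of an alternative with habitat
covariates *x*₁,…,*x*ₚ is

    w(x) = exp( s₁(x₁) + s₂(x₂) + … + sₚ(xₚ) )

and a set's likelihood is w(chosen) / Σⱼ w(j).  The *s*ₖ are penalized
cubic regression splines (quantile knots, roughness penalty, potential
df < 4 per term by default); smoothness is chosen by a GCV-style grid
search, effective degrees of freedom come from the penalized-information
trace, a smooth that collapses to EDF 1 is refit as a parametric line,
and candidate models are ranked by AIC = −2ℓ + 2·EDF with Akaike weights
(the most parsimonious model within ΔAIC ≤ 2 is selected).  Covariates
follow riverine crane-habitat conventions: unobstructed channel width
(UOCW), total channel width (TCW), unforested channel width (UFCW),
distance to nearest riparian forest truncated at 400 m (NF), and the
flow metrics UD (discharge / wetted width) and DIS (discharge / total
width).  The methods vignette
(`vignettes/riversel-methods.Rmd`) gives the full account.

## Worked example

```r
library(riversel)
land    <- generate_landscape(seed = 42)              # 145-km synthetic corridor
truth   <- selection_spec(n_use = 85, n_avail = 20)   # plateau truth: 200 m UOCW, 160 m NF
choices <- simulate_stopovers(land, truth, seed = 42)

screen  <- screen_collinearity(choices, riverine_model_list())
fits    <- lapply(screen$admissible,
                  function(m) linear_fallback(fit_dcgam(choices, m)))
ranking <- rank_models(fits)
head(ranking, 4)
#>         model n_cov    df   aic delta_aic  weight selected
#> 1     UOCW+NF     2 2.821 474.8     0.000 0.84143     TRUE
#> 2 UOCW+NF+DIS     3 3.440 479.4     4.579 0.08524    FALSE
#> 3        UOCW     1 1.831 480.4     5.597 0.05125    FALSE
#> 4    UOCW+DIS     2 2.724 482.6     7.738 0.01756    FALSE
```

The generating structure (UOCW + NF) is ranked first with Akaike weight
0.84; the `df` column is the summed effective degrees of freedom.

```r
sel <- fits[[which(sapply(fits, function(f) f$model$name) ==
                     attr(ranking, "selected_model"))]]
sel
#> <dcgam> model UOCW+NF: 85 choice sets
#>   loglik -234.5882, total EDF 2.821, AIC 474.8193
#>   UOCW [smooth] edf = 1.821, lambda = 26.1
#>   NF [linear] edf = 1

peak_and_plateau(response_function(sel, "UOCW", choices))
#>  peak_value plateau_low
#>    360.6863    249.4273
```

The scaled relative selection ratio for UOCW is maximized at 361 m, but
values from 249 m up are statistically similar to the peak (overlapping
90% intervals) — selection saturates, consistent with the 200-m plateau
onset used to generate the data.

```r
validate_model(choices, sel$model, n_reps = 200, seed = 42)
#> <validation_result> 200 replicates (0 skipped), 20 bins
#>   mean slope 1.079 (95% CI 0.433 to 1.818): Good
```

The binned calibration slope averages ~1 and its 95% interval contains 1
but not 0, so the selected model validates as **Good**.

## Pipeline and CLI

`run_pipeline(run_config(seed = 1), "out/")` executes
simulate → metrics → choice sets → screen → fit → rank → respond →
validate and writes `choices.csv`, `landscape.geojson`, `ranking.csv`,
per-covariate response CSV/JSON, `validation.json` and a run manifest.
The same stages are scriptable via `exec/riversel`
(`simulate | metrics | choicesets | fit | rank | respond | validate | all`).

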