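# countspec

Automated, extensive hypothesis testing for count-data regression — the kind
of model an analyst builds for crash frequencies per road segment, injuries
per site, or any event count with many candidate contributing factors.

Specifying such a model means deciding, for every candidate factor, whether
to include it, how to transform it (`ln`, `sqrt`, `exp`, squared, cubed,
factorial, `arcsinh`, or none), whether its coefficient should be a **random
parameter** capturing unobserved heterogeneity across observations — and if
so under which mixing distribution (normal, uniform, triangular, gamma,
Lindley) — and which count family to use (Poisson, negative binomial,
generalized Poisson). `countspec` treats all of these as one discrete
optimization problem:

- each candidate specification is a chromosome
  (α<sub>k</sub>, r<sub>k</sub>, f<sub>k</sub>, τ<sub>k</sub> per factor,
  plus the model selector κ), subject to the constraint that a random
  parameter implies its fixed effect (α<sub>k</sub> ≥ r<sub>k</sub>);
- each chromosome is estimated by **maximum simulated likelihood**
  with Halton draws,
  ln L = Σ<sub>i</sub> ln[(1/H) Σ<sub>h</sub> P(y<sub>i</sub> |
  λ<sub>i</sub><sup>(h)</sup>, m)], with
  λ<sub>i</sub> = exp(X<sub>i</sub>β + offset) and
  β<sub>k</sub> = b<sub>k</sub> + r<sub>k</sub> f<sub>k</sub>(ω<sub>k</sub>);
- an automatic **repair** step removes statistically insignificant terms
  (p > 0.1 by default) and re-estimates, mimicking the analyst's pruning;
- specifications are selected by **BIC** (AIC / log-likelihood optional)
  using discrete **Harmony Search**, **Simulated Annealing**, or discrete
  **Differential Evolution**, with an evaluation cache keyed on the
  canonical chromosome.

Analyst knowledge enters through pre-specifications: forced
inclusion/exclusion, forced randomness or distributions or transformations
per factor, restricted decision sets, and an optional initial solution.

## A worked example

```r
library(countspec)

# a synthetic ground truth: 2 fixed effects, 1 normal random parameter,
# 3 pure-noise factors, Poisson counts averaged over 100 repetitions
truth <- synthetic_truth(n_obs = 500, intercept = 1,
                         fixed = c(FIXED1 = 0.6, FIXED2 = -0.4),
                         random = data.frame(name = "RANDOM1", mean = 0.5,
                                             omega = 0.4, dist = "normal"),
                         n_noise = 3)
gen <- generate_synthetic(truth, seed = 208)

space <- search_space(gen$dataset)      # full decision sets
cfg <- search_config("SA", max_time = 90, hdraws = 30,
                     t_alpha = 0.9, t_steps = 3, drop_all = TRUE, seed = 1008)
res <- simulated_annealing(gen$dataset, space, cfg)

tidy(res$best_fit)[, c("term", "transformation", "distribution",
                       "estimate", "std.error", "p.value")]
#> # A tibble: 5 × 6
#>   term            transformation distribution estimate std.error  p.value
#>   <chr>           <chr>          <chr>           <dbl>     <dbl>    <dbl>
#> 1 (Intercept)     NA             NA              1.02     0.0628 1.23e-59
#> 2 FIXED1          identity       NA              0.577    0.0415 5.36e-44
#> 3 FIXED2          identity       NA             -0.421    0.0408 5.65e-25
#> 4 RANDOM1         identity       NA              0.311    0.0387 9.42e-16
#> 5 RANDOM1 (scale) identity       lindley         4.95     0.450  4.56e-28

score_recovery(res, truth)
#> <recovery report>
#>   model type match: TRUE
#>   true factors included: 3/3
#>   noise factors falsely included: 0
#>   random parameters detected: 1/1 (exact dist 0, shape-confusable 0)
#>   max |coefficient error|: 4.90 SE units
```

The search (BIC 1759.25, log-likelihood −864.09) recovered the generating
structure exactly where it matters: all three true factors, no noise factor,
no spurious transformation, Poisson, and a random parameter on `RANDOM1`.
The mixing law it settled on is Lindley rather than the generating normal —
on this dataset the long-tailed law fits the realized heterogeneity slightly
*better* than the true specification (BIC 1759.25 vs 1759.46), the
distribution-confusion phenomenon the recovery report tracks; the biased
random-parameter mean under the wrong mixing law is what the 4.9-SE
coefficient error reflects. `autoplot(res)` draws the BIC-vs-iteration
convergence plot, and `render_report(res$best_fit)` prints the coefficient
table with significance stars and the scale-parameter block.

Real data enter through `load_dataset("crashes.csv", response = "ACCIDENT")`
or `count_dataset(df, "y", offset = "log_exposure")`, and a full run —
space, config, artifacts on disk — through `run_search(run_config(...))` or
the CLI at `inst/cli/countspec` (subcommands `search`, `fit`, `simulate`,
`report`).

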