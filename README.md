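# propp

Bayesian dynamic borrowing for single-arm trials whose **treatment** arm is
augmented with external patient-level data — typically an expanded-access
(compassionate-use) programme running alongside the trial.  The external
patients received the same drug and the same dichotomous endpoint, but they
differ from trial patients both in measured characteristics (broader
eligibility) and in unmeasured ones.  `propp` implements a two-stage
safeguard against both:

1. **Propensity stage.**  A logistic model for trial membership,
   λᵢ = Pr(zᵢ = 1 | xᵢ), is converted into per-patient borrowing weights.
   The default scheme targets the trial population: trial patients get
   wᵢ = 1 and external patients the capped membership odds
   wᵢ = min{1, λᵢ/(1 − λᵢ)}, so no external patient ever counts more than a
   trial patient and the total external weight cannot exceed roughly N₀
   even when Nₑ ≫ N₀.
2. **Dynamic borrowing stage.**  A modified power prior raises the weighted
   external likelihood to a power δ ∈ [0, 1] with its own prior and scaling
   constant C(δ) = B(δ·aₑ + 1, δ·bₑ + 1), where aₑ = Σwᵢyᵢ and
   bₑ = Σwᵢ(1 − yᵢ) over external patients.  Residual outcome conflict
   pushes δ toward 0; agreement pushes it toward 1 (pooling).

With a uniform prior on the response rate θ everything is conjugate:
θ | δ ~ Beta(δ·aₑ + a₀ + 1, δ·bₑ + b₀ + 1), and δ is drawn by exact
rejection sampling from its closed-form marginal — no MCMC.  The package
also provides the comparators (ignore, pooling, unweighted modified power
prior), a simulation harness for RMSE / type-I-error operating
characteristics, a bootstrap check of propensity design uncertainty, and a
synthetic case-cohort generator.

## Worked example

The real motivating cohort (a 132-patient melanoma trial, 75 responders,
plus a 241-patient expanded-access cohort, 129 responders) is under
restricted access, so the example runs on the shipped synthetic stand-in
with the same published structure:

```r
library(propp)
cohort <- generate_case_fixture(seed = 7)     # 132 trial + 241 external
report <- run_case_analysis(cohort, seed = 11)
report
#> Two-source case analysis
#>   zero-weight external patients: 44
#>         method   mean  lower  upper
#>     trial_only 0.5448 0.4603 0.6280
#>  external_only 0.5885 0.5261 0.6495
#>          propp 0.5565 0.4857 0.6260
#>   effective external weight: 69.5 patients
```

Reading the numbers: the trial-only posterior mean response rate is 54.5%
with equal-tailed 95% credible interval (46.0%, 62.8%); borrowing through
the weighted power prior moves the mean to 55.7% and *narrows* the interval
to (48.6%, 62.6%).  The 44 external patients with weight 0 are exactly the
synthetic patients whose ECOG grade (≥ 2) or stage ("unresectable III")
never occurs in the trial — the propensity fit quasi-separates for them and
they are excluded automatically.  The effective external weight says that
borrowing amounted to about 69 fully counted external patients out of a
total external weight of 123.

On the published summary counts the closed-form comparators reproduce the
reported reanalyses exactly:

```r
tidy(fixed_delta_posterior(counts_from_totals(75, 132), delta = 0))
#> # A tibble: 2 × 6
#>   parameter  mean median lower upper n_draws
#>   <chr>     <dbl>  <dbl> <dbl> <dbl>   <int>
#> 1 theta     0.567  0.567 0.483 0.650   10000
#> 2 delta     0      0     0     0       10000
tidy(fixed_delta_posterior(counts_from_totals(0, 0, 129, 241), delta = 1))
#> # A tibble: 2 × 6
#>   parameter  mean median lower upper n_draws
#>   <chr>     <dbl>  <dbl> <dbl> <dbl>   <int>
#> 1 theta     0.535  0.535 0.472 0.597   10000
#> 2 delta     1      1     1     1       10000
```

That is: trial only, posterior mean 56.7% with interval (48.3%, 65.0%);
external only, 53.5% with interval (47.2%, 59.7%).

The joint result on the restricted individual-patient data (mean 56.4%,
interval (49.4%, 63.3%), effective weight ≈ 67 patients) requires access to
the original cohort and is documented in the vignette as the pipeline's
intended real-data output.

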