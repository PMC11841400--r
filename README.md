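# triagebt

Bayesian estimation of raters' latent decision thresholds, and
threshold-adjusted inter-rater agreement, for binary triage decisions.

## The problem

In telephone triage an emergency nurse assigns each call a priority code;
the decisive split is binary — "green code or less" (ordinary vehicle)
versus "at least yellow code" (vehicle with emergency devices).  Two
nurses can produce different overt decisions while judging a call's
severity identically, simply because their personal decision criteria
differ; conversely they can agree overtly while disagreeing in judgement.
Plain agreement statistics conflate these effects, and systematic
criterion differences are themselves clinically meaningful (tendencies to
over- or under-triage).

`triagebt` is for researchers and training coordinators who want to
separate the two ingredients.  It models each overt decision by the rule

> decide "at least yellow code" ⟺ BM<sub>ir</sub> > BT<sub>r</sub>

where BM<sub>ir</sub> ∈ [0,1] is rater *r*'s latent **Belonging Measure**
for scenario *i* (implicit severity judgement) and BT<sub>r</sub> ∈ [0,1]
is the rater's **Belonging Threshold**, a stable personal cutoff.
BT < 0.5 indicates over-triage, BT > 0.5 under-triage; 0.5 is the
standard threshold that minimizes *spurious* agreements and disagreements
(those caused purely by threshold differences) and is attributed by
definition to the reference experts.

Per rater, the package samples the joint posterior of
(BT, BM<sub>1</sub>..BM<sub>n</sub>) by MCMC, with truncated-normal
priors on the BMs centred on normalized reference-expert severity ratings
(SD 0.15) and a Bernoulli likelihood whose logistic link (steepness
τ = 0.05) smoothly approximates the hard rule.  Agreement — Cohen's κ,
with marginal-product chance correction — is then computed on
**BT-adjusted decisions**: the estimated BMs dichotomized at 0.5, i.e.
the decisions each rater would have made with the ideal threshold.
A grid-integration oracle, a synthetic-study generator with known ground
truth, and a full agreement/reporting pipeline are included.

## Worked example

```r
library(triagebt)

# a complete synthetic study with known truth: 21 raters x 15 scenarios
# x 2 reference experts, written as CSV inputs
st <- make_fixture_study(seed = 7, dir = "study")

cfg <- pipeline_config("study/responses.csv", "study/experts.csv",
                       "study/historical.csv", out_dir = "study/out",
                       mcmc = mcmc_config(seed = 7))
res <- run_pipeline(cfg)

res$report
#> <agreement_report> 21 raters, 15 scenarios
#>   mean kappa vs experts (adjusted): 0.773
#>   mean pairwise kappa: 0.709 (0.736 after excluding r13, r20, r3)

res$fits[[1]]
#> <rater_fit> r1: BT = 0.579 [0.422, 0.742]

sprintf("mean BT = %.3f (SE %.3f)", res$summary$mean_bt, res$summary$se_bt)
#> [1] "mean BT = 0.524 (SE 0.033)"

sprintf("predictivity rho = %.2f", res$predictivity$rho)
#> [1] "predictivity rho = 0.83"
```

Reading the output: the group mean threshold (0.524) sits near the ideal
0.5, so this synthetic panel shows no strong collective over- or
under-triage; rater `r1`'s threshold posterior mean is 0.579 with a 95%
credible interval [0.422, 0.742]; adjusted agreement with the experts
(mean κ = 0.773) exceeds the "acceptable" 0.60 cutoff; dropping the three
raters least concordant with the experts raises the mean pairwise κ from
0.709 to 0.736; and the estimated thresholds correlate strongly
(Spearman ρ = 0.83) with each rater's simulated historical percentage of
low-priority codes — the thresholds predict everyday triage behaviour.
On this run the estimated thresholds recover the generator's true ones
with mean absolute error 0.086.

The threshold-optimality demonstration is a one-liner:

```r
sw <- spurious_rate_sweep(seq(0.05, 0.95, 0.05), n_sim = 100000, seed = 1)
sw$argmin
#> [1] 0.5
round(sw$spurious_rate[which.min(abs(sw$t - 0.7))], 3)  # closed form: 2a(1-a) = 0.32
#> [1] 0.322
```

A command-line interface with subcommands `simulate`, `fit`, `agree`,
`predict`, `report` and `run` lives at `inst/cli/triagebt.R`:

```sh
Rscript inst/cli/triagebt.R simulate --out study --seed 7
Rscript inst/cli/triagebt.R run --responses study/responses.csv \
    --experts study/experts.csv --historical study/historical.csv \
    --out study/out --seed 7
```

See `vignettes/belonging-threshold-methods.Rmd` for the model, its
assumptions, the synthetic generator's design, and known limitations.

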