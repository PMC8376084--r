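# igseqr

Hierarchical Bayesian analysis of immunoglobulin-coated gut bacteria
(IgA-seq) for longitudinal cohort studies — built around the canine
chronic-enteropathy setting: healthy dogs plus dogs classified by treatment
response (diet / antibiotic / immunosuppressant), sampled at active disease
and remission, with flow-sorted faecal bacterial fractions (pre-sort input,
Ig-positive, Ig-negative) sequenced for both IgA and IgG.

## What it computes

**Flow-cytometry coating model.** Ig-positive cell counts out of totals are
modelled as a hierarchical binomial regression on the logit scale,

    positive_i ~ Binomial(total_i, p_i)
    logit(p_i) = x_i' beta + u_d(i) + v_d(i) * IgG_i,   (u_d, v_d) ~ N2(0, Sigma)

with the full `Ig * disease * treatment` fixed-effect expansion, flat priors
on `beta`, half-t(3, 0, 2.5) priors on the random-effect SDs and a uniform
prior on their correlation. Posterior summaries use 90% credible intervals,
split-R̂/ESS convergence diagnostics, and Nakagawa marginal/conditional R².

**Taxon model and enrichment ratio.** Counts of M focal taxa plus an
`other` remainder follow a baseline-category multinomial logit,

    log(p_m / p_other) = x' beta_m + u_{d,m},   u_{d,m} ~ N(0, sigma_m)

with `N(0, 5)` priors on all regression coefficients, fitted per Ig class.
The headline statistic is the **posterior Ig enrichment ratio** — a
model-based analogue of the Palm index: per taxon and MCMC draw, the ratio
of predicted proportional abundance in the Ig-bound condition over a
baseline condition (pre-sort input by default, Ig-negative optional),
summarised by the posterior median with central 50% and 90% intervals.
Values above 1 mean the taxon is preferentially targeted by the
immunoglobulin. A raw, data-level Palm-style index is provided as a
comparator.

**Preprocessing and diversity.** Feature-table hygiene as in standard
amplicon practice: samples under 500 reads and features under 10 total
reads removed (strict boundaries), replicate/run merging, singleton
pruning, prevalence-based decontamination against negative controls
(one-sided exact hypergeometric score, threshold 0.5, sequencing run as
batch factor, per-batch scores combined by minimum), rarefaction to 1000
reads, and top-11-family + `other` aggregation. Diversity: Shannon index
with a `log(Shannon) ~ Ig * disease * treatment + (1 | Dog)` REML mixed
model and marginal means with 95% CIs; CLR transform (pseudocount 1),
Aitchison and Bray–Curtis distances, PERMANOVA (999 permutations), and
UPGMA clustering with Newick export.

**Synthetic data.** Because the original raw data are not public, the
package ships a first-class generator that reproduces the study's
statistical structure (cohort sizes 11/11/8/3, an unbalanced dog, duplicate
replicates across two runs, ~14,000 reads/sample, contaminated negative
controls, binomial coating counts and multinomial fraction counts with
dog-level random effects) and records the ground truth for every recovery
test.

## Worked example

```r
library(igseqr)

design <- simulate_cohort(n_healthy = 11, n_dre = 11, n_are = 8, n_ire = 3,
                          seed = 1)
params <- generator_params(
  beta_flow = c("(Intercept)" = qlogis(0.28), stageafter = -0.15),
  seed = 1)
flow <- simulate_flow_counts(design, params)
head(flow, 3)
#>   dog_id  cohort  stage ig_class positive total    true_p
#> 1 dog_01 healthy before      IgA     2313 10000 0.2333568
#> 2 dog_01 healthy  after      IgA     2096 10000 0.2076000
#> 3 dog_01 healthy before      IgG     2269 10000 0.2287247

fit <- fit_flow_model(flow, chains = 4, iter = 1000, warmup = 1000, seed = 1)
predict_proportions(fit,
  grid = expand.grid(ig_class = c("IgA", "IgG"), cohort = "healthy",
                     stage = c("before", "after"), stringsAsFactors = FALSE))
#>   ig_class  cohort  stage median lower upper
#> 1      IgA healthy before   0.23  0.18  0.29
#> 2      IgG healthy before   0.22  0.17  0.28
#> 3      IgA healthy  after   0.21  0.16  0.26
#> 4      IgG healthy  after   0.20  0.15  0.25
round(glmm_r2(fit), 3)
#>    marginal conditional
#>       0.021       0.127
```

The predicted coating proportions recover the generating world (28% before
treatment, dropping after; the 90% intervals reflect between-dog spread),
and the R² split shows most explained variance sits in the dog random
effects, as expected when fixed effects are modest.

The full analysis — simulate → validate → preprocess → flow model → taxa
models per Ig class → diversity — runs from one config:

```r
cfg <- pipeline_config(simulation = list(n_healthy = 11, n_dre = 11,
                                         n_are = 8, n_ire = 3))
run_pipeline(cfg, "run1")   # writes TSV reports + manifest.json
```

or from the command line via `exec/igseqr`:

```sh
Rscript -e 'igseqr::igseqr_cli()' run-all --config cfg.json --out run1
```

## Vignette

`vignettes/igseqr-methods.Rmd` documents the models and priors, the MCMC
scheme (adaptive Metropolis-within-Gibbs with Fisher-information joint
proposals and likelihood-invariant translation moves), what the synthetic
generator does and does not emulate, numerical choices (boundaries,
tie-breaking, pseudocounts), and known limitations.
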