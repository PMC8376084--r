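---
title: "Models and methods in igseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in igseqr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(igseqr)
```

# The scientific problem

IgA-seq experiments sort gut bacteria by whether host immunoglobulins
(IgA or IgG) coat them, then sequence the sorted fractions. Two questions
drive the analysis: *how much* of the community is Ig-coated (a
flow-cytometry proportion per animal, Ig class and visit), and *which taxa*
the immunoglobulins preferentially target (a compositional shift between
the Ig-bound fraction and a baseline). Both are longitudinal, repeated
within subject, and noisy at very different scales — tens of thousands of
flow events versus compositional read counts — which is why the package
uses hierarchical Bayesian models with subject-level random effects
throughout.

# The flow-cytometry coating model

Data are `positive` Ig-coated cells out of `total` counted cells for each
dog × stage × Ig-class record. The model is a binomial GLMM on the logit
scale with the full `Ig * disease * treatment` interaction expansion
(treatment coding; references IgA / healthy / before) and a correlated
per-dog intercept and IgG slope:

$$\mathrm{logit}(p_i) = x_i^\top\beta + u_{d(i)} + v_{d(i)}\,
\mathbb{1}[\text{IgG}_i], \qquad (u_d, v_d) \sim
\mathcal{N}_2(0, \Sigma).$$

Priors follow the "keep the defaults" philosophy of the applied setting:
improper flat priors on $\beta$ (a proper $\mathcal{N}(0,\sigma_0)$ is
available via `prior_sd`), half-Student-t(3, 0, 2.5) on the random-effect
SDs, and a flat (LKJ(1)-equivalent) prior on the 2×2 correlation. The
formula's "Antibody" and "Ig" grouping terms denote the same factor; the
IgG indicator is coded 0/1 against the IgA reference.

Summaries use the posterior median with central 90% credible intervals.
`predict_proportions()` reports population-level proportions (random
effects at zero) or, in marginal mode, Monte-Carlo-averages
$\mathrm{plogis}(x^\top\beta + u + v\,\mathbb{1}[\text{IgG}])$ over
$(u,v) \sim \mathcal N_2(0, \hat\Sigma)$ per draw — both are offered
because figure-level predictions in applied work are ambiguous between the
two. `glmm_r2()` computes the Nakagawa decomposition on the logit scale
per draw, with latent residual variance $\pi^2/3$ and random-effect
variance $\sigma_u^2 + 2\rho\sigma_u\sigma_v\,\overline{ig} +
\sigma_v^2\,\overline{ig^2}$ (the full quadratic form; it reduces to the
common two-term version when $\rho = 0$).

# The taxon model and the enrichment ratio

For M focal taxa plus an `other` remainder, per-sample counts are
multinomial with baseline-category logits

$$\log\left(\frac{p_m}{p_{\text{other}}}\right) = x^\top\beta_m + u_{d,m},
\qquad u_{d,m} \sim \mathcal N(0, \sigma_m),$$

fitted separately per Ig-class dataset with the sorting fraction, disease
cohort, treatment stage and their interactions as fixed effects
(references presort / healthy / before). All regression coefficients get
$\mathcal N(0, 5)$ priors — wide on the log-odds scale, proper enough to
keep rarely-observed cells finite; the per-taxon random-intercept SDs get
half-t(3, 0, 2.5). Random intercepts are independent across taxa, the
minimal structure consistent with a `(1 | Dog)` term; cross-taxon
correlation is a known omission (see Limitations).

The **enrichment ratio** is computed from posterior prediction, not from
raw counts: per draw, push $\beta$ (plus $u_{d,\cdot}$ in subject mode)
through the softmax at the bound condition and at the baseline condition
and take the per-taxon ratio. Summaries are the posterior median and
central 50%/90% intervals. The baseline defaults to the pre-sort input
fraction — the input community is what "enrichment by sorting" is most
naturally measured against, and it is explicitly sequenced in this design
— with the Ig-negative fraction available via the `baseline_condition`
argument; the field uses both conventions and the original description
does not pin one down. `raw_palm_index()` implements the data-level
comparator, $(\bar a_{\text{bound}} + \psi)/(\bar a_{\text{base}} + \psi)$
on mean relative abundances, so the two routes can be cross-checked (they
agree within ~20% on large, weak-random-effect simulations; a dedicated
test asserts this).

# MCMC: scheme and the two moves that matter

No probabilistic-programming backend is assumed: both models are sampled
by an adaptive Metropolis-within-Gibbs scheme written in C++ (Rcpp).
Per iteration:

1. **Per-coordinate random-walk updates** of each fixed effect, each dog's
   random effect (2-d jointly in the flow model), and each hyperparameter
   (on log-SD / atanh-correlation scales, with Jacobians). Proposal scales
   adapt by Robbins–Monro toward standard acceptance targets during warmup
   only.
2. **Joint fixed-effect moves** with proposal covariance from the
   conditional Fisher information at the end of the first warmup half
   ($X^\top \mathrm{diag}(n_i p_i(1-p_i)) X$, and its multinomial
   analogue), scaled by $2.38/\sqrt{P}$ with a globally adapted factor.
   Binomial likelihoods with $10^4$ trials make the stage-contrast block
   extremely tight and strongly correlated; per-coordinate walks alone mix
   it at ESS of a few per thousand draws, the Fisher-covariance move fixes
   that.
3. **Translation moves**: a fixed-effect column constant within every dog
   (intercept, cohort indicators) is likelihood-confounded with the dog
   intercepts; columns of the form `IgG × (dog-level indicator)` are
   confounded with the dog Ig slopes. Shifting $\beta_j$ by $\delta$ while
   subtracting $\delta c_d$ from the corresponding random effects leaves
   every linear predictor unchanged, so the move is accepted on the
   random-effect prior alone and mixes these otherwise-slow directions in
   a few sweeps. This is the Metropolis analogue of the usual
   centred/non-centred reparameterisation trade-off.

Defaults are 4 chains × 1000 warmup + 1000 kept (the original analysis
does not state its sampler settings; these are artifact choices). All
randomness flows through R's RNG, so a seed plus config reproduces draws
bit-for-bit; chain seeds derive from the master seed via
`spawn_seed()`. Convergence is gated, not assumed: split-R̂ < 1.05 and
ESS > 100 per fixed effect and SD, with failures warned and flagged on the
returned object. Split-R̂ can dip a few 1e-5 below 1 by construction of
the pooled-variance estimator; it is reported as computed. ESS uses mean
within-chain autocovariances with Geyer's initial-positive/monotone
truncation, capped at the total draw count; constant chains yield `NA`
rather than a number.

# What the synthetic generator emulates — and what it does not

The generator's defaults are the stated world of the study design:

* 11 healthy + 11 DRE + 8 ARE + 3 IRE dogs; stages before/after; one
  diseased dog (chosen reproducibly) providing only the active-disease
  visit.
* Fractions presort / Ig⁺ / Ig⁻ for IgA and IgG; duplicate sequencing
  replicates assigned to two runs; negative controls (sheath fluid,
  water, buffer) alternating across runs.
* Flow counts: Binomial with 10,000 trials per sample around
  `plogis(qlogis(0.28))` — the reported average coating before treatment —
  with dog intercept SD 0.5 and IgG-slope SD 0.3 on the logit scale
  (plausible between-subject spread; the paper reports no such SDs).
* Reads: depth ~ Poisson(14,000) truncated at 1 (only "~14,000" is
  stated; a one-parameter unimodal law suffices); taxon probabilities from
  the same baseline-category softmax the fitting module assumes, with
  per-dog, per-taxon intercept SD 0.5. The default community uses eleven
  real canine faecal families with a geometric-decay composition and one
  focal taxon at 0.10 pre-sort vs 0.30 Ig-bound (true ratio 3), the
  anchor used by the recovery tests.
* Contamination: negative controls are pure contaminant at mean depth
  2,000 (low-biomass controls sequence shallower); true samples receive
  Poisson leakage at `contaminant_load = 1e-4` of their depth — well under
  one read per contaminant per sample, i.e. stochastic presence/absence,
  which is the regime where prevalence-based detection is a meaningful
  test rather than a tautology (at high loads a contaminant is present
  everywhere and prevalence carries no signal).

Not emulated: raw reads and denoising (the artifact starts from a feature
table), chimeras, PCR/primer bias, taxonomic misassignment, phylogeny,
clinical scores, and real ecological correlation structure between taxa.
A green recovery test therefore establishes that the estimators invert the
assumed generative model at realistic sizes — not that the model is true
of any particular dog's gut.

# Numerical and design choices

* Filter boundaries are literal: "< 500 reads" and "< 10 total" are
  strict; a sample with exactly 500 reads survives. Filters are idempotent
  and order-configurable; the default order is depth → abundance →
  decontamination → merge → singleton prune.
* Decontamination score: one-sided exact hypergeometric tail (small =
  contaminant-like), presence meaning count ≥ 1; per-run scores combined
  by minimum (conservative: flagged if contaminant-like in any run);
  classification at score < 0.5. Features absent everywhere score `NA`,
  are flagged as undefined and retained.
* Rarefaction is a single seeded multivariate-hypergeometric draw, not an
  average; samples below the target depth are dropped.
* Shannon uses natural log (configurable base); samples with H ≤ 0 are
  excluded from the log-Shannon LMM with a report (they arise only from
  single-taxon compositions post-rarefaction).
* PERMANOVA permutes labels freely (the original analysis reports plain
  Adonis calls on repeated measures; a `strata` argument allows
  within-dog restriction but is not the default), with the
  `(1 + \#\{F^* \ge F\})/(1 + n_{perm})` estimator, and an exhaustive
  mode for exact small-n enumeration.
* UPGMA ties break by lexicographic order of cluster leader labels, making
  trees deterministic; node heights are half the merge distance, Newick
  branch lengths are height differences.
* Marginal means average fixed-effect predictions over non-grid factor
  levels with equal weights and use normal-approximation CIs (no
  small-sample df correction) — a deliberate simplification, adequate at
  these sample sizes.
* The `other` category is always the multinomial reference and the last
  table row; relabelling focal taxa permutes outputs without changing
  values (tested).

# Limitations

* Per-taxon dog intercepts are independent; real compositions induce
  cross-taxon covariance that the model ignores (its effect shows up as
  modest extra dispersion).
* The multinomial has no overdispersion term beyond the random
  intercepts.
* The enrichment ratio's baseline (pre-sort vs Ig-negative) is a
  convention, not an estimate; both are implemented and must be stated
  when reporting.
* Fisher-information proposal covariance is computed once per chain at
  mid-warmup; pathological posteriors (all-zero taxa, prior-dominated
  cells) fall back to coordinate-wise mixing, slower but still correct —
  all-zero taxa are warned about.
* Reported R² values are plug-in Nakagawa decompositions; they inherit
  that framework's interpretation caveats on the latent scale.
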