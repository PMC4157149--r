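---
title: "Spurious marker-by-exposure interaction under gene-environment dependence: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spurious marker-by-exposure interaction under gene-environment dependence: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerGxE)
```

## The problem

Interaction tests in genetic epidemiology are almost always run on a
genotyped marker `M` (a tag SNP) rather than on the causal variant `D`
itself. The marker is a *misclassified* version of `D`, and — unlike
classical measurement error — the misclassification probabilities are
determined by linkage disequilibrium and are unknown by design. When `D` is
also associated with the environmental exposure `X` (by mediation,
pleiotropy, or confounding such as population structure — three mechanisms
that all induce the same statistical tilt and therefore need no separate
machinery here), the misclassification rate differs between exposure
strata, and a marker-by-exposure interaction appears even when `D` and `X`
do not interact. This package computes that bias exactly, inverts it, and
checks it by simulation.

## Haplotype algebra (`haplotype_joint`, `haplotypes_from_ld`, `ld_stats`)

The canonical object is the haploid joint distribution of the two alleles
on one chromosome, four masses `h_DM, h_Dm, h_dM, h_dm`. All forward
calculations operate on chromosomes; diploid genotype views are derived
under Hardy–Weinberg equilibrium by squaring the haplotype distribution
(`diploid_expansion`), never stored. Joints are built from the two minor
allele frequencies plus either D′ or r²; the r² route needs an explicit
sign because r² is sign-blind, and the package convention is that positive
association means the causal allele is enriched on the minor-marker
background. Feasibility is enforced by the Fréchet bounds on `h_DM`
(boundary values accepted exactly, anything beyond rejected with the
violated bound named); masses must sum to 1 within `1e-9` and are validated,
never rescaled silently.

## Forward bias on the risk-ratio scale (`marker_rr`, `stratum_marker_rrs`)

With per-allele disease risk ratio `R`, cell `(d, m)` is weighted by `R^d`;
the marker risk ratio is the weighted-to-unweighted mass ratio of the
`M = 1` class over the `M = 0` class. The exposed stratum is the joint
tilted by `θ^d`, where θ is the per-allele risk ratio of the causal allele
on the exposure. All ratios are computed from *unnormalized* masses: the
disease baseline and stratum normalizations cancel, so the results are
invariant to rescaling the masses and carry no dependence on disease or
exposure prevalence. Observed odds ratios are treated on the risk-ratio
scale throughout (the rare-disease convention), which is also how the
worked breast-cancer example must be read.

## GLM marginalization (`marker_eta_grid`, `lemma_conditions`)

The marker-scale linear predictors are
`η_{m,x} = h(Σ_d h⁻¹(β₀* + β_D* d + β_X* x + β_DX* d x) Pr(d|m,x))` and
`β_MX` is their double difference. Variables are binary allele-level codes
in this module; dosage-coded diploid analysis is delegated to the
simulator's regression. Two stratification conventions relate the haplotype
joint to `Pr(d|m,x)`:

* **baseline_unexposed** (default): the joint describes the unexposed
  stratum and the exposed stratum is the tilted, renormalized joint. This
  reproduces the stratified worked tables exactly and is what
  `stratum_marker_rrs` assumes. Only per-stratum conditionals are defined,
  so the stored three-way mass uses equal exposure weights, which leaves
  every `Pr(d|m,x)` unchanged.
* **marginal**: the joint is the population marginal and
  `Pr(X=1|d) = κ θ^d` with κ solved against a target exposure prevalence
  (rejected as infeasible when `κθ > 1`).

The published example does not state which convention its GWAS-scale
calculation used; both are provided, the default being the one that
reproduces the printed numbers. Coefficients (log-RRs for the log link),
not ratios, are the internal currency; conversion happens at the interface.

`lemma_conditions` reports, at a configurable tolerance (default `1e-9`),
which of the four no-interaction conditions hold: (1) `β_D* = 0`;
(2) `Pr(D = M) = 1`; (3) `D ⟂ M | X`; (4) `D ⟂ X | M`, the last
guaranteeing `β_MX = 0` only under the identity or log link. Under the
logit link condition (4) gives `β_MX → 0` only in the rare-outcome limit;
the property suite checks that `|β_MX|` decreases monotonically and is
below `1e-6` at baseline log-odds −20.

## Sensitivity inversion (`invert_marker_effects`, `sensitivity_scan`)

Given observed marker effects `rr₀` (baseline stratum) and `rr₁` (tilted
stratum), an assumed causal MAF and D′, the solver recovers the causal
`(R, θ)` reproducing both. Two facts make this essentially algebraic:

* the baseline-stratum equation is **linear in `R`** for any joint (the
  unexposed marker RR is a ratio of affine functions of `R`), so the
  disease-side solution is unique and exact;
* the tilted-stratum equation, cross-multiplied, is **quadratic in θ**,
  degenerating to linear when `h_Dm = 0` (D′ = 1 with `p_D ≤ p_M`, the
  setting of the published sensitivity analysis), where the tilt is unique.

When `h_Dm > 0` the exposed-stratum marker RR tends to 1 both as `θ → 0`
and `θ → ∞` (either limit makes the exposed stratum monomorphic at the
causal locus), so *two* positive tilts generally reproduce the same
observations exactly. Both are returned; the primary solution is the root
with the smaller `|log θ|` — the weakest gene–environment dependence
consistent with the data, the conservative choice for a sensitivity
analysis — and the other is reported as `rr_exposure_causal_alt`. The
quadratic is solved in the cancellation-stable form (`q/a` and `c/q`), with
a relative threshold `|a| ≤ 1e-12(|b| + |c|)` routing effectively-linear
instances to the single finite root; without this, D′ = 1 joints whose
`h_Dm` is zero only up to roundoff lose half the digits of the tilt. A
damped 2-D Newton iteration with a bisection fallback and a final
`uniroot` polish is kept as an independent numerical path
(`method = "newton"`); the test suite checks that the two paths agree to
`1e-10` on unique-tilt instances.

Degenerate inputs: `rr₀ = rr₁ = 1` is flagged non-identifiable (R = 1, θ
undetermined) rather than an error; a perfect proxy (`p_D = p_M`, D′ = 1)
cannot absorb differing stratum effects and is reported infeasible, as is
any configuration without a positive solution — in particular the reversed
stratum assignment of the worked breast-cancer example. That assignment
(baseline stratum = menarche > 12 with marker OR 0.906; tilted stratum =
≤ 12 with OR 0.979) is forced: the reverse has no positive solution.

## Power (`interaction_information`, `sample_size_for_interaction`)

The sample-size calculation uses the standard Wald expected-information
asymptotics for the interaction coefficient of a logistic model on the
2×2×2 (marker, exposure, case status) case-control table. Expected cell
probabilities are built from the diploid scenario with carrier coding of
the marker (defaults: balanced cases/controls, exposure prevalence 0.5,
baseline disease risk 0.01 — all overridable and echoed in the output);
`n = (z_{1−α/2} + z_{power})² / (log IR² · info)`, rounded up. With binary
marker, exposure and outcome the logistic interaction model is saturated,
so the information-based variance equals the classic sum of reciprocal
cell probabilities — which is exactly the independent oracle the tests
compare against. The headline "over a million subjects" conclusion for the
GWAS-scale scenario holds by three orders of magnitude and survives any
reasonable change of design defaults, so the precise asymptotic flavour is
immaterial there.

## Simulator (`simulate_cohort`, `simulate_case_control`, `fit_interaction_glm`)

Each subject is two independent haplotype draws (HWE), a Bernoulli exposure
and a Bernoulli outcome from the causal GLM evaluated at causal *dosage*.
Configurations are validated before any sampling (log-link risk at the
extreme dosage-2, exposed cell must be ≤ 1; infeasible `κθ²` rejected).
Everything is reproducible from the integer seed, and case-control
sampling rejection-samples whole cohort batches until the requested counts
are met, erroring out when a batch budget is exhausted.

Exposure assignment supports the same two conventions as the analytic
module. Under `marginal` (`Pr(X=1|d) = κθ^d`) the *unexposed* stratum is
tilted by `1 − κθ^d`, which does not factorize over haplotypes; the fitted
dosage-level log-link interaction then converges to
`log(rr₁/rr₀) + O(κ(θ−1))` — measured at +0.0099 for exposure prevalence
0.1 and +0.043 at 0.3 in the worked scenario — rather than to the
stratified-table value. Under `baseline_unexposed` (exposure drawn first,
haplotypes from the untilted or per-allele tilted distribution) both strata
factorize exactly, `E[Y | marker dosage, x]` is exactly log-linear in
dosage with stratum-specific slope, and the fitted interaction converges to
the analytic `β_MX` with no convention bias. The Monte-Carlo confirmations
of the stratified tables therefore use `baseline_unexposed`; `marginal`
remains the default for population-style simulations where the joint is a
population marginal.

The fitter is an in-package IRLS (identity/log/logit, binomial variance,
fractional responses with prior weights allowed) so that the simulation
oracle carries no external fitting dependency; `stats::glm` is used in the
tests as a second opinion, never as the implementation. Convergence is
declared at a maximum coefficient change below `1e-10` (default, 100
iterations); non-convergence and quasi-separation are warned about, never
returned silently. Fitting on *expected* cell tables (weights =
probabilities, fractional outcomes) reproduces the analytic η-grid to
`1e-8`, which is the strongest internal consistency check between the
simulator and the marginalization module.

## What the generator emulates — and what it does not

The simulator emulates exactly the idealized world of the analytic model:
biallelic loci in HWE, a binary exposure whose dependence on genotype is a
clean per-allele tilt, multiplicative per-allele risks, no covariates, no
genotyping or exposure measurement error beyond the marker/causal-variant
distinction, and no population stratification beyond the induced D–X
association itself. Passing tests therefore show the *algebra* is right,
not that real cohorts behave this way: real exposures are measured with
error (which biases interactions toward the null and can interact with the
mechanism studied here), real risks need not be multiplicative, and real
LD patterns involve more than two loci.

## Problem sizes and tolerances used by the test suite

Randomized property suites use 1000 draws for the no-interaction theorem
and the forward–inverse round trip (tolerances `1e-10` and `1e-8`), 200–300
draws for LD round trips and diploid/haploid equivalence (`1e-12`). The
Monte-Carlo confirmation of the stratified tables uses one cohort of 10⁶
subjects (a few seconds; agreement within 3 SE and byte-identical
replay under a fixed seed), SE calibration uses 200 replicates of 4 000
subjects, and the empirical power check uses 500 multinomial replicates of
the expected case-control table. These sizes were chosen so the binomial
noise floor sits well below the effects being verified.

## Known limitations

* Biallelic loci only, one marker and one causal variant; no multi-locus
  haplotypes, no VCF/genotype-file ingestion — parameters are supplied, not
  estimated.
* Binary exposure and outcome; identity/log/logit links only; no covariate
  adjustment.
* The inversion assumes the observed stratum effects are exact; published
  confidence intervals are not propagated (that would need the original
  study's covariance structure).
* Additive-scale (risk-difference) interaction measures such as RERI are
  out of scope; "interaction" here is multiplicative throughout.
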