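---
title: "Training a 23-weight network on a Taguchi L36 array: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training a 23-weight network on a Taguchi L36 array: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two national cross-sectional surveys (2013 and 2019, 27,801 respondents
together) track seventeen chronic non-communicable diseases in Serbia by
region, age band and gender. The modelling task is to estimate the
prevalence percentage of a disease in a stratum-year from a small set of
descriptors, and to do so with a network so small and a training procedure
so cheap that the whole experiment fits in a handful of iterations.

The estimator is a fixed feed-forward network with exactly 23 connection
weights. Instead of backpropagation, the weights are treated as *factors*
of a designed experiment: each weight takes one of two or three candidate
*levels*, a mixed-level orthogonal array prescribes 36 level combinations,
the 36 candidate networks are scored, and the level grid is re-centred and
contracted around the winner. A full factorial over 11 two-level and 12
three-level factors would need $2^{11} \cdot 3^{12} = 1\,088\,391\,168$
evaluations; the orthogonal plan needs 36 per iteration, a reduction of
$1 - 36/2^{11}3^{12} \approx 99.9999967\%$.

## The array

`oa_l36()` returns the 36-run array $OA(36, 2^{11}3^{12})$ of strength 2,
transcribed as package data and re-validated on every load: each two-level
column holds each level 18 times, each three-level column 12 times, and
every column pair shows every level combination equally often (9 for
two-level pairs, 6 for mixed pairs; the transcription is in fact balanced
for three-level pairs as well, 4 each). The array is *data*, not
generated code: mixed-level array construction is a specialised topic and
the printed plan is the ground truth the experiment uses. A corrupted
transcription cannot load (`oa_balance()` names the offending column or
pair).

## The network

`build_network()` wires a 10-2-1 topology: ten inputs, two logistic hidden
units without hidden bias, one linear output with bias,

$$\hat y = W_{23} + W_{11}\,\sigma\!\Big(\sum_{i=1}^{10} W_i f_i\Big)
          + W_{22}\,\sigma\!\Big(\sum_{i=1}^{10} W_{11+i} f_i\Big).$$

This is the unique small topology in which the 23 weights split exactly as
the array's column types do: the 11 two-level factors are one hidden
pathway plus its output gain ($W_1..W_{10}$, $W_{11}$), and the 12
three-level factors are the second pathway, its gain and the output bias
($W_{12}..W_{21}$, $W_{22}$, $W_{23}$). Two-level factors are cheap to
probe but coarse; the finer three-level resolution goes to the pathway
that, in practice, carries the fit. The output is bounded by
$|W_{23}| + |W_{11}| + |W_{22}|$ and networks differing only in
hidden-unit order are equivalent (a symmetry the tests assert).

## Coding of inputs and targets

Four coding functions are implemented (`coding_fit()`): a triangular
three-term fuzzy partition with peak-centroid defuzzification, a
$\log(1+x)$ compression, min-max normalization and z-standardization. All
are monotone with exact inverses; the fuzzify/defuzzify round trip is the
identity on the support because triangular Ruspini partitions with
peak-weighted centroids reconstruct their input exactly.

Three decisions here are worth spelling out:

* **Natural support for percentages.** The encode module defaults to
  observed data ranges, but the prevalence pipeline codes percent-scale
  quantities on the natural domain $[0, 100]$. A support fitted to a
  training split changes with the split and forces clamping of out-of-range
  test values; the natural domain is split-invariant and needs no clamping.
  For the equally spaced default peaks the scalar fuzzy code on $[0,100]$
  is simply $x/100$; the fuzzy machinery still matters when peaks are
  placed unevenly, and the configuration keeps that pluggable.
* **Headroom.** Coded targets are mapped into $[0.05, 0.95]$, the usual
  convention for regressing on a scale produced by saturating units.
* **Both inputs and targets are coded.** Which of the two the original
  experiment coded is not recorded; coding both is the default and each is
  configurable. Errors are always computed after decoding, on the percent
  scale.

## Feature vector

Each prevalence-table row becomes ten features: survey-year indicator,
gender code, region one-hot (4), age-band midpoint, the *base-rate logit*,
a stratum-share slot, and a constant 1. Two constructions matter:

* **Base rate on the logit scale.** The overall share of the disease in
  that survey year is a published marginal and enters as
  $\mathrm{logit}(0.05 + 0.9\,p)$ with $p$ the share in $[0,1]$. The logit
  is the canonical scale for a share feeding a logistic unit: a hidden unit
  with unit weight on this feature reproduces the share exactly, so the
  network contains exact solutions with small integer weights — precisely
  the points a coarse level grid can reach. Without this, the best
  reachable fits sit orders of magnitude above the observed optimum.
* **Inert constants.** A feature that is constant across the table carries
  no information, yet coded at a nonzero constant it acts as a second bias
  and drags ten irrelevant weights into the search. Constant slots are
  therefore coded 0; the explicit constant slot already provides the bias
  path. On the transcribed survey table this collapses the active search space from
  23 to 9 weights.

## The search

Per iteration (`run_search()`):

1. instantiate the 36 candidate weight vectors from the array and the
   current level table (`candidates_from_array()`);
2. score each by training MMRE on the decoded percent scale
   (`evaluate_candidates()`);
3. record the winner row (`ANN1..ANN36`; ties to the lowest index);
4. additionally evaluate the *confirmation run*: the classical Taguchi
   main-effects prediction that combines, per factor, the level with the
   best marginal mean objective;
5. cache the best candidate ever evaluated (the incumbent), re-centre
   every factor's levels on it, and contract the spacing
   $\delta \mapsto 0.5\,\delta$ — *only after an iteration that failed to
   improve the incumbent*;
6. stop when the improvement of the best objective is below the threshold
   $\varepsilon = 0.01$ (relative by default, absolute available) on two
   consecutive iterations, or at `max_iterations` (20).

Three of these choices depart from the plainest reading of the procedure
and were forced by experiment:

* **Mesh-adaptive contraction (5).** Contracting every iteration
  regardless of success provably stalls: after re-centring, all 36
  candidates move *every* weight simultaneously by $\pm\delta$-scale
  steps, and at a freshly halved spacing none of the 36 fixed directions
  needs to be a descent direction. In runs on the transcribed survey table the
  unconditional schedule freezes at the iteration-1 winner forever.
  Contracting only on failure is the textbook pattern-search schedule: a
  spacing that just produced an improvement is kept, a spacing that
  produced none is halved. (`refine_levels()` itself implements the
  prescribed contraction; `run_search()` decides when to apply it.)
* **Confirmation run (4).** Orthogonal arrays exist to estimate main
  effects; evaluating the predicted-optimum combination is standard
  Taguchi practice and costs one extra evaluation out of 37.
* **Patience (6).** With a single-iteration criterion, any iteration in
  which no candidate improves the incumbent fires the stop (zero
  improvement is below every threshold) — terminating runs at iteration 2
  with the fit barely begun. Requiring two consecutive sub-threshold
  iterations lets one stalled mesh contract and retry.

Initial levels are $\{-1, +1\}$ for two-level and $\{-1, 0, +1\}$ for
three-level factors ($\delta_0 = 1$) on the coded scale — a symmetric
cover of the coded ranges whose grid points include the exact solutions
described above. The best-so-far incumbent is returned even when the
contracted grid no longer contains it, which makes the reported trace
non-increasing by construction. Given the split, the search is entirely
deterministic; the only randomness in a fit is the seeded 70/30
year-stratified train/test split.

On the transcribed survey table with fuzzy coding the search reaches the
exact interpolating solution (training MMRE at numerical zero, Pearson
1.0) in 5 iterations on every split seed tried, by settling onto the
all-grid-point solution $W_{19}=-1, W_{22}=-1, W_{23}=1$ (output
$1 - \sigma(-f_8) = \sigma(f_8)$, the inverse of the target coding). With
log-coded targets no such grid-aligned solution exists and the search is
markedly less reliable (training MMRE in the 10–45% range depending on
split); the ranking — fuzzy best — matches the published comparison,
though the implementation's gap is far larger than the published one. A
*constant*-target dataset converges to under 1% MMRE but needs most of
the 20-iteration budget: with all informative features inert the bias
weight must drift to the coded constant at the geometric mesh rate.

## What the transcribed-table fitting exercise does and does not show

For the overall per-year rows of the published tables the base-rate
feature *is* the target, so the fit is a consistency and recovery
exercise: it demonstrates that the Taguchi search can locate an exact
solution of the network on data the network can represent, under the
published study conditions — it is not evidence of out-of-sample
predictive skill. Genuine covariate-to-target structure appears when the
model is fitted to stratified tables from the synthetic cohort (where the
stratum prevalence differs from the overall share), and the
planted-network recovery test is the capability check: data generated by a
hidden 23-weight network on the initial grid is recovered to under 0.5%
training MMRE.

## Evaluation

`mmre()` is $100 \cdot \mathrm{mean}(|a_i - \hat y_i| / a_i)$ on the
percent scale; zero actuals are an error, never patched with an epsilon.
`pearson()`/`spearman()` wrap `stats::cor` with the report's input checks;
`r2_cubic()` is the determination coefficient of the ordinary
least-squares fit of estimates on $\{1, a, a^2, a^3\}$ — the standard
"cubic" curve estimation, with the direction (estimated on actual) fixed.
Correlations are pooled over both year panels; cubic $R^2$ is reported
per year. `run_experiment()` scores ANN-L36 under each coding and any
requested baselines through this one path and emits the comparison tables.

## Synthetic cohort

`generate_cohort()` emulates the surveys' composition: per-year totals
(14,623 / 13,178), region, age-band and gender counts as printed, combined
as independent margins with largest-remainder rounding so every total is
exact; disease flags are independent Bernoulli draws at the canonical
per-year prevalences. Where the publication disagrees with itself
(hypertension 2019 appears as 32.2, 32.3, 32.4 and 33.2), the region-wise
table is canonical and all variants are retained in the fixture with their
sources. The generator does **not** model comorbidity correlation,
age/region/gender-specific disease gradients (unless per-stratum
probabilities are supplied), survey weights, or missingness — so passing
tests show correct sampling behaviour, not epidemiological realism.

The closed-form contingency statistics (`odds_ratio()` with Woolf
intervals and explicit, opt-in Haldane–Anscombe correction;
`two_proportion_test()` pooled z) support prevalence-difference analyses
of generated cohorts. Multivariate logistic regression is deliberately
out of scope: it is a routine library fit whose published inputs
(microdata) are unavailable.

## Baselines

The decision-tree (`rpart`), support-vector-regression (`e1071`, linear
and polynomial kernels) and Gaussian RBF (`kernlab::gausspr`,
standardized or normalized features) comparison models are thin wrappers
behind one fit/predict contract; their internals are intentionally not
re-implemented, and the RBF regressor stands in for a fuzzy-means-trained
RBF network whose training algorithm is out of scope. Their published
accuracy figures depend on the original microdata and are not reproduction
targets; `gain_ratio()` (information gain over split information, base 2)
is implemented in full.

## Problem sizes and determinism

The shipped experiment operates on the transcribed table of the ten most
prevalent diseases over two years (20 rows; 14 training rows under the
70/30 split) — deliberately small, since one search iteration costs only
37 forward passes over the training rows. Cohort generation at the full
printed size (27,801 respondents, 17 diseases) takes well under a second.
All randomness (splits, cohort draws) flows from explicit integer seeds;
fits with equal seeds are bit-identical, and the headline protocol
(five split seeds, best training MMRE reported) is implemented as
`best_of_seeds()`.
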