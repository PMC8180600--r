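---
title: "Ideal-response-pattern priors for Bayesian-network cognitive diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ideal-response-pattern priors for Bayesian-network cognitive diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnirp)
```

## The problem

Cognitive diagnostic assessment classifies examinees on K binary skill
attributes from J dichotomous item responses, guided by a Q-matrix
(`q[j, k] = 1` iff item j requires attribute k). A discrete Bayesian network
is a natural carrier for this model: attribute nodes are latent, item nodes
are observed, item parents come from the Q-matrix rows, and optional
attribute-to-attribute edges encode a prerequisite hierarchy. Fitting the
network's conditional probability tables (CPTs) by maximum likelihood — EM
or gradient methods over the latent-attribute mixture — is notoriously
fragile here: nothing forces the estimates to respect monotonicity (more
mastered skills should never lower an item's success probability), the
likelihood has many label-flipped local optima (any subset of the K
attributes can swap the meaning of 0 and 1 with little or no likelihood
cost, giving up to 2^K equivalent optima of which only one matches the
intended skill labels), and random starts land in the wrong one most of the
time. `fit_plain()` exists to exhibit exactly this failure.

The remedy implemented here uses information every diagnostic test carries
for free: the **ideal response patterns** (IRP). Under a condensation rule —
conjunctive DINA (`prod(alpha^q)`, all required attributes needed) or
disjunctive DINO (`1 - prod((1-alpha)^q)`, any one suffices) — each
admissible attribute pattern implies an error-free response vector. The IRP
table (one row per pattern) is a complete-data training set: counting its
frequencies yields CPTs that are already monotone and correctly labelled.
These counts are then carried forward as an informative Dirichlet prior (and
starting point) for EM or conjugate-gradient refinement on the observed
responses, which adds the empirical item-quality information the IRP alone
lacks.

## Estimation details

**Inference.** Item nodes are conditionally independent given the full
attribute pattern, so exact inference enumerates the admissible pattern
space (2^K, or fewer under a hierarchy; practical to K of about 12). Message
passing would return identical numbers on this two-layer graph; enumeration
is chosen because it is trivially verifiable against a brute-force oracle
(the test suite does so at 1e-10). All likelihood accumulation is in log
space; logs are clamped at `log(1e-300)` inside the vectorized batch path,
while the scalar path (`pattern_likelihood`, `posterior_over_patterns`)
preserves exact zeros.

**Priors.** `count_cpts(data, structure, smoothing)` sets each row to
`(count + smoothing) / (count(config) + 2 * smoothing)` and stores
`count + smoothing` as the Dirichlet exponent table. With the IRP data each
item row's total prior weight is the number of patterns sharing that parent
configuration (`2^(K - K*_j)` per reduced configuration): the IRP table is
literally entered as data into a counting learner. The default smoothing
pseudo-count is 0.01: raw IRP counting yields 0/1 item rows (exactly
reproducing the worked four-row example) that are absorbing in the E-step —
a zero item probability permanently zeroes every posterior that disagrees —
so the refinement stage needs strictly positive priors. 0.01 is small enough
to leave the prior's shape untouched.

**EM.** Dirichlet-MAP EM: E-step pattern posteriors, M-step
`(prior + expected count)`, normalized. The log-posterior
(`loglik + sum(prior * log p)`) is asserted non-decreasing every iteration;
convergence is a relative change below `tol = 1e-6` with at most 500
iterations — beyond the precision of anything reported.

**Conjugate gradient.** The same objective is minimized (negated) over
per-row logits with `stats::optim(method = "CG", type = 2)` — Polak-Ribière
with restarts. The analytic gradient for a row with probability p is
`(e1 + a1)(1 - p) - (e0 + a0) p`, with `e1`/`e0` the E-step expected counts
at the current point; it is verified against central finite differences to
1e-6. The iteration cap (600, each iteration spending about three
objective/gradient evaluations in its line search, so about 2000 evaluations
in total) costs less than 0.001 in the classification rates relative to an
uncapped run on the slowest conditions; if CG fails to improve on the
starting point, the start is returned, so the final log-posterior is never
below the prior-only model's.

**DINA to DINO fallback.** The source method switches to the disjunctive IRP
when the conjunctive-prior refinement is "trapped", without defining
trapped. It is operationalized as: relative log-likelihood gain over the
prior-only model below `10 * tol`, **or** more than 50% of comparable
item-CPT parent-configuration pairs violating monotonicity by more than
0.01. The margin matters: conjunctive generators tie all non-complete
configurations exactly, and sampling noise on tied rows (SE around 0.03 at
N = 1000) must not count as violation. The final arbiter is a likelihood
comparison between the two fits, so a false alarm only costs a second fit.

**G-DINA baseline.** The saturated identity-link model: each item has a free
success probability per reduced pattern (the delta expansion is available
via `prob_to_delta()` / `delta_to_prob()`), estimated by marginal-ML EM over
the pattern mixture with free mixing proportions, no monotonicity
constraint, deterministic initialization (success probability linear in the
fraction of required attributes mastered, 0.2 to 0.8; uniform mixing).
Classification is MAP with lexicographic tie-breaks, matching the BN side.

## The synthetic world

The replication engine reproduces the canonical simulation design: the
30-item / 5-attribute Q-matrix (ten single-, ten double-, ten
triple-attribute items), true profiles either uniform over the 32 patterns
or thresholded multivariate normal (unit variances, compound-symmetry
correlation 0.5, attribute k mastered iff the latent score reaches
`qnorm(k/6)`, so marginal mastery falls from 5/6 to 1/6), item parameters
with endpoints fixed by the guess/slip setting (flat: g = s = 0.2
everywhere; mixed: three 10-item blocks at 0.3 / 0.2 / 0.1) and intermediate
reduced-pattern probabilities drawn uniformly between the endpoints with a
monotonicity rejection step, redrawn each replication; N of 500 or 1000; 30
replications; replication r seeded with `base_seed + r`. Performance is the
pattern classification rate (PCR, exact pattern matches) and the average
attribute classification rate (AACR, per-attribute agreement averaged over
attributes); the reported "standard error" is the sample SD of the
per-replication rates, whose magnitude (0.01-0.07) matches the printed
dispersions, not an SD divided by the root of the replication count.

What a green simulation test does establish: the full pipeline — profile
samplers, monotone item generator, Bernoulli simulation, both estimators,
MAP scoring — lands within three between-replication SDs of the published
cell means. What it does not: real response data (the G-DINA world is the
generating model for the comparison baseline, so the baseline is favoured by
construction), missing data, polytomous items, or the behaviour of the
particular commercial implementation behind the published plain-EM/GD
baseline columns, which depend on its undocumented random initialization and
are reproduced only qualitatively (very low PCR with occasional lucky
label orientations).

The BN-generated conditions (`run_bn_generated_condition`) close the other
loop: a BN fitted to source data by the IRP-EM pipeline forward-samples new
datasets whose patterns mimic the source's, without assuming the G-DINA form.

## Numerical and design choices where the design was open

- **Classification is MAP over full patterns** (ties to the
  lexicographically smallest bit-string); thresholded marginal posteriors
  would answer a different question and are not what PCR measures.
- **Attribute nodes stay independent roots under the mvnorm generator**: the
  Q-matrix alone induces no attribute edges, and results under correlated
  profiles are reported for that same structure (the misspecification is the
  point of the condition — the saturated G-DINA mixing proportions can
  absorb the correlation, the product-Bernoulli BN prior cannot, which is
  why the baseline leads there).
- **Plain-IRP classification uses the smoothed (0.01) CPTs.** Raw 0/1 tables
  assign zero likelihood to every non-ideal response vector, which makes
  classification of noisy data impossible; the published nonzero IRP-only
  rates are only reachable with smoothing.
- **IRP case weight 1 per pattern**, matching the worked counting example; a
  global multiplier is exposed but never tuned.
- **Parameter-recovery checks are calibrated to the noise floor.** At
  n = 2000 the 30x5 design has 140 item-CPT cells with per-cell binomial SE
  near `sqrt(p(1-p)/250)`; the maximum absolute error over the cells then
  has a noise floor above 0.05 for any generator with endpoint noise above
  about 0.05 — even for a complete-data oracle that knows the true profiles.
  The recovery tests therefore use a low-noise generating BN, where the
  max-abs bound measures estimator correctness rather than the order
  statistic of sampling noise, and the G-DINA endpoint check additionally
  requires the marginal-ML estimates to match the complete-data oracle's
  accuracy on the same draw.
- **Hierarchy semantics** are prerequisite closure: a pattern is admissible
  iff every mastered attribute has all transitive hierarchy ancestors
  mastered — the only reading under which the admissible set shrinks below
  2^K. The shipped buoyancy hierarchy is a synthetic stand-in (same shape
  class as the published expert hierarchy, which is not redistributable) and
  feeds workflow tests only.

## Limitations

Exact enumeration bounds K at roughly 12 attributes; no missing data or
polytomous responses; no model-fit indices (flagged as future work in the
source method); no MCMC route; the identity link only for G-DINA. The plain
EM/GD baselines are faithful to their described failure mode, not to any
particular software's internals.

## A worked call

```{r example, eval = FALSE}
Q <- qmatrix_sim30()
space <- enumerate_patterns(5)
set.seed(1)
profiles <- sample_uniform(1000, space)
data <- simulate_gdina(profiles, gen_item_params(Q, "flat"))

fit <- fit_with_irp_prior(data, Q, method = "GD")
pred <- classify_responses(fit$cpts, data, space)
score(profiles, pred)
```

The README shows the full worked example with the numbers it prints.
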