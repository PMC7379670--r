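---
title: "Removal models with temporary emigration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removal models with temporary emigration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(remer)
```

## The model

Removal sampling estimates the size of a closed population by capturing and
permanently removing individuals over a sequence of occasions, so that the
expected catch depletes over time. The classic geometric (Moran–Zippin)
removal model assumes every animal is available for capture at every
occasion; for secretive taxa such as reptiles and amphibians that assumption
fails, because part of the population is temporarily hidden (underground, in
refugia, off the plot) and undetectable for stretches of the study. Treating
the depressed catch curve as if it reflected capture probability alone
misallocates animals: the practical consequence is a misleading picture of
how many animals remain when a mitigation translocation or invasive-removal
project stops.

`remer` models this with a two-state hidden Markov (multievent) structure
inside a robust design. The study comprises `T` primary periods; primary
period `i` holds `k_i` secondary occasions (`K` occasions in total).
Individuals move between an on-site, observable state and an off-site,
unobservable state only **between** primary periods — a first-order Markov
chain with transition probabilities $\phi^{12}_i$ (on-site to off-site) and
$\phi^{21}_i$ (off-site to on-site) — while the population is closed within
a primary period. A proportion $\pi$ starts on-site. At secondary occasion
$(i,j)$ every on-site, not-yet-removed individual is captured (and removed)
with probability $p_{i,j}$.

The probability that a given individual is removed at occasion $(i,j)$ is a
product of $2\times 2$ matrices along the forward chain,
$$L_{i,j} = \boldsymbol{\pi}\, Q_{1,1}\cdots Q_{1,k_1}\,\Phi_1\,
Q_{2,1}\cdots Q_{2,k_2}\,\Phi_2 \cdots \Phi_{i-1}\,
Q_{i,1}\cdots Q_{i,j-1}\, P_{i,j}\, \mathbf{1}_2,$$
with $\boldsymbol{\pi} = (\pi, 1-\pi)$, $Q_{i,j} =
\mathrm{diag}(1-p_{i,j},\,1)$, $P_{i,j} = \mathrm{diag}(p_{i,j},\,0)$, and
$L_0$ (no removal by the end) the same product run to the final occasion.
The cells always satisfy $L_0 + \sum_{i,j} L_{i,j} = 1$. With counts
$n_{i,j}$ removed at each occasion, $D = \sum n_{i,j}$ removed in total and
$n_0 = N - D$ never removed, the likelihood is multinomial:
$$L(\pi, \phi, p, n_0) = \frac{N!}{n_0! \prod_{i,j} n_{i,j}!}\,
L_0^{\,n_0} \prod_{i,j} L_{i,j}^{\,n_{i,j}}.$$
Several populations removed independently (age classes, species) multiply
their likelihoods; shared parameters across populations — a shared capture
model, or an additive logit offset $\gamma_w$ on the transitions — make
this an integrated model.

`cell_probabilities()` evaluates the cells by a forward pass over the
two-state chain (O(K) per population, no matrix products materialised), and
`removal_loglik()` evaluates the log-likelihood.

## Constraints and model codes

The fully time-dependent model has $K + 2T$ parameters against $K$ observed
counts and is parameter redundant, so constrained sub-models are the
practically relevant family. The constraint letters follow the field's
naming convention (`model_code()` / `parse_model_code()`):

* **S** — $\pi$ fixed at the mean over time of the first element of the
  stationary distributions of the transition matrices,
  $\pi = \frac{1}{T-1}\sum_i \phi^{21}_i / (\phi^{12}_i + \phi^{21}_i)$;
  **N** — $\pi$ free.
* **R** — random emigration, $\phi^{21}_i = 1 - \phi^{12}_i$ (the
  probability of being off-site next period does not depend on the current
  location); **E** — even flow, $\phi^{21}_i = \phi^{12}_i$; **V** — the
  relaxation $\phi^{12}_i + \phi^{21}_i = v$ with $v \in (0,2)$ an extra
  free parameter; **N** — both directions free. Suffix **t** marks
  time-varying transitions, **2** equates the last two transitions (the
  usual device for identifying the final transition of a Markovian robust
  design), **a** adds the per-population additive logit offset.
* **C** — constant capture probability; **Z** — the covariate-logit model
  $\mathrm{logit}(p_{i,j}) = \alpha + \beta z_{i,j}$; **T** — one free
  $p_{i,j}$ per occasion.

A design with a single secondary occasion per primary period (`k_i = 1`)
is the degenerate, non-robust case; codes then drop the `R-` prefix, and
integrated models use `IR-` with population subscripts on `S`.

## Parameterisation and fitting

All free parameters are optimised on unconstrained scales — logit for
probabilities, $\mathrm{logit}(v/2)$ for $v$, log for $n_0$, identity for
regression coefficients and offsets — so any finite optimiser iterate maps
to a valid parameter set (`pack_parameters()` / `expand_parameters()`).
$n_0$ is treated as continuous through the log-Gamma relaxation of the
multinomial coefficient; reported abundances are left continuous. The
multinomial constant is included in reported log-likelihoods, so AIC values
are comparable across models fitted to the same data, including the
geometric baseline.

`fit_removal()` runs BFGS from a depletion-ratio moment start
($p_0 = 1 - n_{1,2}/n_{1,1}$, clipped to $[0.05, 0.9]$; probabilities at
0.5; $n_0$ at $D/2$) plus random restarts (10 by default — near-redundant
surfaces are multimodal and restarts are the cheap insurance), then
re-polishes the best optimum until the objective stops improving. Estimates
with a probability within $10^{-4}$ of 0/1 (or $n_0$ of 0) are flagged as
boundary estimates; Hessian standard errors (numerical Hessian +
delta method) are reported only at interior optima, and the nonparametric
bootstrap (`bootstrap_removal()`) is the recommended uncertainty measure
otherwise. The bootstrap resamples the `D` observed removal records across
occasion cells with `D` held fixed and refits; this reconstruction of the
resampling unit is a package choice (the records, not the unobserved
individuals), and an alternative parametric scheme — redrawing whole data
sets of size $\hat N$ from the fitted model — is available via
`scheme = "parametric"`.

Missing occasions (no sampling effort) are part of the design and handled
by forcing $p_{i,j} = 0$ there: the occasion contributes no information and
no removals are possible. How real studies handled skipped visits is rarely
documented; this convention is ours.

## Parameter redundancy diagnostics

Whether a constrained model is estimable is decided by the rank of the
Jacobian of the exhaustive summary $\kappa(\theta)$ — here the vector of
all cell probabilities $(L_{1,1},\ldots,L_{T,k_T},L_0)$ per population —
with respect to the free parameters (excluding $n_0$, whose information
enters only through the multinomial total; parameter counts in the
redundancy tables follow that convention, while AIC counts include one
$n_0$ per population). `check_redundancy()` computes the Jacobian by
central finite differences at five random interior parameter draws and
takes the numeric rank from the singular values with a relative threshold
of $10^{-8} s_{\max}$; the deficiency is $d = h - \max r$. This is a
numerical surrogate for symbolic rank computation: it cannot prove results
for all `K`, but at spot-checked designs it reproduces the known
classification of the constrained model lattice exactly, and the rank is
stable across evaluation points and difference step sizes. Covariate
capture models are ranked with a fixed standardised, non-constant synthetic
covariate sequence (`redundancy_covariate()`), since the rank depends on
the covariate actually varying.

A full-rank model can still behave badly when it sits close to a nested
redundant model. `near_redundancy()` builds the expected multinomial
information $I(\theta) = N\, J^\top \mathrm{diag}(1/\kappa)\, J$ at
supplied parameter values and flags near redundancy when the
smallest-to-largest eigenvalue ratio falls below $10^{-6}$. Two points
matter in practice. First, the flag is scenario-dependent by nature — it
describes the information at particular parameter values, not the model in
the abstract. Second, the classic emigration-heavy test point
($\pi = 0.2, \phi^{12} = 0.8, \phi^{21} = 0.2$) lies **exactly on** the
stationary + random-emigration submodel, so the unconstrained constant
model's information is numerically singular there ($\sim 10^{-16}$ ratio)
even though its generic rank is full: "near redundant" and "redundant at a
measure-zero point" coincide at such truths. The threshold cleanly
separates these from the well-conditioned constrained fits
($\sim 10^{-2}$).

For redundant single-secondary models only parameter combinations are
estimable. `check_estimable_combinations()` verifies invariance of the
cells for parameter pairs matched on the combinations — closed-form
matching for the known sets
($\{\pi p,\ \phi^{21} p,\ (\phi^{12}-1)p - \phi^{12} - \phi^{21}\}$ for
the unconstrained model; $\{\pi p,\ (\phi^{12}-1)p\}$ under random
emigration; $\{(\phi^{12}-1)p\}$ with stationary $\pi$ as well), or a
numerical solve for user-supplied combination functions. A deliberately
insufficient set fails the check, which is the useful negative control.
We note the unconstrained set is stated in parts of the literature with
$\phi^{12} p$ as the second member; the Jacobian null space is orthogonal
to $\nabla(\phi^{21} p)$ but not $\nabla(\phi^{12} p)$, and $\phi^{21} p$
is the member consistent with the random-emigration set (where
$\phi^{21} p = -(\phi^{12}-1)p$), so the package uses $\phi^{21} p$.

## The simulator and the study conditions

`removal_scenario()` packages the generating truths used throughout the
recovery studies: a closed population with `K/2` primary periods of two
secondaries each, constant capture `p = 0.3`, and

* constant transitions with either an emigration-prone truth
  ($\phi^{12} = 0.8, \phi^{21} = 0.2$, scenario 1) or a site-faithful truth
  ($\phi^{12} = 0.4, \phi^{21} = 0.6$, scenario 2), `N = 500`;
* time-varying random-emigration truths (fixed $\phi^{12}$ vectors for
  `K = 10` and `K = 20`), `N = 500`; and
* an integrated two-population variant (`N = 300`, `M = 200`) whose second
  population is shifted by $\gamma_2 = -0.5$ on the logit of
  $\phi^{12}$.

$\pi$ is always the stationary-mean value implied by the transition truth.
`simulate_removal()` draws data either individual-by-individual (explicit
hidden-state trajectories, removal on capture) or as one multinomial draw
from the model cells; the two are distributionally identical and the tests
compare them by chi-square on aggregated cell counts. The simulator
emulates the model's own data-generating process — closed population, exact
Markov movement, homogeneous capture within an occasion. It does not
emulate individual heterogeneity in capture or movement, covariate-driven
transitions, mortality or recruitment, so passing recovery tests show
correctness of the estimator under the model, not robustness to real-data
violations of it.

`run_removal_study()` derives one sub-seed per replicate from the master
seed, so any replicate is reproducible in isolation, and records
non-convergent replicates rather than failing. Each replicate also carries
a boundary flag, and `summarise_study()` excludes boundary replicates from
the reported moments by default: a replicate whose MLE sits on the edge of
the parameter space (a transition probability at 0/1, a diverging group
offset) has no finite interior estimate for the affected parameter, and a
single such replicate can move a 100-replicate mean by several tolerances
(at the integrated conditions, roughly 9% of replicates are flagged and
one in a hundred diverges outright). The excluded count is always visible
in the study table. Study sizes in the packaged checks are 100 replicates
(recovery) and 200 replicates (baseline-bias demonstration) with 2–3
optimiser restarts per replicate fit; these sizes give Monte-Carlo standard
errors comfortably inside the tolerances asserted while keeping the default
suite quick to run.

## The geometric baseline and its bias

`grm_spec()` provides the classic geometric removal model — occasions
flattened to a single index, every uncaptured animal assumed present — both
as an AIC competitor and as the negative control. Under an
emigration-heavy truth the geometric fit attributes the slow depletion to
low capture probability: $\hat p$ collapses (about 0.05 against a truth of
0.3 at `K = 20`). Its remaining-animal count $\hat n_0$ is best compared
against the number of animals actually remaining **at the study area**
(never removed and on-site, about 11% of $N - D$ under the scenario-1
truth at `K = 20`): against that quantity the geometric model overestimates
in essentially every replicate, which is the operationally relevant error —
it reports a large pool of catchable animals that is not there. Against
the *total* never-removed count $N - D$ the comparison is unstable: the
geometric $\hat n_0$ distribution under emigration has a very long right
tail (replicates with $\hat p \to 0$ push $\hat n_0$ into the thousands),
so its mean exceeds $N - D$ erratically while its median sits below.
`grm_bias_demo()` reports both truths per replicate.

## Worked example

```{r example, eval = FALSE}
scn <- removal_scenario("constant", scenario = 2, K = 20)
dat <- simulate_removal(scn, seed = 1)
spec <- rmer_spec(attr(dat, "design"), pi = "stationary", phi = "random")
fit <- fit_removal(dat, spec, seed = 1, compute_se = TRUE)
glance(fit)
tidy(fit)
autoplot(fit)

rank_models(dat, list(spec, grm_spec()), seed = 1)
check_redundancy(spec)
```

## Known limitations

* The redundancy diagnostic is numeric: it certifies ranks at the designs
  and points it evaluates, not theorems in `K`.
* Near-redundancy flags depend on the supplied truth and on the calibrated
  eigenvalue-ratio threshold; report the ratio, not just the flag.
* Abundance estimates are continuous (no integer profiling in the default
  path) and can be unstable when capture probability or availability is
  low — exactly the regimes the diagnostics are there to flag.
* Survival/mortality, recruitment, more than two latent states,
  covariate-driven transitions and spatial structure are out of scope.
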