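---
title: "Likelihood inference for isolation-with-initial-migration models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood inference for isolation-with-initial-migration models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iimfit)
```

## The model

`iimfit` fits two-deme speciation models to counts of segregating sites
between pairs of haploid sequences at many independent loci. The fullest
model is the isolation-with-initial-migration (IIM) model: an ancestral
population of relative size $a$ splits at time $\tau_0$ (in units of $2N$
generations, $N$ being the size of subpopulation 1 during the gene-flow
period) into two subpopulations of relative sizes $1$ and $b$ that exchange
migrants at scaled rates $M_1, M_2$ ($M_i = 4Nm_i$, so a single lineage in
deme $i$ migrates at rate $M_i/2$ in coalescent time). At time $\tau_1 \le
\tau_0$ gene flow stops, and the subpopulations continue, completely
isolated, at relative sizes $c_1, c_2$ up to the present.

Each locus contributes one pair of sequences, sampled in one of three
configurations (its *state*): both from population 1, both from population
2, or one from each. The genealogy of a pair is a succession of three
Markov chains, one per stage. During isolation, states 1 and 2 coalesce as
Kingman pairs at rates $1/c_1$ and $1/c_2$; state 3 cannot coalesce.
During the migration stage the pair moves on the states $\{1, 3, 2\}$ with
migration rates off the diagonal and coalescence rates $1$ and $1/b$ into
an absorbing state; the density of the absorption time is a signed mixture
of three exponentials whose decay rates are the absolute values of the
negative eigenvalues of the generator, and whose coefficient matrix $A$
comes from the left eigenvectors (`migration_spectrum()`). When only one
migration rate is positive, the eigen-system degenerates gracefully and the
package uses fully explicit coefficients derived from the
moment-generating-function system of the chain by partial fractions; with
no gene flow, states 1 and 2 are plain exponentials and state 3 must wait
for the ancestral stage. The assembled density of the pairwise coalescence
time is piecewise across the three stages (`coal_time_density()`).

Under the infinite-sites assumption, the number of segregating sites $S$ at
a locus with relative mutation rate $r_j$ is Poisson with mean $r_j \theta
T$ given the coalescence time $T$, where $\theta = 4N\mu$ is the average
scaled mutation rate. Integrating $T$ out gives a closed-form PMF with one
piece per stage (`seg_sites_pmf()`); no numerical integration is involved
anywhere in the likelihood.

## Numerical design

The printed closed form of the PMF contains truncated Poisson sums
$e^{-x}\sum_{l \le s} x^l/l!$ and geometric factors $x^s/(1+x)^{s+1}$ that
overflow for counts beyond a few hundred. The implementation therefore

* evaluates every truncated sum as a Poisson CDF (a regularised
  incomplete-gamma call, `ppois(..., log.p = TRUE)`), never by term
  summation;
* keeps all factors in log space and combines the (signed) pieces with a
  signed log-sum-exp, so the log PMF is finite and accurate for counts of
  $10^4$ and mutation rates of 50 and beyond;
* clamps negative residuals within $10^{-12}$ (relative) of zero that stem
  from rounding in the signed mixture, and raises an error for anything
  larger rather than silently flipping signs.

Degenerate spectra (repeated eigenvalues, e.g. $M_2 = 2$ in the
unidirectional closed forms) lie on a measure-zero set of the parameter
space; the package perturbs $M_1, M_2, b$ multiplicatively by $10^{-9}$ and
warns, since the likelihood is continuous there. Eigenvalues are sorted
decreasingly with the matching columns of $A$, making the spectrum
reproducible. Empty stages ($\tau_1 = 0$, or $\tau_1 = \tau_0$) are exact
limits: the corresponding PMF pieces carry no mass by construction, with no
epsilon adjustments.

## Parameterisation and fitting

Fitting works in the identifiable mutation-scaled parameterisation $\phi =
(\theta_a, \theta, \theta_b, \theta_{c1}, \theta_{c2}, T_1 = \theta\tau_1,
V = \theta(\tau_0 - \tau_1), M_1, M_2)$. The model family
(`iim_model()`) fixes or ties subsets of $\phi$: ISO (isolation only), IM1
(gene flow until the present), IIM1 (gene flow ending at $T_1$), IIM2 (the
full model, with separate isolation-stage sizes) and IIM3 (IIM2 with $M_1
= 0$).

The per-locus log-PMF evaluation runs in compiled code (a C++ kernel whose
truncated Poisson sums use a short linear-space series within its safe
range and the regularised incomplete gamma outside it; a pure-R reference
implementation is retained and the two are tested against each other), so
one likelihood evaluation on $4\times 10^4$ loci takes tens of
milliseconds.

`fit_iim()` maximises the composite log-likelihood with a two-stage local
search per start — a Nelder–Mead simplex polish followed by bounded
L-BFGS-B (forward-difference gradients with a shared evaluation cache),
optionally repeated (`rounds`) to escape quasi-Newton stalls on ridges.
Sizes are optimised on the log scale; $T_1, V, M_1, M_2$ are bounded below
by zero so boundary hypotheses are exactly representable. Starts are
placed around a method-of-moments centre (matching per-state means of
$s/r_j$) with Latin-hypercube jitter; the default is 10 starts and the
whole procedure is deterministic given `(data, model, n_starts, seed)`.
For data sets beyond the `subsample` control (default 12{,}000 loci) the
multistart search runs on a stratified subsample; the start optima are
then re-ranked by their *full-data* likelihood (distinct basins can order
differently under subsampling noise) and the winner is re-polished on the
full data by cycles of central-difference L-BFGS-B and short simplex
rounds (`polish_cycles`). Convergence is declared at $10^{-8}$ relative
tolerance in the simplex stage and `factr = 1e7` in L-BFGS-B; Hessians use
central finite differences with step $10^{-4}(1 + |\phi_k|)$, switching to
a one-sided stencil at the zero boundary.

A practical caveat that the estimation experiments below quantify: at
generating values where gene flow is hard to distinguish from a longer
shared history (moderate $M$, short isolation stage), the likelihood
surface has several near-equal local optima strung along long, nearly
flat, curved ridges. Single-data-set estimates of $\theta$ and the
migration rates then scatter substantially along the ridge (with $\hat
M_1$ often collapsing to its zero boundary) even at $4\times 10^4$ loci,
while nested-model log-likelihood differences remain stable. Two practices
mitigate the resulting optimisation hazard and are used throughout the
shipped checks: *laddering* — fit the nested seven-parameter model first
and warm-start the full model from it (`init`), as `forward_selection()`
does automatically — and *repeated attempts* with different seeds (hence
different search subsamples), keeping the attempt with the best
log-likelihood. Medians across replicate data sets remain the meaningful
summary of estimator behaviour; single-data-set point estimates of
ridge-coupled coordinates should be read together with their profile
intervals.

## Intervals, conversion, model choice

`wald_ci()` inverts the observed information; `profile_ci()` bisects the
profile log-likelihood to the $\chi^2_1$ half-quantile drop (1.9207 at
95%), re-optimising nuisance parameters at every probe, and flags
one-sided intervals at search bounds. `convert_estimates()` maps $\phi$ to
demographic units with a calibrated per-locus mutation rate
(`calibrate_mu()`, the molecular-clock reading $\hat\mu = \bar k g / (2
t_{div})$): effective sizes $\hat\theta_x/4\hat\mu$, times
$(g/2\hat\mu)\hat T$, forward migrant fraction $\hat\mu \hat M_2 \hat
b/\hat\theta$ and migrant count $\hat M_2 \hat b/2$. `delta_method_ci()`
recomputes the Hessian directly in the conversion parameterisation
$(\theta_a, \theta, \theta_b, \theta_{c1}, \theta_{c2}, T_1, T_1+V, M_2
b/\theta)$ — rather than chain-ruling — and applies the diagonal linear
map to demographic units, so profile endpoints transfer by likelihood-ratio
invariance.

Nested models are compared with `lrt()`. When the null pins parameters to
the boundary (ISO vs IM1, IM1 vs IIM1), the asymptotic null is a mixture
of chi-squares and the naive $\chi^2_r$ p-value is conservative;
`boundary_null_study()` reproduces this by simulation
(simulate-under-null, fit both, collect $D$), warm-starting the
alternative from the null optimum so $D \ge 0$ by construction.
`forward_selection()` walks the ladder and then removes boundary-valued
parameters whose removal costs no likelihood (the IIM2 $\to$ IIM3 step
when $\hat M_1 = 0$).

For linked loci the product likelihood is a composite likelihood:
`godambe_info()` estimates the score covariance from user-supplied blocks
($\hat V = \sum_j U_j U_j^\top$, block scores by central finite
differences) and returns the sandwich covariance $\hat H^{-1}\hat V\hat
H^{-1}$; `block_reduce()` builds the blocks from genome order, discarding
every other block so retained blocks are separated by a full block length
(by default the first block is discarded, so a trailing partial block also
drops out; `keep = "odd"` retains it instead). `robust_lrt()` approximates
the null of the composite LRT by the scaled-shifted chi-square matched to
the first two moments of $\sum_i \omega_i \chi^2_1$, with weights the
eigenvalues of $((H^{-1})_{\psi\psi})^{-1}(\hat G^{-1})_{\psi\psi}$ for the
tested block $\psi$, evaluated at the interior alternative optimum (finite
differences are ill-defined at the boundary null). Whether this
approximation remains conservative for boundary hypotheses is an open
question, so the boundary flag is retained on robust tests.

## The simulator

`simulate_iim_data()` emulates the study design used throughout: locus
states in fixed proportions (default $1/4, 1/4, 1/2$ for states 1, 2, 3),
relative mutation rates drawn once per data set from Gamma(15, 15) (mean
1, sd $\approx 0.26$; a fixed vector can be supplied to reuse rates across
data sets), coalescence times drawn exactly from the piecewise law (inverse
sampling during isolation, a vectorised Gillespie walk through the
migration stage, a shifted exponential beyond $\tau_0$ — no
eigen-decomposition is involved, so the simulator is an independent check
on the analytic densities), and $s \sim
\text{Poisson}(r_j \theta T)$. `simulate_multiepoch_data()` generalises to
an arbitrary list of piecewise-constant two-deme epochs, which is how
gradual-change or secondary-contact misspecification experiments are set
up; the IIM model is its two-epoch special case and the equality of the
two code paths is tested. The two shipped misspecification configurations
are illustrative scenarios, not reproductions of any published figure.

What passing simulation tests does *not* show: robustness to intralocus
recombination, to finite-sites mutation, to errors in the relative rates
(treated as known constants), or to linkage beyond the block structure —
real data violate all of these to some degree.

```{r example}
phi <- phi_vector(theta_a = 1.5, theta = 2, theta_b = 2.5,
                  theta_c1 = 3, theta_c2 = 4, T1 = 2, V = 2,
                  M1 = 0.5, M2 = 0.75)
d <- simulate_iim_data(4000, phi = phi, seed = 1)
fit <- fit_iim(d, "IIM1", n_starts = 2, seed = 1)
fit
```

## Problem sizes used in the shipped checks

The test suite exercises the analytic core against matrix-exponential,
quadrature and high-precision oracles at full accuracy, and keeps
fit-based checks at a few thousand loci with the smaller model masks. The
replicate-recovery and boundary-type-I-error studies run at their design
sizes — five replicate data sets of $4\times 10^4$ loci, three fitting
attempts each, for the nine-parameter model; twenty replicate data sets
of $8\times 10^3$ loci for the boundary study — in the acceptance script,
and in lightly reduced form (smaller boundary-study loci counts) in the
test suite; these sizes keep a complete run in the tens of minutes on one
core while matching the published study design.

## Known limitations

* Two sequences per locus; more lineages, more demes, or time-varying
  rates within a stage are out of scope.
* The infinite-sites assumption; no finite-sites correction is applied.
* Relative mutation rates enter as known constants; their estimation error
  is not propagated.
* Near-flat likelihood ridges at weakly identified generating values make
  single-data-set point estimates of $\theta$ and migration rates
  unstable even with many loci (the model-selection statistics are much
  more stable); profile intervals or replicate medians are the honest
  summaries there.
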