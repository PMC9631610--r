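---
title: "Modelling genomic GC-content evolution with randomly perturbed mutation rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling genomic GC-content evolution with randomly perturbed mutation rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcsde)
```

## The model

Genomes that obey Chargaff's within-strand parity (%A ≈ %T, %G ≈ %C) can
summarise their base composition by a single number, the GC fraction
(GC% = 100% − AT%). For an asexually reproducing, non-recombining
organism, write $F_t \in (0,1)$ for the genomic GC fraction at
(dimensionless) time $t$, $a$ for the AT→GC mutation-rate constant and
$b$ for the GC→AT constant. The deterministic balance of gains
($a F_t$ on the GC fraction) and losses ($b(1-F_t)$ on the AT fraction)
gives

$$\frac{dF_t}{dt} = a F_t + b (1 - F_t),$$

whose solution relaxes exponentially, at rate $a - b$, towards the
equilibrium GC fraction $b/(b-a)$. Throughout, the default regime is
$a - b < 0$: mutation in non-recombining organisms is biased towards AT,
and the 2:1 ratio of GC→AT to AT→GC rates reported for prokaryotes
motivates the canonical parameter choice $a = -2$, $b = 1$ used in the
examples and tests (with the sign convention that $a$ enters the drift
as written above; `rate_parameters()` requires an explicit flag to leave
this regime, but every formula stays valid outside it).

Mutation rates are not constant in a changing environment. Both rates
are perturbed by the *same* Gaussian white noise scaled by a
deterministic, time-varying schedule $c(t) \ge 0$:
$\alpha = a + c(t)W_t$, $\beta = b + c(t)W_t$. Because the GC and AT
fractions sum to one, the perturbation enters the dynamics additively,
and in differential form the model is the linear SDE

$$dF_t = \big(a F_t + b(1 - F_t)\big)\,dt + c(t)\,dB_t.$$

The schedule $c(t)$ is the model's handle on selective pressure: small
$c$ describes tight mismatch-repair control and purifying selection;
growing $c$ describes accumulating, unchecked variability (the regime
associated with genome decay by Muller's ratchet); decaying $c$
describes increasing selective pressure or a bottleneck. The package
ships the four families used throughout: constant $c_0$,
$\kappa\sqrt{t}$, $\kappa(T-t)$ and $\kappa(T-t)^2$ (defaults
$\kappa = 1/2$, $T = 1$, the three canonical non-constant scenarios).

### Closed forms

The integrating factor $Y_t = e^{-(a-b)t}F_t$ reduces the SDE to a pure
stochastic integral and yields the explicit solution

$$F_t = -\frac{b}{a-b} + \Big(F_0 + \frac{b}{a-b}\Big)e^{(a-b)t}
      + \int_0^t c(s)\,e^{(a-b)(t-s)}\,dB_s.$$

The Itô integral has zero mean, so the expectation is the deterministic
trajectory (`expected_gc()`, `deterministic_gc()`), and for $F_0 = 0$ it
reduces to $\frac{b}{a-b}(e^{(a-b)t}-1)$. The variance follows from the
Itô isometry (`variance_gc()`):

$$\mathrm{Var}(F_t) = \int_0^t c(s)^2\, e^{2(a-b)(t-s)}\,ds,$$

which has no closed form for general $c$ and is evaluated by adaptive
quadrature.

## Numerical choices

* **Quadrature.** `variance_gc()` treats $c$ as a black box:
  `stats::integrate()` with absolute tolerance $10^{-10}$, falling back
  to a composite trapezoid rule on $10^4$ nodes if the adaptive rule
  fails. Tests pin the constant-$c$ case to the analytic antiderivative
  at $10^{-8}$ and the non-constant schedules to an independent
  $10^6$-node trapezoid oracle at $10^{-6}$.
* **The removable $a = b$ singularity.** The closed forms are $0/0$ at
  $a = b$; for $|a-b| < 10^{-10}$ the analytic limits are used instead
  ($F_0 + bt$ for the mean, $bx$ for the SNP curve, $\int c^2$ for the
  variance kernel). The model is unchanged; only the evaluation is.
* **Unclamped outputs.** The model statement $0 < F_t < 1$ is an
  interpretation constraint, not something the linear SDE enforces.
  Closed forms and simulated paths are returned unclamped (with a
  warning, and per-path exit flags on ensembles) because clamping would
  silently bias every comparison against the closed forms. An opt-in
  clamp to $[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-6}$, is
  available on the simulators.
* **Itô (left-endpoint) evaluation.** Both simulators evaluate $c$ at
  the left endpoint of each step, the non-anticipating convention the
  calculus above assumes. The discretised stochastic integral uses
  Brownian increments $\Delta B_i \sim N(0, \Delta s)$; the variant
  reading that multiplies the increment by a further $\Delta s_i$ does
  not reproduce the Itô-isometry variance and is available only as a
  debug flag (`literal_increment`) for comparison.
* **Seeding.** All increments are drawn in path-major order from one
  seeded stream, so an ensemble is bit-reproducible from its master
  seed and growing `n_paths` leaves earlier paths untouched. The global
  RNG state is saved and restored around every draw.

## Simulators as mutual oracles

`simulate_em()` implements Euler–Maruyama,
$F_{i+1} = F_i + (aF_i + b(1-F_i))\Delta s + c(s_i)\Delta B_i$. Because
the diffusion coefficient is state-independent the scheme is already
strong order 1.0, and higher-order schemes (Milstein) would add nothing.
`simulate_exact()` samples the transition law of the linear SDE exactly:
deterministic propagation over each step plus a Gaussian innovation
whose variance is the local Itô-isometry integral, precomputed per step.
Its marginals match the closed forms at any resolution — even one step —
which the test suite exploits: the two simulators must agree within
Monte-Carlo error, EM must converge strongly to the exact map of its own
increments as the step halves, and both must reproduce
`expected_gc()` / `variance_gc()` at the canonical scenario parameters.

## The Girsanov layer

With $\varphi \equiv 0$ in the drift-matching equation, the change of
measure that turns $Y_t$ (and hence $F_t$) into a driftless process uses
$u(t) = b/c(t)$ — the *reciprocal* of the schedule. The derivation only
divides by $c(t)$, so strict positivity of $c$ on $[0,T]$ is the actual
requirement; monotonicity (an invertible schedule, the reading suggested
by laboratory-evolution interpretations) is kept as advisory metadata
and a warning, not an error. For deterministic $u$ the Novikov condition
reduces to finiteness of $\exp(\frac12\int_0^T u^2 ds)$
(`novikov_check()`), and the Radon–Nikodym weights
$\log M_T = -\sum u\Delta B - \frac12\sum u^2\Delta s$
(`radon_nikodym_weights()`) are exactly lognormal with mean one.
Weights live in log space and are normalised by a shifted exponential,
because $\int u^2 ds$ grows quickly as $c$ shrinks.

`validate_driftless()` is the operational statement of the theorem:
reweighting terminal increments of $Y_t = e^{-(a-b)t}F_t$ by $M_T$ must
produce a drift statistically indistinguishable from zero ("GC content
as likely to increase as to decrease"), while the unweighted drift
equals $\int_0^T b e^{-(a-b)s}ds$ — for the canonical scenario with
$c \equiv 1/2$, that is $(e^3-1)/3 \approx 6.36$ against a weighted
drift within four (weighted) standard errors of zero. Standard errors
for weighted means use the effective sample size $(\sum w)^2/\sum w^2$;
at $u = 2$ the weights carry log-variance 4 and the effective sample is
roughly $e^{-4} n$, which the chosen $n = 10^5$ accommodates.

## The Luria–Delbrück connection

Setting the GC→AT rate to zero turns the balance equation into
stochastic exponential population growth with rate $k + pW_t$; its Itô
solution is geometric Brownian motion, and scaling by the per-capita
mutation rate $\mu$ gives the mutation-count process

$$M_t = P_0\,\mu\,\exp\Big(\big(k - \tfrac{p^2}{2}\big)t + pB_t\Big),$$

a stochastic, continuous-time version of the classical
Luria–Delbrück fluctuation model. `simulate_mutations()` uses the exact
lognormal step, so $E[M_t] = P_0\mu e^{kt}$ and
$\mathrm{Var}[M_t] = (P_0\mu)^2 e^{2kt}(e^{p^2t}-1)$ hold at every grid
time. The canonical scenarios are $P_0 = 1$, $\mu = 5$, $k = 1$ with
$p \in \{1/2, \sqrt2, 2\}$; as $k$ approaches $p^2/2$ the median path
flattens while the mean keeps growing — the regime where random
fluctuation, not growth, dominates mutation accumulation, which the
tests assert as a decreasing median/mean ratio in $p$.

Two testing choices are worth stating. The raw sample variance of a
lognormal with log-variance $p^2 t = 4$ (the $p = 2$ scenario) has a
sampling error governed by eighth moments ($\sim e^{16}$) and carries no
power at any feasible ensemble size, so the variance identity is tested
on the log scale (mean and variance of $\log M_t$, an equivalent
statement) for all three $p$, and on the raw scale only at $p = 1/2$.
The heavy-tailed sample *mean* at $p = 2$ does remain within its 4·SE
band at $n = 10^5$.

Counts are continuous intensities throughout, as in the model;
`poisson_mutation_counts()` is a clearly-labelled integer overlay for
fluctuation-style analyses, not part of the model. The AT/GC split
(`decompose_mutations()`) multiplies the balance terms by the genome
size and takes moduli, $M^{GC} = |g\alpha F_t|$,
$M^{AT} = |g\beta(1-F_t)|$, so the decomposition conserves the total
regardless of rate signs; by default the unperturbed constants $a$, $b$
stand in for $\alpha$, $\beta$ (whether the instantaneous white-noise
perturbation should be included is left to the caller, who can pass
perturbed per-instant rates instead).

## Estimating the rates from SNP data

Because the Brownian term vanishes in expectation, the $F_0 = 0$
expectation curve evaluated at the core-genome GC fraction $x$ in place
of $t$,

$$f(x) = \frac{b}{a-b}\big(e^{(a-b)x} - 1\big),$$

is the model for SNP GC content against core-genome GC content, and $a$,
$b$ can be estimated without ever touching the stochastic term. The
time/GC-fraction identification is used as stated, without unit
conversion — both are dimensionless. `fit_rates()` performs weighted
nonlinear least squares with Levenberg–Marquardt, an analytic Jacobian,
and the reparameterisation $a = b - e^{\delta}$ that keeps the fit in
the $a < b$ regime while letting it approach $a = b$ smoothly (data from
the boundary regime fit without failure; $\hat a \to \hat b$ from
below). Standard errors come from the Gauss–Newton covariance via the
delta method. $F_0 = 0$ is fixed, not fitted: the SNP curve is defined
by the zero-initial-condition expectation.

`generate_snp_data()` makes parameter recovery testable with no external
data: $x$ uniform on a sub-interval of $(0,1)$, additive Gaussian
observation noise truncated to $[0,1]$. Gaussian noise is the
least-structured choice consistent with least squares; truncation keeps
observations in the admissible range. What the generator deliberately
does *not* emulate: phylogenetic correlation between species,
heteroscedastic measurement error, or non-uniform coverage of the
GC range — recovery results on synthetic data therefore demonstrate
correctness of the estimator, not robustness to real comparative data.
The default test conditions are $n = 200$ observations at noise SD 0.01
(recovery within 10%), $n = 50$ noise-free (recovery to $10^{-6}$), and
200 replicates for the bias check.

## Problem sizes

The test suite and the reproduction script use $10^4$ paths (with 1000
Euler steps) for mean/variance recovery of the GC process, $10^5$ paths
(200 steps) for the Girsanov validation where importance weights shrink
the effective sample, $10^5$ paths (50 steps) for the mutation-count
moments, and $2\times10^5$–$10^6$ quadrature nodes for brute-force
variance oracles. These sizes put every 4·SE Monte-Carlo band well
inside the tolerances being asserted while keeping a full run in the
low minutes on one core.

## Limitations

* The model treats $a$ and $b$ as constants; time-varying rate
  *constants* (as opposed to the white-noise perturbation) are out of
  scope.
* Paths are not reflected or absorbed at the (0,1) boundary; for large
  $c$ the linear SDE happily leaves the admissible range, and the
  package reports rather than represses this.
* The estimation layer fits the expectation curve only; it does not
  model SNP-calling error, core-genome construction, or phylogenetic
  non-independence.
* The Girsanov machinery covers deterministic drifts $u(t) = b/c(t)$;
  path-dependent drifts (stochastic $c$) are out of scope.
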