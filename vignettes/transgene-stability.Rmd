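---
title: "Estimating mutation and selection behind transgene loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mutation and selection behind transgene loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transloss)
library(ggplot2)
set.seed(2026)
```

## The problem

Microbes engineered to carry a foreign transgene usually pay for it: the
insert is at best neutral and often costly, and mutants that delete or
silence it grow faster. Under extended propagation the engineering is
therefore transient. Two distinct forces set its lifespan — the
per-replication probability $\mu$ that an engineered parent produces a
transgene-free (*revertant*) offspring, and the selection coefficient $s$ by
which carriage reduces the per-capita growth rate. Knowing *which* force
dominates matters practically: a high loss rate calls for removing the
mutational hot-spots, a high cost for cheaper constructs. `transloss`
estimates both jointly from the kind of data stability assays already
produce: serial-transfer experiments in which $n$ individuals are genotyped
at each transfer and $x$ of them still carry the transgene.

## The model

Within a culture, engineered ($N_E$) and revertant ($N_R$) individuals grow
logistically, with mutation acting as a redirected birth (no back
mutation):

$$
\frac{dN_E}{dt} = r(1-s)\,N_E\left(1-\tfrac{N}{K}\right)(1-\mu),\qquad
\frac{dN_R}{dt} = r\,N_R\left(1-\tfrac{N}{K}\right)
 + r(1-s)\,N_E\left(1-\tfrac{N}{K}\right)\mu,
$$

with $N = N_E+N_R$ and carrying capacity $K$. While the population is large
enough for drift to be negligible yet far below $K$, the transgene frequency
$p = N_E/N$ obeys $dp/dt = -rp\,[\mu + s(1-p-\mu)]$, which integrates to the
closed form implemented in `frequency_trajectory()`:

$$
p(t) = \frac{p_0\,a\,e^{-rat}}{\mu + s\left[1-\mu-p_0(1-e^{-rat})\right]},
\qquad a = s(1-\mu)+\mu .
$$

Genotyping counts are binomial, $x_j \sim \mathrm{Bin}(n_j,\,p(t_j))$, and
replicates are independent lineages sharing $(\mu, s, r, p_0)$, so the
log-likelihood is a sum over all samples. `fit_mle()` minimises its
negative; the growth rate $r$ must be supplied (it is not identifiable from
frequencies alone), and a misassigned $r$ biases both estimates in the
opposite direction to the error — a property the test suite checks.

From a pure culture the evolutionary half-life — the time until half the
population has lost the transgene — is

$$
t_{50} = \frac{\ln\!\left(\dfrac{\mu(1-s)}{\mu(1-s)+s(1-\mu)+\mu}\right)}
  {-r\,[s(1-\mu)+\mu]},
$$

reducing to $\ln 2/(r\mu) \approx 0.7/(r\mu)$ when $s=0$.
`half_life_gain()` turns this into an engineering planning tool: the ratio
of half-lives after dividing $\mu$ by $k_\mu$ and $s$ by $k_s$ shows whether
effort is better spent on the loss rate or on the cost (near-vertical
contour isoclines mean mutation-dominated, near-horizontal mean
selection-dominated).

```{r gain-grid, fig.width = 5, fig.height = 3.5}
base <- model_params(r = 0.1, s = 0.1, mu = 1e-4)
plot_gain_grid(half_life_gain_grid(base, k_max = 100, n = 25))
```

## Worked example

```{r example}
truth <- model_params(r = 0.1, s = 0.08, mu = 5e-3, K = 2e6)
design <- transfer_design(duration = 720, seed = 11)
counts <- simulate_experiment(truth, design)
fit <- fit_mle(counts, r = 0.1, compute_ci = TRUE)
tidy(fit)
glance(fit)
```

```{r fit-plot, fig.width = 5, fig.height = 3.5}
autoplot(fit)
```

The grey ribbon is the binomial sampling envelope at the fitted parameters
(`fit_envelope()`): observed frequencies falling outside it indicate model
violations such as several distinct revertant classes, in which case the
estimates should be treated with caution.

## The stochastic simulator

`simulate_experiment()` generates the same kind of data stochastically and
is both the validation engine and the test-fixture factory. Each culture is
advanced by midpoint tau-leaping over the three birth reactions implied by
the growth model — engineered birth, mutational birth (engineered parent,
revertant offspring) and revertant birth, each with the logistic factor
clamped at zero. Numerical choices, made once:

* **Leap control.** The leap is capped at 0.5 h and shortened so the
  expected number of births changes neither the population nor its headroom
  below $K$ by more than 5%. Propensities are re-evaluated at the expected
  mid-leap state; this midpoint rule removes the $O(\tau)$ downward bias in
  realised evolution that a plain Poisson leap leaves behind (with $r=0.1$
  and $\tau=0.5$ h a plain leap under-evolves frequencies by roughly 2% per
  cycle, which is visible against Monte-Carlo error).
* **Exact fallback.** Below 1000 individuals the exact Gillespie algorithm
  is used; leap approximations are worst exactly where bottleneck cultures
  are small.
* **Transfers.** Bottlenecks are hypergeometric draws of $\beta$ founders
  from the culture, and the genotyped $n$ are drawn from those founders; if
  $\beta$ exceeds the population the whole culture transfers. The time-0
  sample is drawn from the founding culture itself, so pure cultures give
  $x_0 = n$ deterministically.
* **Seeding.** One master seed spawns independent per-replicate streams,
  recorded in the output metadata; a fixed seed reproduces counts exactly.

Defaults mirror a cytomegalovirus-motivated protocol: $r=0.1$/h, $K=2\times
10^6$, 24 h between transfers, $\beta = 10^4$ founders, $n=100$ genotyped,
3 replicates, 150 days. The simulator emulates demographic stochasticity,
bottleneck drift and binomial genotyping; it does **not** emulate deaths,
multiple revertant classes, culture adaptation, or within-host spatial
structure — so passing validation says the estimator works when its model
is true, not that real data obey the model.

## Validation by parameter recovery

`recovery_study()` repeats the published validation protocol: draw truths
($s \sim U(0.005, 0.2)$; $\mu \sim$ Gamma, shape 10, mode $1.5^i \times
10^{-5}$ growing with the dataset index $i$), simulate, re-estimate, and
regress estimates on truth. Literal Gamma modes exceed 1 for $i \gtrsim 29$,
which is not a probability; draws are capped at 0.1 — the upper end of the
range the estimator can resolve under daily transfers — and the cap is
flagged per dataset. With 24-h transfers both regression slopes sit near 1
(bundled 50-dataset runs give $0.96\!-\!0.98$ for $\mu$ and $0.95\!-\!1.0$
for $s$); with 72-h transfers cultures saturate at $K$, realised evolution slows
while the estimator assumes exponential growth, and both slopes drop by
roughly a quarter. The package's acceptance checks recompute these slopes
from scratch.

## Estimation details

* **Optimisation.** `optim(method = "L-BFGS-B")` on $(\log_{10}\mu,\, s)$
  with bounds $\mu \in [10^{-9}, 0.5]$, $s \in [0, 0.95]$, from a $5\times5$
  multistart grid ($\mu$: $10^{-7}\dots10^{-1}$ log-spaced; $s$:
  $0.005\dots0.5$); convergence tolerance $10^{-10}$ on the NLL via
  `factr`. Inside the optimiser, probabilities are clamped to
  $[10^{-300}, 1-10^{-12}]$ so the surface stays finite; the reported NLL
  is recomputed unclamped at the optimum. Estimates pinned at bounds are
  flagged rather than hidden, and all-engineered data (no loss signal)
  yield $\hat\mu$ at its lower bound with an explicit
  `s_unidentifiable` flag.
* **Initial frequency.** By default $p_0$ is the pooled time-0 sample
  frequency, treated as known (the time-0 term then contributes a constant
  and is retained for reporting). Alternatives: fix $p_0 = 1$, supply a
  number, or free it as a third parameter — useful for gauging sensitivity
  to impure starting cultures, whose main effect is underestimating $s$.
* **Confidence intervals.** Profile likelihood at the $\chi^2_1$ 95% cutoff
  (1.92 NLL units), endpoints by root finding, clipped at the parameter
  bounds with a flag. The intervals are approximate in a specific sense:
  they treat all dispersion as independent binomial sampling, which is
  exact when counts are drawn from the frequency curve (simulated coverage
  then sits at the nominal 95%), but serial-transfer bottlenecks add
  correlated drift around the deterministic trajectory that the likelihood
  does not model, so on drift-affected series the intervals are too narrow
  and undercover. Treat them as likelihood-curvature summaries, not
  guaranteed frequentist coverage.
* **Numerics.** Binomial coefficients via `dbinom`'s log-gamma path (no
  overflow at $n = 10^6$); the closed form for $p(t)$ is arranged so the
  exponential underflows gracefully to 0 at large $t$ and the $\mu = 0$,
  $p_0 = 1$ case stays exactly 1; the degenerate $s=\mu=0$ case returns
  $p_0$ (its continuous limit); `half_life()` returns 0 for starts already
  at or below one half, so gain grids never abort.

## The per-transfer alternative

When within-culture growth is unknown or non-exponential (viral passages
with latent phases, transfers inside host organisms), `fit_mle_discrete()`
drops the growth model entirely. One transfer cycle multiplies engineered
weight by $(1-S)(1-U)$ against revertant weight 1:

$$
p' = \frac{p(1-S)(1-U)}{p(1-S) + (1-p)} ,
$$

the standard discrete mutation–selection recursion with loss applied to
engineered offspring; it is a reconstruction chosen because one cycle
matches the continuous closed form to $O(\text{parameter}^2)$ under
$U = 1-e^{-rT\mu}$, $S = 1-e^{-rT s}$. Only the cycle index enters, so
transfers must be equally spaced. $(\hat U, \hat S)$ are per cycle and must
not be compared numerically with the per-hour $(\hat\mu, \hat s)$ — though
which force dominates should agree between engines, and the half-life it
reports is in transfer cycles.

## Problem sizes and limitations

The bundled checks use one 50-dataset recovery batch per transfer interval,
200-seed simulator calibrations, and a 100-dataset coverage run — sizes at
which the Monte-Carlo error of each summary is small against the effect
being demonstrated. Known limitations, inherited from the model: a single
revertant class (the first large-effect mutation dominates estimates);
selection tied to growth rate (growth confounded with clearance in vivo
shifts $\mu$, $s$ and $r$ jointly, though $t_{50}$ is more robust); $r$
must be supplied; and continuous-time estimates assume transfers frequent
enough that cultures never approach $K$ — the 72-h validation scenario
quantifies exactly what happens when they do.
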