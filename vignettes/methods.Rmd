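---
title: "Models and methods in neuralwm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in neuralwm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In continuous-report working-memory tasks an observer reproduces a
remembered stimulus feature — here orientation — on an analog circular
scale. Recall error grows with the number of memoranda (set size), and
it also varies with the *value* of the target: orientations near the
cardinal axes are recalled more precisely, and responses are repelled
away from the cardinals toward the obliques. `neuralwm` implements a
population-coding account of both effects, a discrete-capacity
competitor, the machinery to fit and compare them on trial tables, and
generators for synthetic observers and adaptation experiments.

Orientations in files live on $[-90^\circ, 90^\circ)$ and are mapped
internally to $[-\pi, \pi)$ radians by $\theta = \theta_{deg}\pi/90$;
every quantity below is in mapped radians.

## The neural resource model with efficient coding

Encoding uses $M$ neurons (default 100) with von Mises tuning of
shared basis width $\kappa$. Efficient coding enters as a remapping of
the stimulus through the cumulative distribution function $D(\theta)$
of the environmental stimulus distribution $p(\theta)$ (the *prior*):

$$f_i(\theta) = \exp\{\kappa(\cos(F(\theta) - \phi_i) - 1)\}, \qquad
F(\theta) = 2\pi D(\theta) - \pi,$$

with preferred phases $\phi_i$ evenly spaced. Where the prior is dense
the map $F$ is steep, so more neurons (with narrower effective tuning)
cover cardinal orientations. The gain prefactor of the classical
tuning equation is absorbed by normalization, so tuning is implemented
peak-one; this is mathematically equivalent after the divisive step
and numerically stabler.

Divisive normalization fixes total activity per trial: with $N$ items,

$$r_i(\theta) = \frac{\gamma}{N}\,
  \frac{f_i(\theta)}{\sum_j f_j(\theta)}.$$

We divide by the instantaneous population sum rather than a constant,
so $\sum_i r_i = \gamma/N$ holds *exactly* at finite $M$ (the paper
tier of models appeals to the large-$M$ constancy of the sum; both
agree as $M \to \infty$). Spiking is independent Poisson over a unit
interval, and decoding evaluates the posterior
$p(\theta\,|\,\mathbf n) \propto L(\theta\,|\,\mathbf n)\,p(\theta)$
on 100 evenly spaced points and reports its **circular** mean (the
arithmetic mean is ill-defined on the circle). The same prior thus
shapes both encoding and decoding. The default prior is the bimodal
cardinal-peaked density $p(\theta) \propto 2 - |\sin\theta|$, which
matches the distribution of orientations in natural images and is also
the congruent nontarget distribution of the adaptation design.

Free parameters for fitting: $\gamma$ (population gain) and $\kappa$
(basis tuning width). The model produces, with no further parameters,
repulsive bias away from cardinals growing with set size, and
cardinal-over-oblique precision advantages shrinking with set size.

### Numerical choices

* Rates are floored at $10^{-12}$ inside logarithms; $\kappa$ up to 10
  underflows tuning tails at far-flank angles.
* A posterior whose resultant is numerically zero (e.g. zero spikes
  under a uniform prior) carries no directional information; the
  decoder returns a uniform random angle and flags it, which is the
  behavioural reading of an uninformative posterior.
* Built-in priors use closed-form densities and CDFs; `custom` priors
  tabulate the CDF on 4096 intervals (configurable) with monotone
  interpolation. Note that the $2-|\sin\theta|$ prior has derivative
  kinks at the cardinals, so quadratures of different resolution agree
  only to $\sim 10^{-4}$ there; exactness checks of the decoder are
  run with smooth priors, where the 100-point periodic trapezoid rule
  converges spectrally and matches a $10^4$-point reference to
  $10^{-8}$.

## The slots-plus-averaging competitor

The extended discrete-capacity model stores items in $K$ fixed-
precision slots distributed as evenly as possible; an item holding $S$
slots is recalled with von Mises concentration $S\,\kappa_1$ (the
high-concentration Gaussian approximation, taken at face value as in
its source), items holding none are answered uniformly at random with
rate $g_N = 1 - K/N$. Stimulus-specific structure is grafted on with
two trigonometric modulators:

$$\kappa_1(\theta) = \kappa_1\,(1 - \lambda|\sin\theta|), \qquad
\mu(\theta) = \eta\,\sin(2\theta),$$

giving the response density

$$p(\hat\theta\,|\,\theta) = (1 - g_N)\,
\mathrm{VM}\!\big(\hat\theta;\ \theta + \mu(\theta),\
\kappa_n(\theta, N)\big) + \frac{g_N}{2\pi}.$$

The exact printed forms of the two modulators are not recoverable from
the source rendering; the forms above were chosen because $\mu$ is
stated verbatim for the contamination model (which the source reuses
for bias), and $1 - \lambda|\sin\theta|$ spans the fitted
$\lambda \in [0,1]$ grid exactly while putting maximal precision at
the cardinals. Both are isolated in single functions and swappable.
When modulation drives $\kappa_1(\theta)$ to zero it is floored at
$10^{-3}$. Note the structural contrast with the neural model: the
bias offset here is identical at every set size, and bias and
precision are free to vary independently.

## Fitting and comparison

Both models are fit by maximizing a **binned** likelihood: a $J \times
Q$ ($25 \times 25$) stimulus-by-response probability matrix per set
size. For the neural model each matrix row is a Monte-Carlo histogram
of decoded responses ($10^4$ per stimulus value at reference scale);
every cell receives a 0.5 pseudo-count before row normalization so an
observer response in a rare bin cannot contribute $-\infty$. Targets
are assigned to the nearest stimulus bin center (the minimal-
distortion reading of binning observer responses "in the same way").
The slots-plus-averaging likelihood is computed analytically — bin
probabilities by midpoint quadrature of the response density over each
response bin — which is exact, fast, and equal in expectation to the
simulation estimate; a simulation path is retained behind
`method = "simulate"`.

Grid search covers $\kappa \in [0.1, 10] \times \gamma \in \{1..100\}$
(neural, $100 \times 100$) and $K \times \kappa_1 \times \eta \times
\lambda$ (SPA) at 0.1 steps. The RNG is re-seeded identically before
every neural grid point (common random numbers), which removes
simulation jitter from likelihood *differences* across the grid and
makes fits bit-reproducible. Two further refinements matter for the
stochastic (neural) surface. First, the plug-in $\log \hat p$ of a
histogram estimate is biased by $-(1-p)/(2np)$, and the bias differs
across grid cells — enough to tilt a flat likelihood ridge by a few
log-units at moderate `reps`; the grid evaluator applies the
delta-method correction $+(1-\hat p)/(2n\hat p)$ uniformly. Second,
`fit_grid(refine_top = k)` runs a cheap screening pass and
re-evaluates the $k$ best cells at higher `refine_reps`, a budgeted
approximation to running the whole grid at reference fidelity.

Identifiability caveat: $\kappa$ and $\gamma$ trade off along a flat
ridge (wider tuning, more spikes), and at a few hundred trials per set
size the Kullback–Leibler separation between ridge neighbours one
coarse grid step apart is only a handful of log-units over a whole
dataset, so grid-recovery of both parameters is near the estimator's
resolution limit at those sizes. Recovery tests place synthetic
targets on the 25 stimulus-bin centers; with continuously uniform
targets, nearest-center assignment injects within-bin jitter
comparable to the $N = 1$ decode SD and biases the fit along the
ridge.

Test and example fits use coarser grids (flagged `reduced = TRUE` in
the result) and 500 Monte-Carlo reps per stimulus bin with a
`refine_top` pass at the reference $10^4$ reps, where the full
reference grid at full fidelity would take hours on one CPU. Model
comparison uses
$\mathrm{AIC} = -2\ln\mathcal L + 2P$ ($P = 2$ neural, $P = 4$ SPA),
with $\Delta\mathrm{AIC} = \mathrm{AIC}_{neural} -
\mathrm{AIC}_{spa}$, negative favoring the neural model.

## Descriptive curves

Bias and precision as functions of target orientation are estimated at
50 evenly spaced points with von Mises kernel weights; the kernel
concentration solves $I_1(\kappa)/I_0(\kappa) = e^{-h^2/2}$ so its
circular SD equals the stated bandwidth ($h = 0.61$ for bias, $0.23$
for precision — bias curves are noisier and get the broader kernel).
Weights are renormalized at each evaluation point, as the weighted
circular mean implies. Precision is $1/\sigma^2$ of the weighted
circular SD, capped at $10^{12}$ (i.e. $\sigma = 10^{-6}$) for
degenerate concentrations so downstream tables stay finite. Smoothing
is per observer and is for display only — fitting always uses raw
responses.

## The contamination mixture and the adaptation analysis

Block-wise bias is denoised with a purely statistical mixture: errors
$\Delta\hat\theta$ follow
$\lambda\,\mathrm{VM}(\Delta\hat\theta;\ \eta\sin(2\theta),\ \kappa) +
(1-\lambda)/2\pi$, with $\eta > 0$ meaning repulsion from the
cardinals. $\lambda$ multiplies the von Mises (memory) component —
the source states only "$\lambda$ is the mixture weight", so the
convention is fixed here and carried through everywhere. No
psychological meaning is attached to $\lambda$ or $\kappa$.

Fitting is Nelder–Mead on unconstrained transforms
($\log\kappa$, $\eta$, $\mathrm{logit}\,\lambda$) from 100 random
starts ($\kappa \sim U(0.5,20)$, $\eta \sim U(-0.5,0.5)$,
$\lambda \sim U(0.5,1)$; start ranges are this package's choice, the
source is silent). Per-subject summaries are the block-8 minus block-1
contrast and the OLS slope of $\hat\eta$ over adaptation blocks 2–7.
Group-level mixed-effects inference is deliberately out of scope.

## What the synthetic generators emulate — and what they do not

`gen_observer` mirrors the layout of the three fitted datasets:
uniform targets, set sizes such as $\{1,2,4,8\}$ or $\{1,2,3,6\}$,
hundreds of trials per condition, responses from either generative
model. `gen_adaptation_experiment` reproduces the adaptation design:
8 blocks × 72 trials of 4-item arrays, uniform targets throughout,
nontargets uniform in blocks 1 and 8 and drawn from
$\propto 2-|\cos\theta|$ (incongruent) or $\propto 2-|\sin\theta|$
(congruent) during blocks 2–7. Two response backends exist: a
phenomenological per-block mixture schedule (fast; used in recovery
tests, with $\eta$ falling linearly 0.2 → 0.03 across adaptation — the
reported per-block adaptation rate — and persisting into block 8), and
a mechanistic one in which per-block
priors interpolate between the natural prior and the adaptation
distribution. The interpolation weights are a knob, not a theory: no
dynamic model of prior adaptation is implied, because none is
specified anywhere authoritative.

The generators do **not** emulate: spatial array positions (no
in-scope analysis uses them), swap errors, response times, fixation
control, or subject heterogeneity beyond what parameters encode. A
green recovery test therefore establishes self-consistency of the
pipeline under the stated generative world — not that human data would
yield the same numbers.

Sizes used in stochastic tests were fixed from the designs above or by
a priori power analysis (e.g. null-calibration blocks of 500 trials
give $\mathrm{SE}(\hat\eta) \approx 0.022$, so $|\hat\eta| < 0.05$
holds with probability $\approx 0.97$ per replicate) and were not
adjusted after observing test outcomes.

## Known limitations

* The exact parametric form of the natural-image prior in the source
  is unrecoverable; $2-|\sin\theta|$ is adopted as stated for the
  congruent experimental distribution. Sharper cardinal peaks are a
  one-line `custom` prior away.
* The binned neural likelihood is a Monte-Carlo estimate; with common
  random numbers it is reproducible but still biased by the 0.5
  pseudo-count floor at small `reps`.
* The SPA precision-additivity approximation fails at low
  concentrations; it is retained deliberately for fidelity to the
  competitor being emulated.
* Decoder exactness to $10^{-8}$ against dense quadrature holds for
  smooth priors; kinked priors limit cross-resolution agreement to the
  quadrature order, not to machine precision.
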