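---
title: "Multi-state diffusion analysis of noisy single-particle tracks"
author: "TrackStates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-state diffusion analysis of noisy single-particle tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TrackStates)
```

## The problem

Single-particle tracking follows individual fluorescently labelled
molecules through microscopy movies. Many membrane and DNA-binding proteins
switch between motion states — typically a bound (immobile) state and one or
more freely diffusing states — on time scales of a few frames. Two features
make such data hard to analyse:

* **Localization error.** Each observed position is the true position plus
  a Gaussian error of SD $\sigma$ (typically 20 nm). When the per-frame
  diffusion length $d = \sqrt{2 D \Delta t}$ is comparable to $\sigma$,
  single displacements of bound and mobile molecules are statistically
  almost indistinguishable.
* **Short tracks and fast transitions.** Bleaching and defocalization cut
  tracks to a handful of positions, and molecules may switch state every
  few frames, so time-averaged statistics (MSD fits) cannot be applied per
  molecule.

The remedy is to model the *whole* track probabilistically. Consecutive
positions of an immobile molecule scatter independently around one point,
while consecutive positions of a diffusing molecule are nearly uncorrelated;
the full spatio-temporal correlation structure separates the states even
when single displacements cannot.

## The model

A track is a sequence of observed positions $C = (c_1,\dots,c_n)$ at frame
interval $\Delta t$. Hidden behind it are the true positions
$R = (r_1,\dots,r_n)$ and the motion states $B = (b_1,\dots,b_n)$ of a
continuous-time Markov chain with $N$ states. The model parameters are
$\theta = (\sigma, d_i, F_i, k_{ij})$: the localization error, per-state
diffusion lengths, initial state fractions, and transition rates (stored
per frame; multiply by $1/\Delta t$ for rates per second). The track
density factorizes as

$$f(C,B,R\mid\theta) \;=\; \underbrace{F_{b_1}\prod_i p_{b_i b_{i+1}}}_{\beta,
\text{ state prior}} \;\times\; \prod_i f_{\delta_i}(r_{i+1}-r_i)
\;\times\; \prod_i f_\sigma(c_i-r_i),$$

where $f_x$ denotes a centred Gaussian density of SD $x$. Two conventions
matter:

* **Mid-step transitions.** The displacement SD of step $i$ mixes the
  flanking states, $\delta_i = \sqrt{(d_{b_i}^2 + d_{b_{i+1}}^2)/2}$.
  Attributing the whole step to the departing state systematically
  overestimates time spent diffusing and underestimates binding rates at
  fast switching.
* **Per-pair transition probabilities.** By default
  $p_{ij} = 1 - e^{-k_{ij}}$ for $i \ne j$ (diagonal as remainder). This
  slightly damped conversion compensates the residual bias of the mid-step
  discretization; the exact generator exponential $P = e^{G\Delta t}$
  (`transitionMode = "generator"`, via `Matrix::expm`) is available and both
  agree to first order in $k$.

### Integrating out the hidden positions

For a fixed state sequence the integral over $R$ is a chain of Gaussian
convolutions and products with closed-form updates
(`recursionStep()`): carrying a belief $(\mu_i, s_i^2)$ about the next true
position plus an accumulated log-weight,

$$s_i^2 = \frac{\delta_i^2\sigma^2 + \delta_i^2 s_{i-1}^2 + \sigma^2
s_{i-1}^2}{\sigma^2 + s_{i-1}^2},\qquad
\mu_i = \frac{\mu_{i-1}\sigma^2 + c_i s_{i-1}^2}{\sigma^2 + s_{i-1}^2},$$

with log-weight increment equal to the log Gaussian density of
$c_i - \mu_{i-1}$ with variance $\sigma^2 + s_{i-1}^2$. Axes are
independent, so 2D/3D tracks multiply per-axis densities under one shared
state prior. The uniform prior over the first true position is dropped,
which makes every computed density invariant under translations — tested
explicitly. Per-frame localization-error scales (e.g. from photon counts)
simply rescale $\sigma$ at that frame.

### The sliding window over state sequences

Summing over all $N^n$ state sequences is intractable for long tracks, but
the belief about the current position barely depends on the state many
frames ago. The engine therefore merges sequences that share their last
$m$ (sub-)states into a single belief, with merge weights $\alpha$
proportional to each branch's joint density: $\mu^* = \sum\alpha\mu$,
$s^{*2} = \sum\alpha s^2$ (averaging variances, not SDs), and weights
adding. The cost is $O(n N^{m+1})$. Merging is *lazy*: a branch is only
collapsed when the next expansion needs the room, so for $m \ge n-1$ the
sum is exact — the test suite holds this to $10^{-10}$ against exhaustive
enumeration, and uses it as the reference to show the approximation error
decreases monotonically with $m$ (at $m = 5$ the mean per-track error is of
order $10^{-3}$ in log density; individual ambiguous tracks can deviate
more, which is why windows of 7 (2 states) / 5 (3 states) / 4 (more) are
the fitting defaults and annotation defaults to 10).

All weights live in log space with log-sum-exp stabilization; the raw
per-sequence weights underflow beyond roughly 50 frames otherwise.

### Sub-steps

With `substeps = u` each frame interval is divided into $u$ sub-intervals:
the state chain runs at the finer resolution (per-sub-step probabilities
from rates $k/u$), observations attach to every $u$-th sub-state, and the
per-frame displacement SD becomes
$\delta_i = \sqrt{\sum_k \delta_{i,k}^2 / u}$ over the sub-steps. This
represents multiple transitions per frame and transition times away from
the mid-point; it is recommended when fitted rates exceed about 0.4 per
frame, and it measurably improves the calibration of per-frame state
probabilities even at moderate rates (the window is counted in sub-steps,
so double it when doubling $u$). The window should not be shorter than $u$;
`likelihoodConfig()` warns otherwise.

### Finite field of view

Diffusive molecules leave the observable region (TIRF stripe, focal depth),
so long tracks over-represent slow molecules ("defocalization bias"). With
`fovCorrection = TRUE` each sequence's density is multiplied by the
probability of observing exactly this track length:
$(1-p_K)^{n-1}\prod_i (1-p_L(\delta_i)) \cdot
[p_K + (1-p_K) p_L(\delta_n)]$, with $p_K$ a state-independent per-frame
termination probability (bleaching, detection loss) and $p_L(\delta)$ the
probability that a molecule at a uniformly random position inside an
observable length $l$ steps outside it:

$$p_L(\delta) = 1 - \frac1l\int_0^l
\left[\Phi\!\left(\frac{l-x}{\delta}\right) -
\Phi\!\left(\frac{-x}{\delta}\right)\right]dx,$$

evaluated in closed form through $G(t) = t\Phi(t) + \phi(t)$. Two choices
here are deliberate: the integral is normalized by $1/l$ so that $p_L$ is a
probability under the stated uniform-position assumption, and the final
factor's $\delta_n$ uses the diffusion length of the sequence's last state,
applied inside each per-sequence weight rather than as a global
post-factor, because the track-length factor multiplies the per-sequence
densities. Several finite axes combine as
$1 - \prod_a (1 - p_{L,a})$.

Two consistency factors complete the track-length model. First, analyses
keep only tracks of at least `fovMinLen` positions (3 by default, matching
the input filter), so each track's density is conditioned on
$P(n \ge \mathrm{minLen} \mid \theta)$, computed by a short survival
recursion over states; without this factor the silently discarded short
tracks pull fits toward immobile-rich parameters (on data generated
exactly from the termination model, the initial immobile fraction fits at
0.74 instead of 0.5). Second, tracks whose length equals `fovMaxLen` (the
movie length or analysis cap) are censored by the end of the observation,
not terminated, and receive no final termination bracket.

Known residual limits of the correction, measured on the membrane-geometry
simulations: with the observable width at 2–3 diffusion lengths the
correction removes the gross binding-rate inflation (from $\sim$40%
error to under 10%) and keeps the mobile diffusion length within 10%, but
the *unbinding* rate stays $\sim$25% low. Two mechanisms, both consequences
of approximations the method makes by design, explain this: the
uniform-position form of $p_L$ ignores that surviving mobile molecules are
depleted near the view boundary and that re-entering molecules start right
at it; and a sequence ending in the immobile state has $p_L(0) = 0$, so
unbind-and-exit track endings cannot be attributed to the exit channel.
Estimates of the unbinding rate from view-limited geometries should
therefore be treated as lower bounds at small view widths.

## Fitting

`fitTracks()` maximizes the summed log density over all tracks with
Powell's derivative-free direction-set method (implemented in the package,
with Brent line searches and the standard direction-replacement rule;
Nelder–Mead is available as a fallback). The search runs in transformed
coordinates — $\log\sigma$, $\sqrt{d_i}$ (so $d = x^2$ can reach exactly
0), $\log k_{ij}$, additive log-ratios for free fractions, logit for
$p_K$ — and any subset of parameters can be fixed. Initial fractions can be
tied to the steady state of the rates; the default keeps them free for
two-state models (where the initial immobile fraction is a quantity of
interest) and ties them for three or more states. Convergence uses a
relative function tolerance of $10^{-6}$ with a budget of 1000 evaluations
per free parameter; a typical two-state fit converges in 5–8 direction-set
iterations (400–600 evaluations). Fitted states are re-sorted by ascending
$d$ so replicate comparisons are label-stable.

The default starting point is data-driven but deliberately crude: $\sigma$
from the lower quartile of squared one-frame displacements (immobile
molecules dominate there, $E[\Delta c^2] = 2\sigma^2$), diffusion lengths
from quantiles of per-track mean squared displacements, all rates at 0.05
per frame, uniform fractions. Recovery is insensitive to the start —
initial $d/\sigma$ anywhere between 0.3 and 10 reaches the same optimum in
the tests.

Identifiability diagnostics come from `profileObjective()` (log-likelihood
along one parameter) and dispersion estimates from `splitReplicates()` +
`fitReplicates()` (the package reports no Hessian standard errors; model
non-regularity at $d_1 = 0$ makes them unreliable).

When several diffusive states are practically indistinguishable, fit a
coarse model and aggregate: `aggregateStates()` collapses state groups
using steady-state occupancies — group fractions add, the coarse rate from
group $A$ to $B$ is the occupancy-weighted mean outflow
$\sum_{i\in A} F_i \sum_{j \in B} k_{ij} / \sum_{i\in A} F_i$, and the
coarse diffusion length is the occupancy-weighted root mean square of the
members. These formulas are this package's definition (chosen so that
steady-state flux between the groups is preserved, verified in the tests);
other conventions are possible.

## Annotation

`annotateTracks()` reports $P(b_i = s \mid C, \theta)$ for every time point
by running the same windowed recursion with the state at frame $i$ clamped
to $s$ and dividing by the unconstrained density. Because the constrained
densities partition the unconstrained one, rows sum to 1 by construction.
One pass per (frame, state) is needed, but no optimizer loop, so the
default window is larger (10). On matched simulations the probabilities
are *calibrated*: among time points predicted diffusive with probability
$p$, a fraction $p$ is truly diffusive, which the tests check bin-wise
(0.01–0.05 bins) against binomial confidence intervals. Two caveats are
documented rather than hidden: the simulator switches states in continuous
time while the likelihood uses the discrete mid-step model, which leaves a
percent-level calibration bias at $u = 1$ (halved at $u = 2$); and with
$\sim$40 populated bins a perfectly calibrated annotator still misses a
95% CI in $\sim$5% of bins, so the tests allow the chance-level number of
misses rather than demanding every bin inside.

Categorical labels take the argmax per time point with ties resolved
toward the slower state. Mislabel rates against ground truth
(`mislabelRate()`) fall as $d/\sigma$ grows and degrade only slowly when
global parameters are off by ±30%.

## Position refinement

`refineTrack()` estimates the posterior of each true position,
$f(r_i \mid C, \theta)$, a Gaussian mixture over state sequences. Per
state at frame $i$ three Gaussians multiply: the forward belief about
$r_i$ given all earlier observations, the backward belief given all later
observations (the forward machinery run on the reversed track — valid
because the positional model is time-symmetric given the states; the
reversed pass starts from the stationary fractions and the doubly counted
stationary occupancy of the shared state is divided out, which is exact
for reversible chains and all two-state models), and the local observation
term. The mixture is summarized by its first two moments rather than
evaluated on a grid, which is what makes long tracks cheap.

For a single-state model this reproduces the exact fixed-interval smoother
(tested to $10^{-8}$ against a direct Gaussian-posterior solve), and an
immobile segment of $n$ localizations attains the $\sigma/\sqrt n$ limit.
For multi-state models the summary SD includes between-state mean spread,
so at ambiguous frames it can modestly exceed $\sigma$ — the mixture is
honest about state uncertainty; the median SD stays well below $\sigma$
and refined positions are closer to the truth than the observations,
severalfold on immobile stretches.

## State-duration histograms

Dwell-time distributions beyond the Markov assumption come from
`durationHistogram()`: the most likely state sequences of each track
(exact enumeration when feasible, otherwise a beam search keeping the
`bTop = 1000` highest-weight partial sequences; the window approximation
cannot be used here because whole sequences must be retained) are weighted
by their posterior probabilities, and runs of consecutive equal states are
tallied by state and duration. Runs touching a track edge are flagged:
`censored` (true duration longer than observed) and `exit_observed`
(FALSE only for runs cut by the track end — a run starting at the track
edge is left-truncated but, dwell times being memoryless, still contributes
its observed exit). `fitExponentialRate()` uses exactly this bookkeeping
for a censoring-consistent geometric MLE converted to a continuous rate
$k = -\log(1-p)$; `exponentialMixtureTest()` compares one against two
dwell components by likelihood ratio (with survival terms for censored
runs) to reveal hidden states, e.g. two bound sub-populations with
distinct lifetimes that a two-state fit lumps together. The chi-square
p-value it reports is a descriptive reference — mixture LRTs are not
regular — so decisions should rest on the size of the statistic and on
refitting with more states.

## The simulator

`simulateTracks()` is the package's ground-truth generator, not a test
fixture: states switch at fine resolution $\tau = \Delta t/50$ (per-$\tau$
switch probability $k\tau$ by default; exact exponential waiting times
selectable), displacements per $\tau$ are Gaussian with SD
$d\sqrt{\tau/\Delta t}$ per axis, and observed positions add localization
noise. The default scenario *is* the reference protocol used throughout
the tests: 10,000 tracks (scaled down per test) of 10 positions in 2D,
$\sigma = 0.02$ µm, $\Delta t = 0.06$ s, an immobile and a diffusive state
($d = 0$ and $0.1$ µm), symmetric rates 0.1 per frame, stationary initial
states. Options cover per-frame termination ($p_K$), chi-square
track-to-track heterogeneity of $\sigma$ or $D$ (`chiSquareScaled()`),
reflecting confinement, and finite-field-of-view geometries in which one
particle yields several observed tracks as it leaves and re-enters the
view. For the membrane geometry the simulation box is three view-widths
wide with periodic boundaries (the out-of-view majority of the cylinder
surface); for the focal-depth geometry the last axis is periodic with
period three times the depth and the central third observable — the
under-specified part of that protocol (how the out-of-focus space wraps)
is resolved this way and documented here. `scenarioSixState()` packages a
six-state model (one bound state, five closely spaced diffusive states
with a full 30-rate matrix) used to exercise coarse-grained fitting plus
aggregation.

What the simulator does *not* emulate — blinking, motion blur within the
exposure, anisotropic PSF noise, spatially varying rates — bounds what
green tests mean: they validate the inference machinery against its own
generative assumptions plus the continuous-time/discrete-model mismatch,
not against every artefact of real microscopy data.

## Numerical choices and edge cases

* Degenerate inputs: tracks need $\ge 2$ frames; gaps are split at input
  (`readTrackCSV()`, `readTrackMateXML()`) because the likelihood has no
  missing-observation term; per-pair transition conversion refuses rate
  rows whose probabilities would exceed 1; reducible rate matrices warn
  and return a boundary stationary distribution.
* Merging with all-dead branches (from state constraints) propagates
  $-\infty$ weights without NaNs.
* `d = 0` is an interior point of the search thanks to the $d = x^2$
  transform; two states collapsing onto the same $d$ with diverging rates
  is flagged as a degenerate fit.
* Defaults follow the track-length advice used for the experimental
  protocols: at least 3 positions, at most the first 50.
* Test problem sizes are chosen for a laptop-scale run: 3 replicates of
  2,000 tracks for the recovery benchmark (the reference protocol uses
  10,000), 2,000–2,500 tracks for calibration and defocalization checks,
  200–250 longer tracks (21–30 frames) for duration histograms.

## Limitations

Anisotropic diffusion, per-state localization errors, persistent/directed
motion, anomalous diffusion and spatial rate maps are out of scope. The
number of states is a user choice: the recommended workflow is to start
with two or three states, inspect duration histograms for multi-exponential
dwell times, and expand or aggregate as indicated.
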