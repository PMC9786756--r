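---
title: "Movement-integrated spatial capture-recapture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-integrated spatial capture-recapture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrmove)
```

## The problem

Classic spatial capture-recapture (SCR) estimates population density from
spatially referenced detections of identifiable individuals at known
detector locations. It does so by positing a latent *activity center*
$s_i$ for each individual, uniform (or intensity-weighted) over a state
space $M$, and a detection function that decays with the distance between
the center and the trap,
$$p_{ij} = p_0 \exp\left\{-\frac{\|x_j - s_i\|^2}{2\sigma_{det}^2}\right\}.$$
Real animals move. When space use is dynamic — transient individuals,
resource-driven drift, behavioural switching — the static-center assumption
biases the detection scale badly and understates uncertainty. `scrmove`
replaces the static center with an explicit discrete-time movement process
for the (expected) location $s_{it}$, simulates data from the joint
process, and fits the resulting model by maximum likelihood after
marginalizing the latent trajectories with a hidden Markov model (HMM)
over a pixelated state space.

## Movement kernels

All kernels share the form $\mu_t \sim N(\mu^*_t, \Sigma)$ with unit time
step; they differ in the mean:

| kernel | $\mu^*_t$ | parameters |
|---|---|---|
| simple RW | $\mu_{t-1}$ | $\sigma^2$ |
| correlated RW | $\mu_{t-1} + R(\mu_{t-1} - \mu_{t-2})$ | $\gamma, \beta, \sigma^2$ |
| biased RW | $\mu_{t-1} + \rho(a - \mu_{t-1})$ | $\rho, a, \sigma^2$ |
| biased correlated RW | both terms | all of the above |
| potential function | $\mu_{t-1} + \sum_k \delta_k \nabla c_k(\mu_{t-1})$ | $\delta, \sigma^2$ |
| Langevin RSF | $\mu_{t-1} + \frac{\sigma^2}{2}\sum_k \delta_k \nabla c_k(\mu_{t-1})$ | $\delta, \sigma^2$ |

with $R = \gamma\left[\begin{smallmatrix}\cos\beta & -\sin\beta\\
\sin\beta & \cos\beta\end{smallmatrix}\right]$ (counterclockwise turn
$\beta$, damping $\gamma \in [0,1]$). Setting $\gamma = 0$, $\rho = 0$, or
$\delta = 0$ collapses each kernel to the simple random walk — exactly, and
in simulation bit-for-bit under a shared seed, which the test suite
exploits as a free correctness oracle. A two-state behavioural switching
kernel (encamped simple RW with $\sigma_1$ vs exploratory correlated RW
with $\sigma_2 > \sigma_1$) and a range-resident Langevin variant (Langevin
drift plus $\rho(a - \mu_{t-1})$) complete the set.

Two limiting distributions are available in closed form and anchor the
stochastic tests: the biased RW is stationary with
$N\!\left(a, (1-(1-\rho)^2)^{-1}\Sigma\right)$ (the variance diverges as
$\rho \to 0$, so the simple RW has none), and the Langevin RSF kernel has,
for small steps, the standard resource-selection surface
$$\pi_{LD}(\mu) = \frac{\exp\{\sum_k \delta_k c_k(\mu)\}}
  {\int_M \exp\{\sum_k \delta_k c_k(z)\}dz}$$
as its approximate stationary law.

### Numerical choices in the movement layer

* **Covariates** are bilinear interpolations of pixel-center values; drift
  uses the *analytic* gradient of that surface (deterministic, exact for
  the interpolant), accepting discontinuities at cell boundaries. Between
  the extent edge and the outermost centers values are clamped, so the
  drift component along a clamped direction is zero.
* **CRW initialization**: the first step is a simple-RW step
  ($\mu_0 := \mu_1$) — parameter-free, and consistent with the $\gamma = 0$
  reduction.
* **Switching chain**: the behavioural state follows a first-order
  two-state Markov chain (standard in movement ecology HMMs); the initial
  state is drawn from the chain's stationary distribution, a choice the
  model structure leaves open.
* **Boundary policy**: the default is rejection resampling against $M$
  (truncation); box-edge reflection is offered for rectangular masks. Both
  induce some edge effect on movement near the boundary, which is why the
  recommended state spaces buffer the trap array by several $\sigma_{det}$.
* One movement step per sampling occasion ($\Delta t = 1$); sub-occasion
  movement is deliberately out of scope in this discrete-time formulation,
  and the interpretation of $\sigma_{det}$ consequently mixes
  within-occasion movement with detection proper.

## Population and detection models

Abundance follows a homogeneous or covariate-driven Poisson point process
($E[N] = e^{\beta_0}\int_M e^{\sum_k \beta_k c_k(s)}ds$, pixel-midpoint
quadrature) or the binomial/data-augmentation form $N \sim
\mathrm{Bin}(M_{aug}, \psi)$ for simulation. Sampled locations choose a
pixel proportionally to its intensity and then jitter uniformly within it,
so continuous-space distances are well defined. A resident/transient
mixture assigns each individual a class with probability $\phi$ — a
parameter we introduce explicitly (with a logit link) because the mixture
needs a membership law; residents start from the RSF surface, transients
uniformly.

Detection is Bernoulli per trap and occasion, either Gaussian in the
distance to the occasion's expected location (above) or, for continuous
paths, an integrated hazard
$p = 1 - \exp\{-\int_{t-1}^t h(x_j, \mu(\tau))d\tau\}$ with
$\log h = \beta_0 + \beta_1\|x_j - \mu(\tau)\|$, evaluated by midpoint
quadrature on a piecewise-linear path (default $L = 10$ substeps; exact
for a stationary animal at any $L$). The hazard model is simulation-only:
inside the HMM likelihood it would require within-occasion path states.

## The fitting engine

The state space is discretized into pixels; each pixel is one HMM state.
For a position-Markov kernel the transition matrix has
$$P_{ij} \propto N(\mathrm{center}_j;\ \mu^*(\mathrm{center}_i),\ \Sigma)$$
restricted to a $(2r+1)\times(2r+1)$ pixel neighborhood and renormalized
(this is the truncation form of boundary handling; excluded pixels get
zero mass). The default radius is $\lceil 4\sigma/\mathrm{cell}\rceil$ and
a warning fires when the window holds less than $1 - 10^{-6}$ of the
untruncated mass. During optimization the radius is frozen at its
starting-value size so the likelihood stays continuous in $\sigma$.
Correlated kernels are not Markov in position (they would need pair-state
augmentation), so transients are fitted with a larger-dispersion simple
random walk — which is also the classical transient model this package
uses for its recovery experiments.

Per individual, occasion emissions are
$e_t(z) = \prod_j p_{jz}^{y_{jt}}(1-p_{jz})^{1-y_{jt}}$ at pixel centers,
and the scaled forward recursion
$\alpha_t = (\alpha_{t-1}P)\circ e_t$ accumulates per-step log scaling
constants (never raw products), yielding the exact marginal $[y_i]$ over
pixel paths. The all-zero history gives the overall detection probability
$p^* = 1 - [y = 0]$, and the semi-complete-data likelihood with a Poisson
abundance model is
$$\log L = n\log\Lambda - \Lambda p^* - \log n! + \sum_{i=1}^n \log [y_i],
\qquad \Lambda = D\|M\|.$$
The Poisson form is chosen over the binomial/data-augmentation form
because it factorizes cleanly for maximum likelihood; the binomial form is
Bayesian-oriented and out of scope. Under the resident/transient mixture,
$[y_i] = \phi[y_i|\mathrm{res}] + (1-\phi)[y_i|\mathrm{tra}]$ with
class-specific transitions and initial distributions, and $p^*$ mixes the
same way. The initial pixel distribution for non-mixture dynamic fits is
uniform over $M$ (configurable); the model family itself does not dictate
one.

Telemetry locations $u$ with known measurement-error covariance
$\Sigma_u$ enter as occasion emission factors
$N(u_t;\ \mathrm{center}_z,\ \sigma_{det}^2 I + \Sigma_u)$ — the marginal
obtained by integrating the two-stage specification
$u|\mu \sim N(\mu, \Sigma_u)$, $\mu|s \sim N(s, \sigma_{det}^2 I)$ over
the instantaneous location. Telemetry contributes only for detected
individuals in this version; whether undetected tagged animals should add
a likelihood term is a genuinely open modeling question we deliberately
leave out.

Optimization is quasi-Newton (BFGS) on link scales — log for density and
dispersions, logit for probabilities, identity for selection coefficients
— with central-difference Hessians (step $10^{-4}$ on the link scale),
delta-method standard errors, and Wald intervals back-transformed from the
link scale so endpoints respect range constraints. Default starts are
moment-flavored: $\sigma_{det}$ from the mean pairwise distance of each
individual's detection traps, density from $n/(0.5\|M\|)$. AIC is reported
for model comparison; nothing fancier.

## What the synthetic-data generator emulates

`simulate_scr_dataset()` reproduces the full generative chain: population
(abundance, classes, initial locations) → per-individual trajectories
(class-specific kernels, per-individual pre-drawn seeds so simulation is
order-independent) → Bernoulli encounter tensor → thinning to detected
individuals (all-zero histories never appear in real data; the truth block
retains everything for recovery tests) → optional telemetry with Gaussian
measurement error on a uniformly tagged subset. It does **not** emulate:
irregular occasion lengths, unmodeled individual heterogeneity in
detection, trap saturation or multi-catch competition, non-random
("convenience") tagging except through an optional weighting, or partial
identification. Passing tests therefore demonstrate internal consistency
of the model-simulator-fitter triple, not robustness to those real-data
features.

## Study conditions used by the test suite

Chosen once, as representative mid-density designs on the $\sigma_{det} =
1$ length scale:

* **Static design**: $10\times10$ traps spaced $1.5\sigma_{det}$, $T = 5$,
  $p_0 = 0.3$, $E[N] = 100$ on a $21.5 \times 21.5$ state space (trap
  array buffered by $4\sigma_{det}$), fitting grid cell $0.5\sigma_{det}$;
  100 simulate-fit replicates.
* **Transient design**: $7\times7$ traps spaced 2, $\sigma_{move} = 2$,
  $E[N] = 60$ on a $20\times20$ space, coarse unit-cell grid; 30
  replicates, with a strongly transient variant ($\sigma_{move} = 3$) for
  the paired misspecification comparison.
* **Limiting-law runs**: $2\times10^5$ biased-RW steps ($\rho = 0.1$);
  $4\times10^5$ Langevin steps at $\sigma^2 = 0.5$ on a two-covariate
  (quadratic bowl + ramp) landscape, where the stationary spread
  ($\approx 1.6$ cells) keeps boundary contact negligible and the
  occupancy comparison is made against the pixel-midpoint RSF surface.

The Langevin tolerance (total variation 0.05) absorbs three error sources
simultaneously: Monte Carlo noise under autocorrelation, the
$O(\delta\sigma^2)$ gap between the Euler-type kernel's stationary law and
the continuous-time RSF surface, and pixel-midpoint discretization.
Shrinking $\sigma^2$ shrinks the second at the price of slower mixing;
$\sigma^2 = 0.5$ balances the two at these run lengths.

## Known limitations

* Wald intervals from the observed information undercover somewhat for
  $\sigma_{det}$ in sparse dynamic designs (a few detections per
  individual): the likelihood surface is a curved $p_0$–$\sigma_{det}$
  ridge, and on the transient design above the empirical spread of
  $\hat\sigma_{det}$ runs roughly 15–20% above the mean reported standard
  error, i.e. true coverage nearer 90% than 95%. Profile-likelihood
  intervals would repair this but are out of scope; treat reported
  $\sigma_{det}$ intervals in weak designs as approximate.
* Fitting supports homogeneous Poisson abundance; covariate-driven
  intensity is simulation-only in this version.
* The pixel HMM inherits discretization bias; the included
  grid-refinement check (halving the cell moves the log-likelihood by
  under 0.5%) is the recommended diagnostic before trusting a grid.
* Identifiability of the mixture weight $\phi$ and class-specific
  dispersions from SCR data alone is fragile; the
  `recovery_experiment()` harness is the instrument to probe it on a
  per-design basis, and no general claim is made.
* Open-population dynamics, continuous-time inference (Kalman filtering
  of exact diffusions), Bayesian data augmentation, and acoustic or
  mark-resight observation models are out of scope.
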