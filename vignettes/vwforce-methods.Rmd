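---
title: "Models and numerical methods in vwforce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in vwforce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

vwforce implements two connected pipelines around the force sensing of
von Willebrand factor: extraction of unbinding kinetics from
single-molecule force spectroscopy (SMFS), and a Brownian-dynamics (BD)
model of a wall-grafted VWF multimer in shear flow whose backbone
tension feeds those kinetics. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic
data generator does and does not emulate.

## Rupture-force kinetics

### Single-barrier (Evans–Ritchie / Bell–Evans) model

A bond whose off-rate grows exponentially with force,
$k(F) = k_\mathrm{off} e^{x_\beta F/k_BT}$, loaded at a constant rate
$r$ (pN/s), ruptures with density

$$p(F\mid r) = \frac{k_\mathrm{off}}{r}\,
  e^{x_\beta F/k_BT}\,
  \exp\!\Big[-\frac{k_\mathrm{off}k_BT}{r\,x_\beta}
  \big(e^{x_\beta F/k_BT}-1\big)\Big].$$

`fit_bell_evans()` maximises the summed log-density over
$(\log k_\mathrm{off}, \log x_\beta)$, each event entering with its own
loading rate $r_i = k_{\mathrm{eff},i}\,v_i$ (the per-event slope at
rupture times the pulling velocity). Standard errors come from the
observed information matrix; optimisation uses a Nelder–Mead pass from
four spread-out starts followed by a BFGS polish. The distribution is
analytically invertible, which the synthetic generator uses for exact
inverse-CDF sampling; the test suite checks that sampler against an
independent rejection sampler.

The lifetime law $\tau(F)=\tau_0 e^{-x_\beta F/k_BT}$
(`bell_evans_lifetime()`) converts a mean backbone tension into a
complex lifetime, with $\tau_0 = 1/k_\mathrm{off}$.

### BSK model and the choice of barrier shape

The Bullerjahn–Sturm–Kroy picture parameterises rupture by a barrier
height $E$, a bound-state-to-barrier distance $x_b$ and a diffusion
constant $D$ along the pulling coordinate, and remains valid at
MD-scale loading rates where the Bell picture fails. The free energy is
a harmonic well terminated by a sharp (cusp) barrier. We fix this shape
— rather than the smooth linear-cubic alternative — because the
zero-force activation rate used downstream,

$$k_0 = \frac{2DE}{x_b^2 k_BT}\sqrt{\frac{E}{\pi k_BT}}\,e^{-E/k_BT},$$

is precisely the Kramers escape rate of the cusp-parabolic well (the
linear-cubic prefactor would be $3DE/(\pi k_BT x_b^2)$); internal
consistency of $k_0$, the force-dependent rate and the density requires
the cusp form. Tilting by a force $F$ leaves the well curvature
unchanged and gives barrier $E_b(F)=E(1-F/F_c)^2$ with critical force
$F_c = 2Ek_BT/x_b$, so

$$k(F)=k_0\,(1-F/F_c)\,
  \exp\!\big[E(1-(1-F/F_c)^2)/k_BT\big]\Big/ g\big(E_b(F)\big),$$

where $g(E_b)=1+\varepsilon+3\varepsilon^2+15\varepsilon^3$,
$\varepsilon = k_BT/(2E_b)$, is the moment series of the boundary-layer
integral — a finite-barrier correction that keeps the closed form
within a fraction of a percent of the exact mean-first-passage-time
(MFPT) rate for barriers above ~10 $k_BT$. The rupture-force density at
loading rate $LR$ is the usual hazard construction
$P(F)= (k(F)/LR)\exp[-\int_0^F k/LR]$, truncated at $F_c$; the mass
surviving to $F_c$ sits there as a point mass (the tilted barrier has
vanished and rupture is immediate). The test suite validates the
density against an independent oracle that evaluates $k(F)$ by double
numerical quadrature of the Smoluchowski MFPT over the same tilted
potential, at 10% sup-norm tolerance for barriers of 15 $k_BT$ and
above (observed agreement is ~0.1%).

### Gaussian-summary likelihood and the confidence band

Per velocity, the first-peak Gaussian $(\mu,\sigma)$ of the force
histogram — not the raw forces — is the BSK input, with loading rate
$LR = V\langle k_e\rangle$ averaged over cycles. Each velocity
contributes $\mathbb{E}_{F\sim N(\mu,\sigma)}[\log P(F;LR,\theta)]$,
evaluated by 32-node Gauss–Hermite quadrature; MD-regime rupture forces
enter as point log-densities at their loading rate. Because the
$(E,D)$ pair is nearly ridge-degenerate over AFM rates alone, the
optimiser uses eight seeded multi-starts in log-parameter space
(simplex, then quasi-Newton). A flag drops the single largest MD force
before fitting, for constructs in which that event stems from a process
the construct itself forbids (A2 unfolding in the bridged variant).

The Gaussian-summary likelihood is a KL projection of per-velocity
Gaussians onto a skewed density family, so the fitted mean-force curve
carries a small systematic offset (a few percent at intermediate
loading rates) that does not vanish with sample size. A parametric
bootstrap reproduces that offset in every replicate; the *basic*
(reflected) bootstrap interval therefore cancels it to first order,
while a raw percentile interval stays centred on the offset. For this
reason `bsk_confidence_band()` defaults to the basic interval
(percentile remains available via `type=`). Bands default to 1000
replicates; the examples and tests use 80–200 replicates, which is
sufficient for 95% quantiles of a smooth one-dimensional curve.

## Force–distance-cycle analysis

`detect_rupture()` estimates the baseline as the median and the noise
as the MAD of the final 20% of the retraction (far from the surface).
The detection statistic is the sample-to-sample force increment, whose
noise is $\sqrt2\sigma$; thresholding it at `snr_threshold` (default 4)
times its own standard deviation keeps the false-positive rate per
trace at the percent level. For each jump the stretching segment — from
the last near-baseline sample, capped at `fit_window` (default 10 nm) —
is fitted with a quadratic (the parabolic elastic-linker signature;
order configurable). The rupture force is the gap between baseline and
the fitted force at the jump onset, and $k_\mathrm{eff}$ is the fitted
slope magnitude there. Jumps within a few samples of contact are
discarded: they leave no stretch segment to fit, and near-contact
adhesion is nonspecific by construction. When a cycle contains several
events, the farthest rupture is kept for kinetics (the standard SMFS
convention; configurable). On noiseless synthetic traces the detector
inverts the generator exactly, because a quadratic fit through exact
parabola samples is exact.

The first-peak Gaussian fit (`fit_first_peak()`) histograms the forces
(Freedman–Diaconis bins by default), smooths counts with a running
median, takes the lowest-force local maximum above 10% of the global
peak, and fits $A\exp[-(x-\mu)^2/2\sigma^2]$ by nonlinear least squares
restricted to bins below the following antimode, so a second
higher-force population cannot bias the fit. Forces inside the closed
interval $[\mu-\sigma, \mu+\sigma]$ are retained for kinetic fitting
(`select_mu_sigma()`). The binding probability is the fraction of
cycles with at least one detected event; its collapse when the tip
ligand is saturated with free receptor is the specificity signature the
blocked synthetic condition emulates.

## The coarse-grained VWF chain

Each bead is one protomer with radius of gyration $a = 30$ nm; the
chain energy is

$$U = \varepsilon\sum_{i<j}\Big[\big(\tfrac{2a}{r_{ij}}\big)^{12}
  - 2\big(\tfrac{2a}{r_{ij}}\big)^{6}\Big]
  + \frac{\kappa}{2}\sum_i (r_{i,i+1}-2a)^2,$$

with $\varepsilon = 2\,k_BT$ (enough to collapse an untethered chain,
as circulating VWF is) and no cutoff on the attractive tail. The
default $N = 20$ gives 19 bonds of 60 nm — a 1.14 µm contour.

**Spring constant.** The literature value "203" for $\kappa$ is
dimensionally ambiguous between $k_BT/\mathrm{nm}^2$ and $k_BT/a^2$.
We adopt $\kappa = 203\,k_BT/a^2$ (0.2256 $k_BT/\mathrm{nm}^2$): with
the per-nm² reading, explicit Euler–Maruyama integration at the model's
own 55 ns time step has $\mu_0\kappa\Delta t \approx 91 \gg 2$ and
diverges immediately, whereas the per-$a^2$ reading gives
$\mu_0\kappa\Delta t\approx 0.10$ and is the convention of bead–spring
shear-flow studies. The `chain_config()` field remains in
$k_BT/\mathrm{nm}^2$, so any stiffness can be supplied explicitly.

**Wall.** A truncated, shifted 10–4 potential of range
$\sigma_R = 45$ nm repels beads from the grafting plane; its bracket
vanishes at the cutoff and diverges at contact, so the repulsive branch
is necessarily the near-wall one ($z<\sigma_R$), and the amplitude
(default the dimensionless prefactor $2\pi\sigma_R/a\,k_BT$) is
configurable — only its order of magnitude matters, and all shipped
checks are amplitude-independent. Bead 1 is grafted at $(0,0,a)$ rather
than exactly on the plane, keeping the wall-corrected mobility finite;
since it never moves, this choice only affects hydrodynamic coupling.
The wall potential is *not* applied to the grafted bead itself: the
anchor constraint, not the wall, holds it, and applying it would inject
a large constant vertical force into every mobile bead through the
mobility coupling.

## Brownian dynamics with wall-corrected hydrodynamics

Internally the engine works in reduced units (length $a$, energy
$k_BT$, mobility $\mu_0 = 1/6\pi\eta a$, time
$\tau_a = a^2/\mu_0 k_BT \approx 1.1\times10^{-4}$ s for
$\eta = 0.89$ mPa s at 298 K); the published 55 ns step is
$\approx 5\times10^{-4}\,\tau_a$. Unit conversion happens only at the
I/O boundary. Each step applies, in order: shear advection
$\dot\gamma z_i$ scaled by the normalised self-mobility
$\mu^{xx}_{ii}/\mu_0$ (the model's stated update rule; a literal
unscaled variant is available behind `literal_shear` for sensitivity
checks), the hydrodynamically coupled deterministic forces
$\sum_j \mu_{ij}F_j$, the drift correction, and correlated noise with
covariance $2k_BT\Delta t\,\mu$ realised by a Cholesky factor (with an
eigenvalue-clipping fallback should the approximate mobility lose
definiteness). Beads that step across the plane are reflected
($z\to-z$); the wall potential supplies the physical repulsion, and
crossings are rare noise events.

The mobility is Rotne–Prager–Yamakawa for pairs (with the overlap form
below $r=2a$, preserving definiteness) plus wall corrections: for pair
blocks, the point-Stokeslet Blake image system (image Stokeslet plus
source- and Stokeslet-doublets), which restores no-slip on the plane
exactly at point level — the suite checks that the induced velocity at
near-wall points vanishes to within the finite-size residual; for self
blocks, the classic far-field expansions
$\mu_\parallel/\mu_0 = 1-\tfrac{9}{16}s+\tfrac18 s^3$ and
$\mu_\perp/\mu_0 = 1-\tfrac98 s+\tfrac12 s^3$ ($s=a/z$) resummed as
$[0/3]$ Padé forms, which agree with the expansions to $O(s^3)$ while
remaining positive and monotone for all $z>0$ (the raw truncations turn
unphysically non-monotone below $z\approx1.15a$). The drift term is
$k_BT\,\partial_z \mu^{zz}_{ii}$ of this self-mobility, evaluated
analytically — the position dependence of the pair blocks is neglected
in the drift, consistent with the model's stated update rule. The
remaining approximation error of the point-image pair terms is
$O((a/R)^3)$ and shows up as a few-percent residual at bead–bead
separations of order $2a$; no lubrication corrections are included.

**Observables.** Bond lengths are block-averaged over 100 steps; the
profile value is the mean of block means,
$f_i = \kappa(\langle r_{i,i+1}\rangle - 2a)$ in pN. Standard errors
aggregate blocks into ~30 superblocks, absorbing residual
autocorrelation between adjacent blocks. One physical subtlety: a
discrete 3D bond has a positive thermal mean extension from the radial
Jacobian, $\langle r\rangle - 2a \approx 2k_BT/(2a\kappa)$, i.e. a
zero-shear tension baseline of ~0.14 pN for the default chain. A long
run resolves this baseline as significantly positive, so "no tension at
zero shear" should be read as "at the thermal baseline", and shear
responses should be judged against the zero- or lowest-shear profile —
the shipped checks do exactly that.

**Problem sizes.** The published production scale ($10^8$ steps,
5.5 s simulated) is configuration-driven; the shipped tests and the
acceptance script run desk-scale productions of $10^5$–$1.2\times10^5$
steps with $3\times10^4$-step equilibrations from a compact-coil start,
which resolve grafted-end tensions of a few pN against standard errors
of ~0.1–0.2 pN across the eight-rate shear sweep (5.5 to 18175 s⁻¹).
Statistical assertions are made in units of the runs' standard errors;
because the chain's slowest conformational modes relax on ~50 $\tau_a$
— comparable to a desk-scale production — within-run superblock errors
understate replicate-to-replicate noise, and "profiles overlap" checks
are therefore judged against a same-rate replicate baseline rather than
against the nominal SE alone. Longer runs only sharpen all of these
comparisons.

## The synthetic-data generator

The generator emulates: retraction traces at 1 sample/nm with zero-mean
Gaussian baseline noise; a parabolic stretching segment whose slope at
rupture is the series stiffness of cantilever and linker, ending in a
discontinuous jump whose magnitude is drawn from the Evans–Ritchie
density at the cycle's loading rate (closed-form inverse CDF); a
configurable fraction of cycles with smooth short-range nonspecific
adhesion near contact; a "blocked" condition with strongly reduced
specific fraction; and per-event effective spring constants drawn from
a truncated Gaussian (floor 0.1 pN/nm), since real cycles show
cycle-to-cycle stiffness variation with no published distribution.

It does **not** emulate approach curves, instrument drift, worm-like-
chain nonlinearity of the linker beyond the parabolic approximation,
multiple tethers, or correlated noise. Passing round-trip tests
therefore shows that the analysis inverts this idealised data model —
including at realistic noise levels — not that it is robust to every
instrumental artifact of real AFM data; the detector is an automated
stand-in for the interactive event marking used in practice.

## Configuration and reproducibility

Run configurations are YAML (`read_run_config()`); note that a bare `N`
is a YAML 1.1 boolean, so chain configs spell the bead count
`n_beads`. Every pipeline run writes a JSON manifest with the package
version, the config, the root seed and input digests. All randomness —
including the normals drawn inside the compiled BD core — flows through
R's RNG, so a single `set.seed()`/`--seed` reproduces any run
bit-for-bit.

## Known limitations

- Point-image (rather than finite-size image) wall corrections for pair
  mobilities; accurate far from the wall and to $O((a/R)^3)$ near it.
- The drift correction covers the self-mobility only, per the model's
  update rule; the neglected pair-term divergence is smaller by a
  factor $\sim(a/r)^2$.
- The Gaussian-summary BSK likelihood is a projection estimator with a
  small non-vanishing bias; use the basic bootstrap band (default) for
  curve uncertainty, and prefer raw-force fitting when per-event data
  are available.
- No bending or torsional stiffness, no monomer-resolved A-domain
  structure, no association/dissociation dynamics of the multimer.
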