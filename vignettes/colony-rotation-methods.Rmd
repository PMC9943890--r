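---
title: "Modelling and measuring collective rotation in freely expanding cell colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring collective rotation in freely expanding cell colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonyrot)
```

Epithelial colonies growing freely on a substrate — with no micropatterned
confinement — can spontaneously develop coherent angular motion (CAM): all
cells in a near-circular cluster rotate persistently about the cluster
centroid, clockwise or counterclockwise with equal probability.  This
package implements both halves of the computational story behind that
phenomenon: a continuum active-nematic simulator in which rotation emerges
spontaneously from activity, and the trajectory/growth analysis pipeline
used to quantify CAM and colony growth in time-lapse microscopy data.
Seeded synthetic-data generators stand in for the microscopy data, so every
analysis stage is testable offline.

## The continuum model

A colony is described by three coupled fields on a periodic 2D lattice:

* a conserved concentration $\phi$ ($\phi = 1$ tissue, $\phi = 0$ cell-free
  background),
* a traceless symmetric nematic tensor
  $Q = S(nn^T - I/2)$ carrying the coarse-grained cell orientation,
* an incompressible velocity field $u$ at suspension density $\rho$.

The free-energy density is

$$ f = \tfrac{C}{2}\left(1 + \tfrac{1}{2}\mathrm{Tr}\,Q^2\right)^2
     + \tfrac{B}{2}\phi^2(1-\phi)^2
     + K_\phi |\nabla\phi|^2 + \tfrac{K}{2}|\nabla Q|^2 . $$

The first term makes the *isotropic* state the bulk minimum, so any nematic
order must be induced by activity.  The double well creates colonies with a
diffuse interface; with the stiffness written as $K_\phi$ (not $K_\phi/2$)
the equilibrium interface profile is $\phi = \tfrac12(1+\tanh(x/d))$ with
$d = \sqrt{8K_\phi/B}$, and the chemical potential carries a factor of two:
$\mu = B\phi(1-\phi)(1-2\phi) - 2K_\phi\nabla^2\phi$.

The fields evolve by Beris–Edwards dynamics, an incompressible
Navier–Stokes equation, and advected Cahn–Hilliard dynamics:

$$ \partial_t Q + u\cdot\nabla Q - W = \gamma H, \qquad
   \rho\, D_t u = \nabla\cdot\Pi, \qquad
   \partial_t\phi + u\cdot\nabla\phi = \Gamma_\phi \nabla^2 \mu , $$

with $H$ the molecular field, $W$ the generalized advection (co-rotation
plus flow alignment with parameter $\lambda$), and a stress
$\Pi$ containing viscous, elastic (Ericksen plus antisymmetric) and active
parts; the active stress $\zeta Q$ is extensile for $\zeta < 0$, the cell
monolayer case.

Three places where the printed form of this model family is internally
inconsistent were resolved in favour of the standard Beris–Edwards
structure, which is also what the described physics requires:

* **Bulk sign.** A bulk term $-\tfrac{C}{2}(1+\mathrm{Tr}\,Q^2/2)^2$ would
  destabilize the isotropic state, contradicting the statement that order
  is activity-induced.  The default implements the stabilizing sign;
  `convention = "printed"` exposes the alternative for sensitivity checks.
* **Trace correction in $W$.** A correction term $-\lambda(Q+I)\,
  \mathrm{Tr}(QE)$ does not preserve $\mathrm{Tr}\,Q = 0$; the standard 2D
  form $-2\lambda(Q+I/2)\mathrm{Tr}(QE)$ does, exactly, and is used.
  Tracelessness is additionally structural: tensor fields store only the
  $(xx, xy)$ pair.
* **Conjugate term in $\Pi$.** The corresponding first elastic-stress term
  is implemented as $2\lambda(Q+I/2)(Q\!:\!H)$, the conjugate of the
  corrected $W$ (the printed $(Q+I)$ variant has the same
  $(Q+I)$-versus-$2(Q+I/2)$ mismatch).

One further convention matters and is easy to get wrong: with the vorticity
defined counterclockwise-positive,
$\omega = (\partial_x u_y - \partial_y u_x)/2$, the antisymmetric tensor
entering $W$ must be the *rotation generator* with $\Omega_{xy} = -\omega$
(the formula is written in the Jacobian convention $\partial_j u_i$).  The
package pins this with a co-rotation oracle: at $\lambda = 0$ a uniform
director in a rigidly rotating flow must rotate *with* the flow.

## Numerical scheme

The solver is the standard hybrid for this model family: a D2Q9 BGK
lattice-Boltzmann scheme with Guo forcing for the flow, explicit
second-order finite differences for $Q$ and $\phi$, at $dx = dt = 1$ in
lattice units.  Pressure enters through the LB ideal-gas equation of state
and the viscous stress through the BGK collision, so neither is duplicated
in the forcing.  Numerical choices worth recording:

* **Laplacian stencil.** The driver defaults to the isotropic 9-point
  laplacian.  This is not cosmetic: the Cahn–Hilliard biharmonic stability
  limit with the compact 5-point stencil is $dt < 2/(D\,\lambda_{max}^2)
  \approx 0.78$ at the default $D = 2K_\phi\Gamma_\phi = 0.04$
  ($\lambda_{max} = 8$), i.e. *unstable* at $dt = 1$, while the 9-point
  stencil ($\lambda_{max} = 14/3$) is comfortably stable.  The module-level
  operators default to the compact stencil, and `phi_substeps` provides
  further margin if wanted.
* **Discrete energy consistency.** `free_energy_density()` evaluates the
  square-gradient terms with forward differences by default, which makes
  the summed discrete energy *exactly* the potential whose
  derivatives are the compact-laplacian $H$ and $\mu$; the functional
  derivative tests then hold to $O(\varepsilon^2)$ of the probe, not merely
  to stencil accuracy, and relaxational dynamics decreases the energy
  monotonically.
* **Viscosity.** The reference parameter set prints no viscosity.  With
  $\tau_{LB} = 1$ at $\rho = 40$ ($\eta = \rho c_s^2/2 \approx 6.7$) the
  activity-induced-ordering growth rate $\lambda|\zeta|/(2\eta)$ barely
  exceeds the bulk relaxation rate $\gamma C$, and ordering takes $\sim
  10^5$ steps.  The default is $\tau_{LB} = 0.55$, i.e. $\eta = 2/3$ in
  lattice units — a standard choice in LB studies of this model family —
  which places the instability safely above threshold; `tau_lb` is
  configurable.
* **Activity localization.** With the active stress $\zeta Q$ acting
  everywhere, weak order leaking past the colony interface stirs the
  background fluid and the droplet fragments.  The default weights the
  active stress by the cell phase, $\Pi^a = \zeta\phi Q$, confining
  activity to the tissue; `active_phi = FALSE` restores the unweighted
  form.
* **Guards.** A Mach guard (`u_max`) and an order-magnitude guard
  (`s_max`) abort a run with the offending step index rather than letting
  an instability propagate silently.

### What the simulator reproduces

At the reference parameters, an extensile droplet of intermediate size
develops nematic order from a small random director seed, and the ordered
droplet spontaneously rotates with a sign set by the random initial
condition; over many seeds both signs occur with equal probability, and
within a run the sign persists.  The passive limit ($\zeta = 0$) neither
flows nor orders.  Very small droplets do not rotate (the activity in the
droplet is insufficient against elastic smoothing), and the largest
droplets lose *net* rotation to transient multi-vortex (active-turbulent)
flow.  At desk scale (boxes of $64^2$–$128^2$ rather than the $300^2$
reference configuration) the dependence of the rotation plateau on droplet
area is dominated by this onset-then-turbulence structure; a clean
monotone decrease of $|\omega|$ across the whole rotating range, as seen
in experiments, is not resolved at these box sizes (see the acceptance
suite for exactly what is asserted).  Colony area, mean angular velocity
(counterclockwise positive, measured as the colony average of
$(\hat{r}\times u)_z / r$ about the $\phi$-weighted periodic centroid),
mean speed, mean order and total free energy are recorded as time series,
and `rescale_to_experiment()` performs the affine axis matching used to
compare simulated and experimental rotation curves.

## Trajectory kinematics

The analysis half mirrors how tracked positions are processed: for each
cell and each 2 h interval, the radial velocity $V_\rho$ (reported in
µm/min) and angular velocity $\omega$ (rad/h, counterclockwise positive)
are computed about the same-frame cluster centroid, with angle differences
unwrapped to $(-\pi, \pi]$.  Design choices:

* The centroid is the arithmetic mean of tracked cell positions; a
  contour-derived centre may be supplied instead (`centers`).  The mean is
  the right default for rigid rotation — the point-cloud centroid
  co-rotates, so angles and radii relative to it are exact — but under
  radial expansion the estimated centroid drifts slightly; radial
  velocities are unbiased only about the true centre, which the synthetic
  generators therefore expose.
* Cells within `r_eps = 2` µm of the centroid lose their angular velocity
  (undefined at the pole) but keep the radial one.
* Sampling at 2 h bounds detectable angular velocities to
  $|\omega| < \pi/2$ rad/h (Nyquist); beyond it the measured rate aliases.
  The default coherent-rotation magnitude in the generators, 0.05 rad/h,
  sits far inside this bound.
* Region labels (inner/outer at a split radius, fixed at the first
  analyzed frame), population means and SDs per region and interval, and
  per-cluster time-averaged velocities (equal interval weights) follow the
  reference analysis; cluster geometry (mean radius, aspect ratio, area)
  is estimated from the principal axes of the position covariance, with
  semi-axes twice the principal standard deviations (exact for uniform
  coverage of an ellipse).

## Growth analysis

Cell counts follow $N(t) = N_0 2^{t/t_d}$; the fit fixes each cluster's
$N_0$ at its first observation and pools a log2 regression through the
origin, making $t_d$ the only adjustable parameter (log scale because the
noise is multiplicative).  Confluence curves $A_s(t)$ from different
seeding densities are aligned into a master curve by horizontal time
shifts against a reference sample (the one with median initial
confluence); each shift minimizes the summed squared difference of
$\log_2 A_s$ over the overlap (golden-section search), capped points
($A_s \ge 1$) are excluded, and the pooled fit of $A_s = A_{s0}2^{t/\tau}$
recovers the occupancy doubling time.  The noiseless alignment has the
closed form $\Delta_i = \tau\log_2(A_{s0,i}/A_{s0,\mathrm{ref}})$, which
anchors the tests.  The critical area separating free expansion from
proliferation inhibition is $A_c = 4\pi\tau^2 v_\rho^2$, homogeneous of
degree two in $\tau$, with µm/min inputs converted exactly (0.04 µm/min =
2.4 µm/h); equivalent diameter is $2\sqrt{A/\pi}$.

## Synthetic data: the stated world

The generators encode the study's reported scales and return ground truth
alongside each dataset:

* **Coherent cluster**: 52 cells in an ellipse of mean radius 84 µm and
  aspect ratio 0.83 (or 28 cells, radius 70 µm, aspect 0.65 for the less
  circular case), rotating rigidly at a signed `omega0` with radial drift
  0.04 µm/min, sampled every 2 h for 12 h.  Optional placement quotas put
  exactly 23/29 (or 11/17) cells inside/outside the split radius *relative
  to the sample centroid* (a thin annulus around the split radius is
  avoided so the classification is stable under centroid estimation).
* **Incoherent cluster**: per-cell zero-mean random walks in angle and
  radius with displacement variance matched to the coherent case — the
  negative control.
* **Growth counts**: $N_0$ uniform in 5–50, $t_d = 71$ h, lognormal noise
  $\sigma = 0.15$, counts every 12 h over 6 days; areas tied to counts at
  ~500 µm² per cell (constant-density free expansion), with an optional
  boundary-spreading mode for the rising small-cluster regime.
* **Confluence curves**: $A_{s0} \in \{0.05, 0.1, 0.2, 0.4\}$,
  $\tau = 50.8$ h, $\sigma = 0.05$, capped at 1.

Two defaults are assumptions rather than reported values, and are stated
as such: the positional noise model (isotropic Gaussian, 1 µm — a
manual-tracking error scale) and the coherent rotation magnitude
(0.05 rad/h, chosen so a 2 h step advances ~5.7°, well inside the
unwrapping bound).  What a green test establishes is correspondingly
limited: the generators emulate rigid-body kinematics with additive noise,
not cell rearrangement, division, or shape change.

## Known limitations

* The simulator is 2D, periodic, and explicit-Euler in time; no
  proliferation term exists, so simulated colonies are initialized at a
  size rather than grown (colony growth lives entirely in the analysis
  half and its generators).
* Droplets erode slowly under sustained active stirring (the diffuse
  interface loses mass to the background); quantitative plateau
  measurements are therefore windowed before late-time erosion.
* Defect tracking/classification and polar forces are out of scope.
* Field snapshots are plain CSV (one row per node) rather than a binary
  container, keeping the toolchain dependency-free.
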