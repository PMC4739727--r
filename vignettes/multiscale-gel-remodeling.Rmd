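---
title: "Multi-scale mechanics of fibroblast-driven fibrin gel remodeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale mechanics of fibroblast-driven fibrin gel remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The system being modeled

When clusters of dermal fibroblasts (explants) are placed on the surface of
a fibrin gel, the cells pull on the surrounding fibers. Over the first 24
hours this traction compacts the explants, drags the surrounding matrix
inward, and aligns fibrin fibers along the corridors between neighboring
explants. How far this reorganization reaches depends on the gel's
mechanical constraints: a gel left attached to its mold walls (*Fixed*)
behaves very differently from one released so that only a small central
patch adheres to the glass below (*Free*).

`fibrogel` implements a coupled two-scale finite-element description of
this experiment together with the image-analysis operators used to
quantify it, and synthetic data generators so that every stage can be
validated against known ground truth without wet-lab data.

# The multi-scale model

## Microscopic scale: fiber-network RVEs

The gel microstructure is represented by representative volume elements
(RVEs): cross-linked fiber networks living in a unit cube. A single fiber
carries the axial force

$$F(\lambda) = \frac{E_f A_f}{B}\left[e^{B\varepsilon_f} - 1\right],
\qquad \varepsilon_f = \tfrac12(\lambda^2 - 1),$$

where $\lambda$ is the fiber stretch, $\varepsilon_f$ its Green strain,
$E_f A_f$ the modulus-area product and $B$ the strain-stiffening exponent.
The defaults, $E_f A_f = 3\times10^{-10}$ N and $B = 4$, are values fitted
to a uniaxial test of a 6.8 mg/mL fibrin gel; `B = 0` is handled as the
linear limit $F = E_fA_f\,\varepsilon_f$. The law is applied as printed
for $\lambda < 1$ (compression) — fibers are pin-jointed single segments
with no bending resistance or buckling cutoff.

Given prescribed boundary-node positions, `solve_equilibrium()` drives the
net fiber force on every interior node to zero by damped Newton iteration
with a backtracking line search on the total strain energy. The
macroscopic Cauchy stress of a solved RVE is the boundary sum

$$\langle\sigma_{ij}\rangle = \frac{1}{V}\sum_{\text{bnd}} x_i F_j$$

over deformed boundary positions $x$ and reaction forces $F$. For a finite
network this sum is not exactly symmetric; the symmetric part is used (the
asymmetry norm is attached for inspection).

## Macroscopic scale and coupling

The gel volume is a regular mesh of trilinear hexahedral elements. At each
element (or at each of its eight Gauss points, in the full configuration)
an RVE is deformed affinely by the local macroscopic deformation gradient
$F$; its volume-averaged stress, plus an additive compressible
neo-Hookean term

$$\sigma^{nH} = \frac{G}{J}(B - I) + \frac{2G\nu}{J(1-2\nu)}\ln(J)\, I$$

($G = 1$ Pa, $\nu = 0.3$, $B = FF^T$, $J = \det F$), forms the element
stress, which enters a standard total-Lagrangian internal-force vector.
Macro equilibrium is solved by Newton iteration with a
finite-difference element tangent built from a linearization of the RVE
stress response (nine warm-started RVE re-solves per element per
iteration).

The full balance also contains a surface term coupling the fluctuation of
the microscopic stress to the gradient of the RVE boundary displacement.
Its quadrature is not uniquely defined on a discrete network; it is
implemented as the boundary-node estimator
$q_j = \frac1V \sum_b [F_j^b - \langle\sigma\rangle_{mj} n_m A_b]\,
(n^\top \nabla u\, n)$, is **off by default**, and its magnitude relative
to the Eq-averaged stress is logged on every solve so the choice is
observable (`coupling = TRUE` adds it as a body force).

## Cell traction

Cell traction is not modeled by forces applied at cell boundaries but by
uniformly shortening the reference lengths of all fibers inside the
*cellular* elements — three explant patches in the top element layer. The
total 24% shortening (chosen so the simulated explant area ends near the
measured 24-hour area) is applied in equal multiplicative increments, with
macro equilibrium re-solved after each. An increment that fails to
converge is bisected automatically (up to four levels).

# What is calibrated, and how

**Network generation.** The generation procedure is the package's own
design (the underlying construction is not prescribed by the reference
data): straight segments through uniformly random points are clipped at
the unit-cube faces; where two segments pass within a capture radius
(default 0.02), a cross-link node is created at the midpoint of their
mutual perpendicular and both segments are split. Segment directions come
from a randomly rotated Fibonacci-sphere point set rather than iid
sampling: at ~100 segments, iid direction sampling fluctuates enough that
individual networks fail the near-isotropy requirement
($\alpha < 0.15$ for the 2D projection), while the quasi-uniform set
guarantees it; a network failing the isotropy or face-percolation check is
regenerated from the seed's next substream. Counts follow
fibers $= N + 2C$ and nodes $= 2N + C$ for $N$ segments and $C$
cross-links; with the measured pair cross-link rate
$\kappa = 0.0259$ per pair at the default radius, $N$ is chosen from the
quadratic $N + \kappa N(N-1) = \text{target}$. The defaults give a mean
of ≈337 fibers (seed-to-seed SD ≈ 30) and ≈320 nodes (≈1,000 nodal degrees
of freedom), matching the reference microstructure scale.

**RVE physical scale.** Networks are generated in a dimensionless unit
cube; converting the boundary sum to Pa requires the RVE's physical edge
length. It is a single config scalar, default $20\ \mu m$ — a realistic
sample size for fibrin microstructure — which puts network stresses at
O(1–10 Pa) against the 1 Pa continuum modulus. All macro lengths are mm,
forces N, stresses Pa.

# Numerical choices

* **RVE Newton.** Residual tolerance $10^{-8} \times E_fA_f$
  ($3\times10^{-18}$ N at the defaults) on the max interior nodal force
  norm; this scales with the material because the absolute forces are
  pN-scale and any fixed tolerance in N would be meaningless. Pin-jointed
  networks have floppy (mechanism) modes at the stress-free state — every
  cross-link node has rank-2 axial stiffness — so the tangent always
  carries a small Levenberg damping, the per-iteration nodal move is
  capped at 0.2 RVE units, and the fiber-law exponent is clamped so
  rejected line-search probes stay finite. A solve that stalls short of
  the target but below $\max(10^{-3}\,F_{\max},\ 3\times10^{-4}E_fA_f)$
  is accepted as equilibrated: the resulting stress error
  (~$10^{-4}$ Pa at the default scale) is far below the stresses that
  drive the macro problem.
* **Macro Newton.** Relative residual tolerance $10^{-4}$ with an
  absolute floor of $10^{-6}$ Pa·mm² — set above the noise floor that the
  RVE residual tolerance induces in the assembled forces. Newton steps
  are capped at a quarter of the smallest element edge per node (the
  *Free* gel has a nearly rigid in-plane rotation about its small anchor
  patch, and uncapped steps along that soft mode diverge), with
  backtracking line search and automatic increment bisection on failure.
* **Element tangent.** Finite differences of the element internal-force
  vector with the network stress linearized about the converged RVE state
  (exact continuum term); perturbation $10^{-7}\times$ element size. The
  RVE stress tangent itself uses forward differences with step $10^{-4}$
  on the deformation-gradient entries, warm-started from the converged
  state.
* **Degenerate inputs.** Zero-projected-length fiber sets, inverted
  elements ($J \le 0$), empty explant masks and constant image tiles all
  raise informative errors (or, for the constant tile, a flagged isotropic
  result).

# Image analysis operators

**Bead tracking** uses normalized cross-correlation of a square template
(halfwidth 10 px) against a search window (halfwidth 20 px) between
successive frames, with quadratic sub-pixel peak refinement, template
re-sampling at each new position, and a lost-bead threshold of 0.5 on the
peak correlation. NCC makes the tracker exactly invariant to global
intensity gain and offset. Displacement statistics follow the
net-displacement convention: cumulative displacement is
$|p_t - p_0|$, not path length — this is what makes the 6-hour
period-average rates telescope to the cumulative value — and an
alternative path-length reading would double-count back-and-forth motion.

**Fiber alignment** is measured from the FFT power spectrum of a
Hann-windowed, mean-subtracted tile: the spectrum is band-passed to
0.10–0.30 cycles/px, binned into 180 angular bins by *mean* power per bin
(sum-based binning is biased by the square grid's anisotropic frequency
density), rotated 90° from spectral to fiber space, and reduced to the
orientation tensor, $\alpha = 1 - \omega_1/\omega_2$, and the principal
angle. The band-pass keeps mid frequencies because finite fiber length
broadens the angular energy at low frequency and finite line width
suppresses it anisotropically at high frequency; the 0.10–0.30 window
recovers $\alpha$ of von Mises textures within 0.05 of the closed form
$\alpha = 2A/(1+A)$, $A = I_1(\kappa)/I_0(\kappa)$, across
$\kappa \in [0.5, 4]$. These spectral parameters are declared design
choices, not values inferred from data.

# Synthetic data: what it does and does not emulate

The bead-scene generator renders Gaussian spots (σ = radius/2) advected by
uniform, radial-contraction, or arbitrary functional displacement fields,
with Gaussian noise, 8-bit quantization, and exact sub-pixel ground truth.
It does **not** simulate DIC shading, depth-of-focus loss, or bead
overlap, so a passing tracker validates the geometric contract
(localizable blobs under known motion), not robustness to real DIC
imagery. The texture generator composites anti-aliased line segments with
uniform or axial von Mises orientations (sampling $2\theta$ from a von
Mises distribution); its ground truth is the equal-weight second moment of
the sampled angles plus the analytic distribution value. It does not
emulate confocal speckle, fiber curvature, or 3D projection effects.

# Problem sizes

Three presets are provided. `full` reproduces the reference
configuration exactly — 46×46×4 elements (8,464 elements, 11,045 nodes),
three 4×4-element explants (area 0.484 mm², centroid spacings
2.09/2.03/2.03 mm), eight ~337-fiber RVEs per element (67,712 networks),
24 × 1% shortening increments — and is intended for cluster use; it is
not exercised by the test suite. `desk` (12×12×1 mesh, single-element
explants, one ~60-fiber RVE per element with the network stress sampled
at the element centroid and full 2×2×2 quadrature for the continuum term,
6 increments to the same 24% total) preserves the qualitative mechanics
at laptop cost and is the configuration the ordering tests run; `mini`
(4×4×1) is a seconds-scale smoke geometry. The desk scale reproduces the
orderings — ECM displacement Free > Fixed, fiber force Fixed > Free,
axial alignment above far-field, realignment concentrated near the
explants — but not the full-scale magnitudes.

# Known limitations

* Single-segment pin-jointed fibers cannot collapse locally or transmit
  moments; representing fibers as chains with torsional joints would be
  needed to reproduce pericellular densification.
* Constant incremental shortening has no force feedback, so predicted
  displacement *rates* rise with time, opposite to the decaying rates seen
  in live-gel tracking; this is a documented model limitation, not a bug
  to be tuned away.
* The affine RVE boundary condition and the discrete form of the
  stress-fluctuation coupling term are modeling choices; the term is off
  by default and its logged relative magnitude lets users judge it.
* Explant area is measured as the deformed top-surface patch polygon area;
  alternative readings (e.g. network-density-based) would differ slightly.
* Fibrin degradation, collagen deposition, cell migration and long-term
  remodeling are out of scope.
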