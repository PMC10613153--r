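---
title: "A coupled growth, nutrient and phase-field model of arterial wall disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled growth, nutrient and phase-field model of arterial wall disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`arterysim` simulates two arterial pathologies that share a common origin
in malfunctioning vasa vasorum (VV) — the microvessels that nourish the
outer wall of medium and large arteries. When VV become occluded, the
outer wall is starved of nutrients and responds with inflammatory
overgrowth (atherosclerosis); when VV rupture, blood seeps into the wall
(intramural hematoma) and drives interlayer tearing (dissection). Both
are modelled in one continuum framework with four coupled fields on an
annular cross-section of a coronary artery:

* **Displacement** $\mathbf u$ — quasi-static finite-strain equilibrium
  $\nabla\cdot\boldsymbol\sigma = 0$ with a multiplicative split
  $\mathbf F = \mathbf F_e\,\mathbf F_g$ of the deformation gradient. The
  growth part is isotropic, $\mathbf F_g = (1+\alpha)\,\mathbf I$, with a
  scalar internal variable $\alpha$ stored at each Gauss point.
* **Nutrient concentration** $c\in[0,1]$ — steady diffusion–reaction,
  $\nabla\cdot(D\nabla c) - R_c = 0$, with diffusivity interpolated
  between healthy and inflamed tissue, $D = \phi D_{\min} +
  (1-\phi)D_{\max}$. The transient term is omitted because diffusion is
  much faster than the disease processes.
* **Inflammation / hematoma phase field** $\phi\in[0,1]$ — Allen–Cahn
  dynamics $\dot\phi = -M\,f'(\phi) + \epsilon^2\nabla^2\phi + S_\phi$
  with the double-well barrier $f(\phi) = 16M\phi^2(1-\phi)^2$. The
  source couples the fields: in dissection mode
  $S_\phi = R_s\,c\,d$ (blood perfuses only where tissue is ruptured and
  supplied), in atherosclerosis mode a threshold ramp
  $S_\phi = R_s\,\max(c_{th}-c,0)/c_{th}$ (inflammation grows only in
  starved tissue).
* **Damage phase field** $d\in[0,1]$ — regularized fracture,
  $\eta_d\,\dot d = -d + l^2\nabla^2 d + S_d$ with crack driving force
  $S_d = -g'(d)\,\Psi_{\max}/(\Psi_{cri}/l)$ and degradation
  $g(d) = (1-d)^2 + d\,d_{\min}$. $\Psi_{\max}$ is the running maximum of
  the tensile part of the stored energy, which freezes during unloading
  and makes damage irreversible.

Growth follows the phase field through
$\dot\alpha/(1+\alpha) = k_g\,\dot\phi$; the implicit Gauss-point update
$\alpha_{n+1} = (\alpha_n + k)/(1-k)$ with $k = k_g\,\Delta\phi$ solves
the local residual in closed form and integrates to the saturation law
$1+\alpha = e^{k_g\phi}$.

The stored energy is a nearly incompressible neo-Hookean law split into
an isochoric part $\Psi_{iso} = \tfrac{\mu}{2}(\hat I_{1e}-3)$ (always
degraded by $g(d)$) and a volumetric part (degraded only in volumetric
tension, $J_e>1$, so that a closed crack still transmits pressure). The
crack driver is the *undegraded* tensile part
$\Psi_{iso} + (1-H_J)\Psi_{vol}$: degrading the driver itself would
stall crack growth as soon as it starts.

## A note on the volumetric energy

The volumetric energy implemented here is
$$\Psi_{vol} = \frac{\nu\mu}{1-2\nu}(J_e-1)^2 + \mu\,(J_e - 1 - \log J_e).$$
A form sometimes written for this model,
$\kappa(J_e-1)^2 - \mu\log J_e$ together with the isochoric first
invariant, is not stress-free at the reference state — it produces a
spurious hydrostatic stress $-\mu\mathbf I$ at $\mathbf F_e = \mathbf I$,
so an unloaded artery would not be in equilibrium. The additional
$\mu(J_e-1)$ term is exactly the one that cancels the logarithmic
pressure at $J_e = 1$ (in classical texts it accompanies the full first
invariant). It preserves the printed penalty modulus, the logarithmic
barrier as $J_e\to 0$, and the small-strain limit: for
$\nu = 0.49$ the stress matches linear elasticity with
$E = 2\mu(1+\nu)$ to better than 1%.

# Geometry and the VV tree

The domain is an annular sector (default: half annulus, symmetric about
the horizontal axis) with inner radius $D/2 = 600\,\mu m$ and wall
thickness $t = 400\,\mu m$, meshed with bilinear quads. The radial
spacing follows the fine target size; the angular spacing is fine inside
a sector around the VV tree and coarse elsewhere. In 3D the section is
extruded into trilinear hexahedra (8 nodes, 6 unknowns per node).

The VV network is a binary tree fractal rooted on the outer wall: a
trunk of length $L_0 = 80\,\mu m$ pointing radially inward, then three
branching generations with length ratios $\lambda_k$ and sibling opening
angles $\gamma_k$ (each child leaves at $\pm\gamma_k/2$ from the parent
axis; $\gamma = 2\pi/3$ gives the characteristic wide bifurcations).
Only the branch angles are stochastic — each is perturbed by a uniform
jitter (default amplitude $5^\circ$, a realistic irregularity that keeps
the tree recognizably fractal) drawn from a single seeded generator, so
trees are bit-reproducible. Segments are clipped so the network reaches
at most mid-wall depth. The occlusion sits at arclength $S = 30\,\mu m$
along the trunk from the outer wall; everything distal of it (and all
its descendants) stops delivering nutrient. Nutrient delivery is by
Dirichlet nodes: mesh nodes within one fine element size of an
unoccluded segment are pinned at $c = 1$, as are the lumen nodes.

What the generator does **not** emulate: the layered intima/media/
adventitia structure, collagen fiber anisotropy, anatomic (non-circular)
geometry, 3D VV trees (in 3D the tree is extruded), residual stresses
and perfusion dynamics inside the VV. Passing tests therefore show that
the coupled field mechanics behaves as designed on an idealized vessel,
not that patient-specific predictions are validated.

# Parameters

| Parameter | Meaning | Default | Unit |
|---|---|---|---|
| $\mu$ | shear modulus | 30 (constitutive) / 60 (scenarios) | kPa |
| $\nu$ | Poisson ratio | 0.49 | – |
| $k_g$ | growth coupling | 10 | – |
| $R_c$ | nutrient consumption | $10^{-2}$ | model units |
| $D_{\max}, D_{\min}$ | diffusivity healthy/inflamed | $10^3$, 1 | $\mu m^2/T$ |
| $R_s$ | phase-field source magnitude | 100 | model units |
| $M$ | double-well barrier height | 1 | – |
| $\epsilon$ | interface parameter | 25 | $\mu m$ |
| $l$ | damage length scale | $2h_{fine}$ | $\mu m$ |
| $\eta_d$ | damage viscosity | 0.01 | – |
| $d_{\min}$ | residual stiffness | $10^{-4}$ | – |
| $\Psi_{cri}/l$ | fracture resistance $G_f$ | 100 | kPa |
| $p_{\max}$ | systolic lumen pressure | 120 mmHg $\approx$ 16 kPa | kPa |
| $c_{th}$ | inflammation nutrient threshold | 0.5 | – |
| $K_c, K_\phi, K_d$ | weak-form conditioning scalings | 1 | – |

Three of these deserve comment.

**$\epsilon$ is a length.** The interface parameter enters as
$\epsilon^2\nabla^2\phi$ on a micrometre mesh, so dimensional
consistency requires $\epsilon$ in $\mu m$; the value 25 gives an
interface a few fine elements wide.

**$k_g$ is dimensionless.** The growth law relates two rates, so the
coupling is a pure number; its printed value 10 makes the saturated
overgrowth $1+\alpha = e^{10\phi}$. This is an extremely strong
coupling: a region reaching $\phi = 0.5$ would demand a linear growth
stretch $e^5 \approx 148$, which no mesh can follow. Desk-scale runs
therefore probe the *early-lesion* regime ($\phi \lesssim 0.2$, growth
stretches up to $\sim e^2$) and the run horizons below are chosen
accordingly.

**The scenario wall uses $\mu = 60$ kPa.** A neo-Hookean tube of this
geometry has a finite quasi-static inflation capacity: tracing the
pressure–displacement curve, the wall balloons without bound as the
pressure approaches $\approx 0.49\,\mu$ (the incompressible thick-wall
asymptote is $\mu\ln(b/a) \approx 0.29\,\mu$; compressibility and the
follower load raise it). With $\mu = 30$ kPa the capacity
($\approx 14.7$ kPa) lies *below* the systolic load of 16 kPa, so no
equilibrium exists at full pressure. Since the wall stiffness is the one
constant known only approximately (literature values for coronary wall
stiffness scatter widely), the scenario harness doubles it to 60 kPa,
placing the working point at $\approx 55\%$ of capacity with margin for
the damage-weakened wall; `material_params()` keeps 30 kPa as the
generic constitutive default. At 16 kPa the stiffer wall still reaches
$\approx 20\%$ hoop stretch — firmly finite-strain.

**$c_{th} = 0.5$** (invented, atherosclerosis source only): lumen-fed
diffusion against uniform consumption drops $c$ by
$R_c t^2/2D_{\max} \approx 0.8$ across the wall, so a threshold at half
the luminal concentration marks roughly the outer third of an unsupplied
wall as starved — the region the VV exist to rescue. The ramp form
$S_\phi = R_s \max(c_{th}-c,0)/c_{th}$ rises linearly to the full rate
$R_s$ for completely starved tissue.

# Discretization and solver

* **Elements** — plain bilinear quads (plane strain, 5 DOF/node) and
  trilinear hexes (6 DOF/node) with full $2\times 2(\times 2)$ Gauss
  quadrature; no mixed or stabilized formulations. Near
  incompressibility at $\nu=0.49$ therefore produces the classical
  checkerboard pressure oscillation at Gauss level; volume-weighted
  patch averaging is used for nodal stress recovery and path plots.
* **Integration** — all integrals are pulled back exactly to the
  reference configuration ($dv = J\,dV$, spatial gradients via
  $\mathbf F^{-T}$); the damage gradient term uses material gradients,
  consistent with the damage field being defined in the reference
  configuration.
* **Element tangent** — central-difference perturbation of the element
  residual (step $3\times 10^{-6}$ scaled per DOF). Because the local
  growth update runs inside every residual evaluation, the perturbation
  tangent automatically carries the consistent sensitivity
  $\partial\alpha/\partial\mathbf D_e$.
* **Monolithic Newton with line search** — all four fields solve
  together; convergence is measured by per-field RMS residual norms
  scaled by their first-iteration values (tolerance $10^{-8}$). A
  residual-based backtracking line search (accept the largest step in
  $\{1, 1/2, \dots\}$ not substantially worse than the current residual)
  globalizes the iteration; the tension/compression indicator and the
  history-variable kinks make mild non-monotonicity legitimate, so the
  accept factor is 1.5.
* **Continuation** — the lumen pressure ramps on the intact wall first,
  then any Dirichlet phase-field values (the dissection damage nucleus)
  ramp at full pressure; both legs halve their increment on failure.
  During evolution, backward Euler steps cut $\Delta t$ by half on
  Newton failure (up to 8 cuts).
* **Safeguards** — $\phi$ and $d$ are clamped to $[0,1]$ before entering
  the constitutive laws; the consumption sink is multiplied by a smooth
  cutoff vanishing for $c\le 0$ (saturating at $c = 0.05$) so the
  nutrient cannot be driven far negative; accepted steps clamp nodal
  damage to its running maximum, enforcing irreversibility that
  Allen–Cahn relaxation alone would not guarantee.
* **Sources fully implicit** — $S_\phi$ uses current-iterate $c$ and
  $d$; a semi-implicit freeze at the previous iterate coincides at
  convergence but is less stable.
* **Time step** — $\Delta t = 2\times 10^{-4}$ resolves the fastest
  source time scale ($1/R_s = 10^{-2}$) by fifty steps and keeps the
  per-step growth increment $k_g\,\Delta\phi \lesssim 0.2$. Scenario
  horizons: $10^{-3}$ (atherosclerosis) and $1.4\times 10^{-3}$
  (dissection) model-time units — long enough for a developed lesion /
  opened hematoma, short enough that $e^{k_g\phi}$ growth stays
  mesh-resolvable. The broad inflammation band tolerates less growth
  than the localized hematoma, hence the shorter horizon.
* **Problem sizes** — tests and the acceptance analysis run the
  scenarios on the full coronary geometry with 20 $\mu m$ fine elements
  ($\approx 1.3\times 10^3$ quads, $\approx 7\times 10^3$ unknowns,
  $\lesssim 30$ accepted steps); unit and convergence studies use
  strips, patches and single elements.

# Scenario construction

Both scenarios share the half-annulus mesh, the occluded VV tree and the
boundary conditions: $c = 1$ on lumen and unoccluded VV nodes, zero
tangential displacement on the radial cut faces (a rotation
transformation handles skew faces; the half-annulus faces reduce to
$u_y = 0$ plus one translation pin), follower pressure on the deformed
lumen facets, natural zero-flux conditions for both phase fields.

*Atherosclerosis*: the fracture resistance is overridden with
$10^9$ kPa so damage never activates ($d$ stays at machine zero), and
the inflammation ramp source drives $\phi$ in the starved outer wall.

*Dissection*: the printed $G_f = 100$ kPa is kept and a damage nucleus —
a disc of radius $2h_{fine}$ pinned at $d = 1$, centred at the occlusion
point — represents the ruptured VV. The nucleus value ramps together
with the load continuation, which is equivalent at the end of the ramp
but avoids pressurizing an already-ruptured wall through the inflation
instability. Hematoma then grows inside the ruptured zone
($S_\phi = R_s c d$), swells it ($k_g$), loads the crack front
($\Psi_{\max}$) and propagates $d$ — the hydraulic-fracture loop.

# Known limitations

* The printed growth coupling caps how far the lesion can develop before
  growth stretches destroy any mesh; field states with $\phi \to 1$ are
  out of numerical reach, so assertions about the "lesion core" use the
  strongly inflamed region $\{\phi > 0.5\max\phi\}$ rather than an
  absolute $\phi > 0.5$.
* At desk resolutions the Gauss-level radial stress inside the lesion
  core is dominated by the near-incompressible checkerboard oscillation
  of plain quads: hoop compression in the core and the tensile
  surrounding shell reproduce robustly, while the core-averaged radial
  stress hovers around zero with positive sign. A mixed or B-bar element
  would fix this at the cost of leaving the printed element formulation.
* The hematoma aperture reaches a near-stress-free hydrostatic state
  (von Mises a few per mill of the wall peak) with only a slight net
  pressure: at the printed occlusion depth ($30\,\mu m$ under the free
  outer surface) the thin outer flap bulges rather than confines the
  swelling. Net compression strengthens with resolution and with
  hematoma development.
* No fluid–structure interaction with the lumen blood, no fiber
  anisotropy, no multi-layer wall, no long-range axial propagation; the
  3D path is a coarse extrusion intended for architecture checks, not a
  resolved 3D study.
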