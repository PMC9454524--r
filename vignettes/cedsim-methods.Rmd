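---
title: "Modelling combined antiangiogenic and liposomal cytotoxic drug delivery by CED"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling combined antiangiogenic and liposomal cytotoxic drug delivery by CED}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cedsim` simulates convection-enhanced delivery (CED) of a combination
therapy — an antiangiogenic antibody (bevacizumab-like) co-infused with a
cytotoxic drug (temozolomide-like), either free or liposome-encapsulated —
into a heterogeneous brain tumor whose tissue properties are quantified
voxelwise from dynamic contrast-enhanced (DCE) MR signals.  This vignette
documents the model, its assumptions, the numerical choices, and what the
synthetic phantom does and does not emulate.

## The tissue model

The tumor and its holding tissue are treated as a porous medium in which the
microvasculature acts as a distributed source.  Each voxel is partitioned
into plasma, extracellular space (ECS), cell membrane (CM) and intracellular
space (ICS) with volume fractions closing to one:
$\epsilon_{BL} + \epsilon_{ECS} + \epsilon_{CM} + \epsilon_{ICS} = 1$.
The CM/ICS ratio is fixed (0.154 in tumor, 0.188 in normal tissue), so the
closure determines $\epsilon_{ICS}$ and $\epsilon_{CM}$ from the two
imaging-derived fractions.

Interstitial fluid flow is quasi-steady Darcy flow with Starling
transvascular exchange,
$$-\nabla\cdot\!\left(\tfrac{\kappa}{\mu}\nabla p\right) = F_{BL}(p) + q_{in},
\qquad
F_{BL} = L_{BL}\,\varphi \tfrac{S_{BL,0}}{V_T}\,
\big[p_{BL} - p - \sigma_{BL}(\pi_{BL}-\pi_{ISF})\big],$$
with the infusion entering as a volumetric source in the catheter-tip cell.
The full momentum balance also contains inertia and Brinkman drag, but at
tissue scales ($v \lesssim \mu$m/s, $\kappa \sim 10^{-14}\,$m$^2$) the Darcy
drag term exceeds the neglected terms by more than six orders of magnitude,
so the reduced quasi-steady form is solved and simply re-solved whenever the
vasculature (hence $F_{BL}$) has changed appreciably.  The fluid density is
retained in the property tables for completeness but is not used by the
reduced solver.

Three species are transported in the ECS: the liposome carrier
($C_{LP}$), the released free cytotoxic drug ($C_{FD}$, with equilibrium
protein binding $K_{BC}$ and cell partitioning $H_{IE}$, $H_{CE}$ folded
into the capacity factor
$\omega = \epsilon_{ECS}(1{+}K_{BC}) + \epsilon_{ICS}H_{IE}(1{+}K_{BC}) +
\epsilon_{CM}H_{CE}$), and the antiangiogenic antibody ($C_{AA}$).  Sinks
are liposome release ($k_{rel}$), transvascular drainage
($k_{\cdot,b} = P_{TV}\,\varphi S_{BL,0}/V_T$, scaling linearly with the
vascular state), and first-order elimination ($k_e$).  The convection terms
appear in the governing equations as
$-v\cdot\nabla(\epsilon C) - F_{BL}\,\epsilon C$; because the discrete face
velocities satisfy $\nabla\cdot v = F_{BL} + q_{in}$ exactly, this pair is
implemented as the conservative upwind divergence
$-\nabla\cdot(\epsilon C\, v)$, which keeps the global drug budget closed to
the solver tolerance.  The free-drug ICS elimination term is generalized to
$(\epsilon_{ECS} + \epsilon_{ICS}H_{IE})k_e$, which reduces to the printed
$(\epsilon_{ECS}+\epsilon_{ICS})k_e$ form at the default $H_{IE}=1$.

Antiangiogenesis acts through a scaling factor $\varphi \in [0,1]$ on the
microvascular surface density,
$$\frac{d\varphi}{dt} = \varphi(\alpha + \beta\varphi + \gamma\varphi^2)
 - k_a \varphi C_{AA},$$
with the natural-angiogenesis coefficients summing to zero so that
$\varphi = 1$ is exactly stationary without drug.  Vessel shrinkage releases
plasma volume into the ECS: $\epsilon_{BL} = \varphi^2\epsilon_{BL,0}$ with
CM and ICS held constant and ECS absorbing the difference.

## DCE quantification

The imaging chain mirrors a 2-minute T1-perfusion acquisition (TR 6.27 ms,
TE 3.0 ms, flip 10°, 3.8 s temporal resolution; gadoterate relaxivities
R1 = 3.5, R2 = 4.9 mM$^{-1}$s$^{-1}$).  Signal enhancement follows the SPGR
steady-state equation including the $\exp(-TE\,R_2 C)$ attenuation;
inversion to concentration uses bracketed root finding restricted to the
monotone low-concentration branch $[0, C^*]$ (the first stationary point),
returning the smallest nonnegative root — appropriate for the concentrations
reached in a short acquisition.  Ratios that dip below the pre-contrast
level (noise) clamp to zero with a warning.

Pre-contrast T1 is estimated from three fast spin-echo images by a
two-ratio method: the equal-TR T2-weighted/PD pair yields
$T_2 = (TE_2 - TE_3)/\ln(S_{PD}/S_{T2w})$, after which the T1-weighted/PD
ratio equation is solved for $T_1$.  The upstream reference for this step
describes only the inputs, so the method here is declared explicitly and
validated against its own forward model (exact inversion without noise,
median error under 5% at 1% noise).

Voxel kinetics use the leaky tracer kinetic model (LTKM):
$$C(t) = \epsilon_{BL} c_b(t)
 + K^{trans}\!\int_0^t c_b(\tau)\,e^{\frac{K^{trans}}{\epsilon_{ECS}}(\tau-t)}d\tau
 + \lambda_{tr}\!\int_0^t c_b(\tau)\,d\tau,$$
with trapezoid quadrature at the acquisition sampling (a 1000x oversampled
quadrature oracle bounds the discretization error below 0.5% in tests).  The
leakage constant $\lambda_{tr}$ is taken in s$^{-1}$ for dimensional
consistency.  Fitting is bounded Levenberg–Marquardt (fractions in $[0,1]$,
rates in $[0,1]$ s$^{-1}$) from three deterministic starts, keeping the
lowest residual and breaking ties toward the smaller leakage constant;
fixing $\lambda_{tr}=0$ recovers the general (non-leaky) model.  The
microvascular surface density map is scaled from the Ktrans map,
$S_{BL,0}/V_T = (K^{trans}/K^{trans}_{avg})(S_{BL}/V_T)_b$, with the average
taken over the tumor mask only and the per-region literature baselines
($2.0\times10^4$ m$^{-1}$ tumor, $7.0\times10^3$ m$^{-1}$ normal); normal
voxels use the same voxelwise ratio against the normal baseline.

## The synthetic phantom

No patient data accompany the model, so every stage is exercised on a
synthetic phantom: an ellipsoidal tumor (default semi-axes 12/16/14 mm,
between the two—mutually inconsistent—published descriptions of the
reference tumor as "16 mm equivalent radius" and "5461 mm$^3$") inside a
box of homogeneous normal tissue (58 x 97 x 72 mm at 0.9 x 0.9 x 6 mm
voxels by default).  Tumor fields are Gaussian random fields (white noise
smoothed with a Gaussian kernel at the stated correlation length, affinely
rescaled into the target range): the plasma fraction spans
$2.22\times10^{-14}$–$9.66\times10^{-2}$ and the intracellular fraction
starts at 0.5808, matching the spread reported for patient maps.  Two
deliberate deviations from a literal reading of those published numbers:

* the published upper intracellular bound of 0.999 is infeasible under the
  closure with $\epsilon_{CM} = 0.154\,\epsilon_{ICS}$ (the feasible
  maximum is $1/1.154 \approx 0.866$); the generator clips the
  intracellular field so the ECS keeps a small positive floor (0.005);
* the intracellular field is anticorrelated with the plasma-fraction field
  (mixing weight 0.6 by default).  Patient maps show exactly this joint
  structure — low porosity and low microvascular density where cell density
  is high — and drawing the fields independently can place the
  maximum-vascularity voxel (the default catheter site) on the porosity
  floor, which no real densely-vascularized tumor region exhibits.

Ktrans is proportional to the plasma fraction (correlated vascularity) with
tumor mean $3\times10^{-3}$ s$^{-1}$; the leakage constant spans
$0$–$10^{-4}$ s$^{-1}$.  Normal tissue gets homogeneous textbook values
(plasma fraction 0.008, ECS 0.20, Ktrans $2\times10^{-5}$ s$^{-1}$, T1 1.0 s
vs 1.4 s in tumor).  The arterial input is a delayed double-exponential
bolus (arrival 10 s, rise 0.1 s$^{-1}$, washout 0.01 s$^{-1}$, peak ~5.6 mM)
with an optional second washout compartment, off by default; with it off the
curve's mode has the closed form $t_0 + \ln(m_f/m_s)/(m_f - m_s)$.  Signal
noise is additive Gaussian at a chosen fraction of baseline — real MR
magnitude noise is Rician, so the phantom understates bias at very low
signal; fits are only exercised at enhancement levels where the Gaussian
approximation is benign.  Passing the phantom round trip therefore shows
the estimator chain is self-consistent and noise-robust, not that it is
unbiased on scanner data.

## Numerics

The flow system is a symmetric positive definite 7-point finite-volume
stencil (harmonic-mean face conductances, Dirichlet zero-gauge outer
boundary, no-flux exterior/catheter cells, Starling exchange folded into
the diagonal) solved by Jacobi-preconditioned conjugate gradients to a
relative residual of $10^{-8}$ by default ($10^{-10}$ in verification
runs); discrete fluid balance closes to better than $10^{-6}$.  Transport
uses operator splitting per time step: (i) the per-cell linear reaction
system (release -> free drug, drainage, elimination) is integrated
*exactly* via its closed-form solution, so well-mixed kinetics match scalar
ODE references to round-off; (ii) conservative first-order upwind
convection on the face fluxes, sub-cycled to a Courant number of 0.5;
(iii) implicit (backward-Euler) diffusion per species.  Infused species are
held at the infusion concentration in the tip cell (Dirichlet) for the
infusion duration; the outer boundary is zero-diffusive-flux with free
convective outflow (a pure zero-total-flux condition would contradict the
zero-gauge pressure outflow).  The catheter shaft is a line of blocked
cells from the entry boundary to the tip.  Flow and transport are coupled
through $\varphi$: the flow problem is re-solved whenever
$\max|\Delta\varphi|$ since the last solve exceeds 0.01 ($F_{BL}$ varies
only through $\varphi$ and $p$).  The vascular ODE takes one classical RK4
step per transport step, accurate to ~$10^{-8}$ at these rates.

The default transport step is 60 s (release and reaction timescales are
$\gtrsim 10^3$ s); study-scale runs in the test-suite and acceptance script
use 120 s steps on a 32$^3$ grid (48 mm box, 1.5 mm cells, 3 simulated
days), which a step-halving check shows changes Day-end tumor-averaged
concentrations by under 0.1%.  First-order upwinding adds numerical
diffusion of order $vh/2$; near the tip this is comparable to the free
drug's physical diffusivity and far exceeds the liposome's, so sharp
near-tip gradients are smoothed at coarse resolution — regimen *orderings*
are robust to this in refinement checks, absolute near-tip concentrations
are not grid-converged at 1.5 mm.

Point-source verification compares the infusion pressure field against
$Q\mu/(4\pi\kappa r)$ with analytic Dirichlet boundary values.  The
comparison is made on spherical-shell averages (the same construction as
the distance-course metric) because the discrete lattice Green's function
of the 7-point stencil deviates ~8% from $1/(4\pi r)$ at two cells
on-axis — a stencil property that does not vanish with refinement at fixed
$r/h$ — while shell averages agree to better than 1% from $2h$ outward.

A deliberate non-goal: the reference patient study reports infusion-site
pressures above $10^5$ Pa, which are not recoverable from the printed
homogeneous parameters with a volumetric-source inlet (they depend on
unstated inlet/porosity treatment and patient geometry).  The solver is
instead verified to raise the tip pressure above the no-infusion
equilibrium and to scale with $Q$ exactly.

## Delivery metrics

Four outcome measures are computed over the tumor mask by default (a
whole-tissue option exists): the ECS-volume-weighted spatial average of the
free drug; distance courses (volume-weighted shell means around the
infusion site, shell width defaulting to the 0.9 mm in-plane cell size — the
shell definition is otherwise unspecified upstream); the distribution
non-uniformity NUN (weighted mean absolute deviation over the mean); and
the effective distribution volume $V_{eff}$, the tissue volume at or above
the free drug's LD90 ($3.9\times10^{-5}$ M), threshold inclusive.  Whether
$V_{eff}$ should include normal tissue is unstated upstream; tumor-only is
the default and a mask argument makes it configurable.

## Regimens and orchestration

Four regimens share the infusion settings (3.0 uL/min for 3 days): plain
cytotoxic drug, plain + antiangiogenic, liposomal, and liposomal +
antiangiogenic; infused species are held at $5.15\times10^{-3}$ M
(cytotoxic, free or encapsulated) and $7.26\times10^{-5}$ M (antibody) in
the tip cell.  The default catheter site is the maximum-plasma-fraction
tumor cell (densest microvasculature); site-sensitivity sweeps select tumor
cells at chosen quantiles of plasma or intracellular fraction.
`run_experiment()` orchestrates phantom -> optional DCE fitting ->
simulations -> metrics, writing NIfTI maps, CSV series and a JSON log, and
is bit-reproducible for a fixed seed.  For the non-infused cytotoxic
species in liposomal regimens the tip cell is an ordinary cell (the
zero-free-drug-flux wall condition applies to the catheter wall, which is
blocked); released drug may accumulate there.  Because the governing
equations convect the quantity $\epsilon_{ECS}C$ (not $C$), a steep
porosity drop next to the infusion cell can transiently raise $C$ above
the infused concentration in the low-porosity neighbour — the Dirichlet cap
is a property of the infusion cell itself.

## What the regimen comparison does and does not show

On the default phantom the four regimens separate cleanly on distribution
quality and treatment effectiveness: the liposomal + antiangiogenic
combination yields the most uniform free-drug field (lowest NUN) and the
largest effective distribution volume, the plain infusion alone the most
heterogeneous and least effective — and infusing at denser-vasculature /
lower-cell-density sites improves all three outcome measures.  On
*average* free-drug concentration, however, the plain infusions outscore
their liposomal counterparts here.  This is a direct consequence of the
parameter set: per unit of stored drug the liposome is cleared at
$k_{rel} + P_{TV,LP}\varphi S/V$ (~$2\times10^{-3}$ s$^{-1}$ at baseline
vasculature and more at the densest-vasculature infusion site), whereas
the released drug — buffered by protein binding and cell partitioning
($\omega \approx 1.07$ against $\epsilon_{ECS}\approx0.35$) — is cleared
several-fold more slowly, and both species share the same fate after
release.  Encapsulation with these rate constants trades average exposure
for uniformity and coverage; reports that it also maximizes average
exposure imply a slower-releasing or less-permeable carrier than the
parameter table used here.

## Known limitations

Tissue deformation, catheter backflow, oedema, liposome cell uptake,
multi-catheter designs and staggered infusion schedules are out of scope,
as in the source model.  $\kappa$ is held fixed as the ECS grows under
antiangiogenesis.  Reabsorbing vasculature ($F_{BL}<0$) keeps the same
conservative convective form (drug follows the fluid).  The phantom's
spatial covariance (correlation length, anticorrelation weight) is a free
parameter — patient maps' true covariance is unpublished — so quantitative
results are phantom-specific; only the qualitative regimen and
site-sensitivity patterns are expected to transfer.
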