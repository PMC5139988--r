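---
title: "Modelling small-angle scattering data with atomistic ensembles"
author: "scatterfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling small-angle scattering data with atomistic ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatterfit)
```

## The modelling problem

Small-angle X-ray and neutron scattering (SAXS/SANS) measure the
orientationally averaged intensity $I(Q)$ of particles in solution, with
$Q = 4\pi\sin\theta/\lambda$. The measurement is low-resolution and
one-dimensional, so on its own it cannot determine a structure. The
workflow this package implements inverts the problem with prior knowledge:
start from an atomistic model, generate a large ensemble of physically
plausible conformations by Monte Carlo moves of backbone torsions, compute
each conformer's theoretical curve, and keep the conformers whose curves
agree with the experimental one. The output is a best-fit sub-ensemble and
a density envelope, not a single refined structure — an honest reflection
of what the data can support.

The package covers the four stages around that loop:

1. **Validation** (`scanStructure`, `applySymmetry`) — simulation readiness
   of a starting PDB model: chain gaps, missing heavy atoms, nonstandard
   residues, disulphides, and biological-unit expansion from REMARK 350
   operators.
2. **Ensemble generation** (`runMonomerMC`) — Markov-chain sampling of
   $\varphi/\psi$ torsions in user-declared flexible regions under purely
   geometric acceptance rules.
3. **Curve calculation** (`intensityGolden`, `intensityDebye`,
   `buildSphereModel`/`intensitySphereDebye`, `smearGaussian`,
   `addBackground`) — all-atom and coarse-grained calculators with
   neutron/X-ray contrast handling.
4. **Analysis** (`guinierFit`, `chiSquare`, `rFactor`, `fitEnsemble`,
   `filterModels`, `densityMap`) — goodness-of-fit metrics, best-fit
   selection and volumetric envelopes.

## The calculators and their assumptions

**Debye equation.** The exact orientational average for point scatterers
with amplitudes $f_j$:
$$I(Q) = \sum_j \sum_k f_j f_k \,\frac{\sin Q r_{jk}}{Q r_{jk}}.$$
Cost is $O(n^2)$ per $Q$ point; `intensityDebye` is the reference
implementation every faster path is tested against.

**Golden-vector method.** $I(Q)$ is evaluated as the average of
$|\sum_j f_j e^{i Q \hat u_m \cdot r_j}|^2$ over $M$ quasi-uniform unit
directions $\hat u_m$ from the golden-ratio spiral
($z_k = 1-(2k-1)/M$, azimuth $2\pi k/\varphi_g$). It is exact in the limit
$M \to \infty$ and, at the default $M = 1000$, matches the Debye sum to
well under 1% for the configurations tested (50 atoms, $Q \le 0.5$
Å$^{-1}$). $I(0) = (\sum_j f_j)^2$ holds exactly for every $M$.

**Coarse-grained sphere model.** A cube grid (default side 5.30 Å,
anchored at the coordinate minimum) is laid over the structure; cubes
holding at least 4 atoms become equal spheres of cube-equivalent volume
(radius $5.30\,(3/4\pi)^{1/3} = 3.288$ Å, roughly one sphere per 4–5
atoms). The curve is the Debye sum over sphere centres modulated by the
single-sphere form factor
$g(Q) = [3(\sin QR - QR\cos QR)/(QR)^3]^2$, with unit weight per sphere
(single-density model). The model is meaningful only while the sphere
diameter stays below the structural resolution of the curve, i.e. for
$Q \lesssim 2\pi/(2R_{\rm res})$ with $R_{\rm res} \approx 1$ nm; the
calculator warns beyond that bound. Because all spheres carry the same
weight, the model assumes the particle is homogeneous at the cube scale —
true for packed proteins, increasingly false for loosely packed synthetic
test bodies. Against a homogeneous compact body at protein heavy-atom
density the dry sphere-model curve agrees with the all-atom Debye curve to
an R factor below 5% over the validity range; we quote the agreement as an
R factor because pointwise relative error is dominated by the near-zero
form-factor minima that any below-resolution model misses.

**Hydration shell.** X-ray work sees a bound-water monolayer of about
0.3 g of water per gram of protein; `addHydration` adds water-filled
surface cubes (each $5.30^3 \times 0.6022 = 89.7$ Da, about five waters)
until that mass is reached. Candidate cubes are the *empty* grid cubes
sharing a face with a dry cube — cubes that contain any atoms, even fewer
than the occupancy cutoff, belong to the particle and are excluded, which
keeps the shell outside the molecular envelope and guarantees the hydrated
radius of gyration exceeds the dry one. Candidates are consumed in
decreasing order of dry-neighbour count with ties broken in lattice order,
a deterministic stand-in for the exact monolayer construction of the
original coarse-grained tools. Neutron runs in D$_2$O skip the shell (the
bound water is nearly contrast-matched); the CLI wires this default by
mode.

**Contrast.** Neutron amplitudes are coherent scattering lengths with
labile hydrogens (those on N/O/S, recognized from PDB naming) interpolated
between $b_H$ and $b_D$ by the solvent D$_2$O fraction times an exchange
fraction (default 1). X-ray amplitudes are electron counts — the
$Q$-independent form-factor approximation, adequate for $Q \le 0.5$
Å$^{-1}$. Optional solvent-excluded-volume subtraction uses tabulated
displaced volumes and is off by default (the sphere-model path models the
particle at uniform contrast). `sldMatchpoint` gives the contrast-variation
match point from composition and volume, with water volume 29.9 Å$^3$.

**Instrumental corrections.** Neutron curves can be smeared with a
Gaussian kernel of width
$\sigma(Q)^2 = \sigma_{\rm geo}^2 + (Q\,\Delta\lambda/\lambda)^2/(8\ln 2)$
(the named physical causes are wavelength spread and beam divergence; the
Gaussian form is our choice, evaluated by trapezoidal quadrature on the
curve's own grid with per-point normalization). A linear buffer background
$a + bQ$ models residual incoherent proton scattering.

## The Monte Carlo sampler

Each trial picks a flexible residue uniformly, then one of its allowed
torsions ($\varphi$: N–C$\alpha$ axis; $\psi$: C$\alpha$–C axis), then a
step from $U(-\delta_{\max}, +\delta_{\max})$, and rigidly rotates
everything C-terminal to the bond (the N-terminal side is the anchor).
Acceptance is purely geometric — steric overlap, optional $R_G$ window,
optional distance constraints — with no Boltzmann factor: energetic
refinement belongs to downstream force-field tools. Every accepted state
is stored as a frame and becomes the current state; rejected trials
revert. One seeded generator drives the three draws per trial, so runs are
bit-reproducible.

Parameters that matter:

* `overlapCutoff` (Å, default 3.0 = 0.3 nm): minimum allowed heavy-atom
  pair distance, excluding same- and adjacent-residue pairs (covalent
  neighbours; no bond topology is required). The check uses a cell-list
  grid in compiled code; an $O(n^2)$ scan re-validates frames in the test
  suite.
* `maxStepDeg` (default 30): published workflows span 10–80° depending on
  how local the search should be; 30° balances acceptance rate and
  decorrelation for linker sampling.
* `rgBounds` (Å): accepted frames must lie in this window. Because a state
  is only adopted when it satisfies every constraint, a window that
  excludes the *starting* structure can never be entered — the sampler
  warns in that case. Choose a window containing the start.
* Proline $\varphi$ is formally rotatable but ring-constrained; sampling
  it would tear the pyrrolidine ring, so such moves are refused (dropped
  from the move set with a warning).

Torsion moves are rigid rotations, so bond lengths and bond angles are
exactly preserved. One subtlety: a $\psi$ rotation carries the carbonyl O
with the downstream chain (keeping O anti to the next amide N — the
chemically correct convention), so the *1–4 distances* O–N and O–C$\beta$
inside a sampled residue change with the torsion, as they must. The
chemistry-preservation checks in the test suite therefore verify all
intra-residue distances except pairs split by a sampled torsion axis.

## Curve comparison and filtering

The model curve is interpolated onto the experimental grid (preserving the
experimental uncertainties) and scaled by $c = I(0)_{\rm expt}/I(0)_{\rm
model}$, with the experimental $I(0)$ supplied from Guinier or $P(r)$
analysis; a least-squares `autoScale` is available for curves lacking one.
Metrics:

* $\chi^2 = \sum_i [(I_e(Q_i) - c I_m(Q_i))/\sigma_i]^2$, and the reduced
  form $\chi^2/(N-1)$ — $N-1$ because the scale is the one fitted
  parameter.
* Pearson $\chi^2 = \sum_i (I_e - c I_m)^2/(c I_m)$, for curves without
  usable error estimates ($c I_m$ in the denominator; the alternative
  convention with $I_e$ exists, ours is documented here).
* R factor $= 100 \sum_i |I_e - c I_m| / \sum_i |I_e|$ per cent,
  crystallography-style; best-fit SAXS/SANS analyses typically land at
  2–8%, and a correct model with correctly estimated errors gives reduced
  $\chi^2 \approx 1$.

`filterModels` selects frames by metric threshold, best-$N$ rank and/or an
$R_G$ window; `densityMap` accumulates the selected frames on a voxel grid
(one-voxel margin around the bounding box) and `writeCube` writes the
occupancy (counts/frames) as a Gaussian cube file with lengths in Bohr.

`guinierFit` iterates a weighted fit of $\ln I$ against $Q^2$ until all
included points satisfy $Q R_G \le 1.3$ (the conventional bound for
globular particles; pass a smaller `qrgMax` for very small or elongated
bodies — the expansion is shape-independent only for $Q R_G \lesssim
0.5$).

## What the synthetic fixtures do and do not emulate

`buildPolypeptide` constructs heavy-atom polypeptides with ideal backbone
geometry (N–C$\alpha$ 1.458 Å, C$\alpha$–C 1.525 Å, C–N 1.329 Å, trans
omega) at uniform extended ($-120/120$) or helical ($-57/-47$) torsions;
side chains come from internal-coordinate templates at fixed rotamers,
with the L-configuration set by the improper torsion
N–C–C$\alpha$–C$\beta$ = +123° (measured from a deposited structure).
`makeTwoDomainSystem` joins two helical domains with a 5-residue extended
linker — the minimal multi-domain topology with a flexible inter-domain
region — and `makeNoisyCurve` adds seeded multiplicative Gaussian noise
with $\sigma_i$ equal to the noise fraction times the intensity, emulating
a three-column experimental data file. The default noise of 2% is typical
of well-measured solution curves.

These fixtures deliberately lack hydrogens, realistic rotamer variety,
sequence-dependent geometry, solvent structure and real counting
statistics. Tests passing on them demonstrate that the machinery is
correct (calculators agree with closed forms and with each other, samplers
preserve chemistry and respect constraints, metrics are calibrated), not
that any particular real system is well modelled; conclusions about real
data still require real experimental curves and force-field-quality
starting structures.

## Numerical choices

* Lengths are Å and $Q$ is Å$^{-1}$ throughout (PDB-native); file readers
  and the CLI accept nm$^{-1}$ via a unit flag (factor 10).
* Alternate locations: the first-seen conformer is kept by default.
* DCD files are written little-endian (CHARMM convention, version stamp
  24, no unit-cell block); the reader detects endianness from the first
  record marker and reports the number of complete frames when a file is
  truncated.
* The cube grid is anchored at the coordinate minimum — deterministic, no
  origin search; origin sensitivity is a measured property, not something
  optimized away.
* Curves with zero quoted errors get a tiny positive sigma floor
  ($10^{-6}$ of the peak intensity) so exact curves flow through the
  $\chi^2$ machinery.
* Sphere-model and density-map tie-breaks are lattice-ordered, so every
  output is reproducible bit-for-bit.
* Problem sizes used by the validation suite: 10,000-frame MC runs on the
  29-residue two-domain fixture (145 heavy atoms), 5,000-frame ensemble
  fits against 25-point curves, 20 seeded 50-atom configurations for the
  calculator cross-check, 100 noise replicates for the $\chi^2$
  calibration. These sizes make every claim recomputable in about a
  minute each on one CPU while leaving the statistics comfortably clear of
  their thresholds.

## Known limitations

* Monomer MC handles single-chain flexible regions; multi-segment rigid
  bodies, nucleic-acid torsions and glycan re-modelling are out of scope.
* No energy model: ensembles are sterically plausible, not thermodynamic.
* X-ray form factors are constant per element; beyond $Q \approx 0.5$
  Å$^{-1}$ use a wide-angle tool.
* The hydration rule is a documented geometric stand-in for the original
  monolayer construction; shell densities other than bulk water are not
  modelled.
* PDB parsing covers the fixed-column dialect (no mmCIF); structures with
  insertion codes or >62 chains after symmetry expansion are rejected
  rather than guessed at.

## A compact end-to-end example

```{r example, eval = FALSE}
sys <- makeTwoDomainSystem()
res <- runMonomerMC(sys$structure, sys$region,
                    mcConfig(nAcceptTarget = 5000, seed = 42))

# synthetic "experiment": a compact conformer observed with 2% noise
f <- assignAmplitudes(sys$structure, contrastModel("xray"))
pre <- runMonomerMC(sys$structure, sys$region,
                    mcConfig(nAcceptTarget = 500, seed = 41))
truth <- getFrame(pre@ensemble, which.min(pre@perFrameRg))
q <- seq(0.01, 0.30, length.out = 25)
expt <- makeNoisyCurve(intensityDebye(truth, f, q), 0.02, seed = 99)

fits <- fitEnsemble(res, expt, i0Expt = sum(f)^2, amplitudes = f)
best <- fits[which.min(fits$chi2_reduced), ]
sel <- filterModels(fits, threshold = 2)
writeCube(densityMap(res@ensemble, sel, spacing = 2), "bestfit.cube",
          sys$structure)
```

The $\chi^2$-versus-$R_G$ scatter of `fits` shows the characteristic
U-shape: conformers far from the generating compactness fit poorly on both
sides, and the minimum sits at the truth's $R_G$.
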