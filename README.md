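# scatterfit

Atomistic ensemble modelling of small-angle X-ray and neutron scattering
(SAXS/SANS) data in R.

Solution scattering measures a single orientationally averaged intensity
curve I(Q), with Q = 4π sinθ/λ. On its own that cannot determine a
structure — but given an atomistic starting model it can arbitrate between
conformations. `scatterfit` implements the full arbitration workflow for
flexible biomolecules:

1. **Validate** a starting PDB model for simulation readiness
   (`scanStructure`: chain gaps, missing heavy atoms, nonstandard
   residues, disulphides; `applySymmetry`: biological-unit expansion from
   REMARK 350 operators).
2. **Generate** a conformational ensemble by Markov-chain Monte Carlo over
   backbone φ/ψ torsions in user-declared flexible regions
   (`runMonomerMC`), with purely geometric acceptance: a steric overlap
   cutoff (default 3.0 Å = 0.3 nm on heavy atoms), an optional radius-of-
   gyration window and optional distance constraints. Ensembles read and
   write the binary DCD trajectory format used by the CHARMM/NAMD family.
3. **Calculate** theoretical curves per frame:
   - the exact all-atom Debye equation,
     I(Q) = Σ_jk f_j f_k sin(Q r_jk)/(Q r_jk);
   - the golden-vector method — |Σ_j f_j exp(iQ û_m·r_j)|² averaged over a
     quasi-uniform direction set built from the golden ratio (near-linear
     in atoms per direction, converges to the Debye sum);
   - a coarse-grained sphere model: a 5.30 Å cube grid with a 4-atom
     occupancy cutoff, equal spheres of cube-equivalent volume
     (R = 3.288 Å), Debye sum over centres times the sphere form factor
     [3(sin QR − QR cos QR)/(QR)³]², optionally with a 0.3 g/g hydration
     monolayer of water-filled surface cubes for X-ray work;
   - neutron/X-ray contrast handling (scattering-length tables, H/D
     exchange of labile hydrogens with solvent D₂O fraction, SLD match
     points), Gaussian beam smearing and linear buffer background.
4. **Analyze**: Guinier fits (ln I vs Q², Q·Rg ≤ 1.3), the reduced χ²,
   χ², Pearson χ² and crystallography-style R-factor comparison metrics
   (model scaled by c = I(0)_expt/I(0)_model), best-fit frame selection,
   P(r) and Kratky transforms, and volumetric occupancy envelopes written
   as Gaussian cube files.

A fixtures module (`buildPolypeptide`, `makeTwoDomainSystem`,
`makeNoisyCurve`) generates ideal-geometry polypeptides and synthetic
noisy curves so the entire pipeline runs and is testable with no external
data.

## Worked example

Recover a compact conformation from a noisy synthetic curve:

```r
library(scatterfit)

sys <- makeTwoDomainSystem()      # two helical domains + flexible linker
sys$structure
#> Structure: 145 atoms, 29 residues, 1 chain(s)
#>   title: synthetic two-domain system

res <- runMonomerMC(sys$structure, sys$region,
                    mcConfig(nAcceptTarget = 2000, seed = 42))
res
#> MCResult: 2000 accepted / 2130 trials (93.9%)
#>   rejections: overlap=130, rg_bounds=0, distance=0
#>   Rg range: 8.37 - 16.49 Ang

# synthetic "experiment": a compact conformer observed with 2% noise
f <- assignAmplitudes(sys$structure, contrastModel("xray"))
pre <- runMonomerMC(sys$structure, sys$region,
                    mcConfig(nAcceptTarget = 500, seed = 41))
truth <- getFrame(pre@ensemble, which.min(pre@perFrameRg))  # Rg 8.62 A
q <- seq(0.01, 0.30, length.out = 25)
expt <- makeNoisyCurve(intensityDebye(truth, f, q), 0.02, seed = 99)

guinierFit(expt)[c("i0", "rg")]       # I0 = 917452, Rg = 8.70 A
fits <- fitEnsemble(res, expt, i0Expt = sum(f)^2, amplitudes = f)
fits[which.min(fits$chi2_reduced), c("frame", "chi2_reduced", "r_factor", "rg")]
#>      frame chi2_reduced r_factor    rg
#> 1610  1610        0.974    1.308 8.691

length(filterModels(fits, threshold = 2))
#> [1] 8
```

The best-fitting frame has reduced χ² = 0.97 (statistically perfect for
2% errors), an R factor of 1.3% (well inside the 2–8% range typical of
good solution-scattering fits), and Rg 8.69 Å against the ground truth's
8.62 Å — the curve alone localizes the ensemble to the right compactness.
`densityMap`/`writeCube` turn the 8 accepted frames into an envelope for
a molecular viewer.

A thin command-line front end over the same functions is installed at
`inst/scripts/scatterfit` (subcommands `scan`, `fixtures`, `mc`, `calc`,
`fit`, `envelope`, `interp`).

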