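# solnmr

Quantitative analysis for protein solution-NMR studies of structure,
backbone dynamics and binding, of the kind used to characterize a small
(~10 kDa) inhibitor protein and its target: ^15N relaxation analysis,
residual dipolar coupling (RDC) alignment tensors, structural-ensemble
precision, restraint accounting, and one-site isothermal titration
calorimetry (ITC). It is aimed at spectroscopists who have peak
intensity tables, RDC tables, coordinate ensembles and integrated
injection heats, and want the downstream numbers with explicit error
models and reproducible seeds.

## What it computes

**Relaxation.** Per-residue R1 and R1ρ by monoexponential fitting with
Monte Carlo errors; R2 from R1ρ by the offset correction
`R2 = (R1ρ − R1·sin²θ)/cos²θ`, `θ = arctan(Ω_N/γ_N B1)`; heteronuclear
¹H–¹⁵N NOE as I_sat/I_ref; the global rotational correlation time τc
by numerically inverting the rigid-rotor R2/R1 ratio over trimmed
ordered-region residues; and a per-residue dynamics classification
(rigid / fast / exchange / both / broadened-missing) from the NOE < 0.8
and elevated-R2 criteria.

**RDC tensors.** Linear (SVD) fit of the traceless alignment tensor A
in `D = vᵀAv`, reporting the axial magnitude Da = Azz/2, rhombicity
R = (Axx − Ayy)/(3Da), Euler angles, bootstrap errors and the R-factor
`100·sqrt(mean((Dobs−Dcalc)²)/(2·mean(Dobs²)))`.

**Ensembles.** Kabsch superposition (reflections excluded), coordinate
precision as mean RMSD to the iteratively-refined mean structure over a
residue/atom selection, per-residue RMSD profiles, and restraint
tallies (NOE + dihedral + H-bond + RDC, per-residue density).

**ITC.** One-site Wiseman isotherm with displacement-volume dilution,
dilution-blank subtraction, multi-start nonlinear fitting of
(n, K_D, ΔH), the decomposition ΔG = RT·ln K_D and −TΔS = ΔG − ΔH,
and affinity-enhancement ratios between binding modes.

**Synthetic data.** Every input can be generated with known truth:
Lipari–Szabo model-free rates (S², τc, τe, Rex at a stated field),
noisy exponential decays, couplings from a known tensor, one-site
thermograms, and multi-model coordinate ensembles with controlled
per-residue scatter. All generators take explicit seeds.

## Worked example

```r
library(solnmr)

# tumbling time of 20 rigid residues simulated at 800 MHz
r <- modelfreeRates(SpinParams(s2 = 0.87, tauC = 6.2, tauE = 50,
                               rex = 0, fieldH1 = 800))
rates <- data.frame(residue_id = 1:20, r1 = r$r1, r2 = r$r2, noe = r$noe)
estimateTauc(rates, fieldH1 = 800)
#> TumblingEstimate: tauC = 6.108 ns from 20 residues ( 0 trimmed )

# one-site ITC: 20 x 2 uL of 500 uM titrant into 50 uM cell at 25 C
fitOneSite(simulateItc(1, 4.8e-6, -11.5, InjectionSchedule()))
#> BindingFit (one-site):
#>   n      = 1
#>   KD     = 4800 nM
#>   dG     = -7.3 kcal/mol
#>   dH     = -11.5 kcal/mol
#>   -TdS   = 4.2 kcal/mol

# alignment tensor refit from 79 noise-free synthetic couplings
tens <- AlignmentTensor(da = 7.3, rhombicity = 0.35, euler = c(30, 50, 70))
bv <- randomBondVectors(79, seed = 1)
fit <- svdFit(bv, simulateRdc(tens, bv), nBoot = 0)
c(Da(fit), rhombicity(fit))
#> [1] 7.30 0.35
```

The τc of 6.11 ns recovered from rates generated at 6.2 ns illustrates
the small (≈1.5%) bias of the rigid-rotor inversion when the generator
uses S² = 0.87 with a 50 ps internal motion; the tensor and ITC refits
are exact on noise-free input. `runPipeline()` binds the stages into a
config-driven run that writes per-stage TSV/JSON outputs plus a
manifest sufficient to reproduce them byte-identically.

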