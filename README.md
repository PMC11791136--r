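# calredox

Calcium-coupled redox analysis of multiheme cytochromes.

## The problem

Some c-type cytochromes carry a Ca²⁺ ion bound right next to each heme
iron.  Because the cation electrostatically destabilizes the ferric
state, its presence raises the heme midpoint potential by hundreds of
millivolts — and, by thermodynamic necessity, oxidation of the heme
weakens calcium binding.  Quantifying this coupling takes four distinct
analyses, which this package implements as one tested toolchain:

1. **Multi-transition Nernst fitting** of spectroelectrochemical
   titrations.  The absorbance at the Soret band (417 nm) as a function
   of applied potential *E* is fitted to

   *A*(*E*) = *A*ₒₓ + Σᵢ *aᵢ* / (exp[(*zF*/*RT*)(*E* − *E*ₘ,ᵢ)] + 1)

   with *F* = 96485.34 J V⁻¹ mol⁻¹, *R* = 8.3145 J mol⁻¹ K⁻¹,
   *T* = 293 K, *z* = 1.  Beyond free *n*-transition fits, a
   constrained four-transition model describes a partially
   calcium-loaded diheme protein: two closely spaced pairs of
   transitions (calcium-loaded pair at high potential, calcium-free
   pair at low potential) sharing one within-pair spacing and one
   amplitude per pair; the fractional amplitude of the high pair is the
   calcium-site occupancy.
2. **A four-state thermodynamic square** linking oxidation state and
   calcium occupancy: *F*(*E*ₘ,bound − *E*ₘ,free) = *RT* ln(*K*d,ox /
   *K*d,red).  From it, apparent midpoints and self-consistent
   macroscopic redox/binding states at finite calcium and protein
   concentrations.
3. **Competitive calcium-binding equilibria** among EGTA, a fluorescent
   indicator dye and protein sites — the mass-balance root (and its
   two-ligand closed-form cubic), a fluorescence calibration, and a
   curve-family χ² comparison yielding an upper limit for the protein's
   apparent Ca²⁺ *K*d.  Plus small utilities: elemental ratios
   normalized to Fe and Beer–Lambert heme quantification (ε₅₅₀ =
   62 L mmol⁻¹ cm⁻¹).
4. **A structure survey**: parse PDB/mmCIF coordinate files, locate
   heme irons (Fe in HEM/HEC residues) and Ca²⁺ ions, tabulate all
   Fe–Ca distances, and superpose cofactors (Kabsch RMSD).

Every analysis has a matching forward-model simulator, so the whole
pipeline is testable end to end without instrument data.

## Worked example

Simulate a calcium-loaded titration from the constrained paired model
(pair centers −130.5/+370 mV vs SHE, 30 mV spacing, member amplitudes
0.06/0.44, noise 0.01 of total amplitude, three replicate series) and
refit it:

```r
library(calredox)

sc  <- titration_scenario(paired_model(), noise_sd = 0.01,
                          replicates = 3, seed = 11)
rep <- run_titration_pipeline(list(curves = simulate_titration(sc),
                                   model = "paired4"))
rep
#> calredox titration report
#>   E_m1 =  -140.6 +/- 3.7 mV vs SHE (a = 0.060)
#>   E_m2 =  -110.0 +/- 3.7 mV vs SHE (a = 0.060)
#>   E_m3 =  +355.1 +/- 1.6 mV vs SHE (a = 0.439)
#>   E_m4 =  +385.7 +/- 1.6 mV vs SHE (a = 0.439)
#>   calcium-site occupancy = 88.0%

summary(rep$fit)
#> ...
#> Calcium-site occupancy = 88.0% +/- 0.2%
#> Pair centers -125.3 / +370.4 mV (separation 495.7 mV), spacing 30.6 mV
```

The fit recovers the four transitions (truth −145.5/−115.5/+355/+385
mV), the ~500 mV separation between the calcium-loaded and calcium-free
pairs, and the 88% occupancy of the calcium sites, each with 1σ
uncertainties from the fit covariance.

The competition module reproduces the dye calibration arithmetic
directly from the published constants:

```r
egta <- ligand("EGTA", 1.0e-7, 5e-3)          # 5 mM EGTA, Kd 0.1 uM
dye  <- ligand("CalBryte-590", 1.4e-6, 2e-5)  # 20 uM dye, Kd 1.4 uM
eq   <- solve_equilibrium(competition_system(5e-3, list(egta, dye)))
round(eq$complexes[["CalBryte-590"]] * 1e6)   # Ca.dye complex, uM
#> 18
```

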