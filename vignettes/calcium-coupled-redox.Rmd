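---
title: "Methods: calcium-coupled redox analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium-coupled redox analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the models behind `calredox`, the numerical
choices that are not visible from the function signatures, and the
limits of what the package's closed-loop tests demonstrate.

## The titration model

A spectroelectrochemical titration monitors an optical signal — here
the Soret-band absorbance at 417 nm — while the applied potential is
stepped across the redox transitions of the protein.  For a mixture of
independent one-electron couples the signal is

$$A(E) = A_{ox} + \sum_i \frac{a_i}{\exp\!\big[\tfrac{z_i F}{RT}(E - E_{m,i})\big] + 1},$$

with $F = 96485.34$ J V$^{-1}$ mol$^{-1}$, $R = 8.3145$ J mol$^{-1}$
K$^{-1}$ and $T = 293$ K ($RT/F \approx 25.25$ mV).  Each term falls
from $a_i$ (fully reduced) to 0 (fully oxidized) around its midpoint
$E_{m,i}$; $z_i = 1$ throughout unless overridden.  Potentials are
handled internally in volts and reported in millivolts versus the
standard hydrogen electrode (SHE); raw instrument potentials are
shifted by the reference-electrode offset (+200 mV by default) exactly
once, enforced by a frame tag on every curve.

Key modelling assumptions: the electrode is in equilibrium with the
protein at every step (no kinetics), the couples are independent
(no redox cooperativity between the two heme domains, which is
empirically negligible for this protein), and the optical response is
linear in the reduced fractions.

### The constrained paired model

For a diheme protein whose calcium sites are partially occupied, four
transitions are expected: a high-potential pair from the two
calcium-loaded hemes and a low-potential pair from the two calcium-free
hemes.  Fitting four free transitions to 21-point data is poorly
conditioned, so the `paired4` model imposes the physically motivated
constraints: members of a pair sit at $c \pm s/2$ with a *shared*
spacing $s$ for both pairs, and the two members of a pair share one
amplitude.  That reduces nine free-model parameters to six
($c_{low}, c_{high}, s, a_{low}, a_{high}, A_{ox}$).  The calcium-site
occupancy is the fractional amplitude of the high-potential pair,
$2a_{high}/(2a_{high}+2a_{low})$; its 1σ uncertainty comes from the
delta method on the fit covariance.

The `mutant3` variant fits three free transitions for distal-ligand
mutants: mutating a heme's axial Met to His drops its potential by
roughly 320 mV, so one of the four transitions (the calcium-free
mutated heme, near −450 mV vs SHE) falls below the applied window and
is deliberately not modelled.

### Fitting numerics

* Optimizer: bounded Levenberg–Marquardt least squares
  (`minpack.lm::nls.lm`, `ftol = ptol = 1e-14`, up to 500 iterations).
* Multi-start: midpoint starting values are drawn from a 6-point grid
  across the measured window.  Combinations are taken *with
  repetition* (duplicates split by 12 mV) so that starts can seed two
  transitions in one region — without this, closely spaced pairs are
  reachable only from lucky starts.  At most 24 starts for free models,
  9 for the paired model; the best converged attempt wins.  If no start
  converges the fit aborts with the collected optimizer diagnostics.
* Bounds: midpoints within ±0.8 V vs SHE (the −0.6 … +0.4 V applied
  window plus margin), amplitudes and the pair spacing non-negative.
* $A_{ox}$ is a free baseline parameter by default.  `fix_aox = 1`
  reproduces the convention of normalizing the fully oxidized state to
  1.0; the free default is more honest for simulated data whose
  baseline is not normalized, and the two choices give identical
  midpoints on clean data.
* Uncertainties: 1σ values from $\sigma^2 (J^TJ)^{-1}$ with $J$ the
  central-difference Jacobian of the residual vector at the optimum
  and $\sigma^2$ the residual variance.  Singular $J^TJ$ (flat or
  degenerate data) yields `NA` uncertainties rather than an error.
* Degenerate outcomes are flagged, not hidden: transitions closer than
  1 mV are reported as coincident with a warning, and a total fitted
  amplitude near zero warns that the curve may be flat.
* Amplitude percentages (the 85/15 split, the occupancy) are fractions
  of the *total fitted amplitude*, not of the raw absorbance range.

### Branch handling

Each measured series sweeps oxidatively and then back reductively.
The generator therefore emits both branches per replicate by default,
and the analysis pools them (`pool_branches()`) before averaging, which
is appropriate because the simulator's default hysteresis is zero.
With real hysteresis the branches should be fitted separately — the
package supports that (`branch` arguments throughout) but deliberately
does not model hysteresis itself; the simulator's `hysteresis_offset`
is a constant potential lag used only to exercise the plumbing.

## The thermodynamic square

One heme site has four states: reduced/oxidized × calcium-bound/free.
Free-energy closure around that cycle ties the midpoint shift to the
ratio of dissociation constants,

$$F(E_{m,bound} - E_{m,free}) = RT \ln\frac{K_{d,ox}}{K_{d,red}},$$

so `thermo_square()` derives $K_{d,ox}$ from the other three
parameters (`kd_oxidized = "closed"`) and rejects inconsistent explicit
values.  A 500 mV midpoint separation — the value observed for this
protein — implies $K_{d,ox}/K_{d,red} \approx 4 \times 10^8$: with
$K_{d,red} = 0.1$ µM the oxidized-state constant is ~40 M, i.e. *no
physical calcium concentration saturates the oxidized protein*.
Consequences built into the tests: macroscopic midpoints at realistic
calcium sit strictly between $E_{m,free}$ and $E_{m,bound}$ and rise
with the calcium pool (the EGTA-treated < as-isolated < calcium-loaded
ordering), and genuine saturation limits are only exercised on a
modestly coupled square.

`macroscopic_state()` solves the shared-pool problem: free calcium $x$
satisfies $x + S\,f_{loaded}(x) = \mathrm{Ca}_{tot}$ where $S$ is the
total site concentration and the loaded fraction comes from Boltzmann
weights $1 : x/K_{d,red} : e^{\phi} : e^{\phi}x/K_{d,ox}$ at
$\phi = F(E - E_{m,free})/RT$.  The left side is strictly increasing,
so bracketed root finding on $[0, \mathrm{Ca}_{tot}]$ (`uniroot`
followed by Newton polishing) is globally convergent; mass balance
holds to a relative $10^{-8}$.  The diheme protein is treated as two
independent parallel squares, so "sites" count hemes, not molecules.
Because the reduced fraction, like the Soret absorbance, decreases
with rising potential, `macroscopic_titration()` returns it by default
so its output can be fed straight back into `nernst_fit()`.

The wild-type $K_{d,red}$ is not known (only an apparent upper limit,
measured on a mixed oxidation state, is available); it is therefore a
required argument everywhere, never silently defaulted.

## Competitive calcium equilibria

For any number of independent 1:1 ligands the free calcium $x$ is the
unique root of $f(x) = x + \sum_j T_j x/(K_j + x) - \mathrm{Ca}_{tot}$,
solved by bracketing plus Newton polishing ($f' \ge 1$, so Newton from
the bracketed root is safe).  With exactly two ligands $f$ reduces to a
cubic; `free_calcium_cubic()` solves it in closed form using the
trigonometric branch when all three roots are real and Cardano
otherwise, on concentration-rescaled coefficients (dominant scale
normalized to 1) to avoid catastrophic cancellation between terms that
span $10^{-9}$–$10^{-2}$ mol/L, followed by one or two Newton steps on
the *polynomial*.  The closed form and the iterative solver agree to a
relative $10^{-8}$ over a 1000-system random sweep — they are kept as
two genuinely independent routes.

The affinity assay mirrors the experimental design: a calibration
series (0–5 mM total calcium in 5 mM EGTA, $K_d = 1.0\times10^{-7}$ M,
with 20 µM CalBryte-590, $K_d = 1.4\times10^{-6}$ M) spans Ca·dye
complexes from 0 to ~18 µM; a second-order polynomial maps fluorescence
signal to complex concentration.  Protein sites are modelled as
identical independent 1:1 sites with an effective stoichiometry of 1.6
per molecule (from elemental analysis), competing with the dye for a
2.4 µM background calcium pool.

### The upper-limit criterion

Predicted dye-complex curves are computed for candidate $K_d$ values on
a 1 nM–10 µM log grid and scored by χ² against the replicate-averaged
data; a candidate is consistent when its χ² does not exceed the 95%
quantile at one degree of freedom per concentration.  The reported
upper limit is the largest consistent candidate.  Three decisions make
this criterion robust, all configurable:

* Replicate SDs are pooled (RMS across concentrations): per-point SDs
  estimated from triplicates are so variable that a single
  underestimated point can dominate χ².
* The calibration's RMS inversion residual is added in quadrature to
  the replicate noise, since the polynomial inverse of the instrument
  response is not exact and its error is shared by every converted
  point.  Below roughly 2% assay noise this *structured* calibration
  error dominates, which is why the closed-loop tests run at the
  default 0.1 µM (≈5%) noise.
* A non-binder reference (the flat curve at the protein-free complex)
  is always scored too.  Within the candidate grid even the weakest
  binder (10 µM) measurably depletes a 2.4 µM pool at 3.5 µM protein ×
  1.6 sites, so flat data can reject *every* finite candidate while
  being perfectly consistent with no binding; that case reports the
  grid maximum flagged `unbounded` instead of failing.  Only data
  inconsistent with both the grid and the non-binder reference raise
  an error.

The estimate is quantized to the candidate grid (default spacing a
factor of ~1.27); callers wanting a tighter bracket pass a finer grid.

## The structure survey

`read_structure()` delegates PDB and mmCIF parsing to bio3d (with
`rm.alt = FALSE`, so the package's own altloc policy sees every
conformer) and flattens the result into an atom table.  Policies, all
chosen where the underlying conventions are silent:

* Altlocs: per (chain, residue, atom name), keep the highest-occupancy
  conformer; ties break by altloc letter.
* Multi-model files: first model only.
* Heme irons: Fe atoms in residues named HEM or HEC exactly
  (configurable); an Fe in an iron–sulfur cluster (SF4) never counts.
* Calcium: element Ca in a hetero record.  Requiring the element field
  (with an atom-name fallback only when it is absent) plus hetero
  context excludes both protein Cα atoms (element C) and other metals
  given the atom name "CA".

Distances are plain Euclidean cross products of heme irons × calciums;
survey counts are reported but never asserted against any external
database snapshot, because they depend on the database version.
Superposition is the standard Kabsch construction — SVD of the
covariance of the centered paired coordinates with a determinant
correction excluding reflections — cross-checked in the tests against
bio3d's independent implementation.  `fetch_structure()` can download
accessions for optional checks; nothing else touches the network and
all tests run on fixtures written by `make_fixture_structure()`.

## What the generators emulate, and what they do not

Each simulator is the exact forward model of one analysis stage, which
is what makes closed-loop testing meaningful: parameters in, data out,
parameters back.  The emulated features are the multi-transition
sigmoid structure with the published transition parameters, additive
i.i.d. Gaussian noise (default σ = 0.01 of the total amplitude for
titrations, 0.1 µM for assay complexes), triplicate structure with
both titration branches per series, two-basis-spectrum mixing with
Soret bands at 415 nm (reduced) and 408 nm (oxidized) plus α/β bands,
a constant 700 nm baseline offset, and coordinate files with known
Fe–Ca geometry.

Deliberately not emulated: potential-dependent noise (real replicate
SDs vary across the sigmoid; the constant-σ choice is a
simplification), mediator-cocktail electrochemistry, instrument drift,
dye photophysics and oxidizer–dye interference, genuine kinetic
hysteresis, and conformational heterogeneity of the binding sites.
Passing closed-loop tests therefore demonstrates correctness of the
estimators under the stated noise model — not robustness to every
pathology of real instrument data.

## Problem sizes and runtime

The test suite and acceptance script are sized to run comfortably on
one CPU: titrations use the 21-point, −600…+400 mV in 50 mV steps
program with 3 replicate series; parameter-recovery statistics use 100
seeds for the constrained fit and 50 for the assay coverage check; the
cubic-vs-iterative agreement sweep uses 1000 random systems; spectra
stacks use a 1 nm grid from 350–700 nm.  The full suite completes in
well under a minute.

## Known limitations

* The constrained fit's within-pair spacing is the least determined
  parameter at the study's noise level (1σ ≈ 3 mV from six averaged
  traces); single-seed recoveries can land a few mV off truth even
  when the pair centers and occupancy are tight.
* The χ² upper-limit criterion assumes Gaussian, independent errors
  after calibration; strongly structured residuals (e.g. a miscalibrated
  background) bias it, which is why the pipeline estimates the
  background from protein-free wells and reports the criterion it used.
* `"mutant3"` silently ignores any transition below the applied window
  by design; if data actually contain four resolvable transitions the
  free model with `n_transitions = 4` should be used instead.
* The survey's heme vocabulary is {HEM, HEC}; other porphyrin variants
  (HEA, HEB, SRM, …) are excluded unless passed explicitly.
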