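---
title: "Conformer ensembles, UV-Vis shifts and potency descriptors: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformer ensembles, UV-Vis shifts and potency descriptors: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quinspec)
```

## The scientific problem

4-anilinoquinazoline tyrosine kinase inhibitors (TKIs) bind the ATP pocket
of the epidermal growth factor receptor (EGFR). Across the halogen series
X = H, F, Cl, Br, I at the aniline meta position, measured potencies span
three orders of magnitude (IC50 from 29 nM down to 0.025 nM), yet the
scaffold barely changes. Quantum-chemistry studies of these compounds
produce, per compound, a small ensemble of low-lying conformers (energies,
dipole moments, geometries), a crystal-pose reference structure, and
excited-state "stick" tables (wavelength and oscillator strength per
singlet state). `quinspec` is the post-processing layer for such data: it
turns raw ensembles into strain energies, Boltzmann populations,
crystal-versus-minimum RMSDs, broadened UV-Vis spectra, principal-band
shifts, and descriptor-versus-potency correlations. The
electronic-structure calculations themselves are out of scope; the package
consumes their outputs.

## Thermochemistry

Strain energy is defined relative to the ensemble's global minimum,

$$\mathrm{SE}_i = (E_i - E_{\min}) \times 627.509474\ \mathrm{kcal\,mol^{-1}},$$

with energies kept in hartree internally and converted only at the API
boundary; this avoids precision loss, since total energies of these
molecules sit near $-10^3\,E_h$ while conformer gaps are $10^{-3}E_h$.
Populations follow the Boltzmann distribution over strain energies,

$$p_i = \frac{g_i e^{-\mathrm{SE}_i/RT}}{\sum_j g_j e^{-\mathrm{SE}_j/RT}},
\qquad R = 0.0019872041\ \mathrm{kcal\,mol^{-1}K^{-1}}.$$

Choices and caveats:

* **Temperature.** "Room temperature" is fixed at 298.15 K by default and
  is configurable. Published population tables for this series do not state
  the temperature or energy type used, and are not exactly reproducible
  from electronic energies alone (e.g. a 1.346 kcal/mol two-state gap gives
  a Boltzmann ratio of 0.1031 at 298.15 K, whereas the printed populations
  imply about 0.099). The populations here are therefore validated by
  their mathematical properties (normalisation to $10^{-9}$, the
  $T \to 0$ and $T \to \infty$ limits, the two-state closed form, strict
  monotonicity in SE), not by matching printed percentages.
* **Energy type.** Electronic energies only; no zero-point or thermal
  corrections, matching how such tables are commonly reported.
* **Degeneracy.** Defaults to 1 per conformer; conformational degeneracy is
  accepted as named integers when the user knows it.

## Structural alignment

Two protocols are exposed, because published RMSDs for this series do not
state which was used:

* **Plane-anchored** (default): both structures are rigidly placed in a
  common frame defined by three quinazoline-core atoms (the plane becomes
  $z=0$, the first anchor the origin, the second the $+x$ axis), and the
  RMSD is taken with no further fitting. This frame makes the residual read
  out in the methoxy/anilino torsions, which is where conformational
  deviation actually lives in these molecules — and it is exactly invertible
  for the synthetic generator: a dihedral distortion leaves the anchors
  fixed, so the anchored RMSD equals the RMSD computed directly from the
  constructed coordinates. That exactness is why it is the default.
* **Kabsch** least-squares superposition (SVD of the cross-covariance,
  proper-rotation branch enforced when the unconstrained optimum is a
  reflection). It bounds the anchored residual from below and is validated
  against a brute-force rotation-grid + refinement oracle to $10^{-3}$ Å.

The default atom subset is heavy atoms: hydrogen positions from QM
optimizations are conformation-noisy and would dilute the signal. Atom
correspondence is taken from identical atom ordering (the normal case for
one compound optimized from a common start) or an explicit mapping — never
guessed from element patterns. All atom indices are 1-based, the R
convention.

## Spectra

Stick spectra are broadened with Gaussians in the *energy* domain: each
state contributes a band centred at its transition energy with area equal
to its oscillator strength, and the sum is sampled on a uniform wavelength
grid (default 180–350 nm at 0.1 nm). The default width, FWHM = 0.333 eV,
is a widely used convolution width for TD-DFT spectra; no claim is made
that it matches any particular experiment. Area normalisation in energy
makes the integrated intensity proportional to $\sum f$ (checked to 1%
whenever the grid spans every band by ±5σ).

The principal band, however, is read from the *sticks*, not the broadened
curve: for these compounds one strong transition ($f \ge 0.5$) above
320 nm dominates the long-wavelength edge, and its tabulated
wavelength/oscillator-strength pair is the quantity compared across
structures. `lambda_max()` selects the longest-wavelength state with
$f$ at or above the threshold (ties broken toward larger $f$) and errors
explicitly when nothing qualifies — silent fallbacks would quietly compare
different bands. Below 320 nm many weak states overlap; positions there
are only meaningful on the broadened curve, so `provisional_peaks()`
reports local maxima (3-point test) flagged as provisional.

The shift is $\Delta\lambda_{\max} = \lambda_{\mathrm{crystal}} -
\lambda_{\mathrm{cal}}$; negative values (crystal band at shorter
wavelength) are classified **blue**, positive **red**. `band_onset()`
uses a threshold of 2% of the curve maximum scanned from short
wavelengths; published onset values for this series come with no stated
criterion, so this fraction is a package parameter, documented rather than
fitted.

## Potency correlation

Potency is always ln(IC50 in nM); the API refuses nothing implicitly —
values in other units must be converted by the caller. With five
compounds, Pearson and Spearman coefficients are reported but no p-values
(they would be meaningless at $n=5$); the strongest defensible claim is
the exact rank statement, exposed as `monotone_consistent`: descriptor
ranks identical to, or exactly the reverse of, potency ranks. For the
packaged reference series the five global-minimum dipole moments rank
exactly opposite to ln(IC50) (Spearman $-1$), while the Pearson
coefficient is $-0.82$ — the relationship is monotone, not linear.
`shift_potency_report()` evaluates the statement "every blue-shifted
compound is more potent than every red-shifted one" literally
(max blue ln IC50 < min red ln IC50), returning a vacuous TRUE when either
set is empty and NA for a single compound.

## The synthetic generator

Real inputs require Gaussian-16-scale computation and crystal-pose
coordinates that cannot be redistributed, so the package carries a seeded
generator whose defaults encode the study conditions it emulates:

| parameter | default | rationale |
|---|---|---|
| conformers per compound | 5 | the "top five low-energy" pattern of such ensembles |
| local-minimum SE | 0.15 + Exp(scale 1.2), truncated at 3 kcal/mol | few low-lying conformers within 3 kcal/mol; the offset keeps populations strictly ordered |
| crystal SE | U(1, 9) kcal/mol | crystal poses sit 1–9 kcal/mol above the minimum in this series |
| excited states | 30 per structure | the usual TD-DFT singlet count for these molecules |
| principal band | 330 ± 3 nm, $f \in [0.5, 0.7]$ | the observed principal-transition range |
| congested states | 29 states, U(180, 320) nm, $f < 0.45$ | keeps the $f \ge 0.5$ rule unambiguous |
| dipole→potency | ln IC50 = 20.4 − 2.9·μ + N(0, 0.15) | maps the 5.5–8.5 D dipole range onto the nanomolar ln IC50 range with a negative monotone link |
| shift link | most potent 40% blue; $|\Delta\lambda| = 1.0 + 0.6\,|\ln\mathrm{IC50} - \mathrm{pivot}|$ nm, noise sd 0.3 nm | shifts of a few nm whose sign separates the potent compounds |
| crystal distortion | phenyl dihedral 20° + 120°·(potency rank)/n | more potent ⇒ more twisted crystal pose, so RMSD correlates with potency |

Geometries come from a hard-coded idealized 4-anilinoquinazoline scaffold
(regular hexagons, standard bond lengths, planar core). This is *not* a
quantum-chemistry geometry and is documented as synthetic; what matters is
that every transformation applied to it — torsions, the rigid motion given
to the crystal pose — is recorded in the ground-truth record, so the
pipeline's outputs can be checked exactly. The crystal band position is
clamped to ±9.5 nm around the principal-band centre so the principal
window always contains it; the clamp cannot change a shift's sign.

What the generator does **not** emulate: energy–geometry consistency
(strain energies are drawn, not computed from the geometry), vibronic or
solvent structure in the spectra, and realistic hydrogen placement.
Passing recovery tests therefore demonstrates that the *pipeline* is
correct — that signs, orderings, populations and RMSDs are recovered from
data with the assumed statistical structure — not that any physical claim
about real compounds is reproduced.

Recovery checks: on noise-free bundles the shift signs, strain-energy
ordering, global-minimum population dominance and anchored RMSD are
recovered exactly for every compound; with the default 0.3 nm observation
noise on the crystal band, the shift-sign recovery rate over 200 seeded
replicates (1000 compound-level signs) stays above 95%, because the
smallest true shift magnitude is 1.0 nm by construction.

## Numerical choices and degenerate inputs

* Hartree→kcal/mol: 627.509474 (CODATA); gas constant
  0.0019872041 kcal mol⁻¹ K⁻¹; $hc$ = 1239.84198 eV·nm.
* Collinear point sets are rejected before superposition (rank test at
  relative tolerance $10^{-8}$); reflections are never applied, only
  flagged.
* Wavelength ties in `lambda_max()` break toward larger $f$; zero-variance
  vectors in `correlate()` yield flagged NAs, never silent NaNs.
* Manifest energies are serialized at 15 significant digits so ensembles
  round-trip through disk to $10^{-12}$ relative.
* Problem sizes in the shipped tests: toy point sets of 4–6 atoms for the
  rotation-grid oracle, 5-compound bundles, and a 200-replicate
  Monte-Carlo for sign recovery — small enough to run in seconds while
  exercising every code path.

## Worked example

```{r}
spec <- generator_spec(seed = 42,
  potency_link = list(intercept = 20.4, slope = -2.9, noise_sd = 0),
  shift_link = list(blue_fraction = 0.4, base_nm = 1.0, slope_nm = 0.6,
                    noise_sd = 0))
bundle <- generate_bundle(spec)
res <- run_pipeline(bundle$ensembles)
res$descriptors[, c("substituent", "dipole_moment", "delta_lambda",
                    "shift_class", "ln_ic50", "rmsd")]
res$correlation
recovery_check(bundle)$pass
```

And the packaged reference series of printed per-compound quantities:

```{r}
reference_descriptor_table()
```

## Known limitations

* The anchored RMSD depends on the anchor choice; published RMSD values
  for this series are not reproducible without the (unavailable) crystal
  coordinates, so the alignment module is validated by oracle equivalence
  and generator ground truth instead.
* No torsion-aware or symmetry-corrected RMSD; equivalent-atom swaps
  (e.g. the two methoxy groups) are the caller's responsibility via the
  atom map.
* Broadened-curve quantities (onsets, sub-320 nm peaks) depend on the
  broadening width and are flagged provisional; only stick-level
  quantities are compared across structures.
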