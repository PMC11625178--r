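---
title: "Quantifying labile heme and hemoglobin in plasma: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying labile heme and hemoglobin in plasma: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemeQuant)
```

## The problem

Hemolysis releases hemoglobin into plasma, where oxidation and
degradation shed heme from the globin pockets. The resulting *labile
heme* — free or loosely protein-associated heme — is the biologically
active, cytotoxic species, so it must be quantified separately from the
heme still carried by hemoglobin (four groups per tetramer). The
difficulty is spectral: both analytes absorb in the Soret region
(~380–420 nm), and every common photometric heme assay responds to both.
`hemeQuant` implements the individual methods, their validation
statistics, and a combined procedure that quantifies hemoglobin by the
Harboe polychromatic correction and then subtracts its contribution from
a colorimetric kit signal to isolate labile heme.

## The measurement model

All photometry is Beer–Lambert: the absorbance of a diluted sample at
wavelength $\lambda$ is

$$A(\lambda) = \frac{\ell}{DF}\sum_s \varepsilon_s(\lambda)\, c_s
  \; + \; \text{turbidity} \; + \; \text{noise},$$

with pathlength $\ell$ (cm), dilution factor $DF$, specific absorbances
$\varepsilon_s$ and concentrations $c_s$ of the components (labile heme,
hemoglobin, bilirubin), plus a broadband scattering term for lipemic
turbidity. Hemoglobin is counted per tetramer throughout; ground-truth
bookkeeping fixes heme-per-tetramer at 4, so a composition's total heme
equivalents are $4c_{Hb} + c_{heme}$. Deviations from that ratio reported
by individual assays are treated as assay artifacts, not simulator truth.

The combined estimator reads, with standard operator precedence,

$$c_{labile}\,[\mu M] = DF_{kit}\cdot 25.64\cdot A_{400}
  \;-\; 2.59\cdot c_{Hb,Harboe}/DF_{kit} \;+\; 4.85 .$$

Two conventions in this formula are genuinely open and are handled
explicitly:

* **Parenthesization.** At $DF = 1$ the formula is unambiguous; for
  $DF > 1$ the package's default (`parse = "printed"`) applies the
  factors exactly as written, and a named alternative
  (`parse = "bracketed"`) applies $DF$ to the whole bracket. All exact
  identities in the test suite are pinned at $DF = 1$, where the parses
  coincide; behavior beyond that is documented as convention-dependent.
* **The +4.85 µM intercept** implies a nonzero estimate for a blank.
  Whether one should blank-subtract is not decidable from the equation
  alone, so a zero kit absorbance is surfaced with a `blank_offset` flag
  rather than silently corrected. Negative estimates are likewise
  reported with a `negative_estimate` flag, never truncated or clamped:
  truncation would bias recovery statistics upward.
* **The hemoglobin scale.** The $c_{Hb}/DF$ term takes the Harboe
  hemoglobin on the original-sample scale, which is what the explicit
  $/DF_{kit}$ implies.

## The synthetic-data generator

The simulator exists so that every downstream stage has a testable ground
truth. Its defaults *are* the study conditions and are not tuned per
test.

**Component spectra** are parametric sums of Gaussian bands, not
digitized measurements: labile heme a broad Soret band at 380 nm with a
weak ~500 nm shoulder; hemoglobin a Soret band at 410 nm (within the
405–415 nm range of oxyhemoglobin maxima) plus small Q bands at 540 and
577 nm; bilirubin a single band at 455 nm; turbidity a Mie-like
$(700/\lambda)^{2.5}$ scattering baseline, the only component alive at
700 nm. Two amplitude calibrations tie the synthetic spectra to the
published evaluation equations:

* the hemoglobin amplitude is solved so the Harboe equation is the
  *exact* inverse of a pure-hemoglobin spectrum at the 0.29 cm (100 µL)
  pathlength — possible because that equation has no intercept;
* the heme Soret amplitude is slope-matched to the direct calibration
  (0.029 AU/µM at the 0.58 cm, 200 µL format). The printed direct curves
  carry nonzero intercepts (−0.170, −0.007 AU) that a zero-blank
  Beer–Lambert spectrum cannot reproduce across a range, so exact
  direct-method round trips go through the scalar read-out channels
  (below); the spectrum's direct inversion carries the blank offset.

One further shape parameter is solved rather than chosen: the heme Soret
width (root near 33 nm, i.e. FWHM ≈ 77 nm, a realistically broad free-heme
band) is set so the polychromatic combination $2A_{415}-A_{380}-A_{450}$
exactly nulls the heme component. This encodes the method's defining
property — the correction rejects heme background, and hemoglobin
results are not significantly disturbed by added heme — and it is what
makes end-to-end labile-heme recovery exact at zero noise, which the
test suite requires to $10^{-9}$ relative.

**Scalar read-out channels** (direct A380/A405, kit A400, the Harboe
triplet, pyridine reduced/oxidized channels, SLS A395/A413, apoHRP
nM-equivalents) are generated as the exact affine inverses of each
method's evaluation equation, clamped at 0 AU so all signals are
non-negative at zero noise. The clamp only engages below each method's
valid range (e.g. the kit channel clamps when total heme equivalents are
under the 4.85 µM offset). Consequences worth knowing:

* quantifier ∘ forward is the identity over each registry valid range
  (the package's central self-consistency property);
* the apoHRP forward model carries its +21.86 nM cross-reactivity
  intercept even at zero hemoglobin (the printed relation's value at
  zero), and the apoHRP quantifier is an identity on the nM-equivalent
  signal — so its round trip is exact in the *signal*, offset in the
  concentration; this mirrors the assay's inability to separate the two
  analytes;
* the pyridine channel encodes total heme equivalents with the
  heme coefficient (ε556 = 34.1 mM⁻¹cm⁻¹ at 1 cm), so heme-equivalent
  conservation ($4c_{Hb}+c_{heme}$) is exact on that channel. The
  hemoglobin convention (ε556 = 80.4, interpreted per tetramer) and the
  earlier published ε557 = 34.7 are provided as evaluation modes; on
  signals generated from the fitted linear curve the ε557 convention
  under-recovers, and the suite asserts that ordering (not a value).

**Plasma panels** draw compositions log-uniformly within state-specific
ranges: non-hemolytic Hb 0.3–5 µM, mild 5–100 µM, severe 100–1080 µM
(heme 20–44, 20–250 and 154–1056 µM respectively, following the spans
observed in hemolytic plasma); icteric samples add 50–300 µM bilirubin
(a clinically icteric span — the source panels report no bilirubin
concentrations) at low hemoglobin; lipemic samples add turbidity index
0.5–5 (0.5–5 AU at 700 nm undiluted). Noise is independent Gaussian per
wavelength/channel with σ = 0.005 AU, typical plate-reader precision.
Dilution factors come from a powers-of-two grid {1, 2, …, 128}, covering
the 1–72 range used in practice with a simple deterministic rule:
smallest factor bringing every absorbance in 340–700 nm below 1.0 AU.

What the generator does **not** emulate: matrix effects beyond the four
components (other plasma proteins, drugs), wavelength-correlated
instrument drift, pipetting error, the hyperchromic heme–hemoglobin
interaction (available as an opt-in additive 405 nm cross term with a
free coefficient, default 0, magnitude unquantified in the literature),
and any kinetics (the pyridine time course is reduced to a single
reduced-state read-out; which time point to use is left to the caller).
Passing tests therefore demonstrate internal consistency of the
equations and pipeline logic under idealized noise — not field accuracy
on real plasma.

## Validation statistics

Recovery is $100\cdot\hat c/c$ (defined only for $c>0$); the mean
recovery rate (MRR) is the mean ± sample (n−1) standard deviation of
per-point recoveries — triplicate-style reporting implies the sample
convention. Linearity follows the 15 % back-calculation rule: the
largest contiguous run of levels whose recoveries deviate ≤ 15 % from
100 %. A deviation of exactly 15 % **passes** (the pass criterion is
stated as "<15 % deviation" and the fail criterion as "beyond 15 %";
the boundary is assigned to pass and tested). Ties between equally long
runs resolve toward higher concentrations, since the hemolysis use case
targets high levels. LOD/LOQ use the ICH closed forms 3.3σ/S and 10σ/S.

## Classification conventions

* **Lipemia**: undiluted-scale A700 > 0.3 AU (configurable; the
  literature criterion is qualitative — "milky white and turbid").
  Lipemic samples are excluded from quantification entirely.
* **Icterus**: a local maximum within 445–465 nm, strictly greater than
  both neighbors after 5 nm moving-average smoothing (raw noise creates
  spurious maxima). Bilirubin is flagged, never quantified.
* **Hemolysis grade**: non-hemolytic strictly below 5 µM hemoglobin,
  severe strictly above 100 µM, mild otherwise — both boundary values
  are mild, matching the strict inequalities in the source criteria.

## Numerical and interface choices

* Registry constants are read-only, versioned, and exported to JSON with
  descriptive provenance notes; the chromatographic entries record the
  published pmol ranges and flag the alternative molar spans reported
  elsewhere for the same curves (`rangeAlt` in the note).
* Whether the Harboe 0.155 factor encodes a protocol dilution or a unit
  conversion is unknowable from the printed equation; it is treated as
  an opaque constant, and the 1:1 pyridine sample:reagent mixing is part
  of the caller-supplied dilution factor, keeping round trips exact.
* Reagent-strip bins use closed bounds ([10, 1000] nM heme,
  [2.5, 250] nM hemoglobin): positives are reported at the printed
  endpoints.
* Panel re-dilution divides the measured spectrum (and re-measures the
  kit channel through the forward model with a per-(sample, dilution)
  derived seed), so noise scales down with dilution — an idealization of
  re-measuring a diluted aliquot.
* All randomness flows from explicit integer seeds; repeated calls with
  one seed are bit-identical, and the caller's RNG state is restored.
* Output files embed a configuration fingerprint (a 32-bit polynomial
  rolling hash of the serialized `RunConfig`) and the registry version.

## Problem sizes

The shipped checks use sizes chosen to make the statistics stable while
staying desk-scale: hand-arithmetic equivalence on 25 randomized inputs
per equation at $10^{-12}$ relative; zero-noise round trips with 50
random compositions per method at $10^{-9}$ relative; the spiked-panel
experiment with hemoglobin backgrounds {2, 5, 10} µM × heme spikes
{2, 5, 10, 15} µM × 100 replicates at σ = 0.005 AU; and a 200-sample
known-state classification panel at zero noise.

## Known limitations

The component spectra are band-shape approximations; absolute agreement
with any particular spectrophotometer is neither attempted nor needed
for the package's purpose. The combined estimator inherits the printed
equation's ambiguities (parse beyond DF = 1, blank offset), which are
surfaced rather than resolved. Bilirubin interferes slightly with the
Harboe correction in icteric samples (its band is not exactly nulled by
the three-wavelength combination), which can drive trace-hemoglobin
estimates negative — such values are flagged and reported. HPLC/ESI-MS
are represented only as registry calibration entries; no chromatogram or
mass-spectrum simulation is included, and the unreliable commercial
hemin kit variant is deliberately not implemented.
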