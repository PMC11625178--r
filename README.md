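# hemeQuant

Quantification of **cell-free hemoglobin** and **labile heme** in plasma.

During intravascular hemolysis, red cells release hemoglobin into plasma,
where it degrades and sheds its heme groups. The resulting *labile heme*
(heme not buried in a hemoprotein pocket) is cytotoxic and
pro-inflammatory, so laboratories need to quantify hemoglobin and labile
heme **separately** — but every common photometric heme assay responds to
both analytes, because hemoglobin carries four heme groups per tetramer.
`hemeQuant` implements the standard quantification methods, ICH-style
validation statistics, and a combined estimator that deconvolutes the two
analytes, together with a ground-truth spectral simulator so the whole
pipeline can be exercised and validated without instrument data.

## Methods implemented

**Harboe polychromatic hemoglobin** (three-wavelength correction that
isolates the oxyhemoglobin Soret band from background):

    c(Hb) [µM] = DF · 0.155 · (83.6 · (2·A415 − A380 − A450))

**Combined labile-heme estimator** — the package's headline procedure.
The colorimetric heme-assay-kit signal at 400 nm responds to labile heme
*plus* a linear hemoglobin contribution; subtracting the independently
measured Harboe hemoglobin isolates labile heme:

    c(labile heme) [µM] = DF(kit) · 25.64 · A400 − 2.59 · c(Hb, Harboe)/DF(kit) + 4.85

Also provided: direct UV/Vis Soret calibration (heme at 380 nm,
hemoglobin at 405 nm), the pyridine hemochromogen assay under five
evaluation conventions (ε556 = 34.1 / 80.4, ε557 = 34.7,
ε557−540 = 23.98 mM⁻¹cm⁻¹, fitted linear curve), the modified SLS
surfactant method, peroxidase-reconstitution (apoHRP) quantification with
its hemoglobin cross-reactivity relation (3.629·c(Hb) + 21.86 nM),
semiquantitative reagent-strip binning, registry entries for the
published HPLC/ESI-MS calibration lines, and validation statistics
(recovery, mean recovery rate, the 15 % back-calculation linearity rule,
LOD/LOQ as 3.3σ/S and 10σ/S).

The simulator builds plasma spectra as Beer–Lambert mixtures of four
components — labile heme (broad Soret band at ~380 nm), oxyhemoglobin
(Soret maximum at ~410 nm), bilirubin (~455 nm band, icteric samples) and
lipemic turbidity (broadband scattering) — with per-channel forward
models that are exact inverses of the published evaluation equations, so
quantify-after-simulate round trips are testable to machine precision.

## Worked example

```r
library(hemeQuant)

# one sample: Harboe hemoglobin, then hemoglobin-corrected labile heme
hb <- harboeHb(0.05, 0.20, 0.03)
hb
#> QuantResult [harboe] hemoglobin: 4.147 uM (flags: none)
estimateLabileHeme(0.62, dfHak = 1, cHbHarboe = concentration(hb))
#> QuantResult [harboe+kit] labile heme: 10.01 uM (flags: none)

# a small simulated plasma panel through the full pipeline
pan <- simulatePlasmaPanel(6, seed = 42, sigma = 0.005)
analyzePanel(pan)
#>   sample_id df_harboe df_hak  c_hb_uM c_labile_heme_uM         grade icteric
#> 1      S001        16     NA       NA               NA          <NA>   FALSE
#> 2      S002        32     NA       NA               NA          <NA>   FALSE
#> 3      S003         4     16  10.4847           211.75          mild   FALSE
#> 4      S004         8      2  -0.5488            39.33 non-hemolytic    TRUE
#> 5      S005        32     16 309.7624           191.49        severe   FALSE
#> 6      S006         1      2   3.7736            30.92 non-hemolytic    TRUE
#>   lipemic quantifiable                         flags
#> 1    TRUE        FALSE      lipemic;not_quantifiable
#> 2    TRUE        FALSE      lipemic;not_quantifiable
#> 3   FALSE         TRUE                              
#> 4   FALSE         TRUE below_range;negative_estimate
#> 5   FALSE         TRUE                              
#> 6   FALSE         TRUE                              
```

Reading the report: two lipemic (turbid) samples are excluded as not
quantifiable; each remaining sample gets per-channel dilution factors
(chosen so all absorbances stay below 1.0 AU), a Harboe hemoglobin
concentration, a hemoglobin-corrected labile-heme estimate, a hemolysis
grade (non-hemolytic < 5 µM Hb, severe > 100 µM, mild otherwise) and an
icterus flag from the bilirubin band. Negative back-calculations (sample
S004, slight bilirubin interference at trace hemoglobin) are reported
and flagged, never clamped.

A spiked-recovery validation of the combined estimator:

```r
mrrSpikeExperiment(replicates = 25, seed = 42)
#> ValidationReport: MRR 99.61 +/- 11.34 %, linear range empty, LOD NA, LOQ NA, PASS
```

A command-line wrapper covering panel simulation, calibration fitting,
batch quantification and reporting is installed at
`system.file("scripts", "hemequant", package = "hemeQuant")`.

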