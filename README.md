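# epiunmask

Differential solvent-exposure analysis of two-state protein structures,
built for the study of proteolytically activated toxins.

Pore-forming toxins such as the *Bacillus thuringiensis* Vip3 insecticidal
proteins are secreted as protoxins and cleaved by insect midgut proteases
into an activated form. Activation is a conformational change of the same
polypeptide, and it can *unmask* a receptor-binding epitope: residues that
are buried in the protoxin become solvent-exposed in the activated toxin.
`epiunmask` identifies such residues from two deposited structures, and
implements the statistics used alongside that analysis at the bench.

## What it computes

**Core model.** Per-atom solvent-accessible surface area (SASA) by
Shrake–Rupley quadrature (probe radius 1.4 Å, 960-point deterministic
Fibonacci lattice), aggregated per residue and normalised to a Gly-X-Gly
reference area:

    RSA(i) = 100 * SASA(i) / MaxASA(restype(i))   [percent]

A residue is *exposed* if RSA > 50, *buried* if RSA < 20 (strict
inequalities). Between state A (protoxin) and state B (activated toxin), a
residue **becomes exposed** by consensus of two criteria:

* ratio: RSA_B > 50 and RSA_A < 50;
* absolute area: SASA_B >= 1.5 * SASA_A and SASA_B > 50 Å².

Supporting modules: anchor-atom distance geometry (CE for lysine, CB
otherwise, CA for glycine), binding-region inference as intersections of
overlapping binding fragments, conservation mapping of reference positions
onto a multiple sequence alignment, one-site saturation binding
(B = Bmax·x/(Kd+x), Levenberg–Marquardt), probit dose–response
(LC50 = 10^(−intercept/slope) with Fieller 95 % fiducial limits),
fold-change ratios, and cytotoxicity summaries (mortality %, Welch t-test
star categories). Seeded synthetic-data generators cover every input class
so the full pipeline is testable offline.

## Worked example

```r
library(epiunmask)

## a synthetic two-state pair with three planted buried->exposed residues
ps  <- make_paired_structures(n_residues = 45, n_planted = 3, seed = 7)
ps$planted
#> [1] 19 31 42
rep <- run_exposure_pipeline(ps$state_a, ps$state_b)
rep
#> <exposure_report>
#>   paired residues: 45
#>   becomes-exposed (consensus): GLY19, GLY31, GLY42

render_table(rep, "table1")[rep$differential$consensus, ]
#>    residue ratio_protoxin_pct ratio_toxin_pct area_protoxin_A2 area_toxin_A2 ...
#> 19   GLY19                  0           116.1                0        120.76
#> 31   GLY31                  0           116.1                0        120.76
#> 42   GLY42                  0           116.1                0        120.76
```

The detector recovers exactly the planted residues: buried (ratio 0 %) in
state A, fully exposed (116 % of the glycine reference, 120.76 Å²) in
state B.

```r
## dose-response: simulate a 6-dose, 144-larvae bioassay and refit it
ba <- make_bioassay(lc50 = 15, slope = 2, seed = 101)
fit_probit(ba$dose, ba$n, ba$dead)
#> Probit fit: LC50 = 16.28  ( 14.27 - 18.57 ), slope = 2.192

## saturation binding: 8 concentrations, 3 replicates, 5% noise
bc <- make_binding_curve(kd = 29, sd = 0.05, seed = 101)
fit_saturation(bc$conc_nM, bc$response)
#> One-site binding fit: Kd = 29.54 +/- 2.48  Bmax = 0.9945

## fold change as printed in toxin mutant tables
fold_change(2410, 37, 0)
#> [1] 65
```

The LC50 estimate (16.3, fiducial interval 14.3–18.6 ng/cm²) covers the
simulated truth of 15; the fitted Kd (29.5 ± 2.5 nM) recovers the simulated
29 nM; 2410/37 is the 65-fold affinity loss of a binding-deficient mutant
relative to wild type.

See the vignette (`vignettes/differential-exposure.Rmd`) for the model
details, parameter choices and limitations.

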