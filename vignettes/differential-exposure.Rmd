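---
title: "Detecting conformationally unmasked residues from two-state structures"
author: "epiunmask"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conformationally unmasked residues from two-state structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiunmask)
```

## The problem

Some pore-forming bacterial toxins, notably the Vip3 family of *Bacillus
thuringiensis* insecticidal proteins, are secreted as protoxins that must be
cleaved by insect midgut proteases before they can bind their membrane
receptors. The protoxin and the activated toxin are the *same polypeptide*
in two different conformations, and the receptor-binding epitope is hidden
in the first and solvent-exposed in the second. Given deposited structures
of both states, the question "which residues become exposed upon
activation?" is a purely computational one: compute per-residue
solvent-accessible surface area (SASA) in each state, normalise, and compare.

`epiunmask` implements that chain end to end — structure parsing, SASA,
relative-accessibility normalisation, two-state differential classification,
side-chain distance geometry, binding-region inference from
overlapping-fragment binding assays, conservation mapping — together with
the statistics that accompany such a study at the bench: one-site
saturation-binding affinity (Kd), probit dose–response (LC50 with fiducial
limits), fold-change ratios and cytotoxicity summaries.

## Solvent-accessible surface area

SASA is computed by Shrake–Rupley quadrature: every atom carries an
expanded sphere of radius $r_i + p$ (van der Waals radius plus probe radius,
default $p = 1.4$ Å, a water molecule), `n_points` test points are placed on
that sphere, and the atom's area is

$$A_i = \frac{\#\{\text{points outside every neighbour's expanded sphere}\}}{n_\text{points}} \cdot 4\pi (r_i + p)^2 .$$

Neighbour candidates come from a grid cell list with cutoff
$r_i + r_j + 2p$, so cost grows linearly with atom count for globular
structures.

Choices that matter:

* **Quadrature density.** The default is a 960-point Fibonacci (golden
  spiral) lattice — deterministic, RNG-free, and an order of magnitude
  denser than the original 92-point icosahedral set. An isolated sphere is
  recovered to machine-level accuracy of the point fraction (well under
  1 %), and the two-sphere spherical-cap closed form is matched to ~0.1 %.
* **Orientation dependence.** Any fixed point lattice makes per-atom areas
  weakly orientation-dependent: a rigid-body rotation can reclassify points
  near an occlusion boundary. Measured worst-case jitter on randomised
  fixtures is about ten single-point areas (~1.3 Å² per atom at 960
  points), shrinking roughly as $1/n_\text{points}$. The test suite asserts
  a bound of 12 point-areas (1.51 Å²); users who need tighter
  reproducibility across arbitrarily rotated inputs should raise
  `n_points` (3840 brings the jitter under 0.5 Å²).
* **Radii.** A Bondi-style element table is shipped as TSV (C 1.70, N 1.55,
  O 1.52, S 1.80, P 1.80, H 1.20 Å) with per-(residue, atom-name) override
  rows and a default fallback of 1.70 Å; the set is replaceable via
  `read_radii()`. Hydrogens are dropped by default — cryo-EM depositions
  generally lack them, and the web servers this analysis mirrors ignore
  them too.
* **Scopes.** Per-residue areas are aggregated as *total* (all atoms) and
  *side chain* (everything outside N/CA/C/O/OXT; for glycine, the CA
  area). Exposure ratios use the total scope by default.

## Relative exposure and the becomes-exposed consensus

Absolute areas are normalised to a *reference area* per residue type — the
accessible area of residue X in an extended Gly-X-Gly tripeptide — giving
the surface ratio in percent. The shipped reference is the published
theoretical maximum-ASA table of Tien et al. (2013); it is deliberately a
fixed, citable table rather than a regenerated conformer ensemble, and can
be overridden via TSV. Ratios are not capped: terminal or extended residues
can exceed 100 %.

Classification uses strict thresholds: *exposed* above 50 %, *buried* below
20 %, *intermediate* otherwise (the boundary values themselves are
intermediate, since the definitions are "exceeds" and "less than").

A residue **becomes exposed** between state A (protoxin) and state B
(activated toxin) when two independent criteria agree:

* **ratio criterion** — surface ratio strictly above 50 % in B and strictly
  below 50 % in A (the reading a relative-accessibility tool such as
  GETAREA supports);
* **absolute-area criterion** — absolute area grows by at least a factor
  `abs_gain_factor` (default 1.5) *and* ends above `abs_min` (default
  50 Å²) in state B (the reading a raw-Å² tool such as PDBePISA supports).

The consensus flag is the conjunction. The two constants of the
absolute-area rule are a design decision of this package: published
two-program comparisons report the qualitative agreement but no numeric
rule, so we chose a minimal pair — "half again larger, and large enough to
matter" — and exposed both as configuration. On the published Vip3Aa
numbers this consensus accepts K385, N522, K526 and V529 and rejects S536
(whose absolute area is essentially unchanged at ~40 Å²), T466, E656 and
N751, which is exactly the agreement the two web services reached.

Pairing of the two state tables is by author residue number (+ optional
offset) and residue name; number collisions with different names, and
residues present in only one state, are reported, not silently dropped.
For homo-oligomers the per-residue areas are averaged over
symmetry-equivalent chains by default — the deposited copies of a cryo-EM
tetramer differ slightly, and averaging keeps a single local deviation from
deciding a classification; a chain subset can be selected instead.

Two published ambiguities are surfaced rather than resolved: the domain
III–V exposed-residue counts in the source study (30 + 42 + 41 = 113) do
not sum to its stated 118 shared exposed residues, so `domain_summary()`
reports both per-domain counts and totals without reconciling them; and
neither the chain choice nor the ratio scope (total vs side-chain) used by
the original web-server analyses is documented, so both are explicit
options here.

## Distance geometry

Loop-residue proximity is measured between designated side-chain anchor
atoms: the epsilon-carbon (CE) for lysine, the beta-carbon (CB) for valine
and every other side-chain-bearing residue, and CA for glycine. Distances
are plain Euclidean norms within one structure — comparing two states
compares two independently measured intra-structure distances, so no
superposition is needed. Note that for the Vip3Aa K385–K526 pair the
activated-state distance is quoted inconsistently in the source literature
(4.3 Å in running text vs 4.8 Å in the figure legend enumerating all six
values); the enumerated legend values are taken as the benchmark set.

## Binding-region inference from overlapping fragments

Given a tiling of a protein by overlapping expressed fragments, each
scored as binding or non-binding, a candidate binding region is the
intersection of two binding fragments. Non-binding fragments are *not*
subtracted: a fragment can fail to bind because it misfolds or truncates
the epitope, so absence of binding is weak evidence. With the published
Vip3Aa fragment table (F6 and F7 and F8 binding), the two candidates are
residues 400–500 (F6∩F7) and 502–550 (F7∩F8), localising the main binding
determinants to domain III. The result is independent of fragment input
order.

## Conservation mapping

The conservation module consumes a precomputed multiple sequence alignment
(aligned FASTA or Clustal; building the MSA is out of scope). The i-th
non-gap character of a chosen reference row is mapped to residue number
`offset + i` and its alignment column; chosen positions are then reported
as exact per-homolog residue identities plus a conserved-in set (identity
only by default — similarity grouping is deliberately not the default,
because a K→R substitution, chemically conservative, is precisely the kind
of difference such an analysis needs to surface).

## Assay statistics

* **Saturation binding.** The one-site specific-binding hyperbola
  $B(x) = B_\text{max} x / (K_d + x)$ is the decided model — publications
  of this kind rarely print the equation; a shared-intercept variant
  (`background = "shared_intercept"`) covers plates with a nonzero blank,
  and neither variant includes a nonspecific linear term (both readings are
  defensible; the hyperbola is the minimal one). Fitting is
  Levenberg–Marquardt least squares with self-starting values
  ($B_{\max,0}$ = max response, $K_{d,0}$ = interpolated half-max
  concentration); SEs come from the Jacobian covariance.
* **Probit dose–response.** Binomial GLM with probit link on
  $\log_{10}$ dose; $\mathrm{LC}_{50} = 10^{-\alpha/\beta}$. The 95 %
  fiducial limits use Fieller's theorem with the g-correction on the
  parameter ratio; mirroring Polo-style software, a heterogeneity factor
  (Pearson $\chi^2$/df, with Student-t quantiles) inflates the interval
  when the lack-of-fit test is significant at 0.05. Abbott's
  natural-mortality correction is available but off by default. In
  simulation at the study design (6 doses, 144 subjects per dose, slope 2)
  the intervals cover the truth in ~95 % of runs.
* **Fold changes** are plain ratios; reporting supports
  half-away-from-zero rounding and truncation, because published fold
  columns mix the two conventions (e.g. a ratio of 1.757 printed as 1.7),
  and the report tables always carry the exact value alongside.
* **Cytotoxicity.** Mortality is the relative reduction of the mean
  per-image cell count, $(1 - \bar{T}/\bar{C}) \times 100$ % (one published
  rendering of this formula prints "×1000"; since the quantity is defined
  as a percentage, ×100 is implemented), with delta-method SE. Cell-size
  comparisons use Welch's t-test (the unequal-variance default is the safer
  reading of an unqualified "t-test") with the conventional star bands
  (*** < 0.001, ** < 0.01, * < 0.05).

## Synthetic data: what it emulates, and what it does not

Every input class has a seeded generator, so the entire pipeline is
testable without network access or deposited files:

* `make_paired_structures()` builds a pseudo-protein of single-atom
  glycine-like residues on a 10 Å lattice; planted residues are enclosed by
  a 32-atom occluding shell of radius 4 Å in state A and freed in state B,
  and the generator verifies its own plant (buried below 20 % in A,
  exposed above 50 % in B) before returning. The 10 Å spacing makes
  shell-to-neighbour occlusion negligible, so non-planted residues stay
  exposed in both states by construction. These fixtures validate the
  *detector*, not the structural biology: single-radius atoms, no backbone
  connectivity, no rotamers, no realistic packing. Recovering plants here
  shows the SASA/threshold/consensus chain is correct, not that real
  conformational changes are detectable at any particular accuracy.
* `make_binding_curve()` draws Gaussian-noise responses around the exact
  hyperbola on a 2-fold concentration ladder (3–384 nM, 3 replicates,
  5 % noise by default).
* `make_bioassay()` draws deaths as
  $\mathrm{Binomial}(n, \Phi(\beta(\log_{10} d - \log_{10}\mathrm{LC}_{50})))$
  — exactly the model the probit fit assumes, which is what a coverage
  calibration requires.
* `make_cell_population()` draws log-normal cell areas per image, with
  mortality as independent thinning and swelling as a multiplicative shift.

All generators route randomness through one private seeded stream per
invocation (the caller's RNG state is untouched), and a fixed seed gives
byte-identical output.

## Problem sizes and numerical conventions

The shipped checks use: 500 simulated assays for the probit-coverage and
Kd-recovery calibrations, 20 structure pairs for planted-epitope recovery,
and 50–100 randomised small fixtures for the geometric property suite —
sizes at which the Monte-Carlo error of the summary statistics (binomial SE
≈ 1 % at n = 500) is small against the acceptance bands. Areas are kept at
full precision internally and rounded only at render time (two decimals for
Å², one for ratios and distances). Ties in altloc filtering go to the
lexicographically first identifier; multi-model files contribute only their
first model; zero-radius probes and ratios above 100 % are legal inputs.

## Known limitations

* SASA is quadrature-based; no analytic (Lee–Richards / power-diagram)
  surface, no solvent-excluded surface, no atom-depth metrics.
* Agreement with specific web servers (GETAREA, PDBePISA) can only be
  approximate since their radii sets, reference ensembles and point
  densities are unpublished; classification outcomes are robust to this,
  absolute Å² values agree only to a few percent.
* The becomes-exposed absolute-area rule constants are package defaults,
  not published values; sensitivity analyses should vary them.
* Binding-region inference reasons on positive fragments only and cannot
  separate two sites inside one overlap.
* The conservation module does not build alignments and trusts the input
  MSA's quality.
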