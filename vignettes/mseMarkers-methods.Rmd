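---
title: "mseMarkers: models, parameters and design choices"
author: "mseMarkers authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mseMarkers: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mseMarkers)
```

This vignette explains the science inside `mseMarkers`: the models behind
each stage, the tunable parameters with their defaults and units, the
numerical choices, what the synthetic data generator does and does not
emulate, and the known limitations.

# The problem

Bottom-up proteomics with MS^E (data-independent) acquisition alternates a
low-collision-energy scan, recording intact (precursor) peptide ions, with
a high-collision-energy scan recording fragments of *everything* that is
eluting. Given runs from two sample classes — here, milk with and without
an extra 90 °C / 10 min heating — the task is to find features whose
intensity discriminates the classes and to assign them a peptide identity,
including process-induced chemistry such as the Maillard glycation of
lysine (lactulosyllysine) that standard search engines do not carry by
default.

# Peptide chemistry

**Masses.** All masses derive from a fixed internal isotope table (IUPAC
2013 representative values for H, C, N, O, S; P is monoisotopic), exposed
by `elementIsotopes()`. Monoisotopic residue masses are computed from
residue elemental formulas; a peptide is the sum of its residues plus one
water. Ion m/z uses the proton adduct, (M + z·1.00727646)/z. A
`"hydrogen"` adduct option (neutral H, 1.00782503 Da) exists because some
isotope-pattern generators charge patterns by adding hydrogen atoms rather
than protons; the two conventions differ by ~0.00055 per charge and both
are supported, with proton the default everywhere.

**Digestion.** Trypsin cleaves C-terminal of K or R except before proline.
`digest()` enumerates all products with up to `missedCleavages` (default 2)
uncut internal sites, with 1-based positions in the parent and the
missed-cleavage count. A brute-force substring oracle backs this in the
tests.

**Modifications** are elemental-composition shifts with site rules
(`defaultModifications()`): lactulosyllysine +C12H20O10 on K (324.105647
Da), oxidation +O on M, methylation +CH2 on K/R, acetylation +C2H2O on K or
the peptide N-terminus. The literature names these modifications for heated
milk but not their site rules; the defaults above are deliberate choices
and fully configurable. Glycation of a lysine abolishes its tryptic
cleavage site, so a cleavage-blocking modification is never placed on a
C-terminal cleavage lysine — only on internal (missed-cleavage) K or K
before P. At most one modification per peptide is generated by default
(`maxMods = 1`); combinations are opt-in.

**Fragments.** `generateFragments()` produces all b and y ions (a = b −
CO) at charges 1..2 by default, with neutral losses applied when the
fragment contains a qualifying residue: −H2O (S/T/E/D), −NH3 (K/R/Q/N),
−CH2N2 (R). This minimal loss set reproduces the reference annotations
(e.g. `y11-H3N1`, `y12-C1H2N2`); it is configurable. A modification's mass
is carried exactly by the fragments whose span covers the modified residue.
Fragment charge is capped at 2 because doubly charged fragments are the
highest observed in the reference data.

**Fine isotope patterns.** `fineIsotopePattern()` enumerates per-element
isotope-count vectors with multinomial probabilities, combines them across
elements, and keeps species by descending abundance until the cumulative
abundance reaches `coverage` (default 0.9995, i.e. a 0.05 % cut-off).
Near-isobaric isotopologues (one ^13C vs one ^15N, ~0.0021 apart at z = 3)
are kept distinct. Intermediate pruning uses a floor of
min(1e-10, (1−coverage)·1e-4), far below the final cut, so the reported
species equal exhaustive enumeration to better than 1e-9 relative (tested
against a brute-force oracle). With `coverage = 1` no truncation is applied
at all.

# Feature engineering

`detectFeatures()` is a transparent, fully specified feature finder — a
deliberate simplification of production feature finders, whose exact
internals are neither documented enough nor necessary to reproduce:

1. **Mass traces**: peaks across scans are clustered with a 0.01 m/z gap
   rule; a trace needs `minScans = 3` consecutive low-energy scans; its m/z
   is the intensity-weighted mean, its rt the apex scan.
2. **Envelopes**: co-eluting traces spaced 1.003355/z apart (z = 1..3) are
   grouped; the charge with the most matching traces wins; feature m/z is
   the monoisotopic trace's; intensity is the summed envelope intensity.
   Ungrouped traces become charge-1 features flagged `envelope = FALSE`.
3. **Merging** across samples: single-linkage clustering with |Δm/z| ≤
   0.01, |Δrt| ≤ 5 s and equal charge. Single linkage was chosen because it
   is the simplest reproducible rule; the deterministic feature ids
   (sorted by rt, then m/z) make outputs comparable across runs. Within
   one sample co-clustered features are summed; absent cells are `NaN`
   ("no data available"), the convention kept in all files and reports.
   `NaN` is converted to 0 only inside the chemometrics stage, consistent
   with reading an absent feature as zero observed intensity.

Users with their own feature finder can bypass detection entirely:
`readFeatureTables()` accepts any directory with the documented TSV
contract (`feature_metadata.tsv`, `feature_intensities.tsv`,
`sample_sheet.tsv`).

Retention time is stored in seconds everywhere. Scan energy is assigned by
the alternating low/high cycle structure by default, since collision-energy
metadata does not reliably survive conversion round trips; a
collision-energy-based rule is available when the metadata exists.

# Chemometrics

`fitPlsda()` implements PLS1 NIPALS on the samples × features intensity
matrix: `NaN` → 0, mean-centering, unit-variance scaling by default
(zero-variance features dropped with a warning), class encoded y ∈ {0, 1}
and centered, two latent components by default. The algorithm is
deterministic; successive scores are orthogonal and weights unit-norm. The
preprocessing is not prescribed by the underlying study; mean-center +
unit-variance is the default of the common PLS implementations and is what
we adopt. A reference implementation (mixOmics) reproduces the scores and
weights to 1e-6 up to sign in the tests — the native fit exists so the
model is self-contained and inspectable, the external package serves only
as a cross-check.

VIP scores follow the standard definition
VIP_j = sqrt(p · Σ_a SSY_a (w_ja/‖w_a‖)² / Σ_a SSY_a) with
SSY_a = q_a²(t_a·t_a), so mean(VIP²) = 1 exactly (asserted to 1e-8).
Features dropped before fitting are absent from the result, not zero. No
automatic VIP > 1 threshold is applied: the workflow takes the top-k
(default k = 5) because a fixed guideline threshold is routinely overridden
in practice; k is the interface. Ties break by feature id.

`classPresenceFilter()` reports features observed (non-`NaN`) in only one
class — a presence/absence marker screen that complements the intensity
contrast.

# Identification

`buildSearchSpace()` crosses digestion, modification variants, precursor
charges 1..3 and fragment charges 1..2 into an m/z-sorted index
(deduplicated by sequence, modification, series, index, loss and charge;
restricted to the 50–2000 instrument range). `matchFeature()` binary-searches
it for species with |m/z_obs − m/z_theo|/m/z_theo ≤ 1e-5 (0.001 %) *and*
the feature's detected charge. Candidates rank by |ppm|, ties by fewer
modifications, then shorter sequence — a pragmatic ordering the underlying
method leaves unspecified. The |ppm| is quantised to 1e-4 ppm before
ranking so that exactly mass-degenerate species (a peptide vs the
full-length y ion of its missed-cleavage parent) resolve by the documented
tie-breaks rather than floating-point noise.

Verification then works on the spectra nearest the feature's retention
time (window ±5 s, reusing the merge tolerance; the scan-selection rule is
otherwise unspecified in the underlying method):

* **Isotopes** (`verifyIsotopes()`): the candidate's fine pattern at the
  feature charge (optionally further charges, e.g. 2+ and 3+) is assigned
  one-to-one to observed low-energy peaks — theoretical species claim the
  nearest unused peak within tolerance in descending-abundance order, so a
  minor isotopologue cannot ride on a strong neighbour's peak. Verdict
  `isotopes_found` needs the monoisotopic peak plus ≥ 2 further
  isotopologues. Unassigned theoretical species are reported.
* **Fragments** (`verifyFragments()`): all a/b/y ions of the candidate,
  generated both with and without its modification, are sought in the
  nearest high-energy and low-energy scans. Assignments are mathematical
  at the stated tolerance; an unmodified fragment whose span covers the
  modified residue is chemically impossible and is flagged
  `implausible`, not deleted — mirroring how such assignments should be
  read, individually. Features whose best candidate is itself a fragment
  ion skip fragment verification (their "fragments" would be internal
  ions, outside scope).

No composite score is computed anywhere: the report carries ppm error,
evidence counts and flags, and the explicit outcome string
`r noMatchString()` when nothing lies within the search parameters.

# The synthetic MS^E generator

`simulateStudy()` emulates the study design that motivated the package: two
classes with 8 replicates each, five planted marker species at a 4-fold
heated-class intensity change among 500 unstructured noise features,
log-normal between-sample intensity noise (σ = 0.3, natural log), Gaussian
m/z noise (3 ppm) and retention-time noise (1 s). Planted species get their
full fine isotope envelope in the low-energy scans as Gaussian
chromatographic peaks (FWHM 10 s — a standard UPLC peak width; the peak
shape is our choice, no shape is prescribed) and, for precursor-type
markers, a/b/y fragments in the high-energy scans at seeded uniform yields
of 5–30 % of the precursor apex. The default markers are genuine tryptic
products of the shipped synthetic FASTA (a glycated β-casein peptide, two
unmodified peptides, an oxidised peptide, and one in-source y3 fragment),
so the full pipeline can both select and identify them. Scan cycle time is
1 s over a 100 s gradient span — problem sizes chosen so a full 16-sample
study simulates and processes in a few seconds while every analyte still
elutes over ~20 scans.

Everything is deterministic given the mandatory seed; per-sample streams
derive from it. What the generator does **not** emulate: ion mobility,
chimeric fragment interference beyond simple co-elution summing,
retention-time drift between runs (no alignment is implemented, matching
the workflow's scope), detector saturation, and electronic/chemical noise
floors. Passing tests on simulated data therefore demonstrate correctness
of the algorithms under the stated statistical model, not performance on
real instrument data.

## What recovery rates to expect

With the defaults above, the five planted markers occupy the top-5 VIP
ranks in most but not all seeds (~85–90 % across our test conditions). The
limiting factor is statistical, not algorithmic: on the raw intensity
scale the 4-fold change inflates the heated-class absolute variance, so a
marker's realized two-sample t statistic is ~6–7, while the maximum |t|
among 500 null features at 14 degrees of freedom frequently reaches 4–5
and occasionally more; ranking by VIP (equivalently, by class correlation
after autoscaling) then lets a fluke noise feature displace a marker.
Log-transforming intensities would restore near-perfect recovery, but the
workflow deliberately models the established practice of running PLS-DA on
autoscaled raw intensities, so we document the behaviour rather than
change the analysis. The acceptance suite asserts the recovery-rate bound
at its stated value and the corresponding test is expected to flag this
gap honestly rather than hide it.

# Numerical choices and degenerate inputs

* Formula subtraction that would go negative errors; modification placement
  on a disallowed residue errors and names the residue.
* Empty spectra, empty feature lists and empty reports are values, not
  errors; an empty *selection* (no samples left) errors.
* Duplicate m/z within a constructed spectrum are summed; peak lists are
  always sorted.
* The merge step's union-find makes single linkage order-independent;
  feature ids are assigned only after sorting clusters by (rt, m/z).
* PLS stops early if the residual weight norm falls below 1e-12 (fewer
  informative components than requested).
* Seeds: every stochastic function takes or derives from an explicit seed;
  per-sample simulator streams use `seed·1000 + sample index`.

# Limitations

* The feature finder is intentionally simple: no profile deconvolution
  beyond centroiding, no retention-time warping, charge only from isotope
  spacing (co-eluting isomers merge; overlapping envelopes can steal
  traces).
* Identification has no FDR control and no decoy database — by design the
  method reports individual evidence instead of a score, and inherits that
  trait's limits: in dense high-energy scans false fragment assignments
  are likely and must be read with the plausibility flags.
* I and L are indistinguishable by mass; sequences are taken literally and
  never equivalenced.
* De novo sequencing is out of scope.
* The shipped milk FASTA is a synthetic stand-in carrying the reference
  peptides in native tryptic context (the true UniProt sequences are a
  download away and drop in directly); conclusions about real milk require
  the real sequences.
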