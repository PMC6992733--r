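---
title: "Mapping proteolytic cleavage from gel-slice proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping proteolytic cleavage from gel-slice proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pccleave)
```

## The measurement model

A GeLC-MS/MS experiment separates a denatured proteome on SDS-PAGE, cuts
each lane into molecular-weight slices (here ten windows, A = 270–500 kDa
down to J = 10–15 kDa), digests each slice with trypsin and quantifies
peptides by LC-MS/MS ion current. Each peptide observation therefore
carries two coordinates: its residue range on the protein ORF, and the
apparent mass of the proteoform it was cut out of. For an intact protein
all peptides co-migrate in the slice containing the protein's mass. A
proteolytic cleavage between residues *p* and *p*+1 splits the molecule
into fragments of smaller mass, so peptides N-terminal and C-terminal of
*p* migrate to different slices — an abrupt change in the slice
distribution along the sequence is the signature of cleavage, and the
intensity ratio between the two sides measures the stoichiometry with
which the fragments are retained on the vesicle.

The package assumes: (i) slice assignment is driven by fragment mass
(glycans add their carbohydrate mass until removed by Endo H or PNGase F);
(ii) a peptide's ion current is proportional to the molar amount of the
fragments containing it, times a peptide-specific response factor;
(iii) missing observations are censoring (below detection), not zeros.

### Coordinates

All coordinates are 1-based and inclusive. A cleavage site is recorded as
the last residue *p* of the N-terminal product, so the products are
`[1..p]` and `[p+1..end]`; a site "at 3048" means the new N-terminus is
residue 3049. Stated peptide ranges always satisfy
`stop = start + length - 1`.

## Change-point localization

`infer_cleavage_positions()` scores every candidate boundary *b* by the
Jensen–Shannon divergence (base 2, bounded in [0, 1]) between the
intensity-weighted slice distributions of peptides entirely N-terminal
(`stop <= b`) and entirely C-terminal (`start > b`) of the boundary;
spanning peptides are excluded from both sides. Candidates default to the
observed tryptic boundaries (peptide stops and starts − 1) because those
are the only observable breakpoints; annotated positions or all residues
can be supplied instead. Local maxima with divergence at least `jsd_min`
(default 0.1) become calls; adjacent candidates with equal score are
merged, and every call is widened to the gap between the flanking observed
peptides — the honest resolution limit of peptide-level data. Calls with a
single-residue interval are flagged `exact`, all others `interval`.

Two guards handle degenerate inputs: a protein needs at least
`min_peptides = 10` distinct peptides at all (else an empty result with a
warning), and a boundary is scored only when both sides hold at least
`min_support = 3` peptides, which suppresses spurious boundaries near the
termini.

Support deliberately enters as that hard gate rather than as a
multiplicative weight. A score of the form divergence × (smaller side's
peptide count) seems natural, but it systematically prefers boundaries
displaced into the larger region: moving the boundary a few peptides into
a 3000-residue ectodomain raises the smaller side's count faster than the
divergence decays, and in seeded simulations such a weighted score placed
the top call ~100 residues N-terminal of the true site in roughly a third
of runs. The bare divergence has the opposite, desirable property: it is
exactly 1 when the two sides occupy disjoint slice sets — which happens
precisely for boundaries in the gap around the true cut — and strictly
below 1 anywhere else. The count-weighted ranking remains available via
`weight_by_support = TRUE`.

## Stoichiometry statistics

`region_intensity_ratio()` fixes one concrete order of operations for the
pooled ratio: per peptide, intensities are summed across the region's gel
slices within each sample; the per-sample sums are averaged over the
samples in which the peptide was observed (censored mean); the per-peptide
values are averaged within each region; and the ratio of region means is
reported. Summation before averaging matters because a partially cleaved
protein shows the same peptide in several slices, and those ion currents
measure the same molecules split across proteoforms. Averaging over
observed samples only (rather than counting absences as zeros) matches the
censoring assumption; because detection acts per observation, the
detection rate then cancels between regions of equally-many-slice
peptides, and a two-slice peptide's censored mean carries the factor
`p/(1 - (1 - p)^2)` relative to a single-slice peptide, which the
calibrated presets account for. Ratios pool all samples by default; a
`cohorts` argument restricts them. Empty regions yield a flagged,
undefined result rather than an error, and `tail_depletion()` returns 0
with `n_tail = 0` when no tail peptide was detected — absence of evidence
is the finding there.

## Masses, m/z and band algebra

Monoisotopic residue masses drive m/z (`(M + z × 1.007276)/z`, displayed
to 2 decimals, full precision internally); average masses drive all
gel-kDa arithmetic, because SDS-PAGE estimates average mass. Trypsin
cleaves after K/R except before proline; `max_missed` defaults to 2 for
general digests and the detectability window defaults to 700–4000 Da
monoisotopic. Cysteine carbamidomethylation is off by default and
available as a flag. Semi-tryptic products at an annotated cleavage site
are built by pairing the biological terminus with the next/previous
tryptic boundary, and are flagged `fully_tryptic` when the site happens to
coincide with a tryptic boundary.

Band algebra (`contiguity_check()`) uses a default tolerance of 2 kDa —
the scale of gel mass-estimation error implied by whole-kDa band readings
— and reports signed residuals per constraint. Glycan-milestone
localization enumerates all subsets of candidate glycans exhaustively
(counts are small) and keeps those whose treatment-removable mass matches
the observed shift within 0.5 kDa.

The sequon scanner matches N-X-[S/T/C] with X ≠ P by default; the proline
exclusion is standard biochemistry but is exposed as a flag
(`exclude_proline = FALSE`) since the motif is sometimes quoted without
it. Matches may overlap, and a `region` argument restricts the scan.

## The differential screen

`differential_peptides()` compares log2 intensities per
(protein, peptide, slice) key between cohorts with Welch's t-test by
default — the cohorts are unequal (13 vs 18) and there is no reason to
assume equal variances; Student's pooled test is a flag. The log2 scale is
used because ratios are reported in log2 and multiplicative noise is the
natural model for ion current. P-values are deliberately uncorrected at
α = 0.01, mirroring the peptide-level screen this reproduces; a
Benjamini–Hochberg option exists but is off by default. Keys with fewer
than two usable samples in either cohort are emitted with `p_value = NA`
and never pass. Zero intensities are excluded from the log transform as
censored values, never imputed.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` draws an intensity table from: proteoform populations
(cleavage sets with molar fractions), per-fragment retention multipliers
(0 removes a fragment, values above 1 encode super-stoichiometric
retention such as ectodomain excess), per-peptide response factors,
multiplicative log-normal noise, and per-observation detection thinning.
Populations whose fragments co-migrate contribute to a single mixed
(peptide, slice) ion current — noise and detection act on that observation
unit per sample, which is where the mass spectrometer operates. Slice
placement uses the same `assign_expected_slice()` as the analysis side,
from the fragment's average mass.

Response factors are log-uniform over two decades, mimicking the dynamic
range of tryptic-peptide ion currents, and are centred to unit mean within
each inter-site segment so that segment-level abundance ratios equal the
planted stoichiometries exactly in the noise-free limit; this makes
parameter-recovery tests sharp without changing the realistic spread at
default noise.

Defaults are chosen to be realistic for cross-individual urinary vesicle
proteomics: cohort sizes 13 and 18; noise sd 0.5 log2 units (~40%
coefficient of variation, biological plus technical variation across
individuals); detection probability 0.8 per observation; base intensity
10^6 arbitrary ion-current units. Protein sequences are deterministic
pseudo-random sequences at natural amino-acid frequencies (mean tryptic
peptide ≈ 9 residues) with the planted cleavage positions protected from
being tryptic boundaries and sequons planted where the scenario needs
them; real sequences can be supplied via `read_protein_fasta()` instead.

The presets freeze five study scenarios. Their planted values are the
published pooled statistics: ectodomain excess 1.4 for the PC1-like
protein, post-PPC level 58% and residual tail 5.1% for the
fibrocystin-like protein, tail-to-body ratio 13% for the PC2-like protein,
and an uncleaved control increased 2-fold in the case cohort. One
calibration detail: the fibrocystin "58%" statistic is defined over all
B–J peptides stopping after the PPC site, a region that also contains the
5.1% residual-tail peptides, so the mid-region retention multiplier is
solved at preset build time (from the fixed in-silico digest and the
detection factor above) such that the statistic — not the raw multiplier —
equals 58% in expectation.

The generator does not emulate: abundance-dependent detection, retention
time or spectral interference, chromatographic alignment artifacts,
missed-cleavage and semi-tryptic background peptides, glycopeptide mass
shifts at the peptide level, or gel smearing (each fragment maps to
exactly one slice). Passing recovery tests therefore demonstrates that the
statistics are consistent estimators of the quantities the generator
plants under realistic noise — not that real gels are free of smearing or
that detection is abundance-independent.

## Numerical choices

* Gel windows are half-open `[min, max)` descending, so a boundary mass
  belongs to the heavier slice (gels cannot resolve boundaries anyway);
  the top window includes its upper bound. The shipped scheme corrects the
  B window to 140–270 kDa (the source legend misprints "140 kDa–27 kDa",
  which cannot tile between A and C); the raw value is kept in the
  scheme's `note` column.
* Score ties in the change-point scan (within 1e-9) merge into a single
  interval call rather than arbitrary tie-breaking.
* Signal peptides are a feature kind but are never subtracted from
  fragment masses unless explicitly excluded from the range — gel masses
  are estimates, not exact targets.
* Seeding: every stochastic element of a simulation derives from the
  config's single integer seed; the caller's RNG state is saved and
  restored, and identical configs produce byte-identical output files.

## Problem sizes

The bundled scenarios run at desk scale by design: proteins of 968–4302
residues give 96–430 zero-missed tryptic peptides (roughly 230 within the
detectability window for the PC1-like protein), 31 samples, and intensity
tables of a few thousand rows; a full simulate–differential–localize cycle
takes well under a second, and the 100-replicate localization studies run
in a few tens of seconds.

## Limitations

Localization resolution is bounded by tryptic peptide spacing — calls are
intervals, typically 10–25 residues wide here. Stoichiometry ratios
assume the response factor of a peptide cancels between regions, which
holds when regions are compared across the same peptides or averaged over
many; with very few peptides (the PC2 tail region has five detectable
ones) the ratio inherits their sampling noise. Proteoform deconvolution
beyond enumerated cleavage sets, and densitometry-style fractions of
western-blot bands, are out of scope.
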