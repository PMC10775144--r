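---
title: "capsidms: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{capsidms: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsidms)
```

This vignette documents the science and the engineering decisions behind
`capsidms`: the capsid-protein model, the mass arithmetic, the
deconvolution and matching algorithms, the stoichiometry and PTM
statistics, what the synthetic-data generator emulates, and the
numerical conventions. It states no empirical result that the package's
tests and acceptance script do not themselves compute.

## The capsid model

An AAV capsid is a 60-mer of three viral proteins at a nominal 1:1:10
VP1:VP2:VP3 ratio. VP2 and VP3 are C-terminal sub-sequences of VP1
produced from internal start sites, so a serotype is fully described by
its VP1 sequence plus the start positions of the shorter chains.
`capsidms` uses *mature-chain numbering*: position 1 is the residue left
after the initiator Met of VP1 is excised in the cell. Internally the
translated sequence (Met included) is stored and mature numbering is
exposed through a fixed offset of one, because published proteoform
labels ("VP1 (1–734)Ac", "VP3 (203–734)Ac") use mature numbering.
Sources differ on whether the searched VP1 span is written 2–735
(translated numbering) or 1–734 (mature); the two describe the same
residues and the library uses the mature form throughout.

**N-terminal processing.** Met-aminopeptidases remove an initiator Met
when the second residue has a small side chain (A, V, S, T, C, G, P),
and the exposed residue is then co-translationally acetylated
(`apply_nterm_processing()`). Only chains translated from their own Met
are processed: VP1, VP3 (its initiator Met sits immediately upstream of
the mature start, e.g. position 202 for a VP3 starting at A203), and
truncated VP3 variants such as A211-VP3. VP2 initiates at a non-AUG
codon (Thr) and receives no processing. The package infers "Met
initiated" from the definition itself — the mature residue immediately
upstream of the chain start — rather than from a hard-coded list, so
user-supplied serotypes behave correctly.

## Mass arithmetic

Theoretical masses are *average* masses (intact deconvolution at
59–82 kDa and 15k–45k resolving power is isotope-unresolved):

$$M = \sum_i m_{\text{avg}}(r_i) + m_{\mathrm{H_2O}} + \sum_p n_p\,\Delta_p$$

with the standard IUPAC residue table (`residue_masses()`), water
18.0153 Da, and PTM deltas (`ptm_table()`): acetylation +42.037,
oxidation +15.999, deamidation +0.985, NH₃ loss −17.031, succinimide
from Asp (water loss) −18.015, phosphorylation +79.980, Trp→kynurenine
+3.995 Da. The reference study names these PTMs but prints no delta
table, so the standard Unimod-scale average deltas are used and every
entry is overridable in config. Monoisotopic masses are carried
alongside for peptide-level work. Truncated variants
(`truncation_mass()`) subtract the removed prefix's residue masses while
keeping the chain water and assuming the N-terminal modification is
conserved on the new terminus. Mass errors are reported as the ppm
magnitude rounded to one decimal, matching the field's presentation;
the signed value is kept internally.

## Deconvolution

Vendor deconvolution (BioPharma Finder) is proprietary; `deconvolve()`
is a standard charge-ladder re-implementation:

1. scans inside the processing time limits (default 13.00–28.50 min) are
   peak-picked against a run-global robust threshold
   (median + 5 × MAD of all positive intensities — per-scan statistics
   would treat a clean envelope in a sparse centroid scan as its own
   noise floor);
2. picked peaks are clustered across scans into m/z traces; a trace must
   be detected in ≥ 10 scans (the "minimum detected intervals" filter);
3. each trace proposes neutral masses $M = z(m/z - 1.00728)$ for every
   charge in the allowed range (default 20–55, centred on the
   conventional default charge 35) within a plausible mass window;
4. proposals are single-linkage clustered at the 10 ppm merge tolerance;
5. clusters are accepted greedily in decreasing support, each consuming
   its m/z traces. This kills charge-assignment harmonics: the 2M and
   M/2 ghosts reuse exactly the traces of the true mass and are starved
   once it is accepted;
6. accepted features report the intensity-weighted neutral mass, the RT
   apex of the summed trace profile, a trapezoidal area, the number of
   distinct charge states, and a score.

**The score** is `100 · k/(k+3) · 1/(1 + s/(tol/2))` where `k` is the
number of charge states and `s` the ppm spread of the cluster. It is
calibrated only to the ≥ 60 filter semantics: well-supported coherent
envelopes (k ≳ 10, s ≪ tol) score 75–95, sparse or incoherent candidates
score below 50. It is *not* comparable to any vendor score; the
threshold default of 60 carries over the filter rule, not the scale.

## Identity testing

Component matching assigns, for each library component, the
highest-area feature whose RT apex lies in the component's closed RT
window (default ±1.00 min for VP3-like species, ±0.60 min for VP1/VP2)
and whose mass is within the ppm tolerance. The reference method
specifies only "highest peak"; ties are broken by smaller |ppm| then
earlier RT so results are deterministic. The match tolerance itself is
not printed anywhere for the vendor system, so the deconvolution merge
tolerance (10 ppm) is reused as the default; it is configurable and
echoed in every report. Matching uses *theoretical* masses (the
reference workflow explicitly replaced imported observed masses with
theoretical ones).

Replicate consensus keeps a component only when matched in every
replicate injection with score ≥ 60 in each. A serotype is called iff
its full unmodified VP1/VP2/VP3 set is in consensus; modified
proteoforms and VP3 variants support PTM monitoring but are not
required for the call. Any consensus component from another serotype
raises a false-positive flag; zero or multiple qualifying serotypes
yield "none"/"ambiguous" with diagnostics.

## Stoichiometry

With a 60-subunit capsid, `copies_i = 60 · area_i / Σ areas` and
`ratio_i = 12 · area_i / Σ areas` (12 = 1 + 1 + 10 theoretical copies).
Two estimators are provided: FLR (integrated fluorescence peak areas,
including any VP3-prime-like satellite peak in the denominator) and MS
(per-VP sums of proteoform XIC areas; satellite regions without
confident components are excluded). Areas are averaged across
replicates *first* and copies/ratios computed on the means — the order
the reference calculation prescribes, which differs in general from
computing per-replicate and averaging. Copies and ratios conserve their
totals exactly before rounding and are scale-invariant in the areas;
both are reported at 2 decimals, CV% at 2 decimals. Fractional copies
are reported as computed (no integer constraint is imposed).

## Peptide-level PTM quantitation

Records are filtered at ≥ 95% confidence, ≥ 1 × 10⁵ average MS area and
±5 ppm, with adduct / unknown-modification / gas-phase-ion / nonspecific
records excluded. Site-level relative abundance is, per replicate,
100 × (areas of covering records carrying the modification) / (areas of
all covering records), then mean ± SD across replicates; "covering"
means the record's span contains the site position, and the reported
peptide per site is the most abundant modified form. Abundances over a
site's modification states sum to 100% per replicate by construction.
The 1% reporting floor in `ptm_site_table()` is a report-level filter
only. Mobile protons are `max(0, z − #{R,K,H})`; zero mobile protons on
an N-terminal-Gln peptide favours charge-directed NH₃ loss, which is why
high NH₃-loss abundances on such peptides are flagged as potential
sample-preparation artifacts rather than process PTMs.

## The synthetic-data generator

`simulate_run()` emulates a HILIC-FLR-MS capsid run: each proteoform is
a Gaussian elution profile (apex inside 13–28.5 min; the default panel
calibration elutes VP3 ≈ 16.5 min, VP1 ≈ 21, VP2 ≈ 23, matching the
VP3 < VP1 < VP2 elution order of HILIC separations) times a Gaussian
charge envelope centred on z = 35 (σ = 4), emitted as centroid sticks at
$m/z = (M + 1.00728z)/z$ clipped to the m/z 867–2400 scan window, with a
3 s scan interval. The FLR trace is the abundance-weighted Gaussian sum,
normalised so each species' peak area equals `abundance × flr_scale`.
Noise is additive baseline sticks at random m/z plus multiplicative
intensity jitter, both off by default so closed-form oracles hold
exactly. Seeds fully determine the output, and the generator restores
the caller's RNG state.

What it does **not** emulate: peak tailing and co-elution shoulders,
profile peak shapes and isotope structure, adduct series, detector
saturation, retention-time drift between FLR and MS (assumed aligned; a
constant offset is configurable), or electrospray response differences
between VPs. A green end-to-end test therefore establishes that the
algorithms are correct on ideal-shaped data at realistic scales — not
that the tool's accuracy on a specific instrument matches any published
figure. Published observed masses and abundances depend on the study's
raw files, which are not deposited; they are covered by parameter-
recovery properties instead.

`simulate_peptide_table()` tiles the protein with contiguous peptides
and splits site-covering peptides into modified/unmodified records
around the true abundance. The default base area is 1 × 10⁷ (abundant-
peptide scale). Note an intentional interaction: a form whose split area
falls below the 1 × 10⁵ filter floor is censored by `filter_peptides()`
exactly as on real data — e.g. a 1% form of a 10⁷-area peptide survives,
but the same form on a 10⁶-area peptide does not.

The shipped `synthetic_serotype_panel()` is a stand-in (labelled
synthetic): the real AAV capsid sequences are not printed in the
reference material and must be supplied by the user as config. The
panel reproduces the structural layout — suffix relationships,
Met-initiated chains, the ATGSGAPM VP3 N-terminal stretch and the A211
variant for the AAV2-like entry, VP masses in the 59–86 kDa range
pairwise separated by far more than the 10 ppm tolerance — so
specificity tests on it are structurally meaningful, while its absolute
masses are not those of the real serotypes.

## Numerical conventions and degenerate inputs

- Proton mass 1.00728 Da; average-mass scale throughout intact work.
- RT windows and ppm tolerances are closed intervals.
- Peak integration: local maxima above median + 5 × MAD, valley-to-valley
  bounds, trapezoidal areas; plateau apices resolve to the earliest time
  point; summed peak areas never exceed the total trace integral.
- Empty proteoform lists, empty scan windows, all-zero XICs and empty
  consensus sets are valid results, not errors; all-zero area vectors,
  spans beyond the sequence, and unknown PTM/VP names are errors naming
  the offender.
- An empty amino-acid chain returns the water mass with a warning
  (degenerate but well-defined).
- JSON reports serialize with stable key order so identical results are
  byte-identical; every report embeds the full parameter snapshot and
  tool version.

## Known limitations

- The deconvolution is intact-level only: no isotope-resolved processing,
  no MS2, no mixture deconvolution of co-packaged serotypes.
- The quality score is internally calibrated; absolute values are not
  transferable across tools.
- Config files are JSON (FASTA import is supported for sequences); YAML
  is not parsed.
- Retention-time prediction from sequence is out of scope: expected RTs
  come from calibration runs supplied by the user.
- Whether peptide-level deamidation/NH₃-loss levels are process-related
  or digestion artifacts cannot be resolved by this workflow (a
  limitation inherited from the underlying chemistry); the tool
  quantifies what is in the records.
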