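---
title: "Non-target screening, annotation confidence and feature selection with ntscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-target screening, annotation confidence and feature selection with ntscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Non-target LC-HRMS screening of biological samples (plasma, feces) in a
case/control design — here styled after a Parkinson's disease (PD) versus
healthy-control cohort — produces aligned feature tables: thousands of
(m/z, retention time) signals with per-sample intensities, a subset carrying
data-dependent MS/MS spectra. Turning these into chemistry requires four
ingredients that `ntscreen` implements as one auditable chain:

1. **Quality filtering** against pooled QC injections,
2. **Annotation** — suspect screening by exact mass/adduct, MS/MS library
   search, and molecular-formula annotation,
3. **Confidence communication** — mapping the accumulated evidence to
   identification confidence levels (2a–5),
4. **Feature selection and interpretation** — univariate and multivariate
   statistics with a conjunctive significance rule, set-overlap reports and
   pathway over-representation.

Because real cohort raw data of this kind are rarely releasable, the package
ships a first-class synthetic-cohort generator with complete ground truth, so
the entire chain is exercised and tested end to end.

```{r, eval = FALSE}
library(ntscreen)
d   <- generate_cohort(default_cohort_config(), seed = 1)
res <- run_pipeline(d, default_run_config())
```

## Mass and formula conventions

Monoisotopic atomic masses are IUPAC values to at least six decimals;
proton 1.00727646 Da, electron 0.00054858 Da. Adduct m/z is
$(M + \Delta m - z\,m_e)/|z|$ with $\Delta m$ the neutral-atom mass shift of
the adduct. Two conventions matter:

* **`[M]+`** treats the formula as the atoms of an intrinsically charged ion
  (quaternary ammonium species such as choline) and subtracts one electron
  mass. Ignoring the electron shifts choline's m/z by about 5 ppm — more
  than the matching tolerance.
* **Supported adducts** are `[M+H]+`, `[M+Na]+`, `[M+NH4]+`, `[M]+`,
  `[M-H]-`, `[M+HCOO]-`; |z| > 1 is out of scope.

One reference value in the source tables — deprotonated
3-(3-hydroxyphenyl)propionic acid at a printed 165.0547 — sits 6.2 ppm from
the theoretical m/z of C9H10O3 minus a proton. The package flags it in its
test suite as a documented outlier and does not "correct" either side.

Theoretical isotope patterns are convolutions of per-element natural isotope
distributions aggregated on the unit-mass grid (A, A+1, A+2, ...), matching
what an Orbitrap-resolved envelope comparison consumes; fine isotopologue
structure is deliberately not resolved.

## Spectral scores

The upstream ecosystem names its scores without publishing closed formulas,
so the package fixes explicit, testable definitions that preserve each
score's documented range and ordering:

* **Peak pairing** is the one-to-one assignment within a m/z tolerance
  (default 0.01 Da) that maximizes the number of pairs and then minimizes the
  total |Δm/z|. Sorted peak lists admit a non-crossing optimum, computed by
  dynamic programming and verified in tests against exhaustive search.
* **Dot product (0–100)** is 100 × the cosine between square-root-scaled
  intensity vectors over the union of matched and unmatched peak slots — the
  common metabolomics convention. It is symmetric and scale invariant.
* **Fragment presence (0–100)** is the percentage of reference peaks at or
  above 1 % of the reference base peak that are matched.
* **Matched-fragment counts** also apply the 1 % floor, so "≥ 3 ion
  fragments matching" cannot be satisfied by noise peaks.
* **Library score (0–1)** is the normalized dot product. It stands in for a
  MoNA-style match score whose exact algorithm is internal to external
  tooling; the surrogate preserves the [0,1] range and candidate ordering
  that the confidence rules consume. This approximation is deliberate and
  documented here rather than hidden.

Candidates are gated by a 5 ppm precursor window and ranked by library score,
ties broken by |precursor Δppm| and then record index, so ranking is total
and deterministic.

## Formula annotation

`enumerate_formulas()` searches element-count combinations (default bounds
C≤40, H≤80, N≤6, O≤12, S≤3, P≤2, Cl≤3, F≤6, sized for an m/z 60–900 scan
range) whose monoisotopic mass falls within tolerance, filtered by integer
ring-plus-double-bond equivalents ≥ 0 and H/C in [0.1, 3.5]. The H/C rule is
applied only when both carbon and hydrogen are present, so bare carbon (the
mass-12 case) remains valid. The grid is built heaviest element first with
mass pruning; hydrogen is solved from the residual mass. A guard on the
pruned grid size raises an error instructing tighter bounds instead of
exhausting memory.

* **isoScore** is defined as 1 − mean |observed − theoretical| relative
  abundance over the aligned A..A+k envelope, clipped to [0,1]: bounded,
  symmetric, and 1 exactly for identical envelopes.
* **annSimForm** asks how much of the MS/MS spectrum a formula can explain:
  a peak is explainable if it reads as a sub-formula of the candidate,
  ionized for the ESI mode (protonation/deprotonation or electron loss) with
  ±1 H latitude — the standard small-molecule fragmentation latitude. The
  score is the cosine between the spectrum and its explainable sub-spectrum,
  i.e. the square root of the explainable intensity fraction. No
  double-bond-equivalent rule is applied to fragments: the ±1 H latitude
  already covers radical/even-electron ambiguity at these peak counts.
* **annSimComp** folds in structure evidence when a structure-known library
  match exists: `min(annSimForm, dot/100)`.

Candidates are ranked by isoScore, then |ppm error|, then annSimForm, with
Hill-string order as the final tie-break; gap-to-next-candidate values
(`gap_iso`, `gap_ann`) feed the "0.2 higher than the next candidate" rules,
with a single candidate given infinite gaps. Where a rule mentions the gap of
an ambiguous "annSim/iso" pair, both gaps are required — the conservative
reading of an ambiguous rule cell.

## Confidence levels

Three rule cascades map evidence to levels {2a, 2b, 3a, 3b, 3c, 4a, 4b, 5},
one per screening scheme (suspect screening; non-target screening scored by
library/formula evidence; non-target screening scored by dot product and
fragment presence). Design choices:

* Cascades run best level first; a feature receives the best level it
  qualifies for, and level 5 ("unknown mass of interest") is the total
  fallback, so assignment is total and deterministic.
* Printed ranges partition the score axis without overlap: "0.7–0.9" is
  (0.7, 0.9], "70–100" is [70, 100], explicit >/≥ are literal. Hence a
  library score of exactly 0.9 is level 3a in the non-target scheme, not 2a.
* In the suspect scheme the two fragment-count clauses of level 3b are read
  as a disjunction (> 3 fragments match, or fewer than 3 fragments in total
  and all match), and 3b precedes 3c in the cascade.
* Missing evidence never satisfies a rule: a feature without MS/MS can still
  reach 4b on isotope evidence alone, and a feature with nothing reaches 5.
* Level 1 (reference-standard confirmation) has no computational analogue
  and is out of scope.

Levels are assigned per scheme and never merged across schemes; cross-scheme
comparison is reporting only.

## Statistics

The selection chain mirrors the common web-tool workflow so its thresholds
stay auditable:

* **IQR filter**: features ranked by interquartile range across biological
  samples; the least-variable fraction dropped by the size ladder 0 % (< 250
  features), 5 % (< 500), 10 % (< 1000), 25 % (< 2000), 40 % otherwise. Ties,
  including constant features, break by feature id.
* **Sum normalization** (each sample scaled to the mean total — idempotent)
  then **Pareto scaling** (center, divide by √sd; sd-0 rows scale to zero).
  Fold change is computed on the normalized-but-unscaled matrix, the t-test
  on the scaled one — the convention of the web tool this mirrors. Since
  scaling is affine per feature, the Welch p-value is unaffected by it.
* **Welch t-test**, two-sided, no multiple-testing correction by default —
  replicating the study design this emulates, which reported that FDR
  correction at its sample size removed all findings. `fdr = TRUE` provides
  Benjamini–Hochberg adjustment for honest reanalysis. Zero-variance
  features degenerate to p = 1 (identical means) or p = 0 (separated means).
* **O-PLS-DA**: class membership coded −1/+1 and centered; one orthogonal
  component removed (Trygg–Wold), then NIPALS PLS1 with one predictive
  component — the minimal faithful model for a two-class problem. VIP is
  computed on the predictive component:
  $VIP_j = \sqrt{p \sum_a w_{ja}^2 SSY_a / \sum_a SSY_a}$, which satisfies
  $\sum_j VIP_j^2 = p$ exactly (asserted to 1e-8 in tests). Which VIP
  variant the web tool uses is not recoverable from its outputs;
  predictive-component VIP is the documented choice here.
* **Selection rule**: significant ⇔ p < 0.1 AND (FC > 2 OR FC < 0.5) AND
  VIP > 1 — an exact conjunction, verified by an exhaustive truth table,
  including the borderline case of a feature passing p and FC with
  VIP ≈ 0.78 that must be rejected.

## Overlap and pathways

Overlap reports compare annotation sets (across ESI modes, LC modes or
suspect lists) by InChIKey — full key for cross-mode comparison, 14-character
first block for cross-list de-duplication, where stereoisomer entries should
merge. Annotations at levels 2b, 3c and 5 carry no structure identity; they
are excluded from key-based overlap and reported as an excluded count, never
silently dropped.

Pathway over-representation is the exact hypergeometric upper tail
P(X ≥ hits) for drawing the selected compounds from the annotated universe,
computed per pathway after exact name matching (case-folded,
whitespace-normalized — no fuzzy matching, mirroring name-keyed pathway
tools). The universe is always supplied explicitly. Pathway-topology impact
scores are out of scope.

## The synthetic cohort

`generate_cohort()` emulates the study conditions: 10 PD vs 10 Ctrl samples
with 6 pooled QC injections, 500 features, log-normal intensities with 20 %
CV, multiplicative group effects, Gaussian m/z error (SD 1 ppm), 20 features
spiked at fold change 4, and 25 features with a QC RSD target of 80 % to
exercise the filter. Thirty-one annotated compounds — including the named
level-2a identities of the emulated study (valine, choline, alanine betaine,
nicotinamide, isonicotinic acid, levodopa, 3-HPPA, cholic and glycocholic
acids) with their printed formulas, adducts and fold changes — are assigned
to ten evidence *archetypes* whose reference/query spectra, library
membership, structure flags and isotope patterns are engineered so that
every confidence level of every scheme is realized by at least three
compounds. Equal-intensity peak constructions make the cosine scores exact
count ratios (e.g. 5 shared of 6 reference peaks with one extra query peak
gives exactly 100·5/6), so archetypes land deterministically in their rule
bands. Archetype masses were screened for cross-adduct isobars (e.g. a
protonated amine coinciding with the ammonium adduct of an acid 17 Da
lighter) so that adduct assignment cannot flip with the noise realization.

Deliberate simplifications, hence what passing tests do *not* show about
real data: no chromatographic peak shapes, drift or batch effects; no
missing values (absent intensities are zero, as downstream sum-normalization
requires numbers and the emulated workflow described no imputation);
MS/MS noise is controlled rather than stochastic; InChIKeys are
deterministic synthetic stand-ins with the real 14-10-1 layout, not real
database keys; and library spectra are either near-perfect or engineered to
a target band, with none of the instrument-type heterogeneity that degrades
real library matching.

## Problem sizes and budgets

The default cohort (500 features, 26 samples) runs through the full chain in
about two seconds on one core; the recovery analysis repeats generation and
selection over ten seeds. These sizes were chosen so that the complete
statistical behavior — QC filtering, selection sensitivity (≥ 90 % of spiked
features recovered, ≤ 10 % false selections among selected, in practice
100 %/0 % at these effect sizes), null p-value uniformity, and level
coverage — is measurable in seconds while remaining at the scale of a real
pilot cohort.

## Known limitations

* The library score is an ordering-preserving surrogate, not a reimplementation
  of any external tool's proprietary match score; absolute values near rule
  boundaries (0.4/0.7/0.9) can differ from those tools.
* Formula enumeration does not score MS/MS-consistency during enumeration
  (the role GenForm's MS/MS score plays); consistency enters at ranking.
* Charge states |z| > 1, isotopically labeled formulas, in-silico
  fragmentation and retrieval from live chemical databases are out of scope.
* Suspect matching uses mass and adduct only; retention time is carried for
  reporting, as the emulated suspect lists provide none.
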