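---
title: "Marker screening and metabolite annotation with herbmarker: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker screening and metabolite annotation with herbmarker: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbmarker)
```

## The problem

Untargeted LC-MS/MS of herbal material yields thousands of aligned
molecular features per study, of which only a handful are useful quality
control (QC) markers — metabolites whose abundance pattern reliably
discriminates species or cultivars. Two obstacles stand between a raw
feature table and a defensible marker panel. First, most features are
noise, redundant ion forms, or in-source artifacts, so candidate markers
must survive a cascade of quality, chemistry, and statistics filters.
Second, a "marker" that is merely the in-source fragment (ISF) or sodium
adduct of another marker is not an independent compound, and a candidate
identity that relies on a single precursor match is fragile. `herbmarker`
implements the full path: exact-mass bookkeeping, the screening cascade,
satellite deduplication, and rule-based annotation, with a synthetic-study
generator that makes every stage testable against known ground truth.

## Exact-mass arithmetic

All mass computation is anchored on IUPAC/CODATA monoisotopic atomic
masses carried to at least 8 decimal places. A positively charged adduct
adds an **electron-corrected** delta to the neutral monoisotopic mass:
protonation adds the mass of a bare proton (1.00727645 Da), not of a
hydrogen atom. The distinction is one electron mass, about +1.2 ppm at
m/z 433 — larger than the sub-ppm accuracy of a modern Orbitrap, so using
the atom mass visibly corrupts every reported mass error. The test suite
asserts both directions: the proton convention reproduces the mass errors
of the bundled 25-feature worked example to within ±0.05 ppm, and the
atom-mass substitution breaks them.

Candidate molecular formulas for a neutral mass are enumerated
exhaustively over a constrained CHNO box (defaults: C ≤ 60, H ≤ 120,
N ≤ 10, O ≤ 30) by iterating C, N, O and solving for the hydrogen count.
Candidates are pruned by ring-and-double-bond equivalents
(RDBE = C − H/2 + N/2 + 1, allowed range 0–40) and H/C ratio (0.2–3.1).
These bounds cover every formula in the bundled worked example while
discarding chemically absurd compositions; they are fully configurable.
Completeness is verified in the tests against an independent
exhaustive-grid oracle on random masses.

Three rows of the bundled 25-feature table are excluded from the
mass-error regression tests: two print truncated or internally
inconsistent m/z values, and one (a sodiated row at m/z 467.38544) prints
a formula whose recomputed ion mass is tens of thousands of ppm away
under any plain adduct convention. They are carried in the fixture
unchanged but not asserted on.

## The screening cascade

Stages run in a fixed order, and every stage records its survivor count,
so a run reports a six-number funnel
(input → quality → elements → ANOVA → VIP → top-N):

1. **Quality** — keep a feature iff its maximum peak rating across files
   is ≥ 6 (ratings are 0–10 scores from the upstream peak detector;
   consumed, not computed) and its maximum area is ≥ 2 × 10^5. Both
   thresholds are inclusive.
2. **Elements** — keep a feature iff a predicted formula is present and
   uses only C, H, N, O (herbal metabolomes are overwhelmingly CHNO;
   heteroatom predictions at this stage are usually artifacts).
3. **ANOVA** — one-way F-test per feature on log10(x+1)-transformed
   areas, Benjamini–Hochberg adjustment **across features**, cut at
   adjusted p < 10^-4. Tukey HSD pairwise p-values are computed and
   stored per feature. The adjusted quantity is deliberately BH rather
   than the Tukey family-wise p: the cascade needs one p per feature,
   and BH across thousands of features is the standard metabolomics
   reading of "adjusted p". A `p_adjust = "tukey"` mode (minimum pairwise
   Tukey p) is available for users who prefer the family-wise reading.
   Constant features get p = 1 and a degenerate flag rather than an NaN.
4. **VIP** — PLS-DA (below) on autoscaled log areas; keep features with
   VIP ≥ 2.0.
5. **Top-N** — rank the surviving candidates by ascending adjusted p,
   ties broken by descending VIP and then feature id (full determinism;
   permuting input rows cannot change the panel), and keep the top 25.

Log10(x+1) transformation is applied before all statistics because LC-MS
peak areas are log-normal to good approximation; the +1 keeps zeros
finite. Coelution grouping (5 ppm, 0.1 min; representative = largest-area
member, areas summed) is available upstream of the cascade and is applied
first by `run_pipeline()`.

### PLS-DA and VIP

The PLS-DA is a NIPALS PLS2 fit: X is autoscaled (unit variance; Pareto
scaling available), Y is the centered one-hot group indicator, and
components are extracted with deflation of both blocks, which makes score
vectors mutually orthogonal and the fit deterministic given the input
order. Variable importance in projection is the standard definition

$$VIP_j = \sqrt{\,p \cdot \frac{\sum_a SSY_a\, (w_{aj}/\lVert w_a\rVert)^2}{\sum_a SSY_a}\,}$$

with $p$ the number of variables and $SSY_a$ the Y sum of squares
explained by component $a$. Two algebraic identities are enforced in the
tests: the mean of squared VIPs is exactly 1, and a single-variable model
has VIP = 1. The implementation is cross-checked against the independent
`mixOmics` implementation in the test suite. The default of 3 components
matches the low-dimensional class structure that cultivar panels show in
practice; it is configurable, and fits stop early if X or Y deflates to
numerical zero.

## Satellite deduplication

Two detectors emit parent → child relation edges between coeluting
features (default coelution window 0.1 min, reusing the grouping RT
tolerance; no separate ISF window is defined by common practice):

- **Adduct pairs** — the m/z difference matches the difference of two
  registered adduct deltas (e.g. Na−H = 21.981944 Da) within 5 ppm of
  the larger m/z. The declared [M+H]+ member is the parent, else the
  larger-area member.
- **ISF products** — the child's precursor m/z matches a fragment in the
  parent's MS/MS spectrum within 10 ppm; failing that, the precursor
  difference matches a registered neutral loss (water, CO, hexosyl,
  deoxyhexosyl, caffeoyl, malonyl, glucuronyl) within 10 ppm of the
  parent precursor — ppm of the parent, not absolute daltons, for
  consistency with the fragment tolerance; failing that, child precursor
  minus a registered loss is sought among the parent's fragments.
  Parents without spectra participate through the precursor-difference
  rule only.

Connected components of the edge graph are collapsed to compounds.
Satellites are **flagged and annotated** ("ISF product of X"), never
deleted: a genuine compound coeluting with a heavier neighbour that could
fragment into it is observationally indistinguishable from an ISF
product, so the flag must be reversible and the ambiguity stays visible
in the report. When several coeluting parents could claim a child, the
highest-m/z parent with supporting evidence wins.

## Annotation rules

Three complementary methods, mirroring targeted/untargeted practice:

- **Method A (DPI search)** — class-characteristic diagnostic product
  ions (shipped table: the caffeoyl acylium at 163.03897 for
  caffeoylquinic acids; protonated aglycones of luteolin 287.05501,
  apigenin 271.06009, diosmetin 301.07037, acacetin 285.07574 for
  flavonoid glycoside classes) are sought in each spectrum at 10 ppm;
  one DPI hit flags the class, and precursor formulas then come from the
  enumerator. The DPI table is editable data, not code.
- **Method B (database precursor search)** — each database entry is
  projected to [M+H]+ and [M+Na]+ ions; features within 10 ppm are
  candidates, promoted to "identified" only when their spectrum carries a
  DPI of the entry's class (the minimal reading of "complies with the
  fragmentation pattern": at least one class DPI), otherwise "tentative".
- **Method C (library matching)** — entries outside ±20% relative
  collision energy are skipped; fragments are greedily paired within
  10 ppm (highest intensity product first, each peak used once); the
  score is 100 × cosine similarity of square-root intensity vectors over
  the union peak set, and the confidence is 100 × the matched fraction
  of total library intensity. These are documented stand-ins with the
  same 0–100 semantics as proprietary "best match"/"confidence" scores,
  chosen because they are reproducible, standard, symmetric, and
  monotone in spectral agreement. Acceptance requires score ≥ 90 with
  confidence ≥ 60 (cloud-like sources) or score ≥ 90 with ≥ 3 matched
  fragments (vault-like sources); the top 10 results are retained and
  every rejection carries a reason string. The rule is monotone in all
  thresholds.

Two exclusion rules curb false positives: candidates with non-CHNO
formulas are rejected, and when more than two accepted terpene isomers
share one molecular formula on one feature, all are rejected as
indistinguishable ("terpene isomer ambiguity"). Coeluting isomer
candidates with known ClogP are assigned to features in retention order
(higher ClogP elutes later under reversed phase); ties or missing values
yield an explicit "unresolved" flag rather than a guess.

## The synthetic-study generator

`generate_study()` emulates a seven-group cultivar study (batch sizes
10, 9, 12, 13, 12, 12, 12) with full ground truth. Design choices, and
what they do and do not emulate:

- **Areas** are log-normal (sigma 0.2 on the log10 scale) with
  multiplicative group effects — the standard behaviour of LC-MS
  abundances. Marker features carry a ±4-within-group-SD shift.
- **Effect structure**: marker effects follow a small set of latent
  chemotype contrasts (a species axis, a cultivar-cluster axis, a
  single-cultivar axis) rather than arbitrary per-marker patterns.
  Cultivar chemistry differentiates along a few shared axes, and this
  matches the low-dimensional class structure the 3-component PLS-DA
  assumes. With arbitrary high-dimensional effect patterns, a marker
  whose contrast is orthogonal to the extracted components can
  legitimately fall below the VIP threshold.
- **Mass errors** are Gaussian with SD 1 ppm, matching sub-ppm
  instrument accuracy; **RT**: parent compounds elute on an evenly
  spread ladder over 2–48 min (distinct compounds are
  chromatographically resolved), satellites coelute with their parents
  within a 0.01 min jitter SD.
- **Satellites**: each parent plants a coeluting [M+Na]+ twin and/or an
  ISF child with configurable probability. ISF children are built from
  moiety losses only (hexosyl, caffeoyl, malonyl, ...) — in-source water
  loss is chemically the [M−H2O+H]+ adduct form and belongs to the
  adduct channel, so planting it as "ISF" would make the two detectors'
  overlapping verdicts a scoring artifact.
- **Ratings** are drawn from a mixture in which roughly a fifth of
  features fall below the rating-6 threshold, echoing the direction of
  real quality attrition without claiming to reproduce any particular
  dataset's proportions.
- **Spectra** contain the class DPI, random minor fragments, and (for
  ISF parents) the child ion; the library holds the true spectra with
  10% log-normal intensity noise.

Not emulated: chromatographic peak shapes, isotope patterns, batch and
QC drift, correlated matrix interference, missing values. Passing tests
on this generator therefore demonstrate algorithmic correctness and
statistical calibration, not robustness to every failure mode of real
acquisitions.

## Numerical choices and degenerate inputs

- NIPALS convergence: relative change in the score vector below 1e-10,
  max 500 iterations; zero-variance columns are dropped with a warning
  before autoscaling; a component whose residual X or Y is numerically
  zero stops extraction.
- Ranking ties break by VIP then feature id; grouping visits features in
  descending maximum-area order so representatives are deterministic.
- Empty edge sets, singleton tables, constant features, spectra without
  collision energy, entries without formulas — all flow through with
  defined results (identity collapse, trivial trees, p = 1 flags,
  CE gate skipped, consistency check skipped) rather than errors.
- Readers raise typed conditions (`herbmarker_parse_error`,
  `herbmarker_missing_column`, ...) with line or column context; an MSP
  entry whose precursor contradicts its formula/adduct by > 10 ppm is
  quarantined with a warning, never silently dropped.

## Problem sizes used in the shipped checks

The bundled tests run a 520-feature, 70-sample study for marker
recovery, 100 replicate 200-feature null studies for calibration of the
ANOVA stage, 50 random masses for enumeration completeness, and a
60-parent study with ~40% satellite rates for deduplication scoring.
These sizes give stable Monte-Carlo verdicts while keeping a full test
run in the low minutes on one CPU; all are configurable upward through
`sim_config()`.

## Known limitations

- Single positive charge only; negative mode and multiply charged ions
  are out of scope, as is isotope-pattern scoring.
- ClogP is consumed as an input column, never computed.
- The ISF/coeluting-isomer ambiguity is flagged, not resolved; resolving
  it needs orthogonal evidence (peak-shape correlation, standards).
- The library score is not a calibrated probability; its thresholds are
  operating points, and the monotonicity property is what makes them
  safe to tighten.
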