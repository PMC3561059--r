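---
title: "Methods: prostaglandin identification and sperm-guidance scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prostaglandin identification and sperm-guidance scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgsperm)
```

# Scope

`pgsperm` implements two linked analyses of prostaglandin-mediated sperm
guidance in the *C. elegans* reproductive tract:

1. **Identification and quantification of F-series prostaglandins** from
   triple-quadrupole LC-MS/MS data: rule-based annotation of CID
   product-ion spectra against a packaged library of chemically
   synthesized standards, MRM chromatogram peak detection and
   integration, external-standard calibration, and per-compound strain
   comparison.
2. **Sperm-guidance scoring** from time-lapse tracks: uterine zone
   geometry and occupancy, average and directional velocity, reversal
   frequency, track filtering, and group comparison.

Because no instrument raw data are deposited anywhere, the package ships
synthetic generators that emulate the mass spectrometer and the
microscope with retained ground truth, so every analysis stage can be
exercised and round-trip-tested without downloads.

# The standards library

The reference data are two packaged tables: 21 chemically synthesized
prostaglandin standards (F1/F2/F3 stereoisomer families, the D/E/H
compounds PGD2/PGE2/PGH2, a dinor metabolite, and two hydroxylated
forms) and 11 worm compounds (five F1 isomers including CePGF1, CePGF2
and CePGF2b, and four F3 isomers). Each entry is a (name, series,
parent \[M-H\]^-^ m/z, reverse-phase RT, product-ion list, batch) record
— deliberately *not* a chemical structure: the analyses only ever touch
masses, retention times and ion lists.

Two tolerances govern all matching:

* `mz_tol = 0.5` Da — unit-resolution triple-quadrupole data; every
  tabulated mass is an integer.
* `rt_tol = 0.05` min — the chromatography program resolves
  stereoisomers differing by as little as 7 s (0.12 min) and calls
  co-elutions indistinguishable; 0.05 min separates resolvable isomers
  while tolerating run-to-run jitter. The reference tables give one RT per
  standard with no replicate spread, so this cannot be estimated from
  data; it is a stated decision.

Entries carry a `batch_id` because standards acquired on different days
show a small systematic RT shift; RTs are only directly comparable
within a batch, and [align_rt()] estimates the median apex shift over
shared standards when batches must be compared.

# Diagnostic fragmentation rules

F-series prostaglandins share a small set of diagnostic CID features,
all derived from the parent mass:

* the **z1 ion** at parent − 44 Da (loss of C~2~H~4~O), followed by two
  water losses (z1 − 18, z1 − 36);
* the **direct dehydrations** parent − 18 and parent − 36;
* the **cyclopentane ring ions**: m/z 193 for the F2 parent (m/z 353),
  m/z 193 and 191 for the F3 parent (m/z 351);
* m/z 189, a marker of the D/E/H-series compounds detected by the
  351/189 transition;
* m/z 115, abundant only in isomers hydroxylated at C5 (its *absence*
  supports the standard C9/C11/C15 hydroxyl pattern).

Parent masses follow the precursor PUFA: m/z 355/353/351 for the
20:3/20:4/20:5-derived classes, and 327 (28 Da = C~2~H~4~ lighter than
the F1 parent) for an 18:3-derived prostaglandin
(`predict_parent_mz()`).

`classify_spectrum()` maps the parent mass to a candidate series and
accepts it when the spectrum shows the z1 ion, **or** at least two of
the four dehydration-chain ions, **or** (F2/F3/hydroxylated parents) a
ring ion. The two-of-chain fallback is required by the data: two of the
tabulated worm F3 compounds lack the z1 ion 307 but show dehydration-chain
ions and the ring ions, and would otherwise be unclassifiable despite
their established F3 label. A 351 parent showing m/z 189 with no ring ion is
called a `DEH_candidate` instead of F3. The reference tables do not
state how many diagnostic ions suffice for a call; this rule is a
documented reconstruction validated against all of their labels —
the 11 worm compounds classify F1/F2/F3, the three D/E/H standards
classify `DEH_candidate`, and every F-series standard retrieves itself
from its own library.

Spectral comparison (`match_spectrum()`) pairs ions greedily
(nearest-neighbour within tolerance, ascending m/z, each ion used once)
and reports shared/unique ions and their Jaccard fraction. Greedy
pairing was chosen over optimal bipartite matching for transparency; at
integer resolution with 0.5 Da tolerance the two coincide, and the test
suite verifies this against an exhaustive augmenting-path oracle. All
tabulated ion lists are presence-only, so presence-based matching is the
default; when the synthetic CID generator produces intensities, only
ions at or above 5% of the base peak are considered.

Best-match retrieval restricts candidates to entries with a compatible
parent mass and prefers the subset whose RT lies within `rt_tol` of the
query; ties break on RT distance, then name. A call is flagged
`enantiomer_unresolved` when its best match belongs to a co-eluting
enantiomer pair (PGF2a/ent-PGF2a differ by 0.02 min): reverse-phase
chromatography cannot distinguish a compound from its enantiomer, and
resolving that requires chiral-phase methods that are out of scope here.

# MRM processing

The peak model is deliberately plain — vendor acquisition software
reports peaks without disclosing its detection algorithm, so nothing
would be gained by imitating one; every constant below is exposed in
`pg_config()`:

* centred moving-average smoothing (5 points by default, 0.01 min
  sampling ≈ 5 points per σ at the default σ = 0.05 min);
* baseline = median intensity; noise = 1.4826 × MAD (`stats::mad`);
* peaks are local maxima with baseline-subtracted height ≥
  `min_snr` (10) × noise;
* bounds descend from the apex to 5% of apex-above-baseline or a local
  minimum, whichever comes first; the area is the trapezoidal integral
  of the baseline-subtracted raw signal between bounds. A Gaussian
  truncated at the 5% descent retains ≈ 98.6% of its mass, which is why
  the integration tests use a 2% tolerance;
* the limit of detection is baseline + 3 × noise.

Calibration (`fit_calibration()`) is unweighted ordinary least squares
of area on concentration over the five-level serial dilution (1000,
100, 10, 1, 0.1 ng/ml), with the Pearson r reported as the linearity
figure of merit (> 0.99 expected). Quantification inverts the line,
clamps negative estimates to zero and flags estimates outside the
calibrated range. One curve is used per transition — whether non-alpha
isomers share the PGF2a response factor is unknowable from the available
data, and this assumption is recorded here rather than hidden.

Strain comparison detects and integrates peaks in replicate runs from
two groups, matches them to library compounds (a compound responds to a
transition when its parent matches Q1 and its ion list contains Q3, and
claims the nearest peak within 0.1 min of its library RT), and reports
mean areas, B/A fold change, and a qualitative call: `ELEVATED` /
`REDUCED` at ±1.5-fold, `ABSENT_IN_A` / `ABSENT_IN_B` below the LOD in
more than half the runs of one group.

# Sperm-guidance scoring

The guidance axis runs from the vulva to the spermatheca centre; 2-D
positions are scored by orthogonal projection onto it (origin at the
vulva, positive toward the spermatheca). Zone 3 spans the spermatheca
centre plus 50 µm toward the vulva; the remaining region is halved into
zones 1 and 2. Positions projecting behind the vulva score zone 1;
positions at or past the spermatheca centre stay zone 3. The manual
practice of expanding zone 3 around large sperm aggregations requires
human judgment and is *not* implemented — fixed-depth zones only.

Per track (frames every 30 s, durations filtered to the inclusive
2.5–21 min window):

* **average velocity** = path length / duration (µm/min);
* **directional velocity** = net axial displacement from first to last
  frame / duration, positive toward the spermatheca. The assay
  definition (distance travelled along the guidance line from the
  beginning of a trace to its end, divided by time) is start-to-end net
  displacement, not summed per-step axial displacement, and start-to-end
  is what is implemented;
  the projection bound |directional| ≤ average holds for every track.
* **reversals**: a change in migration direction of more than 90° within
  3 consecutive frames. The phrase is ambiguous about pairing, so the
  implemented rule is stated exactly: per-step headings (steps under
  0.5 µm carry the previous heading so pauses never create undefined
  angles); a reversal is scored at step i when the unsigned angle
  between heading i and heading j exceeds 90° for some j ∈ {i+1, i+2};
  scoring then advances past j so one manoeuvre counts once. A strict
  adjacent-step variant is available via `pg_config(reversal_rule =
  "adjacent")`. The rule is verified against an independent exhaustive
  window-scan oracle on 1,000 random tracks.

Zone distributions average per gonad (each gonad one observation, mean ±
SD across gonads), and group comparisons use Welch's two-sample t-test
with means ± SEM, matching how the motility table is presented.

# Synthetic data: what it emulates and what it does not

**MRM traces** are sums of Gaussians (σ = 0.05 min) at each responding
compound's library RT on a 0.01 min grid, scaled by per-strain relative
abundances, with point-wise multiplicative lognormal noise (cv 0.05) and
a Poisson baseline (20 cps). Strain presets encode only the established
qualitative patterns: `fat-1` lacks all F3 compounds with CePGF2
×4; `fat-4` and `fat-1 fat-4` lack CePGF2/CePGF2b and F3, the double
mutant with F1 ×3; `fat-3` loses all 20-carbon compounds; `glp-4` has
F2/F3 at 0.25 (a ~75% reduction); `cyp-31A2` has all classes ×2.
Abundances nothing constrains default to 1. The wild-type-equivalent
concentration is 100 ng/ml with a response factor of 100 area units per
ng/ml — values chosen to place simulated analytes in the upper middle of
the calibrated range, where inversion of the unweighted calibration line
is insensitive to intercept noise (at the bottom decade of a 4-decade
unweighted fit, intercept noise dominates small peak areas, which is a
property of the calibration design, not of the detector). No attempt is
made to simulate ion physics, chromatographic tailing, or co-eluting
interferences; passing round trips show the *analysis contracts* are
honoured, not that real instrument data would behave this gently.

**CID spectra** are a compound's tabulated ion list with lognormal
intensities, optionally plus 1–3 contaminant ions kept > 1 Da from the
compound's own ions (so contamination strictly lowers the match Jaccard
without touching the diagnostic calls).

**Tracks** follow a biased persistent random walk at 30 s frames:
heading ← heading + bias · (signed angle to the spermatheca) + Gaussian
turning noise, with spontaneous 180° ± 10° flips as a Poisson process
whose times are retained as ground truth; step length = speed × Δt;
positions reflect at a rectangular uterus (axis length 220 µm, width
40 µm around the default 200 µm vulva–spermatheca axis). The geometry is
a stand-in scaled so an hour of wild-type motion reaches zone 3 at the
measured speeds — exact uterus dimensions are not available and real
strains differ (some mutants have shorter uteri). Preset speeds and
reversal rates come from the reference motility measurements (wild type
8.6 µm/min, 1.8 rev/hr; guidance-null 3.4 µm/min, 16.2 rev/hr); `bias`
and `turn_sd` are not constrained by any measurement and were fixed once (0.5 and 30°
for wild type) so that the simulated wild type reproduces the > 90%
zone-3 occupancy at 1 h. They are calibration constants of the
generator, not measurements.

Two honest caveats about the walk, verified in the tests rather than
hidden: (1) wall reflections and post-arrival milling around the
spermatheca register as direction changes, so a guided preset's
*measured* reversal rate exceeds its injected rate — parameter-recovery
tests therefore run in an open geometry (`reflect = FALSE`) with low
turning noise; (2) the reversal-scoring rule itself merges flips closer
than its 3-frame window and cannot see a flip on the first step, so the
sharp recovery oracle is the window-censored injected count (at 9
flips/hr the censoring is ≈ 3%).

# Numerical choices and degenerate inputs

* Duration bounds of the track filter are inclusive at both ends; a
  21.0 min trace is retained.
* Zero-variance group comparisons (identical groups) return t = 0,
  p = 1 instead of erroring.
* A flat chromatogram has no strict local maxima and yields an empty
  peak table; noise floors at machine epsilon so noiseless traces do not
  divide by zero.
* Single-measurement replicate sets report SD 0 with an explicit
  `sd_defined = FALSE` flag.
* All generators take a `seed` and restore the caller's RNG state;
  identical seeds give identical outputs byte for byte.
* Library writers format numbers at 15 significant digits, so
  write → read → write is byte-identical in both TSV and JSON.

# Problem sizes used by the shipped checks

The test-suite and acceptance-script simulations use 200 tracks × 120
frames for the zone-distribution check, 500 × 40 for reversal-rate
recovery, 150 × 40 per point of the five-point bias grid, three
replicate chromatograms (1,601 points each) per strain for the
quantification round trips, and 1,000 random short tracks for the
reversal oracle. These sizes give comfortable sampling margins (3 SE
bounds) for every stochastic assertion while keeping the whole suite
fast.

# Known limitations

* Compounds are (mass, RT, ion-list) records; there is no structure
  representation, no isotope modelling, no positive-ion mode, and no
  de novo elucidation.
* Chiral-phase identification is represented only by the
  `enantiomer_unresolved` flag — no chiral reference RTs are available to match
  against.
* mzML/vendor raw ingestion is out of scope; chromatograms arrive as
  CSV time/intensity series tagged with their Q1/Q3 transition.
* Minor product ions of unknown composition (e.g. 157, 167, 223)
  participate in library matching but carry no diagnostic meaning.
* The synthetic walk does not model embryo collisions or the
  spermatheca interior; zone scoring treats the uterus as an empty
  rectangle.
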