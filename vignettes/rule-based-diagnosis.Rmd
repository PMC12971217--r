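---
title: "Rule-based diagnosis of nasal obstruction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based diagnosis of nasal obstruction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhinorules)
```

## The diagnostic model

`rhinorules` encodes expert ENT decision-making over anterior nasal
endoscopy as a decision table. The inputs are four ordinal grading scales,
each assessed on the left and right nostril before and ten minutes after a
topical decongestant (xylometazoline):

* **INV** (internal nasal valve), graded by visibility of the middle
  turbinate: 0 (seen clearly), 1 (partially blocked), 2 (not visible). The
  scale is extended with certainty levels "maybe 0" (1/3) and "maybe 1"
  (2/3) so a reviewer can express doubt between the clear and obstructed
  states without committing to either.
* **IT** (inferior turbinate), graded 1–4 as the quartile of airway space
  occupied; grade g corresponds to up to 25·g % occupancy, so the scale is
  linear in occupancy.
* **DNS** (septal deviation), graded 0 (straight) to 3 (covering more than
  two-thirds of the cavity).
* **Polyps**, graded 0 (none visualized) to 4 (filling the entire cavity).

Five boolean questions condense these 16 grade slots:

1. **Q1 — bilateral polyps** (pre-decongestant): polyps on both sides
   indicate CRSwNP. Unilateral polypoid findings can be neoplastic, so they
   yield FALSE *and* a warning flagging the participant for exclusion
   review; they are never silently treated as CRSwNP.
2. **Q2 — decongestant response**: a fractional IT reduction
   (pre − post)/pre of at least 35% on **both** sides marks reversible
   (allergic) congestion. Because the IT scale is linear in occupancy,
   ratios of grades equal ratios of occupancy fractions. Rebound congestion
   (post > pre) counts as zero response.
3. **Q3 — septal asymmetry**, judged post-decongestant to minimize the
   nasal cycle's influence: an absolute left–right DNS difference of at
   least one grade.
4. **Q4/Q5 — bilateral valve obstruction**, pre- and post-decongestant: INV
   grade of at least 1 on both sides. The certainty grades 1/3 and 2/3 lie
   below the threshold: doubt is read as control-range.

The 32 possible question vectors map through a fixed table to subsets of
{AR, CRSsNP, CRSwNP, DNS}; the empty set is a control. The table's logic is
compact — CRSwNP iff Q1; DNS iff Q3; AR iff Q2 ∧ Q4; CRSsNP iff
¬Q1 ∧ Q4 ∧ (¬Q2 ∨ Q5) — but the implementation deliberately uses the
verbatim 32-row table (embedded in code and shipped as a checksummed CSV
asset), with the closed form kept only as an independent test oracle: the
table is the clinical artifact, and any future expert revision should edit
rows, not boolean algebra.

### Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `it_reduction_threshold` | 0.35 | minimum bilateral fractional IT reduction for Q2 |
| `inv_pathology_threshold` | 1 | minimum bilateral INV grade for Q4/Q5 |
| `dns_asymmetry_min_diff` | 1 grade | minimum post-decongestant L–R DNS difference for Q3 |
| `polyp_presence_min` | 1 | minimum polyp grade counted as presence |
| `polyp_timepoint` | `"pre"` | timepoint(s) at which Q1 looks for polyps |

All thresholds are ≥-comparisons with a 1e-9 tolerance, so
consensus-averaged grades (which can be fractional, e.g. 1.5 from a 2–2
tie, or thirds from INV averaging) compare predictably. Q1 defaults to the
pre-decongestant timepoint because decongestion does not remove polyps and
polyp assessment comes first in the workflow; `"pre_or_post"` is available
for sensitivity analyses. One grade is the smallest expressible septal
asymmetry, hence the Q3 default.

## Consensus aggregation

Multiple raters' gradings are combined per slot (4 scales × 2 sides × 2
timepoints) by a three-stage rule:

1. **mode** of the valid (non-"NV") grades, when a unique most-frequent
   value exists;
2. **arithmetic mean** of the valid grades when the mode is tied — with at
   most four raters a tie is the only way a mode can fail to exist;
3. **predefined default** when every rater marked the slot not visualized.

Means are *not* rounded back to the scale: the rounding direction would be
arbitrary, while threshold comparisons are well defined on fractions. The
shipped defaults (INV 0, IT 1 at both timepoints, DNS 0, polyp 0) are the
least-pathological values that trigger no question on their own — absence
of evidence must not assert pathology. They are fully configurable
(`consensus.defaults` in the YAML config) and every application is recorded
in the aggregation audit attached to the consensus exam. "Not visualized"
is a first-class marker throughout (CSV token `NV`, `NA` in R): an
unviewable structure is distinct from a clear view showing no pathology.

Visual diagnoses are aggregated separately: a condition is consensus-positive
when at least two specialists (`min_votes = 2`) independently named it.

## Accuracy evaluation

Each condition — and "Controls", treated as its own one-vs-rest label whose
positives are the participants with empty gold sets — yields a 2×2
confusion table against the gold standard. Sensitivity and specificity come
with Wilson score intervals by default; Clopper–Pearson is a switch. Wilson
was chosen as the default because it has near-nominal coverage at the small
stratum sizes typical of pilot cohorts (the suite verifies ≥ 93% empirical
coverage at n = 14, p = 0.7) without Clopper–Pearson's conservatism; since
the exact interval method used by any given external analysis may differ,
externally reported interval endpoints are not bit-reproduction targets.

Two methods (e.g. visual inspection vs. the rules engine) are compared
within a gold stratum by conditional logistic regression for 1:1 matched
pairs. For this design the conditional likelihood depends on discordant
pairs only and the maximum is available in closed form — log OR =
ln(n10/n01), SE = √(1/n10 + 1/n01), two-sided Wald p — so the package
implements the closed form and keeps a numeric maximizer of the conditional
likelihood (and `survival::clogit`) as test oracles. Identical predictions
within a stratum are reported as flag `"identical"` (no p-value), an empty
stratum as `"empty"`, and one-sided discordance as `"one_sided"` (infinite
log odds; the Wald p is undefined there and is left `NA` rather than
approximated). No continuity corrections are applied.

The power block uses the two-group comparison of proportions with a
Cohen-type effect size h: per-group n = ((z₁₋α/₂ + z_power)/h)², total
n = ⌈2 × per-group⌉, and achieved power Φ(h·√(n/2) − z₁₋α/₂). At h = 0.3
and α = 0.05 this gives 175 participants for 80% power and 43% achieved
power at n = 71; the model was selected precisely because it reproduces
both of these design anchors simultaneously.

## Inter-rater agreement

Krippendorff's alpha is computed from the coincidence matrix: units with at
least two valid ratings contribute ordered value pairs weighted by
1/(mᵤ − 1); alpha = 1 − D_obs/D_exp. The difference function is nominal
(0/1), interval (squared difference), or ordinal (squared
cumulative-coincidence-margin distance). Grades default to the ordinal
metric (they are ordered categories whose spacing is not interval-scaled);
per-condition diagnosis indicators use the nominal metric. When every
pairable rating is identical, expected disagreement is zero and alpha is
reported as 1 with a degenerate-data flag rather than 0/0.

Bootstrap CIs resample **units** (participants/observations) with
replacement — participants are the sampling units of the study design, and
raters form a fixed panel — with 1,000 iterations and a percentile
interval by default; degenerate resamples are skipped and counted. The
agreement bands are poor (α < 0.667), moderate (0.667 ≤ α < 0.800),
satisfactory (0.800 ≤ α < 1.000) and perfect (α = 1 within 1e-12). Band
definitions that list 0.667 as both a poor and a moderate boundary are
resolved here by assigning the boundary to moderate, making the bands a
partition; boundary values are measure-zero in practice.

## The synthetic cohort generator

Because no grading dataset is deposited with this design, the generator is
the package's test bed. For each participant it:

1. draws a gold diagnosis set from a prevalence table (default: the
   published 71-participant composition — 6 controls, 11 AR-only, 5
   CRSsNP-only, 9 CRSwNP-only, 16 DNS-only, and the six observed
   combinations);
2. picks uniformly among the decision-table rows mapping to that set
   (several rows can produce the same diagnosis; sampling rows exercises
   all of them) and samples grades realizing that row: bilateral polyps iff
   Q1, IT pre/post pairs above or below the 35% reduction on both sides,
   post-decongestant septal grades differing by ≥ 1 iff Q3 (septal grades
   are structural and identical pre/post), INV ≥ 1 bilaterally per Q4/Q5;
3. self-checks that the rules engine maps the truth exam back to the gold
   set — a failed check is a hard error, so generator and engine cannot
   drift apart silently;
4. derives each rater's exam by independent per-slot perturbation: with
   probability `noise` the grade moves one step up or down its scale
   (clipped at the bounds), and with probability `nv_rate` it becomes "NV".

Defaults are 71 participants, 4 raters, `noise = 0.1`, `nv_rate = 0.02`:
one mis-graded step per rater on roughly one slot in ten, which produces
the qualitative rater-disagreement structure reported for this kind of
panel (alphas well below 1 per rater, largely absorbed by 4-rater
consensus) while keeping zero-noise behaviour exactly recoverable. These
are documented stand-ins, not estimates: true per-condition grade
distributions are unpublished. The generator does **not** emulate the nasal
cycle, rater-specific bias or severity correlations between scales, so
passing recovery tests demonstrates the pipeline's correctness, not
clinical performance on real videos.

## Numerical choices and degenerate inputs

* Exact thirds (INV certainty grades) are compared with a 1e-9 tolerance
  everywhere; mode-counting keys on a 9-decimal rendering so averaged
  thirds group exactly.
* Zero-denominator accuracy strata are flagged undefined, never raised.
* `aggregate_grade` is permutation-invariant; ties go to the mean, not to
  an arbitrary element.
* Bootstrap and cohort generation seed the RNG locally and restore the
  caller's RNG state.
* Problem sizes in the test suite (200-participant zero-noise recovery,
  exhaustive alpha-oracle equivalence on all binary matrices up to
  4 units × 3 raters, 10,000-replicate Wilson coverage, 100 random
  discordant tables) were chosen to make each property check exhaustive or
  tightly concentrated while keeping the default suite fast.

## Limitations

* The decision table is a fixed expert consensus; the package validates its
  encoding, not its clinical truth.
* Sensitivity/specificity obtained on synthetic cohorts reflect the
  generator's assumptions and are not clinical estimates.
* The rules engine requires a resolved exam; it deliberately refuses to
  guess around missing grades outside the documented consensus/fallback
  path.
* Only the four grading scales are modelled — no symptom history, allergy
  testing or imaging, which the underlying clinical problem ultimately
  requires.
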