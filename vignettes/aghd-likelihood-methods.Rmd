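---
title: "Methods: rule-based AGHD likelihood stratification on claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based AGHD likelihood stratification on claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Adult growth hormone deficiency (AGHD) is a rare, underdiagnosed endocrine
disorder whose symptoms — altered body composition, fatigue, impaired mood
and concentration — overlap heavily with ordinary aging, and for which no
single reliable serum marker exists. Administrative claims databases see
essentially every insured adult, but carry no laboratory values and no
AGHD-specific diagnosis code. `aghdscreen` implements a computable
phenotype for this setting: a deterministic rule engine that stratifies
every eligible adult into a **high**, **moderate**, or **low** likelihood
of AGHD from nothing but dated diagnosis (ICD-9-CM/ICD-10-CM), procedure
(CPT), and pharmacy (ATC) claims. The intended users are
pharmacoepidemiologists and outcomes researchers who need a screening-scale
prioritisation — who warrants confirmatory GH testing — not a diagnosis.

## Cohort model

A person is a row of `(person_id, sex, birth_year, enroll_start,
enroll_end, death_date)`; an event is `(person_id, service_date, system,
code, kind)` with the kind/system pairing enforced (diagnoses are ICD,
procedures CPT, pharmacy ATC). All dates are whole days and intervals are
closed. Three deliberate modelling choices:

* **Year-granular age.** Claims extracts rarely carry full dates of birth,
  so age is `index_year − birth_year`, both for eligibility and for the
  per-event adult-age rules.
* **Enrollment is the denominator.** Eligibility at the index date
  (default 2017-12-31) requires age ≥ 18, at least 183 days of continuous
  enrollment up to the index date (computed on the enrollment span, never
  on claim dates), and survival past the index date. "Six months of data"
  is read as continuous enrollment; a total-claims-span reading is
  possible but non-standard for claims denominators.
* **Observation bounds** are `[enroll_start, min(enroll_end, index_date)]`
  even for persons with zero claims; the final 365 days of that interval
  anchor the comorbidity window.

Readers (`read_persons()`, `read_events()`) validate row by row: every
input row is either accepted or listed in a rejection report with its
first failed check — never silently dropped — and codes are normalized
(uppercase; dots/whitespace stripped for ICD) before storage.

## The rule engine

Five high-likelihood paths are evaluated in fixed precedence order:

1. **GROUP_A** — ≥ 1 diagnosis from a predefined list of structural or
   congenital conditions, at any age;
2. **GROUP_B** — ≥ 1 diagnosis from a second list of acquired insults,
   only if the service-year age is ≥ 18;
3. **PIT_DEF_3** — diagnoses on ≥ 3 distinct non-GH pituitary axes
   (thyroid, adrenal, gonadal, prolactin, posterior); repeated claims on
   one axis count once, and the GH axis never counts;
4. **GH_RX** — ≥ 1 adult GH prescription (ATC `H01AC`), provided no
   diagnosis from either exclusion list appears anywhere in the person's
   observation;
5. **HRT_3** — ≥ 3 distinct hormone-replacement classes (sex hormones,
   systemic glucocorticoids, thyroid preparations — counted as axis labels
   with the same machinery as rule 3), each filled at least once within a
   single calendar year at adult age, again subject to the exclusion veto.

A person satisfying none of these is **moderate** if they have ≥ 1
GHD-specific diagnostic test (IGF-I, GH serum, or a stimulation test) or
tests on ≥ 3 distinct non-GH axes — test *results* are unknown in claims,
only their occurrence is used — and **low** otherwise. The default
deficiency/test threshold is three axes, not two: the design's final
calibration raised it to improve specificity, and the engine exposes it as
`min_deficiency_axes` (a property test guarantees lowering it back to two
can only grow the high tier).

Three readings were genuinely open and are fixed as follows (each behind
an explicit argument where consequential):

* **Exclusion scope.** The exclusion lists veto only the two
  prescription paths (4 and 5); diagnosis-based paths ignore them. Both
  lists apply as a union, with no temporal relation to the prescription.
* **GH-veto bypass.** A person whose adult GH prescription was vetoed is
  assigned low *directly*, skipping the moderate tier — GH treatment as an
  adult categorically rules out "moderate" in this design. This is the
  single most consequential flowchart reading, so it is surfaced as
  `gh_veto_bypasses_moderate = TRUE`; an HRT-only veto does **not** bypass
  moderate, since the categorical statement concerns GH treatment alone.
* **"Within the same year"** means the same calendar year. A rolling
  365-day window is a plausible alternative; the config enum
  `replacement_window` reserves room for it, but only `calendar_year` is
  implemented.

Precedence affects only the *reported* reason (reporting follows the
group-A-first convention of the reason breakdown), never the tier: the
engine computes all eight person-level predicates set-wise and derives the
tier from them, so event order and duplication are irrelevant by
construction.

## Code lists

The genuine supplementary code lists behind each rule are not public. The
shipped `inst/extdata/codelists.yaml` therefore contains clearly versioned
(`synthetic-defaults-0.1`), deliberately approximate placeholder lists
assembled from uncontroversial terminology anchors (ATC `H01AC` for
somatropin; `G03`/`H02AB`/`H03AA` for the three replacement classes;
TSH/cortisol/FSH-type CPT codes for axis tests), and every report prints
the registry version so locally produced numbers are never mistaken for a
validated configuration. Matching semantics follow each terminology's
structure: hierarchical systems (ICD, ATC) default to positional prefix
matching, atomic CPT codes to exact matching. No test or acceptance check
depends on the clinical content of these lists — only on their structure.

One consequence worth flagging: the shipped comorbidity lists are pairwise
disjoint (breast cancer is its own list, not folded into the aggregate
malignancy list) so that the generator's per-list prevalences are
independently recoverable. Real phenotype definitions often nest these
categories; users supplying their own lists may nest freely.

## Cohort statistics

`tier_proportions()` divides living eligible persons per tier by the
cohort size; reason shares are within-tier. `age_sex_table()` cross-
tabulates sex and index-date age bands (18–30, then decades to 80+), with
every cell a percentage of the *whole* cohort, so tier columns sum
row-wise to the cohort column and the table totals 100.
`comorbidity_incidence()` flags each person once per comorbidity if any
matching diagnosis falls in the last 365 days of their observation
(`[last_date − 364, last_date]`). `diagnostic_test_usage()` reports, for
the high and moderate tiers only, the fraction of persons with each
labelled GHD test anywhere in observation.

Between-tier contrasts use the standard pooled standardized difference for
a binary covariate,

$$d = \frac{p_2 - p_1}{\sqrt{(p_1(1-p_1) + p_2(1-p_2))/2}},$$

with the higher-burden group passed first so elevated burden yields
negative values, `d = 0` exactly when `p1 = p2` (including the degenerate
all-zero/all-one cases), and the conventional `|d| ≤ 0.1` negligibility
flag attached to every emitted pair. The formula choice is documented
rather than assumed universal: published claims analyses do not always
state their variant, and pooled-form values computed from printed
percentages can differ substantially from published effect sizes computed
on the underlying microdata. Display rounding is one decimal for
percentages and two for standardized differences; files keep full
precision otherwise.

## The synthetic generator

`generate_cohort()` makes the whole pipeline testable without access to
any proprietary database. Its design separates logical from statistical
content:

* **Tier membership is planted constructively.** Archetype counts come
  from largest-remainder apportionment of the weights (no sampling), and
  each person receives the exact defining events of their archetype:
  `A_CONDITION` (one group-A diagnosis), `PANHYPOPIT` (three deficiency
  axes), `GH_TREATED_ADULT` (one adult GH fill), `GH_TREATED_EXCLUDED`
  (GH fill plus an exclusion diagnosis — planted to land low via the
  bypass), `TEST_ONLY_MODERATE` (three axis tests, with a fixed 2.2%
  sub-share receiving an IGF-I test instead, so both moderate reasons are
  exercised), `HEALTHY_LOW` (no defining events). A correct classifier
  therefore recovers the truth file with exactly zero error, and the
  recovery test is sharp.
* **Comorbidity flags are sampled** (Bernoulli at per-tier prevalences,
  placed uniformly in the last observation year), because they feed
  statistical recovery checks, not logical ones.

Default conditions emulate a large private-claims cohort: tier weights
0.5% / 6% / 93.5%; female shares 59.3% / 71.6% / 50.4% by tier; age-band
distributions skewing older in the high and moderate tiers (peaks near
60–70 and 50–60) and younger in the low tier; comorbidity prevalence maps
at claims-typical levels (e.g. hyperlipidemia 32.6% / 28.8% / 14.6% across
tiers, breast malignancy 8.8% / 1.3% / 0.5%). Reproducibility uses one RNG
stream per person, with per-person seeds drawn once from a master stream
derived from the run seed — identical `(config, seed)` pairs yield
byte-identical files, and person `i`'s data do not depend on how many
events person `i − 1` produced.

What the generator does **not** emulate: enrollment gaps, claim reversals
or realistic duplicate billing, ICD-9→10 era drift, code-list version
churn, and any correlation between comorbidities (flags are independent
per list, which is why the shipped lists are disjoint). Passing the
recovery tests therefore demonstrates the *engine* is faithful to the
rules and the *statistics* are unbiased estimators on clean data — not
that the shipped code lists would identify true AGHD in production data.

A second generator, `random_claims_cohort()`, is a pure fuzzer: arbitrary
ages (including minors), early disenrollment and pre-index deaths, and
Poisson numbers of events drawn uniformly from the pooled code-list
entries. It exists to stress invariants (partition of the eligible cohort,
the adult-GH-never-moderate rule, threshold monotonicity), not to look
like real data.

## Numerical and scale choices

Exhaustive engine verification runs all 2⁸ predicate combinations through
`make_minimal_person()` against an independently written flowchart oracle.
Routine suite sizes are chosen to keep the default test run fast while
leaving estimates sharp: planted recovery at n = 10,000 (a 0.5% high tier
still yields 50 high-tier persons), fuzz properties over 200 cohorts of
30, and statistical recovery at 2,000 persons per tier over 20 seeds
against 3σ binomial bands (≈ 0.3 percentage points at a 30% prevalence,
≈ 0.5 at 0.5%). Proportion identities are asserted to 1e−12; the
standardized-difference brute-force comparison to 1e−12; equal proportions
return exactly zero by construction, not by tolerance.

## Known limitations

* The shipped code lists are structural placeholders; all substantive use
  requires site-curated lists (and re-validation of the disjointness
  assumption if the comorbidity tables are compared against planted
  prevalences).
* Age is year-granular; persons become "adult" on January 1 of their
  18th-birthday year.
* No NDC→ATC mapping: pharmacy events must arrive ATC-coded.
* The engine is deterministic and rule-based by design — no probabilistic
  scoring, no test-result interpretation, no date-sequencing logic beyond
  the adult-age and calendar-year rules.
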