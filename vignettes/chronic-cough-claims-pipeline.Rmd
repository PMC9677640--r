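---
title: "Identifying chronic cough in monthly-granularity claims: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying chronic cough in monthly-granularity claims: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coughcohort)
```

## The problem

Chronic cough — a cough persisting more than eight weeks — has no dedicated
ICD-10 code, so a claims-database cohort cannot be defined by a single code
lookup. Two features of Japanese claims shape the algorithm this package
implements. First, every diagnosis carries, besides its ICD-10 code, a
*standard disease name* in the Japanese vernacular that is often more
specific than the code: the single code R05 ("cough") splits into chronic
cough, dry cough, atopic cough, post-infectious cough and more. Second,
outpatient diagnoses are consolidated **monthly**: the day of a consultation
is unknown, while prescription fills are day-stamped. Any duration criterion
must therefore be expressed in months, and any duration inferred from
diagnosis codes is conservative.

## The phenotype

The package identifies two mutually exclusive populations over a
26-month selection period (defaults 2017-07 through 2019-08):

* **Population 1** — at least one claim whose (ICD-10, standard name) pair
  is (R05, chronic cough). The index month is the first selection-period
  month carrying it: the month the chronic-cough diagnosis was first
  established.
* **Population 2** — patients whose chronic cough is coded under other cough
  types. The temporal criterion requires cough codes in at least two
  *distinct* months within a three-consecutive-month evaluation window,
  followed by at least one further cough code in the following three months.
  Because months are the finest resolution available, this "two months plus
  a third visit after the window" pattern is the shortest monthly pattern
  that guarantees a span exceeding eight weeks; it is deliberately specific
  rather than sensitive. The index month is the earliest post-window month
  with a cough code and must itself fall in the selection period (so the
  6-month pre-index and 12-month post-index windows stay inside the study
  period, which runs from 6 months before the selection period to 12 months
  after it).

Candidate evaluation windows are enumerated from the study start onwards,
not only from the selection start: the first cough diagnosis may legitimately
precede the index month by up to six months. Among the windows that qualify,
the earliest wins ("first established" semantics). Two design points deserve
a note:

* **Window start normalisation.** The window enumeration considers every
  3-month span, so a qualifying span may begin in a month with no cough
  claim. The reported `window_start` is normalised to the first cough-coded
  month inside the qualifying span. This is provably inconsequential for the
  index month and for subgroup assignment (months between the raw start and
  the first cough month contain, by construction, no cough codes), and it
  makes `window_start` mean what the subtype definition needs: *the first
  diagnosis of cough*. Enumerating all spans rather than only cough-anchored
  spans matters: a pattern with cough codes in three consecutive months
  qualifies only when the evaluation window is allowed to begin one month
  before the first code.
* **Subgroup bound.** Population 2 members receive every cough category
  coded between the first cough diagnosis of the qualifying window and the
  index month, inclusive; subgroups are therefore not mutually exclusive.
  An alternative reading extends the bound to the end of the post-evaluation
  window; `assign_subgroups(..., subgroup_end = "post_window")` implements
  it, but the default follows the narrower bound and the package makes no
  fidelity claim for the alternative.

Anyone eligible for both populations is assigned to Population 1, making the
populations mutually exclusive by construction.

### Eligibility screening

At a candidate index month the following exclusions apply, in the spirit of
an incident-user design:

* **Age < 20 years.** Only year-month of birth exists, so age is the floor
  of completed years between birth month and index month.
* **ACE-inhibitor use** (ATC class C9A or C9B) at any time in the study
  period — ACE inhibitors cause drug-induced cough, and a washout cannot be
  verified at month granularity, so any use excludes.
* **Organic respiratory disease or cancer** coded at any time in the study
  period.
* **Insufficient history**: the first-ever claim (diagnosis or prescription)
  must be at least six months before the index. Enrolment spells are not
  recorded in this kind of database — a beneficiary who leaves simply stops
  producing claims — so presence-by-claims is the only available proxy for
  database history.
* **No post-index claim**: at least one claim of any kind in months
  index+1 .. index+12 is required, the analogous proxy for staying enrolled
  through the follow-up window.

The participant flow records, in order: beneficiaries with any claim; adults
(age ≥ 20 by the selection-period end, the one step where no index month
exists yet) with a selection-period claim; of whom with any cough code; of
whom meeting the temporal phenotype and the age rule; excluded by the
remaining screens; enrolled.

## Analysis windows and denominators

All month intervals are closed on both ends. Three diagnosis windows are
extracted relative to each member's index month *m*: the index month
itself; the pre-index period \[*m*−6, *m*\] (six months **including** the
index month); and Months 10–12, \[*m*+10, *m*+12\]. Counting is always
participant-level — a member counts once per category per window regardless
of claim multiplicity — and categories are not mutually exclusive.

Denominators follow the study's reporting conventions: index-month and
pre-index percentages use the enrolled population; Months 10–12 percentages
use the members *evaluable* there, i.e. those with at least one diagnosis
claim in the window carrying a cough code or a cough-related disease code.
A prescription alone does not make a member evaluable. The three-month width
of the Months 10–12 window is the minimum needed to capture disease-specific
claims reliably in monthly claims.

The persistence partition classifies each evaluable member by priority:
original cohort-defining category present → *retained*; otherwise any other
cough category → *other cough*; otherwise (guaranteed by evaluability) a
cough-related disease code only. Enrolled members not evaluable have *left
the cohort*. The four counts partition the enrolled population exactly — an
identity asserted on every input in the test suite. Note the printed
category tables are non-exclusive while the partition is exclusive by
priority; both views are produced and labelled distinctly.

### Medication windows

Prescriptions are day-stamped, so drug utilisation uses day windows. For the
index month the whole calendar month is used: the index day within the month
is unknown, and "prescribed during the index month" is a month-scoped
statement. For post-index time points k ∈ {1, 2, 3, 6, 9, 12} the window is
four weeks — two weeks either side of an anchor. The anchor day is taken as
the 15th of calendar month *m*+k: the source data record no index day, so
the window is centred on the month. This convention is a declared
approximation; the boundary tests assert exactly the behaviour it implies
(shifting all prescriptions by one day never changes index-month results but
can move a prescription across a ±14-day boundary).

Within a window, a medication class is "with central antitussives" when a
central antitussive also falls in the same window; *antitussive alone*
means the window contains central antitussives and nothing else of interest.
Members on an ICS/LABA combination are not additionally counted under other
bronchodilators. The any-medication denominator counts members with at
least one prescription among the ten classes of interest — ACE inhibitors
are not "of interest" because their users were excluded upstream. For every
class and window, with + without = total, asserted as an invariant.

## Codebooks

Three lookup structures are configuration, not code: the cough codebook
(exact (ICD-10, standard name) pairs → six cough categories; the bundled
default is the published 17-row table, with standard names carried as
romanised opaque keys and matched exactly); the cough-related disease
codebook (ICD-10 prefix → ten disease labels plus two exclusion labels);
and the medication codebook (ATC prefix → eleven classes, where C9A/C9B →
ACE inhibitor is fixed by the phenotype definition and validated at load).
The bundled disease and medication codebooks are **synthetic stand-ins**
built on plausible ICD-10 chapters (J30\* → allergic rhinitis/nasal
inflammation, K21\* → GERD, …) and representative ATC leaves (R05D\* →
central antitussives, …), because the exact production code lists are not
public. Analyses of real data must supply site-specific codebooks; all
results in this package's tests and scripts are internally consistent under
the bundled stand-ins but are not field-comparable disease frequencies.

## The synthetic generator

`simulate_claims()` emulates the *structure* the analysis assumes, with
defaults chosen to mirror the source database's reported characteristics:

| parameter | default | rationale |
|---|---|---|
| `female_fraction` | 0.618 | reported share of women |
| `age_mean` / `age_sd` | 43.7 / 12.2 y | reported age distribution (employee insurance, under 75; truncated 1–74) |
| `annual_attrition` | 0.14 | the database provider's estimate that ~14% of beneficiaries leave within a year |
| `monthly_consult_prob` | 0.12 | a plausible adult monthly consultation rate; scales claim density |
| `cough_category_rates` | chronic 0.015, CVA 0.02, other 0.03, … | per-consultation rates ordered so the emergent subgroup mix (other > CVA > atopic) matches the reported ordering |
| `disease_rates` | ARNI 0.50, asthma 0.35, GERD 0.15, … | per-beneficiary prevalences in the range of the reported index-month proportions |
| `facility_probs` | 0.699 / 0.087 / 0.214 | reported facility-size mix |

Dropout is geometric with monthly leave probability 1 − (1 − a)^(1/12), so
the chance of leaving within any 12 active months is exactly the configured
annual rate; the calibration test recovers it from 20,000 beneficiaries
within binomial bounds. Prescriptions are drawn per consult month
conditional on a trigger (a same-month cough claim, or a held linked
disease) and placed on uniformly random days 1–28, so the day-window logic
is genuinely exercised.

Planted members carry exactly qualifying patterns: Population 1 a chronic
code at a random selection-period index; Population 2 cough codes in months
s, s+1 and s+3 (the minimal qualifying pattern) with categories drawn from
the Population 2 mix; both get a history claim at index−6, a post-index
claim, an adult age, full-span enrolment and no exclusion codes, and planted
Population 2 members never receive a chronic code. On noise-free data
(all background rates zero) the engine must recover them exactly —
sensitivity and specificity 1.0, with matching indices and subgroup sets.
With background noise, recovery may legitimately fall short: a random
chronic claim can pull a planted index before the member's history window,
and the washout excludes them.

What the generator does **not** emulate: physician coding behaviour,
seasonal epidemics, correlated comorbidity structure, staggered enrolment
entry (everyone enters at the study start), or realistic code-list breadth
(one representative code per disease/class). Passing tests therefore show
the pipeline's logic is correct under the stated structural assumptions —
not that its outputs estimate real-world frequencies.

## Numerical and degenerate-input choices

* Year-months are integers (months since year 0), making window arithmetic
  exact; all intervals closed.
* Percentages round **half-up** to one decimal (4.05 → 4.1), the convention
  under which every recomputable published percentage reproduces; an epsilon
  of 1e-9 guards binary representation of exact halves. A zero denominator
  yields `NA`, never an error.
* Facility size at index is the mode over index-month diagnosis claims,
  ties broken toward the larger category, none → "unknown" (the
  characteristics table reports a reduced denominator for this variable).
* Empty bundles, header-only files, zero-member populations and zero planted
  counts all flow through and produce empty—but structurally valid—outputs.
* Window search early-terminates once a window's candidate index passes the
  selection end: the candidate index is non-decreasing in the window start.

## Validation strategy and problem sizes

The test suite validates the engine against an independently coded
brute-force oracle — per-beneficiary loops, its own codebook lookups,
explicit enumeration of every candidate window — on 500 random bundles of
up to 200 beneficiaries over 36 months, plus targeted boundary fixtures
(overlap of the two definitions, ACE exclusion, age 19 at index,
two-months' history, no post-index claim, window-edge prescriptions).
Planted recovery runs at 1,000 beneficiaries noise-free; partition and
row-sum identities are asserted across populations and windows on simulated
data of 2,500 beneficiaries; generator calibration at 20,000. The analysis
scripts run at 20,000 beneficiaries. These sizes were chosen to exercise
every code path at comfortable statistical resolution while keeping a full
run in seconds.

## Known limitations

* The phenotype is specific rather than sensitive by construction; patients
  whose cough is coded only through an underlying disease, or who consult
  infrequently, are not captured — a property of the algorithm, shared by
  its application to real data.
* History and follow-up are proxied by claims presence, so a claim-free
  enrolled beneficiary is indistinguishable from one who left.
* The 15th-of-month anchor for post-index drug windows is a convention; any
  fixed anchor day shifts window contents by at most two weeks.
* The bundled disease/medication codebooks are stand-ins (above); real-data
  use requires site-specific lists.
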