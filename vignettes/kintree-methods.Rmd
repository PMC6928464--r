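---
title: "Methods: kinship coding, roster linkage and family-history analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinship coding, roster linkage and family-history analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kintree)
```

This vignette documents the models and design choices behind `kintree`:
the family-code algebra, the pedigree model, edge inference from
household/insurance rosters, the fourth-degree expansion, the synthetic
population, and the family-history analysis. It also states what the
synthetic data do and do not emulate, and hence what a passing test suite
does and does not show about real administrative data.

## The code algebra

A family code is a sequence of three-character atoms from the subject's
self atom (`0IM`/`0IW`) toward the kin. The valid (degree, relation)
pairs are `0I` self, `0O` spouse, `1A` parent, `1D` child, `2A`/`2D`/`2U`
older/younger/undifferentiated sibling, and `1a`/`1d` step parent/child;
the third character is M/W/X. Conventions the format itself does not fix,
which we chose once and use throughout:

* **Direction.** `FMLY_CD` reads subject → family member. The self atom
  anchors the subject, so `0IM1AM` is "my (a man's) father".
* **Intermediate genders.** The gender letter of atom *i* is the sex of
  the person reached after step *i*, with `X` for unknown. This makes
  inversion well-defined: inverting reverses the tail, swaps A↔D (and
  a↔d, 2A↔2D), and reassigns the gender letters along the reversed chain.
* **Degrees.** Parent/child steps count one degree of kinship, sibling
  steps two, spouse steps zero; step relations count like their blood
  analogues (the format lists them as first degree), with stepness kept
  as metadata. The degree of a code is the sum over its tail, so a
  spouse's father (`0IM0OW1AM`) is first degree.

**Reduction** contracts adjacent atom pairs that do not name a
determinate person when identities are unknown: parent-then-child is
self-or-sibling, child-then-parent is self-or-co-parent,
spouse-then-spouse collapses to self only under monogamy (which we do
not assume, so the result stays flagged), sibling-then-sibling is
self-or-sibling. A self-collapse alternative is kept only when
*realizable* — the sexes of the persons being identified must be
compatible: a man's mother's daughter can only be his sister, while his
mother's son is ambiguously himself or a brother. The child-then-parent
contraction is always flagged ambiguous even when a single alternative
survives, because the spouse atom it produces is only a stand-in:
co-parents need not be married. Reduction is identity-*blind* by design;
identity-*aware* disambiguation happens in the expansion, where person
ids are known.

`classify_family_type()` maps a reduced code to the family-type list
C1/C2 (blood, close/non-close), A0 (spouse), A1/A2 (affinity,
close/non-close), R1 (adoptive). "Close" is degree ≤ `close_threshold`,
default 2 — the underlying variable list does not define the boundary,
so it is a configuration knob. `A3` (old-law affinity) has no computable
semantics and is accepted on input but never produced.

## Pedigree and paths

The pedigree stores persons, typed parent edges (biological, step,
adoptive; at most two biological parents, acyclic, parent born before
child when both years are known) and unordered spouse edges. Sibling
relations are never stored: they are derived from shared biological
parents, which keeps one source of truth; half-siblings get the same
sibling atoms and degree 2 as full siblings because the code set has no
half-sibling atom.

Kinship paths are simple paths over parent/child steps (one degree) and
spouse steps (zero degrees), with two structural exclusions:

* no parent step immediately after a child step — "my child's other
  parent" is a co-parent, not kin along that path; when co-parents are
  married, the spouse edge carries the relationship at degree 0;
* no two consecutive spouse steps — a spouse's spouse is never
  determinate.

By default a path carries at most one spouse step
(`max_spouse_edges = 1`), keeping "relatives by affinity" first-order
(a spouse's blood kin, or a blood kin's spouse), which matches the
A1/A2 semantics. The limit is configurable: with two spouse steps the
expansion also covers pairs like a spouse's sibling's spouse, and that
is the configuration under which the expansion is provably *complete*
against the brute-force path oracle (which knows nothing about affinity
conventions and simply minimizes path weight). The oracle itself,
`kinship_distance_oracle()`, is an intentionally naive exhaustive
simple-path search kept fully independent of the production code.

`path_to_code()` renders a path as a code, contracting each
up-then-down pivot through a shared parent into a sibling atom ordered
by the two siblings' birth years (earlier-born kin → `2A`, later →
`2D`, ties or unknown → `2U`). By construction the emitted codes contain
no contractible pairs, so their degree is always well-defined and equals
the path weight. One canonical record per directed pair is selected by
the deterministic key (degree, spouse steps, step bonds, code string);
the reverse record is generated from the reversed path, which guarantees
that the output is closed under inversion with degree preserved. Records
are sorted by subject and family id, making rebuilds byte-identical.

Persons of unknown sex cannot head a family code (self atoms are
gendered) and are skipped as subjects.

## Roster linkage

The source data are yearly unit rosters — resident-register households
and health-insurance units — with exactly one head per unit-year and
each member coded head → member. Inference proceeds from evidence that
accumulates across years and sources (it never removes an edge):

* single-atom relations of degree ≤ 1 (`1A/1a/1D/1d/0O`) become direct
  edges;
* the head's spouse is linked to each of the head's children — as a
  biological parent when the spouse's age at the child's birth falls in
  a plausible window (default 15–70 years), as a step parent otherwise;
* in three-generation rosters, a member coded through a child of the
  head (`0IM1DM1DM` son's son, `0IM1DM0OW` son's wife) is linked to that
  child only when exactly one co-resident child of the head matches the
  intermediate atom; with several matching children the relation is
  genuinely non-determinable from the roster and is left out.

When the two sources disagree on a pair, the resident register wins (it
is the civil record; the source system documents no adjudication rule)
and the disagreement is logged with both variants. Malformed rows and
unit-years without exactly one head are rejected per row, never fatally.
`HHRR_CD` is computed independently of edge inference: 1 if the pair
ever co-occurred in both a register household and an insurance unit,
2 register only, 3 insurance only.

## Synthetic population

The generator's defaults are the study conditions, not tuning dials.
Founder couples (birth years 1938–1952 by default) marry at age 24–32
and bear Poisson(2.2) children; children of non-final generations marry
with probability 0.8, spouses marry in without recorded parents;
children are only born to married couples. Death ages are Normal(78, 10)
truncated at 30, which produces people who died before the record
systems started. Rosters are emitted yearly: a couple forms its own
household at marriage — except with probability 0.3 the newlyweds spend
their first 5 years in the groom's parents' household, creating
three-generation rosters with multi-atom relation codes and giving
grandchild–grandparent pairs shared household history; unmarried persons
split off at age 30. The insurance unit mirrors the household; what
differs is observability: eligibility data start in 2002 and register
data in 2004, rows before a source's start year survive only with
probability `record_coverage_before_start` (default 0), and a person who
died before a source's start never appears in it. This is the mechanism
that makes parent matching rates rise from old to young birth cohorts,
and reach ~100% when the start years are moved before all births.

Disease is a per-person Bernoulli draw: age-group base prevalence
(increasing ramps per disease, e.g. hypertension reaching 42% at 85+)
multiplied by a parental relative risk (default 2) when at least one
biological parent is affected, capped at 1, drawn in generation order.
Affected persons emit claims rows satisfying the corresponding case
definition — code ranges I10-I15 and E10-E14 with medication for
hypertension and diabetes, admissions with I20-I25 and I60-I69 for
ischemic heart disease and cerebrovascular disease, admissions with a
primary diagnosis in C00-C97 for cancer; decoy rows carry in-range codes
but fail the flags. ICD codes are sampled uniformly within each range:
only range membership matters downstream.

**What the synthetic data do not emulate:** migration, divorce and
remarriage chains (remarriage exists only behind a flag), adoption,
twins' household dynamics, non-marital fertility, misrecorded relation
codes, and any realistic disease model beyond the single parental-RR
multiplier. Passing tests therefore demonstrate that the *machinery* —
coding, inference, expansion, standardization — is correct under the
stated population model, not that real matching rates or prevalences
are reproduced; the published real-population tables require the actual
national database and are out of scope.

## Family-history analysis

Age is reckoned as `reference_year − birth_year` (completed-year
convention; the source material does not state one). A person is a case
if any claims row in or before the reference year satisfies the
definition. Family-history strata are defined by kin filters over the
records; the father-side/mother-side presets select codes whose first
step is `1AM`/`1AW` respectively — side-specific results are published
without a formal selector, so the filter is user-configurable and both
"parents only" and "whole side" predicates ship as presets. Overlapping
strata are allowed (both parents affected puts a person in both sides).

Direct standardization weights the five-year-age-group prevalences by a
standard population; `standard_from_population()` uses a population's
own age mix (the analogue of standardizing to the entire insured
population). The standardized rate equals the crude rate exactly when
the weights equal the study population's own age distribution — with
equal-sized groups, uniform weights are that distribution. Age groups
with standard weight but no observations contribute zero and are counted
in `empty_groups`; empty strata are reported as `NA`, never invented.
The delta-method standard error
`sqrt(sum(w_g^2 p_g (1 - p_g) / n_g))` accompanies every estimate; no
hypothesis tests are performed.

For relative-risk recovery, the analysis population is restricted to
persons with at least one parent record: founders and married-in spouses
have no observable parents, occupy different age groups, and would
otherwise make the history and no-history strata age-incomparable. With
that restriction the ratio of standardized prevalences is an unbiased
estimate of the simulated parental RR, and at roughly 50,000 persons per
replicate (11,500 founder couples, two generations) its delta-method SE
is about 0.05, so recovery is tested within three standard errors.

## Numerical and scale choices

Problem sizes used by the tests and the acceptance script: the
oracle-equivalence check uses 100 random pedigrees of at most 40 persons
(two founder couples, three generations) — small enough for the
brute-force oracle to enumerate all simple paths exhaustively; the
matching-rate analysis uses 150 founder couples over four generations
(≈2,500–3,000 persons) with founder births spread over 1935–1955 so the
birth cohorts span the record-start years; RR recovery uses ten
replicates of ≈50,000 persons. Reductions and expansions are exact
integer computations; the only tolerances are 1e-12 on the
standardization identity and 3 sampling SEs on stochastic recoveries.

## Known limitations

* Relationships outside the atom set (godparents, foster care beyond
  R1) are not representable.
* Under record truncation, a child observed *only* as a grandchild in a
  three-generation roster with several co-resident married sons cannot
  be linked to a parent — the roster genuinely does not determine the
  pivot. This is why full-observation matching can fall marginally short
  of 100% in rare configurations; the same limitation applies to the
  real source data.
* Affinal paths are first-order by default; deeper in-law chains
  (`max_spouse_edges > 1`) are supported but not part of the default
  family-type semantics.
* The expansion is a full rebuild; there is no incremental update path.
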