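# kintree

Administrative health databases usually record family relations only as
"relationship to the head of household", which loses the relationships
among the other members and across households. `kintree` implements the
method behind national family-tree databases built from such rosters:
a compositional **family-code algebra** for interpersonal kinship, pedigree
reconstruction by comparing and complementing two roster sources (resident
register households and health-insurance units), exhaustive expansion of
all kin pairs up to the **fourth degree of kinship**, and the downstream
epidemiology: claims-based case definitions, family-history strata and
directly age-standardized prevalence.

It is aimed at researchers who work with (or emulate) national
health-information data and need interpersonal kinship rather than
head-of-household codes. Since real national data cannot be shipped, the
package includes a first-class synthetic-population generator that
reproduces the structural features that matter: multi-generation
households, source-specific record start years (eligibility 2002,
register 2004) that leave older cohorts under-documented, and familially
aggregated disease.

## The family code

A relationship is a string of three-character atoms read from the subject
toward the kin. The first character is the degree of kinship (chon)
contributed by the step, the second the relation (I self, O spouse,
A parent, D child, A/D/U older/younger/undifferentiated sibling in degree
2, lowercase a/d step relations), the third the sex of the person reached
(M/W/X). Every code starts with the subject's self atom `0IM` or `0IW`:

* `0IM1AM` — a man's father; degree 1.
* `0IM1AM1AW` — father's mother, i.e. the paternal grandmother; degree 2.
* `0IM0OW` — wife; spouse steps add zero degrees.

The algebra supplies, for any code: its **degree** (sum of the tail degree
digits), its **inverse** (the relationship read from the other end), the
**composition** of two codes through a shared person, and an
identity-blind **reduction** that contracts patterns like parent-then-child
into self-or-sibling, returning *all realizable alternatives* with an
ambiguity flag instead of guessing — the same non-determinable codes that
occur when extended relationships are derived from head-of-household data
alone.

## Worked example

```r
library(kintree)

g <- pedigree(data.frame(
  person_id  = c("GF", "GM", "F", "M", "C"),
  sex        = c("M", "W", "M", "W", "M"),
  birth_year = c(1920L, 1922L, 1950L, 1952L, 1980L)))
g <- add_parent_edge(g, "GF", "F"); g <- add_parent_edge(g, "GM", "F")
g <- add_parent_edge(g, "F", "C");  g <- add_parent_edge(g, "M", "C")
g <- add_spouse_edge(g, "GF", "GM"); g <- add_spouse_edge(g, "F", "M")

records <- expand_all(g)
records[records$TG_ID == "C", c("FMLY_ID", "FMLY_CD", "FMLY_DGR", "FMLY_TYPE")]
#>   FMLY_ID   FMLY_CD FMLY_DGR FMLY_TYPE
#> 1       F    0IM1AM        1        C1
#> 2      GF 0IM1AM1AM        2        C1
#> 3      GM 0IM1AM1AW        2        C1
#> 4       M    0IM1AW        1        C1
```

Subject `C` has four kin: father, mother (degree 1), and the paternal
grandparents (degree 2), all close blood relatives (`C1`). The algebra
works on the codes directly:

```r
degree_of("0IM1AM1AW")
#> [1] 2
format_code(invert_code("0IM1AM1AW", subject_sex = "M", family_sex = "W"))
#> [1] "0IW1DM1DM"      # the grandmother sees C as her son's son
compose_codes("0IM1AM", "0IM1DX")   # my father's child
#> <reduction_result> 0IM (ambiguous)
#>   alternatives: 0IM, 0IM2UX       # myself, or a sibling
```

The full pipeline — simulate a population, emit yearly rosters from both
sources, reconstruct the pedigree, expand, and report — is also available
from the shell:

```sh
Rscript inst/cli/kintree.R simulate --seed 1 --out-dir work
Rscript inst/cli/kintree.R link --snapshots work/snapshots.csv \
    --persons work/persons.csv --out-prefix work/linked
Rscript inst/cli/kintree.R expand --persons work/linked_persons.csv \
    --edges work/linked_edges.csv --snapshots work/snapshots.csv \
    --out work/famtree.csv
Rscript inst/cli/kintree.R report --records work/famtree.csv \
    --persons work/persons.csv --out-prefix work/rep
```

Family-tree records use the standard column layout
`TG_ID, FMLY_ID, TG_SEX_TYPE, TG_BYEAR, FMLY_SEX_TYPE, FMLY_BYEAR,
FMLY_CD, FMLY_DGR, FMLY_TYPE, HHRR_CD`, where `FMLY_TYPE` distinguishes
close/non-close blood relatives (C1/C2), spouse (A0), relatives by
affinity (A1/A2), and adoptive relations (R1), and `HHRR_CD` encodes
whether the pair ever shared a household and/or an insurance unit.

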