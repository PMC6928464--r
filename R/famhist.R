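# Family-history analysis ------------------------------------------------------
#
# Case definitions over claims rows (code range plus required medication /
# admission / primary-diagnosis flags), family-history strata driven by the
# family-tree records, direct age standardization by five-year age groups,
# and the two standard reports: parent/grandparent matching rates by birth
# cohort and kin counts by degree and family type.

#' Claims-based case definition
#'
#' @param disease disease name.
#' @param code_range length-2 character, inclusive ICD-10 range on the
#'   letter-plus-two-digit category (e.g. `c("I10", "I15")`).
#' @param requires_medication,requires_admission,primary_dx_only logical
#'   flags a qualifying claims row must satisfy.
#' @return an object of class `case_definition`.
#' @export
case_definition <- function(disease, code_range, requires_medication = FALSE,
                            requires_admission = FALSE, primary_dx_only = FALSE) {
  stopifnot(length(code_range) == 2L,
            substr(code_range[1L], 1L, 1L) == substr(code_range[2L], 1L, 1L))
  structure(list(disease = disease, code_range = code_range,
                 requires_medication = requires_medication,
                 requires_admission = requires_admission,
                 primary_dx_only = primary_dx_only),
            class = "case_definition")
}

#' The five standard case definitions
#'
#' Hypertension (I10-I15) and diabetes (E10-E14) require an in-range
#' diagnosis code together with prescription medication; ischemic heart
#' disease (I20-I25) and cerebrovascular disease (I60-I69) require a
#' hospital admission with an in-range code; cancer (C00-C97) requires an
#' admission with an in-range primary diagnosis.
#'
#' @return named list of [case_definition()]s.
#' @export
default_case_definitions <- function() {
  list(
    hypertension = case_definition("hypertension", c("I10", "I15"),
                                   requires_medication = TRUE),
    diabetes = case_definition("diabetes", c("E10", "E14"),
                               requires_medication = TRUE),
    ischemic_heart_disease = case_definition("ischemic_heart_disease",
                                             c("I20", "I25"),
                                             requires_admission = TRUE),
    cerebrovascular_disease = case_definition("cerebrovascular_disease",
                                              c("I60", "I69"),
                                              requires_admission = TRUE),
    cancer = case_definition("cancer", c("C00", "C97"),
                             requires_admission = TRUE, primary_dx_only = TRUE)
  )
}

# letter + 2-digit category of an ICD-10 code string, NA when unparseable
.icd_category <- function(code) {
  ok <- grepl("^[A-Z][0-9]{2}", code)
  ifelse(ok, substr(code, 1L, 3L), NA_character_)
}

#' Apply case definitions to claims
#'
#' A person is a case for a disease iff at least one claims row in or before
#' `reference_year` carries a code in the definition's range and satisfies
#' all its required flags.  Rows with unparseable ICD-10 codes are skipped
#' and counted in the `skipped_rows` attribute.
#'
#' @param claims data.frame with columns
#'   `person_id,year,icd10,admission,medication,primary_dx`.
#' @param definitions list of [case_definition()]s (default the standard
#'   five).
#' @param reference_year last claims year considered (default 2017).
#' @return data.frame with `person_id` and one logical column per disease;
#'   attribute `skipped_rows` counts unparseable rows.
#' @export
apply_case_definitions <- function(claims, definitions = default_case_definitions(),
                                   reference_year = 2017L) {
  cat3 <- .icd_category(claims$icd10)
  skipped <- sum(is.na(cat3) & !is.na(claims$icd10))
  ok <- !is.na(cat3) & claims$year <= reference_year
  letter <- substr(cat3, 1L, 1L)
  num <- suppressWarnings(as.integer(substr(cat3, 2L, 3L)))
  persons <- sort(unique(as.character(claims$person_id)))
  out <- data.frame(person_id = persons, stringsAsFactors = FALSE)
  for (def in definitions) {
    lo <- as.integer(substr(def$code_range[1L], 2L, 3L))
    hi <- as.integer(substr(def$code_range[2L], 2L, 3L))
    hit <- ok & letter == substr(def$code_range[1L], 1L, 1L) &
      num >= lo & num <= hi
    if (def$requires_medication) hit <- hit & claims$medication
    if (def$requires_admission) hit <- hit & claims$admission
    if (def$primary_dx_only) hit <- hit & claims$primary_dx
    out[[def$disease]] <- persons %in% unique(as.character(claims$person_id)[hit])
  }
  attr(out, "skipped_rows") <- skipped
  out
}

#' Kin-filter presets for family-history strata
#'
#' Predicates over family-tree records selecting which kin count toward a
#' family history: all first-degree kin; parents only; the father's side
#' (family codes whose first step is `1AM`); the mother's side (`1AW`).
#'
#' @param records family-tree records data.frame.
#' @return logical vector over the rows of `records`.
#' @name kin_filters
NULL

#' @rdname kin_filters
#' @export
kin_filter_first_degree <- function(records) records$FMLY_DGR == 1L

#' @rdname kin_filters
#' @export
kin_filter_parents <- function(records) {
  nchar(records$FMLY_CD) == 6L & substr(records$FMLY_CD, 4L, 5L) == "1A"
}

#' @rdname kin_filters
#' @export
kin_filter_father_side <- function(records) {
  substr(records$FMLY_CD, 4L, 6L) == "1AM"
}

#' @rdname kin_filters
#' @export
kin_filter_mother_side <- function(records) {
  substr(records$FMLY_CD, 4L, 6L) == "1AW"
}

#' Family-history flag per person
#'
#' A person has a family history of `disease` iff at least one of their kin
#' selected by `kin_filter` is a case.  Persons whose records contain no kin
#' passing the filter fall in the no-history stratum.
#'
#' @param records family-tree records (from [expand_all()]).
#' @param affected data.frame from [apply_case_definitions()] (or any
#'   data.frame with `person_id` and a logical column named `disease`).
#' @param disease disease column name in `affected`.
#' @param kin_filter one of the [kin_filters], or any function mapping the
#'   records to a logical row mask.
#' @return data.frame `person_id`, `has_history` over all subjects appearing
#'   in `records`.
#' @export
family_history_flag <- function(records, affected, disease,
                                kin_filter = kin_filter_first_degree) {
  sel <- records[kin_filter(records), , drop = FALSE]
  aff_ids <- affected$person_id[affected[[disease]]]
  hit <- unique(sel$TG_ID[sel$FMLY_ID %in% aff_ids])
  subjects <- unique(records$TG_ID)
  data.frame(person_id = subjects, has_history = subjects %in% hit,
             stringsAsFactors = FALSE)
}

#' Standard population weights by five-year age group
#'
#' @param weights named non-negative numeric vector; names are the lower
#'   bounds of five-year age groups (0, 5, ..., 85, the last open-ended).
#'   Weights are normalized to sum to 1.
#' @return an object of class `standard_population`.
#' @export
standard_population <- function(weights) {
  stopifnot(is.numeric(weights), all(weights >= 0), sum(weights) > 0,
            !is.null(names(weights)))
  w <- weights / sum(weights)
  structure(list(age_group = as.integer(names(weights)), weight = unname(w)),
            class = "standard_population")
}

#' Standard population from an observed population
#'
#' Uses the population's own age distribution in `reference_year` as the
#' standard (the analogue of standardizing to the entire insured population).
#'
#' @param persons data.frame with `birth_year` (and optionally `death_year`;
#'   the dead are excluded).
#' @param reference_year the year ages are computed at.
#' @return a [standard_population()].
#' @export
standard_from_population <- function(persons, reference_year = 2017L) {
  alive <- persons$birth_year <= reference_year
  if ("death_year" %in% names(persons)) {
    alive <- alive & (is.na(persons$death_year) |
                        persons$death_year > reference_year)
  }
  age <- reference_year - persons$birth_year[alive]
  grp <- pmin(85L, 5L * (age %/% 5L))
  tab <- table(factor(grp, levels = seq(0L, 85L, by = 5L)))
  standard_population(stats::setNames(as.numeric(tab), names(tab)))
}

#' Direct age-standardized prevalence by stratum
#'
#' For each stratum, computes the five-year-age-group-specific prevalences
#' and weights them by the standard population:
#' sum over groups of `weight_g * cases_g / persons_g`.  Age is
#' `reference_year - birth_year`.  Age groups with standard weight but no
#' persons in the stratum contribute 0 and are counted in `empty_groups`;
#' a stratum with no persons at all is reported as `NA`.
#'
#' @param affected data.frame `person_id` plus a logical disease column.
#' @param persons data.frame `person_id,birth_year` defining the analysis
#'   population (persons absent from `affected` count as non-cases).
#' @param strata data.frame `person_id,stratum`; a person may appear in
#'   several strata.
#' @param standard a [standard_population()].
#' @param reference_year year for age reckoning (default 2017).
#' @param disease disease column in `affected`; defaults to its last column.
#' @return data.frame `stratum, prevalence, se, n, empty_groups`, with the
#'   delta-method standard error of the weighted prevalence.
#' @export
age_standardized_prevalence <- function(affected, persons, strata, standard,
                                        reference_year = 2017L,
                                        disease = NULL) {
  stopifnot(inherits(standard, "standard_population"))
  if (is.null(disease)) disease <- names(affected)[ncol(affected)]
  aff <- stats::setNames(affected[[disease]], affected$person_id)
  is_case <- unname(aff[persons$person_id])
  is_case[is.na(is_case)] <- FALSE
  age <- reference_year - persons$birth_year
  grp <- pmin(85L, pmax(0L, 5L * (age %/% 5L)))
  pdat <- data.frame(person_id = persons$person_id, grp = grp, case = is_case,
                     stringsAsFactors = FALSE)
  out <- lapply(split(strata$person_id, strata$stratum), function(ids) {
    d <- pdat[pdat$person_id %in% ids, , drop = FALSE]
    if (nrow(d) == 0L) {
      return(data.frame(prevalence = NA_real_, se = NA_real_, n = 0L,
                        empty_groups = sum(standard$weight > 0)))
    }
    prev <- 0; var <- 0; empty <- 0L
    for (k in seq_along(standard$age_group)) {
      w <- standard$weight[k]
      if (w == 0) next
      sel <- d$grp == standard$age_group[k]
      n_g <- sum(sel)
      if (n_g == 0L) { empty <- empty + 1L; next }
      p_g <- mean(d$case[sel])
      prev <- prev + w * p_g
      var <- var + w^2 * p_g * (1 - p_g) / n_g
    }
    data.frame(prevalence = prev, se = sqrt(var), n = nrow(d),
               empty_groups = empty)
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(stratum = names(out), stringsAsFactors = FALSE), res)
  rownames(res) <- NULL
  res
}

# birth-decade labels matching the cohort rows of the matching-rate report
.decade_label <- function(birth_year) {
  ifelse(birth_year >= 2010L, "2010s",
  ifelse(birth_year >= 2000L, "2000s",
  ifelse(birth_year >= 1990L, "1990s",
  ifelse(birth_year >= 1980L, "1980s",
  ifelse(birth_year >= 1970L, "1970s",
  ifelse(birth_year >= 1960L, "1960s", "-1950s"))))))
}

.DECADES <- c("2010s", "2000s", "1990s", "1980s", "1970s", "1960s", "-1950s")

#' Parent and grandparent matching rates by sex and birth cohort
#'
#' For each sex and birth decade of the reference population (persons alive
#' in `reference_population_year`), the share with at least one matched
#' father, mother, any parent, and any parent or grandparent.  Only kin with
#' shared household or insurance-unit history (`HHRR_CD` present) are
#' counted.
#'
#' @param records family-tree records with `HHRR_CD` filled.
#' @param persons data.frame `person_id,sex,birth_year` and optionally
#'   `death_year`.
#' @param reference_population_year year defining the reference population.
#' @return data.frame `sex, cohort, n, father, mother, any_parent,
#'   any_parent_or_grandparent` with rates in percent.
#' @export
matching_rate_table <- function(records, persons,
                                reference_population_year = 2017L) {
  alive <- persons$birth_year <= reference_population_year
  if ("death_year" %in% names(persons)) {
    alive <- alive & (is.na(persons$death_year) |
                        persons$death_year > reference_population_year)
  }
  pop <- persons[alive, , drop = FALSE]
  r <- records[!is.na(records$HHRR_CD), , drop = FALSE]
  tail2 <- substr(r$FMLY_CD, 4L, 9L)
  is_father <- nchar(r$FMLY_CD) == 6L & substr(tail2, 1L, 3L) == "1AM"
  is_mother <- nchar(r$FMLY_CD) == 6L & substr(tail2, 1L, 3L) == "1AW"
  is_gp <- nchar(r$FMLY_CD) == 9L & substr(tail2, 1L, 2L) == "1A" &
    substr(tail2, 4L, 5L) == "1A"
  with_father <- unique(r$TG_ID[is_father])
  with_mother <- unique(r$TG_ID[is_mother])
  with_gp <- unique(r$TG_ID[is_gp])
  pop$cohort <- .decade_label(pop$birth_year)
  grid <- expand.grid(sex = c("M", "W"), cohort = .DECADES,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    sel <- pop$sex == grid$sex[k] & pop$cohort == grid$cohort[k]
    ids <- pop$person_id[sel]
    n <- length(ids)
    pct <- function(hit) if (n == 0L) NA_real_ else 100 * mean(ids %in% hit)
    data.frame(sex = grid$sex[k], cohort = grid$cohort[k], n = n,
               father = pct(with_father), mother = pct(with_mother),
               any_parent = pct(union(with_father, with_mother)),
               any_parent_or_grandparent =
                 pct(union(union(with_father, with_mother), with_gp)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Kin counts by sex, birth cohort, degree and family type
#'
#' Counts family-tree records per subject sex and birth decade, split by
#' degree of kinship 1-4 and by consanguinity (family types C1, C2, R1)
#' versus affinity (A1, A2, A3; the spouse record A0, which carries degree
#' 0, is included in affinity only when `include_spouse = TRUE`).  With the
#' default, the degree-wise counts and the consanguinity-plus-affinity
#' totals partition the same record set.
#'
#' @param records family-tree records.
#' @param include_spouse logical; count A0 spouse records in the affinity
#'   column.
#' @return data.frame `sex, cohort, n_subjects, deg1..deg4, consanguinity,
#'   affinity`.
#' @export
kin_count_table <- function(records, include_spouse = FALSE) {
  r <- records
  r$cohort <- .decade_label(r$TG_BYEAR)
  grid <- expand.grid(sex = c("M", "W"), cohort = .DECADES,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    sel <- r$TG_SEX_TYPE == grid$sex[k] & r$cohort == grid$cohort[k]
    d <- r[sel, , drop = FALSE]
    consang <- sum(d$FMLY_TYPE %in% c("C1", "C2", "R1"))
    aff_types <- c("A1", "A2", "A3", if (include_spouse) "A0")
    data.frame(sex = grid$sex[k], cohort = grid$cohort[k],
               n_subjects = length(unique(d$TG_ID)),
               deg1 = sum(d$FMLY_DGR == 1L), deg2 = sum(d$FMLY_DGR == 2L),
               deg3 = sum(d$FMLY_DGR == 3L), deg4 = sum(d$FMLY_DGR == 4L),
               consanguinity = consang,
               affinity = sum(d$FMLY_TYPE %in% aff_types),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
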