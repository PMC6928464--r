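claims_row <- function(person, icd, year = 2010L, admission = FALSE,
                       medication = FALSE, primary = FALSE) {
  data.frame(person_id = person, year = year, icd10 = icd,
             admission = admission, medication = medication,
             primary_dx = primary, stringsAsFactors = FALSE)
}

test_that("case definitions require code range plus the right flags", {
  claims <- rbind(
    claims_row("p1", "I21", admission = TRUE),              # IHD case
    claims_row("p2", "I10"),                                # htn code, no meds
    claims_row("p3", "I10", medication = TRUE),             # htn case
    claims_row("p4", "C50", admission = TRUE),              # secondary dx
    claims_row("p5", "C50", admission = TRUE, primary = TRUE),  # cancer case
    claims_row("p6", "E11", medication = TRUE),             # diabetes case
    claims_row("p7", "I63", admission = TRUE),              # stroke case
    claims_row("p8", "I21", admission = TRUE, year = 2019L) # after reference
  )
  aff <- apply_case_definitions(claims, reference_year = 2017L)
  case_ids <- function(d) aff$person_id[aff[[d]]]
  expect_equal(case_ids("ischemic_heart_disease"), "p1")
  expect_equal(case_ids("hypertension"), "p3")
  expect_equal(case_ids("cancer"), "p5")
  expect_equal(case_ids("diabetes"), "p6")
  expect_equal(case_ids("cerebrovascular_disease"), "p7")
})

test_that("unparseable ICD codes are skipped and counted", {
  claims <- rbind(claims_row("p1", "I21", admission = TRUE),
                  claims_row("p2", "garbage", admission = TRUE),
                  claims_row("p3", "9XX", medication = TRUE))
  aff <- apply_case_definitions(claims)
  expect_equal(attr(aff, "skipped_rows"), 2L)
  expect_equal(aff$person_id[aff$ischemic_heart_disease], "p1")
})

# records where subject "kid" has father "dad", mother "mum", uncle "unc"
hist_records <- function() {
  data.frame(
    TG_ID = c("kid", "kid", "kid", "solo"),
    FMLY_ID = c("dad", "mum", "unc", "far"),
    TG_SEX_TYPE = "M", TG_BYEAR = 1990L,
    FMLY_SEX_TYPE = c("M", "W", "M", "M"),
    FMLY_BYEAR = c(1960L, 1962L, 1958L, 1900L),
    FMLY_CD = c("0IM1AM", "0IM1AW", "0IM1AM2AM", "0IM1AM1AM1AM"),
    FMLY_DGR = c(1L, 1L, 3L, 3L),
    FMLY_TYPE = c("C1", "C1", "C2", "C2"),
    HHRR_CD = c(1L, 1L, NA, NA), stringsAsFactors = FALSE)
}

test_that("family-history flags follow the kin filter", {
  rec <- hist_records()
  aff <- data.frame(person_id = c("dad", "mum", "unc", "far"),
                    htn = c(FALSE, TRUE, FALSE, FALSE),
                    stringsAsFactors = FALSE)
  h1 <- family_history_flag(rec, aff, "htn", kin_filter_parents)
  expect_true(h1$has_history[h1$person_id == "kid"])
  expect_false(h1$has_history[h1$person_id == "solo"])   # no kin in filter
  # mother affected: mother-side history, not father-side
  hm <- family_history_flag(rec, aff, "htn", kin_filter_mother_side)
  hf <- family_history_flag(rec, aff, "htn", kin_filter_father_side)
  expect_true(hm$has_history[hm$person_id == "kid"])
  expect_false(hf$has_history[hf$person_id == "kid"])
  # both parents affected: both side-specific strata (overlap allowed)
  aff2 <- aff; aff2$htn <- c(TRUE, TRUE, FALSE, FALSE)
  expect_true(family_history_flag(rec, aff2, "htn",
                                  kin_filter_father_side)$has_history[1])
  expect_true(family_history_flag(rec, aff2, "htn",
                                  kin_filter_mother_side)$has_history[1])
  # father-side includes paternal kin beyond the father
  aff3 <- aff; aff3$htn <- c(FALSE, FALSE, TRUE, FALSE)
  expect_true(family_history_flag(rec, aff3, "htn",
                                  kin_filter_father_side)$has_history[1])
  expect_false(family_history_flag(rec, aff3, "htn",
                                   kin_filter_parents)$has_history[1])
})

two_group_fixture <- function() {
  # 100 persons aged 30-34, prevalence 0.1; 100 aged 60-64, prevalence 0.3
  persons <- data.frame(person_id = sprintf("q%03d", 1:200),
                        birth_year = rep(c(1985L, 1955L), each = 100L),
                        stringsAsFactors = FALSE)
  affected <- data.frame(person_id = persons$person_id,
                         dz = c(rep(c(TRUE, FALSE), c(10, 90)),
                                rep(c(TRUE, FALSE), c(30, 70))),
                         stringsAsFactors = FALSE)
  list(persons = persons, affected = affected,
       strata = data.frame(person_id = persons$person_id, stratum = "all",
                           stringsAsFactors = FALSE))
}

test_that("direct standardization reproduces the worked two-group value", {
  fx <- two_group_fixture()
  std <- standard_population(c("30" = 0.5, "60" = 0.5))
  res <- age_standardized_prevalence(fx$affected, fx$persons, fx$strata, std,
                                     reference_year = 2017L, disease = "dz")
  expect_equal(res$prevalence, 0.5 * 0.1 + 0.5 * 0.3, tolerance = 1e-12)
})

test_that("standard weights matching the population age mix give the crude rate", {
  fx <- two_group_fixture()
  std <- standard_from_population(fx$persons, 2017L)
  res <- age_standardized_prevalence(fx$affected, fx$persons, fx$strata, std,
                                     2017L, "dz")
  expect_equal(res$prevalence, mean(fx$affected$dz), tolerance = 1e-12)
})

test_that("zero weight on the only affected group yields zero prevalence", {
  fx <- two_group_fixture()
  fx$affected$dz <- fx$affected$dz & fx$persons$birth_year == 1955L
  std <- standard_population(c("30" = 1, "60" = 0))
  res <- age_standardized_prevalence(fx$affected, fx$persons, fx$strata, std,
                                     2017L, "dz")
  expect_equal(res$prevalence, 0)
})

test_that("empty strata and empty age groups are reported, not invented", {
  fx <- two_group_fixture()
  strata <- rbind(fx$strata,
                  data.frame(person_id = "ghost", stratum = "empty"))
  std <- standard_population(c("30" = 0.4, "60" = 0.4, "85" = 0.2))
  res <- age_standardized_prevalence(fx$affected, fx$persons, strata, std,
                                     2017L, "dz")
  expect_true(is.na(res$prevalence[res$stratum == "empty"]))
  expect_equal(res$empty_groups[res$stratum == "all"], 1L)  # nobody aged 85+
})

test_that("matching rates count only kin with shared household history", {
  rec <- hist_records()
  persons <- data.frame(person_id = c("kid", "solo"), sex = "M",
                        birth_year = c(1990L, 1990L),
                        stringsAsFactors = FALSE)
  mt <- matching_rate_table(rec, persons)
  row <- mt[mt$sex == "M" & mt$cohort == "1990s", ]
  expect_equal(row$n, 2L)
  expect_equal(row$father, 50)           # solo's ancestor line has no HHRR
  expect_equal(row$any_parent, 50)
  expect_equal(row$any_parent_or_grandparent, 50)
})

test_that("a person with only a grandparent matched counts only in the wide column", {
  rec <- data.frame(TG_ID = "kid", FMLY_ID = "gf", TG_SEX_TYPE = "M",
                    TG_BYEAR = 2012L, FMLY_SEX_TYPE = "M", FMLY_BYEAR = 1950L,
                    FMLY_CD = "0IM1AM1AM", FMLY_DGR = 2L, FMLY_TYPE = "C1",
                    HHRR_CD = 2L, stringsAsFactors = FALSE)
  persons <- data.frame(person_id = "kid", sex = "M", birth_year = 2012L,
                        stringsAsFactors = FALSE)
  mt <- matching_rate_table(rec, persons)
  row <- mt[mt$sex == "M" & mt$cohort == "2010s", ]
  expect_equal(row$any_parent, 0)
  expect_equal(row$any_parent_or_grandparent, 100)
})

test_that("kin counts partition into degrees and consanguinity plus affinity", {
  sim <- random_pedigree(8)
  snaps <- emit_snapshots(sim$persons, sim$graph,
                          sim_config(seed = 8, n_founder_couples = 2,
                                     n_generations = 3))
  rec <- expand_all(sim$graph, snapshots = snaps)
  kt <- kin_count_table(rec)
  expect_equal(kt$deg1 + kt$deg2 + kt$deg3 + kt$deg4,
               kt$consanguinity + kt$affinity)
  # nuclear family: each child has two degree-1 kin and one degree-2 kin
  ktn <- kin_count_table(expand_all(nuclear_family()))
  boy <- ktn[ktn$sex == "M" & ktn$cohort == "1980s", ]
  expect_equal(boy$deg1, 2L)
  expect_equal(boy$deg2, 1L)
  # spouse records enter affinity only on request
  kts <- kin_count_table(expand_all(nuclear_family()), include_spouse = TRUE)
  expect_equal(sum(kts$affinity), 2L)
  expect_equal(sum(ktn$affinity), 0L)
})

test_that("empty records yield an all-zero kin count table", {
  empty <- expand_all(pedigree(data.frame(person_id = "a", sex = "M",
                                          birth_year = 1980L)))
  kt <- kin_count_table(empty)
  expect_true(all(kt[c("deg1", "deg2", "deg3", "deg4",
                       "consanguinity", "affinity")] == 0L))
})
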