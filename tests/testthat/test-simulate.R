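test_that("simulation is reproducible from the seed", {
  cfg <- sim_config(seed = 99, n_founder_couples = 10, n_generations = 3)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$persons, s2$persons)
  snaps1 <- emit_snapshots(s1$persons, s1$graph, cfg)
  set.seed(cfg$seed)                      # snapshot coverage draws use the RNG
  snaps2 <- emit_snapshots(s2$persons, s2$graph, cfg)
  expect_identical(snaps1[order(snaps1$person_id, snaps1$year, snaps1$source), ],
                   snaps2[order(snaps2$person_id, snaps2$year, snaps2$source), ])
})

test_that("fertility matches the Poisson mean within sampling error", {
  cfg <- sim_config(seed = 3, n_founder_couples = 1000, n_generations = 2,
                    fertility = 2.2, marriage_prob = 0)
  sim <- simulate_population(cfg)
  kids <- sum(sim$persons$generation == 2L)
  mean_kids <- kids / 1000
  se <- sqrt(2.2 / 1000)
  expect_lt(abs(mean_kids - 2.2), 3 * se)
})

test_that("without marriage no spouse edges form beyond the founders", {
  cfg <- sim_config(seed = 8, n_founder_couples = 20, n_generations = 3,
                    marriage_prob = 0)
  sim <- simulate_population(cfg)
  expect_equal(nrow(sim$graph$spouse_edges), 20L)
  expect_true(all(sim$persons$generation <= 2L))
})

test_that("the ground-truth pedigree satisfies the graph invariants", {
  sim <- random_pedigree(55)
  pe <- sim$graph$parent_edges
  expect_lte(max(table(pe$child_id)), 2L)
  bp <- sim$persons$birth_year[match(pe$parent_id, sim$persons$person_id)]
  bc <- sim$persons$birth_year[match(pe$child_id, sim$persons$person_id)]
  expect_true(all(bp < bc))
})

test_that("register rows start in 2004 and eligibility in 2002", {
  cfg <- sim_config(seed = 21, n_founder_couples = 15, n_generations = 3)
  sim <- simulate_population(cfg)
  snaps <- emit_snapshots(sim$persons, sim$graph, cfg)
  expect_gte(min(snaps$year[snaps$source == "register"]), 2004L)
  expect_gte(min(snaps$year[snaps$source == "eligibility"]), 2002L)
  # persons dead before a source's start never appear in it
  dead_pre <- sim$persons$person_id[sim$persons$death_year < 2002L]
  expect_false(any(snaps$person_id %in% dead_pre & snaps$source == "eligibility"))
})

test_that("each unit-year roster carries exactly one head", {
  cfg <- sim_config(seed = 21, n_founder_couples = 15, n_generations = 3)
  sim <- simulate_population(cfg)
  snaps <- emit_snapshots(sim$persons, sim$graph, cfg)
  is_head <- nchar(snaps$relation_to_head) == 3L
  heads <- tapply(is_head, paste(snaps$unit_id, snaps$year, snaps$source), sum)
  expect_true(all(heads == 1L))
})

test_that("full observation recovers every observable parent-child pair", {
  cfg <- sim_config(seed = 42, n_founder_couples = 8, n_generations = 3,
                    eligibility_start_year = 1900L, register_start_year = 1900L,
                    record_coverage_before_start = 1)
  sim <- simulate_population(cfg)
  snaps <- emit_snapshots(sim$persons, sim$graph, cfg)
  res <- infer_edges(snaps, sim$persons)
  true_pe <- sim$graph$parent_edges
  observable <- sim$persons$birth_year[match(true_pe$child_id,
                                             sim$persons$person_id)] <= cfg$end_year
  tk <- paste(true_pe$parent_id, true_pe$child_id)[observable]
  rk <- paste(res$graph$parent_edges$parent_id, res$graph$parent_edges$child_id)
  expect_true(all(tk %in% rk))
  expect_true(all(rk %in% paste(true_pe$parent_id, true_pe$child_id)))
})

test_that("pre-start missingness lowers recovery for older birth cohorts", {
  full <- sim_config(seed = 42, n_founder_couples = 40, n_generations = 3,
                     founder_birth_range = c(1935L, 1955L),
                     eligibility_start_year = 1900L,
                     register_start_year = 1900L,
                     record_coverage_before_start = 1)
  trunc <- sim_config(seed = 42, n_founder_couples = 40, n_generations = 3,
                      founder_birth_range = c(1935L, 1955L))
  rate_for <- function(cfg) {
    sim <- simulate_population(cfg)
    snaps <- emit_snapshots(sim$persons, sim$graph, cfg)
    res <- infer_edges(snaps, sim$persons)
    rec <- expand_all(res$graph, snapshots = snaps, max_degree = 1)
    kids <- sim$persons[!is.na(sim$persons$father_id) &
                          sim$persons$birth_year <= cfg$end_year, ]
    matched <- unique(rec$TG_ID[substr(rec$FMLY_CD, 4, 5) == "1A" &
                                  !is.na(rec$HHRR_CD)])
    old <- kids$birth_year < 1980L
    c(old = mean(kids$person_id[old] %in% matched),
      young = mean(kids$person_id[!old] %in% matched))
  }
  r_full <- rate_for(full)
  r_trunc <- rate_for(trunc)
  expect_equal(unname(r_full["old"]), 1)
  expect_equal(unname(r_full["young"]), 1)
  expect_lt(r_trunc[["old"]], r_trunc[["young"]])
})

test_that("claims satisfy their case definitions exactly", {
  cfg <- sim_config(seed = 14, n_founder_couples = 60, n_generations = 3)
  sim <- simulate_population(cfg)
  cl <- simulate_claims(sim$persons, sim$graph, cfg)
  # every affected hypertensive alive in the claims era has a qualifying row
  aff <- apply_case_definitions(cl$claims)
  alive <- sim$persons$death_year >= cfg$eligibility_start_year
  for (d in names(cfg$disease_params)) {
    truth <- cl$status[[d]] & alive
    got <- cl$status$person_id %in% aff$person_id[aff[[d]]]
    expect_equal(got, truth)
  }
  htn <- cl$claims[cl$claims$person_id %in%
                     cl$status$person_id[cl$status$hypertension] &
                     grepl("^I1[0-5]", cl$claims$icd10), ]
  expect_gt(nrow(htn), 0L)
  expect_true(any(htn$medication))
})

test_that("a unit parental relative risk leaves offspring risk independent", {
  p_vals <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = 9000 + s, n_founder_couples = 400,
                      n_generations = 2, marriage_prob = 0,
                      disease_params = default_disease_params(parental_rr = 1))
    sim <- simulate_population(cfg)
    cl <- simulate_claims(sim$persons, sim$graph, cfg)
    st <- cl$status
    kids <- !is.na(sim$persons$father_id)
    par_aff <- st$hypertension[match(sim$persons$father_id, st$person_id)] |
      st$hypertension[match(sim$persons$mother_id, st$person_id)]
    tab <- table(par_aff[kids], st$hypertension[kids])
    if (any(dim(tab) < 2)) return(1)
    suppressWarnings(stats::chisq.test(tab)$p.value)
  }, numeric(1))
  expect_gte(sum(p_vals > 0.01), 9L)    # independence not rejected at alpha=.01
})

test_that("a doubled parental risk doubles offspring prevalence", {
  cfg <- sim_config(seed = 31, n_founder_couples = 4000, n_generations = 2,
                    marriage_prob = 0)
  sim <- simulate_population(cfg)
  cl <- simulate_claims(sim$persons, sim$graph, cfg)
  st <- cl$status
  # compare within one five-year age band so the base prevalence is constant
  age <- cfg$end_year - sim$persons$birth_year
  kids <- which(!is.na(sim$persons$father_id) & age %/% 5L == 6L)
  par_aff <- st$hypertension[match(sim$persons$father_id[kids], st$person_id)] |
    st$hypertension[match(sim$persons$mother_id[kids], st$person_id)]
  p1 <- mean(st$hypertension[kids][par_aff])
  p0 <- mean(st$hypertension[kids][!par_aff])
  se <- sqrt(p1 * (1 - p1) / sum(par_aff) + 4 * p0 * (1 - p0) / sum(!par_aff))
  expect_lt(abs(p1 - 2 * p0), 3 * se)
})
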