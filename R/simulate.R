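# Synthetic population ---------------------------------------------------------
#
# Generates a multi-generation population with married founder couples,
# Poisson fertility, marrying-in spouses, per-generation mortality, yearly
# household and insurance-unit rosters with source-specific start years
# (emulating incomplete electronization of records before those years), and
# claims with familially aggregated disease.  Children are only ever born to
# married couples, and a newlywed couple may spend its first years in the
# groom's parents' household, which creates multi-step relation-to-head
# codes and gives grandchild-grandparent pairs shared household history.

#' Simulation configuration
#'
#' @param seed integer RNG seed; every downstream draw is reproducible from
#'   it.
#' @param n_founder_couples number of founder couples.
#' @param n_generations total generations including founders (>= 2).
#' @param fertility mean children per couple (Poisson).
#' @param marriage_prob probability a non-final-generation child marries.
#' @param founder_birth_range integer range for founder men's birth years.
#' @param marriage_age integer range of age at marriage.
#' @param household_split_age age at which an unmarried person forms their
#'   own household.
#' @param eligibility_start_year first year of health-insurance eligibility
#'   records (2002 in the source system).
#' @param register_start_year first year of resident-register records (2004).
#' @param end_year last roster/claims year.
#' @param record_coverage_before_start probability a roster row from before a
#'   source's start year is still present (0 = the source simply starts at
#'   its start year).
#' @param p_extended probability a newlywed couple lives with the groom's
#'   parents for `extended_years`.
#' @param extended_years duration of extended-household co-residence.
#' @param death_age_mean,death_age_sd Normal death-age distribution
#'   (truncated below at 30).
#' @param disease_params list of per-disease parameters, see
#'   [default_disease_params()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_founder_couples = 50L,
                       n_generations = 4L,
                       fertility = 2.2,
                       marriage_prob = 0.8,
                       founder_birth_range = c(1938L, 1952L),
                       marriage_age = c(24L, 32L),
                       household_split_age = 30L,
                       eligibility_start_year = 2002L,
                       register_start_year = 2004L,
                       end_year = 2017L,
                       record_coverage_before_start = 0,
                       p_extended = 0.3,
                       extended_years = 5L,
                       death_age_mean = 78,
                       death_age_sd = 10,
                       disease_params = default_disease_params()) {
  stopifnot(n_generations >= 2L, fertility >= 0,
            marriage_prob >= 0, marriage_prob <= 1,
            record_coverage_before_start >= 0, record_coverage_before_start <= 1,
            p_extended >= 0, p_extended <= 1)
  structure(list(seed = as.integer(seed),
                 n_founder_couples = as.integer(n_founder_couples),
                 n_generations = as.integer(n_generations),
                 fertility = fertility, marriage_prob = marriage_prob,
                 founder_birth_range = as.integer(founder_birth_range),
                 marriage_age = as.integer(marriage_age),
                 household_split_age = as.integer(household_split_age),
                 eligibility_start_year = as.integer(eligibility_start_year),
                 register_start_year = as.integer(register_start_year),
                 end_year = as.integer(end_year),
                 record_coverage_before_start = record_coverage_before_start,
                 p_extended = p_extended,
                 extended_years = as.integer(extended_years),
                 death_age_mean = death_age_mean, death_age_sd = death_age_sd,
                 disease_params = disease_params),
            class = "sim_config")
}

#' Default familial-disease parameters
#'
#' Five diseases with the claims-system code ranges used for case
#' definitions (hypertension I10-I15, diabetes E10-E14, ischemic heart
#' disease I20-I25, cerebrovascular disease I60-I69, cancer C00-C97),
#' age-group-specific base prevalence rising with age, and a parental
#' relative risk of 2 applied when at least one biological parent is
#' affected.
#'
#' @param parental_rr relative risk shared by all diseases (default 2).
#' @return named list of per-disease parameter lists.
#' @export
default_disease_params <- function(parental_rr = 2) {
  groups <- seq(0L, 85L, by = 5L)
  ramp <- function(onset, peak) {
    v <- pmin(1, pmax(0, (groups - onset) / (85 - onset)))
    stats::setNames(round(v * peak, 5), groups)
  }
  list(
    hypertension = list(code_range = c("I10", "I15"), requires = "medication",
                        base_prevalence = ramp(18, 0.42), parental_rr = parental_rr),
    diabetes = list(code_range = c("E10", "E14"), requires = "medication",
                    base_prevalence = ramp(20, 0.22), parental_rr = parental_rr),
    ischemic_heart_disease = list(code_range = c("I20", "I25"),
                                  requires = "admission",
                                  base_prevalence = ramp(30, 0.12),
                                  parental_rr = parental_rr),
    cerebrovascular_disease = list(code_range = c("I60", "I69"),
                                   requires = "admission",
                                   base_prevalence = ramp(35, 0.10),
                                   parental_rr = parental_rr),
    cancer = list(code_range = c("C00", "C97"), requires = "admission_primary",
                  base_prevalence = ramp(25, 0.15), parental_rr = parental_rr)
  )
}

.runif_int <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1L))

#' Simulate a multi-generation population
#'
#' Founder couples marry and bear Poisson(`fertility`) children; children of
#' non-final generations marry with probability `marriage_prob`, each
#' bringing in a new spouse with no recorded parents; married couples bear
#' the next generation.  Death years follow a truncated Normal age
#' distribution, producing people who died before the record systems started.
#'
#' @param config a [sim_config()].
#' @return list with `persons` (data.frame: `person_id, sex, birth_year,
#'   death_year, generation, father_id, mother_id, spouse_id, marriage_year,
#'   extended`) and `graph`, the ground-truth [pedigree()].
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_alloc <- 0L
  new_ids <- function(n) {
    ids <- sprintf("P%07d", n_alloc + seq_len(n))
    n_alloc <<- n_alloc + n
    ids
  }
  death_year_for <- function(birth) {
    birth + pmax(30L, as.integer(round(stats::rnorm(length(birth),
                                                    config$death_age_mean,
                                                    config$death_age_sd))))
  }
  cols <- c("person_id", "sex", "birth_year", "death_year", "generation",
            "father_id", "mother_id", "spouse_id", "marriage_year", "extended")
  chunks <- list()
  add_chunk <- function(df) chunks[[length(chunks) + 1L]] <<- df

  nf <- config$n_founder_couples
  mb <- .runif_int(nf, config$founder_birth_range[1L], config$founder_birth_range[2L])
  wb <- mb + .runif_int(nf, -3L, 3L)
  m_ids <- new_ids(nf); w_ids <- new_ids(nf)
  marr <- pmax(mb, wb) + .runif_int(nf, config$marriage_age[1L], config$marriage_age[2L])
  add_chunk(data.frame(person_id = m_ids, sex = "M", birth_year = mb,
                       death_year = death_year_for(mb), generation = 1L,
                       father_id = NA_character_, mother_id = NA_character_,
                       spouse_id = w_ids, marriage_year = marr,
                       extended = FALSE, stringsAsFactors = FALSE))
  add_chunk(data.frame(person_id = w_ids, sex = "W", birth_year = wb,
                       death_year = death_year_for(wb), generation = 1L,
                       father_id = NA_character_, mother_id = NA_character_,
                       spouse_id = m_ids, marriage_year = marr,
                       extended = FALSE, stringsAsFactors = FALSE))
  couples <- data.frame(father = m_ids, mother = w_ids, marriage_year = marr,
                        stringsAsFactors = FALSE)

  for (g in seq_len(config$n_generations - 1L)) {
    if (nrow(couples) == 0L) break
    nk <- stats::rpois(nrow(couples), config$fertility)
    idx <- rep(seq_len(nrow(couples)), nk)
    if (length(idx) == 0L) { couples <- couples[0L, ]; next }
    # distinct birth offsets within each family
    off <- unlist(lapply(nk[nk > 0L], function(k) sort(sample.int(14L, k))))
    cb <- couples$marriage_year[idx] + off
    ids <- new_ids(length(idx))
    sex <- sample(c("M", "W"), length(idx), replace = TRUE)
    married <- g < config$n_generations - 1L &
      stats::runif(length(idx)) < config$marriage_prob
    sp_ids <- rep(NA_character_, length(idx))
    sp_marr <- rep(NA_integer_, length(idx))
    ext <- rep(FALSE, length(idx))
    n_m <- sum(married)
    if (n_m > 0L) {
      sb <- cb[married] + .runif_int(n_m, -3L, 3L)
      s_ids <- new_ids(n_m)
      s_marr <- pmax(cb[married], sb) +
        .runif_int(n_m, config$marriage_age[1L], config$marriage_age[2L])
      sp_ids[married] <- s_ids
      sp_marr[married] <- s_marr
      # couples live with the groom's parents only when the groom is the
      # in-pedigree child
      ext[married] <- sex[married] == "M" & stats::runif(n_m) < config$p_extended
      add_chunk(data.frame(person_id = s_ids,
                           sex = ifelse(sex[married] == "M", "W", "M"),
                           birth_year = sb, death_year = death_year_for(sb),
                           generation = g + 1L,
                           father_id = NA_character_, mother_id = NA_character_,
                           spouse_id = ids[married], marriage_year = s_marr,
                           extended = FALSE, stringsAsFactors = FALSE))
    }
    add_chunk(data.frame(person_id = ids, sex = sex, birth_year = cb,
                         death_year = death_year_for(cb), generation = g + 1L,
                         father_id = couples$father[idx],
                         mother_id = couples$mother[idx],
                         spouse_id = sp_ids, marriage_year = sp_marr,
                         extended = ext, stringsAsFactors = FALSE))
    if (n_m > 0L) {
      husband <- ifelse(sex[married] == "M", ids[married], sp_ids[married])
      wife <- ifelse(sex[married] == "M", sp_ids[married], ids[married])
      couples <- data.frame(father = husband, mother = wife,
                            marriage_year = sp_marr[married],
                            stringsAsFactors = FALSE)
    } else {
      couples <- couples[0L, ]
    }
  }

  persons <- do.call(rbind, chunks)[, cols]
  rownames(persons) <- NULL
  graph <- .pedigree_from_persons(persons)
  list(persons = persons, graph = graph)
}

# bulk pedigree constructor trusting simulation invariants (birth years make
# biological parentage acyclic by construction)
.pedigree_from_persons <- function(persons) {
  g <- pedigree(persons[c("person_id", "sex", "birth_year", "death_year")])
  has_f <- !is.na(persons$father_id)
  has_m <- !is.na(persons$mother_id)
  g$parent_edges <- data.frame(
    parent_id = c(persons$father_id[has_f], persons$mother_id[has_m]),
    child_id = c(persons$person_id[has_f], persons$person_id[has_m]),
    bond = rep("biological", sum(has_f) + sum(has_m)),
    stringsAsFactors = FALSE)
  sp <- persons[!is.na(persons$spouse_id) & persons$person_id < persons$spouse_id, ]
  g$spouse_edges <- data.frame(a_id = sp$person_id, b_id = sp$spouse_id,
                               stringsAsFactors = FALSE)
  if (nrow(g$parent_edges) > 0L) {
    bp <- persons$birth_year[match(g$parent_edges$parent_id, persons$person_id)]
    bc <- persons$birth_year[match(g$parent_edges$child_id, persons$person_id)]
    stopifnot(all(bp < bc))
  }
  g
}

# person-year household segments; internal to emit_snapshots
.household_segments <- function(persons, config) {
  p <- persons
  rownames(p) <- p$person_id
  alive_to <- pmin(p$death_year - 1L, config$end_year)
  names(alive_to) <- p$person_id
  ext_to <- function(id) {
    # last year the owner couple of household `H<id>` has a living member
    w <- p[id, "spouse_id"]
    max(p[id, "death_year"], if (!is.na(w)) p[w, "death_year"] else -Inf) - 1L
  }
  segs <- vector("list", 4L * nrow(p)); ns <- 0L
  seg <- function(person, from, to, hh, role, owner_m, owner_w) {
    if (from > to) return(invisible(NULL))
    ns <<- ns + 1L
    if (ns > length(segs)) length(segs) <<- 2L * ns
    segs[[ns]] <<- list(person, from, to, hh, role, owner_m, owner_w)
    invisible(NULL)
  }
  for (k in seq_len(nrow(p))) {
    id <- p$person_id[k]
    b <- p$birth_year[k]; d_to <- alive_to[[id]]
    marr <- p$marriage_year[k]
    f <- p$father_id[k]; m <- p$mother_id[k]
    child_to <- min(d_to,
                    b + config$household_split_age - 1L,
                    if (!is.na(marr)) marr - 1L else Inf)
    if (!is.na(f)) {
      child_to <- min(child_to,
                      max(p[f, "death_year"], p[m, "death_year"]) - 1L)
      # parents in the grandparents' household during their extended window
      fe <- isTRUE(p[f, "extended"]) && !is.na(p[f, "father_id"])
      gwin_to <- -Inf
      if (fe) {
        gf <- p[f, "father_id"]
        gwin_to <- min(p[f, "marriage_year"] + config$extended_years - 1L,
                       ext_to(gf))
        gm <- p[f, "mother_id"]
        seg(id, b, min(child_to, gwin_to), paste0("H", gf), "grandchild",
            gf, gm)
      }
      seg(id, max(b, gwin_to + 1L), child_to, paste0("H", f), "child", f, m)
      # singleton years between leaving the parental household and marriage
      # (or death, when never married)
      single_to <- min(d_to, if (!is.na(marr)) marr - 1L else Inf)
      seg(id, child_to + 1L, single_to, paste0("S", id), "single", id,
          NA_character_)
    } else {
      # founders and married-in spouses before marriage: own household
      seg(id, b, min(d_to, if (!is.na(marr)) marr - 1L else Inf),
          paste0("S", id), "single", id, NA_character_)
    }
    if (!is.na(marr)) {
      sp <- p$spouse_id[k]
      husband <- if (p$sex[k] == "M") id else sp
      wife <- if (p$sex[k] == "M") sp else id
      own_from <- marr
      ext_flag <- isTRUE(p[husband, "extended"]) && !is.na(p[husband, "father_id"])
      if (ext_flag) {
        gf <- p[husband, "father_id"]; gm <- p[husband, "mother_id"]
        win_to <- min(marr + config$extended_years - 1L, ext_to(gf), d_to)
        role <- if (id == husband) "son" else "son_wife"
        seg(id, marr, win_to, paste0("H", gf), role, gf, gm)
        own_from <- max(marr, win_to + 1L)
      }
      seg(id, own_from, d_to, paste0("H", husband),
          if (id == husband) "owner_m" else "owner_w", husband, wife)
    }
  }
  if (ns == 0L) return(NULL)
  segs <- segs[seq_len(ns)]
  data.frame(person_id = vapply(segs, `[[`, character(1), 1L),
             from = vapply(segs, function(s) as.numeric(s[[2L]]), numeric(1)),
             to = vapply(segs, function(s) as.numeric(s[[3L]]), numeric(1)),
             hh_id = vapply(segs, `[[`, character(1), 4L),
             role = vapply(segs, `[[`, character(1), 5L),
             owner_m = vapply(segs, `[[`, character(1), 6L),
             owner_w = vapply(segs, function(s)
               if (is.na(s[[7L]])) NA_character_ else s[[7L]], character(1)),
             stringsAsFactors = FALSE)
}

#' Emit yearly household and insurance-unit snapshots
#'
#' Renders the simulated population as yearly rosters from both sources.
#' Household ids and membership are identical across sources (the insurance
#' unit mirrors the household); what differs is observability: each source
#' only has rows from its start year on, rows before that survive with
#' probability `record_coverage_before_start`, and a person who died before
#' a source's start year never appears in that source at all.
#'
#' @param persons,graph from [simulate_population()].
#' @param config the [sim_config()].
#' @return a snapshot data.frame
#'   (`unit_id,person_id,relation_to_head,year,source`).
#' @export
emit_snapshots <- function(persons, graph, config) {
  segs <- .household_segments(persons, config)
  if (is.null(segs)) {
    return(data.frame(unit_id = character(), person_id = character(),
                      relation_to_head = character(), year = integer(),
                      source = character(), stringsAsFactors = FALSE))
  }
  segs <- segs[segs$to >= segs$from, , drop = FALSE]
  n_y <- as.integer(segs$to - segs$from + 1L)
  rows <- data.frame(
    person_id = rep(segs$person_id, n_y),
    year = as.integer(unlist(Map(seq, segs$from, segs$to))),
    hh_id = rep(segs$hh_id, n_y),
    role = rep(segs$role, n_y),
    owner_m = rep(segs$owner_m, n_y),
    owner_w = rep(segs$owner_w, n_y),
    stringsAsFactors = FALSE)
  death <- stats::setNames(persons$death_year, persons$person_id)
  sex <- stats::setNames(persons$sex, persons$person_id)
  alive <- function(id, y) !is.na(id) & y < death[id]
  head_id <- ifelse(alive(rows$owner_m, rows$year), rows$owner_m,
                    ifelse(alive(rows$owner_w, rows$year), rows$owner_w,
                           NA_character_))
  keep <- !is.na(head_id)
  rows <- rows[keep, , drop = FALSE]; head_id <- head_id[keep]
  hsex <- sex[head_id]; msex <- sex[rows$person_id]
  self <- rows$person_id == head_id
  rel <- character(nrow(rows))
  rel[self] <- paste0("0I", hsex[self])
  tail_for <- function(role, i) {
    switch(role,
           owner_m = , owner_w = paste0("0O", msex[i]),
           child = paste0("1D", msex[i]),
           son = "1DM",
           son_wife = "1DM0OW",
           grandchild = paste0("1DM1D", msex[i]),
           single = "")
  }
  for (i in which(!self)) {
    rel[i] <- paste0("0I", hsex[i], tail_for(rows$role[i], i))
  }
  out <- list()
  for (src in c("eligibility", "register")) {
    start <- if (src == "eligibility") config$eligibility_start_year else
      config$register_start_year
    prefix <- if (src == "eligibility") "E" else "R"
    never <- names(death)[death < start]       # died before electronization
    ok <- !(rows$person_id %in% never)
    pre <- rows$year < start
    if (config$record_coverage_before_start <= 0) {
      ok <- ok & !pre
    } else if (config$record_coverage_before_start < 1) {
      drop <- pre & stats::runif(nrow(rows)) >= config$record_coverage_before_start
      ok <- ok & !drop
    }
    sel <- which(ok & rows$year <= config$end_year)
    out[[src]] <- data.frame(unit_id = paste0(prefix, rows$hh_id[sel]),
                             person_id = rows$person_id[sel],
                             relation_to_head = rel[sel],
                             year = rows$year[sel],
                             source = src, stringsAsFactors = FALSE)
  }
  res <- rbind(out$eligibility, out$register)
  rownames(res) <- NULL
  res
}

# sample ICD-10 codes uniformly within a range like c("I10", "I15")
.sample_icd <- function(n, range) {
  lo <- as.integer(substr(range[1L], 2L, 3L))
  hi <- as.integer(substr(range[2L], 2L, 3L))
  num <- .runif_int(n, lo, hi)
  suffix <- ifelse(stats::runif(n) < 0.5, "",
                   as.character(.runif_int(n, 0L, 9L)))
  paste0(substr(range[1L], 1L, 1L), sprintf("%02d", num), suffix)
}

#' Simulate disease status and claims rows
#'
#' Disease status is a per-person Bernoulli draw with probability equal to
#' the age-group base prevalence, multiplied by the parental relative risk
#' (capped at 1) when at least one biological parent is affected; parents
#' are always drawn before children (generation order).  Every affected
#' person emits at least one claims row satisfying the disease's case
#' definition (code range plus medication, admission, or admission with
#' primary diagnosis); unaffected persons may emit decoy rows that carry an
#' in-range code but fail the required flags.
#'
#' @param persons,graph from [simulate_population()].
#' @param config the [sim_config()].
#' @param decoy_rate expected decoy rows per person (default 0.1).
#' @return list with `claims` (data.frame
#'   `person_id,year,icd10,admission,medication,primary_dx`) and `status`
#'   (data.frame of true affected flags, one logical column per disease).
#' @export
simulate_claims <- function(persons, graph, config, decoy_rate = 0.1) {
  ref <- config$end_year
  age <- ref - persons$birth_year
  grp <- as.character(pmin(85L, 5L * (pmax(age, 0L) %/% 5L)))
  status <- data.frame(person_id = persons$person_id, stringsAsFactors = FALSE)
  claims <- list()
  fidx <- match(persons$father_id, persons$person_id)
  midx <- match(persons$mother_id, persons$person_id)
  for (dn in names(config$disease_params)) {
    dp <- config$disease_params[[dn]]
    base <- unname(dp$base_prevalence[grp])
    aff <- logical(nrow(persons))
    for (g in sort(unique(persons$generation))) {
      sel <- persons$generation == g
      par_aff <- (!is.na(fidx[sel]) & aff[fidx[sel]]) |
        (!is.na(midx[sel]) & aff[midx[sel]])
      pr <- pmin(1, base[sel] * ifelse(par_aff, dp$parental_rr, 1))
      aff[sel] <- stats::runif(sum(sel)) < pr
    }
    status[[dn]] <- aff
    # claim rows for the affected
    who <- which(aff & persons$death_year >= config$eligibility_start_year)
    if (length(who) > 0L) {
      nrow_i <- 1L + stats::rpois(length(who), 0.5)
      idx <- rep(who, nrow_i)
      yr_lo <- pmax(config$eligibility_start_year, persons$birth_year[idx] + 1L)
      yr_hi <- pmin(ref, persons$death_year[idx])
      year <- yr_lo + floor(stats::runif(length(idx)) * pmax(1L, yr_hi - yr_lo + 1L))
      year <- pmin(year, ref)
      med <- dp$requires == "medication"
      adm <- dp$requires %in% c("admission", "admission_primary")
      claims[[paste0(dn, ".case")]] <- data.frame(
        person_id = persons$person_id[idx], year = year,
        icd10 = .sample_icd(length(idx), dp$code_range),
        admission = adm | stats::runif(length(idx)) < 0.3,
        medication = med | stats::runif(length(idx)) < 0.2,
        primary_dx = if (dp$requires == "admission_primary") TRUE else
          stats::runif(length(idx)) < 0.8,
        stringsAsFactors = FALSE)
    }
    # decoy rows: in-range code, failing flags
    n_dec <- stats::rpois(1L, decoy_rate * nrow(persons))
    if (n_dec > 0L) {
      idx <- sample.int(nrow(persons), n_dec, replace = TRUE)
      claims[[paste0(dn, ".decoy")]] <- data.frame(
        person_id = persons$person_id[idx],
        year = .runif_int(n_dec, config$eligibility_start_year, ref),
        icd10 = .sample_icd(n_dec, dp$code_range),
        admission = dp$requires == "medication",
        medication = FALSE,
        primary_dx = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  claims <- if (length(claims)) do.call(rbind, claims) else
    data.frame(person_id = character(), year = integer(), icd10 = character(),
               admission = logical(), medication = logical(),
               primary_dx = logical(), stringsAsFactors = FALSE)
  rownames(claims) <- NULL
  list(claims = claims, status = status)
}
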