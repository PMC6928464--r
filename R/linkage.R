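# Household / insurance-unit linkage ------------------------------------------
#
# The source data are yearly rosters of units (resident-register households
# and health-insurance units) that record, for each member, only their
# relationship to the unit head as a family code read head -> member.  This
# module turns two such sources into pedigree edges, comparing and
# complementing them: direct head-member relations of first degree or less
# become edges; the one member-member pattern that can be made determinate
# (unit head's spouse vs unit head's child, resolved by parental-age
# plausibility) is inferred; everything else is left to the expansion step.

.SOURCES <- c("eligibility", "register")

#' Relationship between two members of the same unit
#'
#' Given the head's relation codes to members A and B, derives A's relation
#' to B by inverting the first code and composing it with the second,
#' reducing the result.  Ambiguity (e.g. head's son vs head's daughter:
#' sibling, or self when sexes allow) is propagated.
#'
#' @param head_rel_a,head_rel_b family codes (or strings) read head to
#'   member; both must share the same head self prefix.
#' @param sex_a sex of member A, required when `head_rel_a` ends in `X`.
#' @return a [reduction_result()] for the code A to B.
#' @examples
#' member_pair_code("0IM1DM", "0IM1DW")  # head's son vs head's daughter
#' @export
member_pair_code <- function(head_rel_a, head_rel_b, sex_a = NULL) {
  a <- as_family_code(head_rel_a); b <- as_family_code(head_rel_b)
  if (.atom_sex(unclass(a)[1L]) != .atom_sex(unclass(b)[1L])) {
    stop("the two relation codes name different head self prefixes",
         call. = FALSE)
  }
  inv <- invert_code(a, family_sex = sex_a)
  compose_codes(inv, b)
}

.validate_snapshots <- function(snapshots) {
  need <- c("unit_id", "person_id", "relation_to_head", "year", "source")
  stopifnot(all(need %in% names(snapshots)))
  snapshots$unit_id <- as.character(snapshots$unit_id)
  snapshots$person_id <- as.character(snapshots$person_id)
  snapshots$year <- as.integer(snapshots$year)
  ok <- snapshots$source %in% .SOURCES
  snapshots$.reject <- ifelse(ok, NA_character_, "unknown source")
  # relation strings repeat heavily: parse each distinct one once
  uniq <- unique(snapshots$relation_to_head[is.na(snapshots$.reject)])
  utail <- integer(length(uniq)); uerr <- rep(NA_character_, length(uniq))
  for (k in seq_along(uniq)) {
    code <- tryCatch(parse_code(uniq[k]),
                     error = function(e) simpleError(conditionMessage(e)))
    if (inherits(code, "error")) {
      uerr[k] <- conditionMessage(code); utail[k] <- NA_integer_
    } else {
      utail[k] <- length(unclass(code)) - 1L
    }
  }
  m <- match(snapshots$relation_to_head, uniq)
  snapshots$.tail_len <- utail[m]
  bad <- is.na(snapshots$.reject) & !is.na(uerr[m])
  snapshots$.reject[bad] <- uerr[m][bad]
  snapshots
}

# per-(unit, year, source) head checks; groups without exactly one head row
# are rejected wholesale
.flag_headless <- function(snaps) {
  key <- paste(snaps$unit_id, snaps$year, snaps$source, sep = "\r")
  is_head <- !is.na(snaps$.tail_len) & snaps$.tail_len == 0L
  heads <- tapply(is_head, key, sum)
  bad <- names(heads)[heads != 1L]
  idx <- is.na(snaps$.reject) & key %in% bad
  snaps$.reject[idx] <- "unit-year without exactly one head"
  snaps
}

#' Infer pedigree edges from membership snapshots
#'
#' Builds a [pedigree()] over `persons` from roster snapshots of both
#' sources.  Direct head-member relations of a single first-degree-or-less
#' atom (parent, child, spouse, step variants) become edges.  The head's
#' spouse is additionally linked to each of the head's children, as a
#' biological parent when the spouse's age at the child's birth lies within
#' `parental_age` and as a step parent otherwise.  In three-generation
#' rosters, members coded through a child of the head (a grandchild
#' `0IM1DM1DM`, a child-in-law `0IM1DM0OW`) are linked to that child when
#' exactly one co-resident child of the head matches the intermediate atom;
#' otherwise the relation stays undetermined.  Evidence accumulates over
#' years and sources; when the two sources disagree on the same pair the
#' resident register takes precedence and the disagreement is logged.
#' Malformed rows are rejected per row, never fatally.
#'
#' @param snapshots data.frame with columns
#'   `unit_id,person_id,relation_to_head,year,source`.
#' @param persons data.frame with `person_id,sex,birth_year` (extra columns
#'   kept).
#' @param parental_age length-2 numeric, plausible age of a biological
#'   parent at the child's birth (default `c(15, 70)`).
#' @return list with components `graph` (the pedigree), and `report`: a list
#'   with `edges_added`, `edges` (with provenance), `conflicts` and
#'   `rejects` data.frames.
#' @export
infer_edges <- function(snapshots, persons, parental_age = c(15, 70)) {
  snaps <- .validate_snapshots(as.data.frame(snapshots))
  snaps <- .flag_headless(snaps)
  rejects <- snaps[!is.na(snaps$.reject),
                   c("unit_id", "person_id", "year", "source", ".reject")]
  names(rejects)[5L] <- "reason"
  snaps <- snaps[is.na(snaps$.reject), , drop = FALSE]
  # exact-duplicate rows collapse
  snaps <- snaps[!duplicated(snaps[c("unit_id", "person_id",
                                     "relation_to_head", "year", "source")]), ]

  persons <- as.data.frame(persons)
  persons$person_id <- as.character(persons$person_id)
  byear <- stats::setNames(suppressWarnings(as.integer(persons$birth_year)),
                           persons$person_id)
  psex <- stats::setNames(as.character(persons$sex), persons$person_id)

  # evidence rows: one per (pair, type, bond, source, year, basis)
  ev <- list(); n_ev <- 0L
  note <- function(type, p1, p2, bond, source, year, basis) {
    if (type == "spouse" && p1 > p2) { tmp <- p1; p1 <- p2; p2 <- tmp }
    n_ev <<- n_ev + 1L
    ev[[n_ev]] <<- data.frame(type = type, p1 = p1, p2 = p2, bond = bond,
                              source = source, year = year, basis = basis,
                              stringsAsFactors = FALSE)
  }

  # roster compositions repeat across years; extract evidence from one
  # representative year per distinct (unit, source, composition)
  dtt <- data.table::as.data.table(
    snaps[c("unit_id", "person_id", "relation_to_head", "year", "source",
            ".tail_len")])
  data.table::setorder(dtt, unit_id, source, year, person_id)
  dtt[, comp := paste0(person_id, ":", relation_to_head, collapse = "|"),
      by = c("unit_id", "year", "source")]
  dtt[, ryear := min(year), by = c("unit_id", "source", "comp")]
  reps <- as.data.frame(dtt[year == ryear])

  key <- paste(reps$unit_id, reps$year, reps$source, sep = "\r")
  for (grp in split(seq_len(nrow(reps)), key)) {
    g <- reps[grp, ]
    head_row <- g[g$.tail_len == 0L, ]
    head_id <- head_row$person_id[1L]
    src <- g$source[1L]; yr <- g$year[1L]
    members <- g[g$.tail_len > 0L, , drop = FALSE]
    spouse_ids <- character(); child_ids <- character()
    grandchildren <- list(); inlaws <- list()
    bond_by_age <- function(p_id, c_id) {
      bp <- byear[p_id]; bc <- byear[c_id]
      plausible <- !is.na(bp) && !is.na(bc) &&
        (bc - bp) >= parental_age[1L] && (bc - bp) <= parental_age[2L]
      if (plausible) "biological" else "step"
    }
    for (k in seq_len(nrow(members))) {
      atoms <- unclass(parse_code(members$relation_to_head[k]))
      m_id <- members$person_id[k]
      if (length(atoms) == 2L) {
        pair <- .atom_pair(atoms[2L])
        if (pair == "1A") note("parent", m_id, head_id, "biological", src, yr, "head-member")
        else if (pair == "1a") note("parent", m_id, head_id, "step", src, yr, "head-member")
        else if (pair == "1D") { note("parent", head_id, m_id, "biological", src, yr, "head-member"); child_ids <- c(child_ids, m_id) }
        else if (pair == "1d") { note("parent", head_id, m_id, "step", src, yr, "head-member"); child_ids <- c(child_ids, m_id) }
        else if (pair == "0O") { note("spouse", head_id, m_id, "spouse", src, yr, "head-member"); spouse_ids <- c(spouse_ids, m_id) }
      } else if (length(atoms) == 3L) {
        pairs <- .atom_pair(atoms[2:3])
        if (pairs[1L] == "1D" && pairs[2L] == "1D") {
          grandchildren[[length(grandchildren) + 1L]] <-
            list(id = m_id, via_sex = .atom_sex(atoms[2L]))
        } else if (pairs[1L] == "1D" && pairs[2L] == "0O") {
          inlaws[[length(inlaws) + 1L]] <-
            list(id = m_id, via_sex = .atom_sex(atoms[2L]))
        }
      }
    }
    # head's spouse x head's child: parent or step parent by parental age
    for (s_id in spouse_ids) {
      for (c_id in child_ids) {
        note("parent", s_id, c_id, bond_by_age(s_id, c_id),
             src, yr, "spouse-child-inference")
      }
    }
    # three-generation rosters: a member coded through the head's child
    # (son's son, son's wife, ...) is resolved only when exactly one
    # co-resident child of the head matches the intermediate atom
    if (length(grandchildren) > 0L || length(inlaws) > 0L) {
      pivot_for <- function(via_sex) {
        cand <- child_ids[via_sex == "X" | psex[child_ids] == via_sex]
        if (length(cand) == 1L) cand else NA_character_
      }
      gc_parent <- character()
      for (gc in grandchildren) {
        pv <- pivot_for(gc$via_sex)
        if (!is.na(pv)) {
          note("parent", pv, gc$id, bond_by_age(pv, gc$id),
               src, yr, "grandchild-inference")
          gc_parent[gc$id] <- pv
        }
      }
      for (il in inlaws) {
        pv <- pivot_for(il$via_sex)
        if (is.na(pv)) next
        note("spouse", pv, il$id, "spouse", src, yr, "in-law-inference")
        # the in-law spouse is parent to grandchildren resolved to the
        # same pivot
        for (gid in names(gc_parent)[gc_parent == pv]) {
          note("parent", il$id, gid, bond_by_age(il$id, gid),
               src, yr, "in-law-inference")
        }
      }
    }
  }

  graph <- pedigree(persons)
  conflicts <- list(); n_cf <- 0L
  edge_rows <- list(); n_er <- 0L
  if (n_ev > 0L) {
    evd <- do.call(rbind, ev[seq_len(n_ev)])
    # one decision per unordered pair
    lo <- pmin(evd$p1, evd$p2); hi <- pmax(evd$p1, evd$p2)
    for (grp in split(seq_len(nrow(evd)), paste(lo, hi, sep = "\r"))) {
      e <- evd[grp, ]
      variants <- unique(e[c("type", "p1", "p2", "bond")])
      if (nrow(variants) > 1L) {
        # register precedence, then evidence count, then head-member basis
        score <- vapply(seq_len(nrow(variants)), function(v) {
          sel <- e$type == variants$type[v] & e$p1 == variants$p1[v] &
            e$p2 == variants$p2[v] & e$bond == variants$bond[v]
          sum(e$source[sel] == "register") * 1e6 + sum(sel) +
            any(e$basis[sel] == "head-member") * 1e3
        }, numeric(1))
        win <- which.max(score)
        n_cf <- n_cf + 1L
        conflicts[[n_cf]] <- data.frame(
          person_a = e$p1[1L], person_b = e$p2[1L],
          relations = paste(apply(variants, 1L, paste, collapse = ":"),
                            collapse = " | "),
          resolution = paste(unlist(variants[win, ]), collapse = ":"),
          stringsAsFactors = FALSE)
        variants <- variants[win, , drop = FALSE]
      }
      basis_sel <- e$type == variants$type[1L] & e$p1 == variants$p1[1L] &
        e$p2 == variants$p2[1L] & e$bond == variants$bond[1L]
      res <- tryCatch({
        if (variants$type[1L] == "spouse") {
          graph <- add_spouse_edge(graph, variants$p1[1L], variants$p2[1L])
        } else {
          graph <- add_parent_edge(graph, variants$p1[1L], variants$p2[1L],
                                   bond = variants$bond[1L])
        }
        NULL
      }, error = function(err) conditionMessage(err))
      if (is.null(res)) {
        n_er <- n_er + 1L
        edge_rows[[n_er]] <- data.frame(
          type = variants$type[1L], p1 = variants$p1[1L], p2 = variants$p2[1L],
          bond = variants$bond[1L],
          basis = paste(sort(unique(e$basis[basis_sel])), collapse = "+"),
          sources = paste(sort(unique(e$source[basis_sel])), collapse = "+"),
          stringsAsFactors = FALSE)
      } else {
        rejects <- rbind(rejects, data.frame(
          unit_id = NA_character_, person_id = variants$p1[1L],
          year = NA_integer_, source = NA_character_, reason = res,
          stringsAsFactors = FALSE))
      }
    }
  }
  edges <- if (n_er > 0L) do.call(rbind, edge_rows[seq_len(n_er)]) else
    data.frame(type = character(), p1 = character(), p2 = character(),
               bond = character(), basis = character(), sources = character(),
               stringsAsFactors = FALSE)
  conflicts <- if (n_cf > 0L) do.call(rbind, conflicts[seq_len(n_cf)]) else
    data.frame(person_a = character(), person_b = character(),
               relations = character(), resolution = character(),
               stringsAsFactors = FALSE)
  rownames(rejects) <- NULL
  list(graph = graph,
       report = list(edges_added = n_er, edges = edges,
                     conflicts = conflicts, rejects = rejects))
}

# unordered pair -> HHRR code for all pairs ever sharing a unit, by source
.hhrr_pair_table <- function(snapshots) {
  dt <- data.table::as.data.table(snapshots[c("unit_id", "person_id", "year",
                                              "source")])
  dt[, `:=`(unit_id = as.character(unit_id),
            person_id = as.character(person_id))]
  pairs_for <- function(src) {
    d <- unique(dt[source == src, .(unit_id, year, person_id)])
    j <- d[d, on = .(unit_id, year), allow.cartesian = TRUE]
    j <- j[person_id < i.person_id]
    unique(j[, .(lo = person_id, hi = i.person_id)])
  }
  reg <- pairs_for("register"); reg[, in_reg := TRUE]
  eli <- pairs_for("eligibility"); eli[, in_eli := TRUE]
  m <- merge(reg, eli, by = c("lo", "hi"), all = TRUE)
  m[, hhrr_cd := ifelse(!is.na(in_reg) & !is.na(in_eli), 1L,
                        ifelse(!is.na(in_reg), 2L, 3L))]
  as.data.frame(m[, .(lo, hi, hhrr_cd)])
}

#' Shared household / insurance-unit history of a pair (HHRR code)
#'
#' `1` when the pair has ever shared both a resident-register household and a
#' health-insurance unit, `2` household only, `3` insurance unit only,
#' `NA` when they were never co-members.
#'
#' @param snapshots membership snapshot data.frame.
#' @param person_a,person_b person ids.
#' @return integer code or `NA_integer_`.
#' @export
membership_history <- function(snapshots, person_a, person_b) {
  person_a <- as.character(person_a); person_b <- as.character(person_b)
  lo <- min(person_a, person_b); hi <- max(person_a, person_b)
  tab <- .hhrr_pair_table(snapshots)
  idx <- which(tab$lo == lo & tab$hi == hi)
  if (length(idx) == 0L) NA_integer_ else tab$hhrr_cd[idx[1L]]
}

#' Read membership snapshots from CSV
#'
#' Columns: `unit_id,person_id,relation_to_head,year,source`.
#' @param file path.
#' @export
read_snapshots <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE,
                  colClasses = c(unit_id = "character",
                                 person_id = "character",
                                 relation_to_head = "character"))
}

#' Write membership snapshots to CSV
#'
#' @param snapshots data.frame.
#' @param file path.
#' @export
write_snapshots <- function(snapshots, file) {
  utils::write.csv(snapshots, file, row.names = FALSE)
  invisible(snapshots)
}

#' Write a linkage report as JSON lines
#'
#' One JSON object per line: a summary line, then one line per inferred edge,
#' conflict and rejected row.
#'
#' @param report the `report` component of [infer_edges()].
#' @param file path.
#' @export
write_linkage_report <- function(report, file) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(kind = "summary",
                                   edges_added = report$edges_added,
                                   conflicts = nrow(report$conflicts),
                                   rejects = nrow(report$rejects)),
                              auto_unbox = TRUE), con)
  emit_df <- function(df, kind) {
    for (k in seq_len(nrow(df))) {
      row <- as.list(df[k, ])
      row$kind <- kind
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, na = "null"), con)
    }
  }
  emit_df(report$edges, "edge")
  emit_df(report$conflicts, "conflict")
  emit_df(report$rejects, "reject")
  invisible(report)
}
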