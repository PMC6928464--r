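# Kinship expansion ------------------------------------------------------------
#
# Enumerates, for every person, all kin reachable within a bounded degree of
# kinship, selects one canonical relationship path per pair, renders it as a
# family code, and emits family-tree records in both directions with the
# standard column layout:
# TG_ID, FMLY_ID, TG_SEX_TYPE, TG_BYEAR, FMLY_SEX_TYPE, FMLY_BYEAR,
# FMLY_CD, FMLY_DGR, FMLY_TYPE, HHRR_CD.
#
# Kinship paths are simple paths over parent-child edges (one degree each)
# and spouse edges (zero degrees), with two structural exclusions: a child
# step never immediately followed by a parent step (the child's other parent
# is a co-parent, not kin along that path; when co-parents are married the
# spouse edge carries the relationship) and no two consecutive spouse steps
# (a spouse's spouse is never determinate from the graph).

FAMILY_TREE_COLUMNS <- c("TG_ID", "FMLY_ID", "TG_SEX_TYPE", "TG_BYEAR",
                         "FMLY_SEX_TYPE", "FMLY_BYEAR", "FMLY_CD", "FMLY_DGR",
                         "FMLY_TYPE", "HHRR_CD")

# indexed adjacency for fast traversal
.expansion_index <- function(graph) {
  ids <- graph$persons$person_id
  n <- length(ids)
  pe <- graph$parent_edges; se <- graph$spouse_edges
  pi <- match(pe$parent_id, ids); ci <- match(pe$child_id, ids)
  ai <- match(se$a_id, ids); bi <- match(se$b_id, ids)
  empty_int <- vector("list", n)
  mk <- function(from, to, lab = NULL) {
    out <- empty_int
    if (length(from) > 0L) {
      sp <- split(seq_along(from), from)
      for (k in names(sp)) out[[as.integer(k)]] <- sp[[k]]
    }
    out
  }
  list(
    ids = ids, n = n,
    sex = graph$persons$sex,
    byear = suppressWarnings(as.integer(graph$persons$birth_year)),
    # row indices of parent_edges grouped by child (ups) and parent (downs)
    up_rows = mk(ci), down_rows = mk(pi),
    pe_parent = pi, pe_child = ci, pe_bond = pe$bond,
    sp_nbr = {
      out <- empty_int
      if (length(ai) > 0L) {
        from <- c(ai, bi); to <- c(bi, ai)
        sp <- split(to, from)
        for (k in names(sp)) out[[as.integer(k)]] <- sp[[k]]
      }
      out
    }
  )
}

# DFS over kinship paths from one subject.  Returns a list of paths, each
# list(nodes = int vector incl. subject, moves, bonds, degree, n_spouse,
# n_step).
.paths_from <- function(ix, subject, max_degree, max_spouse) {
  acc <- vector("list", 64L); n_acc <- 0L
  push <- function(p) {
    n_acc <<- n_acc + 1L
    if (n_acc > length(acc)) length(acc) <<- 2L * n_acc
    acc[[n_acc]] <<- p
  }
  recurse <- function(nodes, moves, bonds, deg, nsp) {
    cur <- nodes[length(nodes)]
    last <- if (length(moves)) moves[length(moves)] else ""
    # up steps
    if (last != "down" && deg < max_degree) {
      for (r in ix$up_rows[[cur]]) {
        nxt <- ix$pe_parent[r]
        if (nxt %in% nodes) next
        nn <- c(nodes, nxt); mm <- c(moves, "up"); bb <- c(bonds, ix$pe_bond[r])
        ns <- nsp
        push(list(nodes = nn, moves = mm, bonds = bb, degree = deg + 1L,
                  n_spouse = ns))
        recurse(nn, mm, bb, deg + 1L, ns)
      }
    }
    # down steps
    if (deg < max_degree) {
      for (r in ix$down_rows[[cur]]) {
        nxt <- ix$pe_child[r]
        if (nxt %in% nodes) next
        nn <- c(nodes, nxt); mm <- c(moves, "down"); bb <- c(bonds, ix$pe_bond[r])
        push(list(nodes = nn, moves = mm, bonds = bb, degree = deg + 1L,
                  n_spouse = nsp))
        recurse(nn, mm, bb, deg + 1L, nsp)
      }
    }
    # spouse steps
    if (last != "spouse" && nsp < max_spouse) {
      for (nxt in ix$sp_nbr[[cur]]) {
        if (nxt %in% nodes) next
        nn <- c(nodes, nxt); mm <- c(moves, "spouse"); bb <- c(bonds, "spouse")
        push(list(nodes = nn, moves = mm, bonds = bb, degree = deg,
                  n_spouse = nsp + 1L))
        recurse(nn, mm, bb, deg, nsp + 1L)
      }
    }
    invisible(NULL)
  }
  recurse(subject, character(), character(), 0L, 0L)
  if (n_acc == 0L) list() else acc[seq_len(n_acc)]
}

# family-code atoms for an indexed path; sibling pivots (up immediately
# followed by down) contract to a single 2A/2D/2U atom ordered by the birth
# years of the two siblings
.path_atoms <- function(ix, nodes, moves, bonds) {
  sex_of <- function(i) {
    s <- ix$sex[i]
    if (is.na(s) || !s %in% c("M", "W")) "X" else s
  }
  subj_sex <- ix$sex[nodes[1L]]
  if (is.na(subj_sex) || !subj_sex %in% c("M", "W")) return(NULL)
  atoms <- paste0("0I", subj_sex)
  has_step <- FALSE; has_adoptive <- FALSE
  k <- 1L
  while (k <= length(moves)) {
    stepbond <- bonds[k]
    if (stepbond == "step") has_step <- TRUE
    if (stepbond == "adoptive") has_adoptive <- TRUE
    if (moves[k] == "up" && k < length(moves) && moves[k + 1L] == "down") {
      if (bonds[k + 1L] == "step") has_step <- TRUE
      if (bonds[k + 1L] == "adoptive") has_adoptive <- TRUE
      me <- nodes[k]; sib <- nodes[k + 2L]
      b1 <- ix$byear[me]; b2 <- ix$byear[sib]
      pair <- if (is.na(b1) || is.na(b2) || b1 == b2) "2U"
              else if (b2 < b1) "2A" else "2D"
      atoms <- c(atoms, paste0(pair, sex_of(sib)))
      k <- k + 2L
    } else if (moves[k] == "up") {
      pair <- if (stepbond == "step") "1a" else "1A"
      atoms <- c(atoms, paste0(pair, sex_of(nodes[k + 1L])))
      k <- k + 1L
    } else if (moves[k] == "down") {
      pair <- if (stepbond == "step") "1d" else "1D"
      atoms <- c(atoms, paste0(pair, sex_of(nodes[k + 1L])))
      k <- k + 1L
    } else {
      atoms <- c(atoms, paste0("0O", sex_of(nodes[k + 1L])))
      k <- k + 1L
    }
  }
  list(atoms = atoms, has_step = has_step, has_adoptive = has_adoptive)
}

.reverse_moves <- c(up = "down", down = "up", spouse = "spouse")

.reverse_path <- function(p) {
  list(nodes = rev(p$nodes),
       moves = unname(.reverse_moves[rev(p$moves)]),
       bonds = rev(p$bonds),
       degree = p$degree, n_spouse = p$n_spouse)
}

#' Enumerate kinship paths from a subject
#'
#' All simple kinship paths from `subject_id` with degree of kinship at most
#' `max_degree`.  Parent-child steps contribute one degree, spouse steps
#' zero.  Paths never take a parent step immediately after a child step (the
#' co-parent pivot) nor two spouse steps in a row, and carry at most
#' `max_spouse_edges` spouse steps.
#'
#' @param graph a [pedigree()].
#' @param subject_id an existing person id.
#' @param max_degree maximum degree of kinship (default 4).
#' @param max_spouse_edges maximum spouse steps per path (default 1; affinal
#'   relationships stay first-order).
#' @return a list of `relationship_path` objects, each with `person_ids`,
#'   `moves` (`up`/`down`/`spouse`), `bonds` and `degree`.
#' @export
enumerate_paths <- function(graph, subject_id, max_degree = 4L,
                            max_spouse_edges = 1L) {
  stopifnot(inherits(graph, "pedigree"))
  subject_id <- as.character(subject_id)
  .check_person(graph, subject_id)
  ix <- .expansion_index(graph)
  s <- match(subject_id, ix$ids)
  raw <- .paths_from(ix, s, max_degree, max_spouse_edges)
  lapply(raw, function(p) {
    structure(list(person_ids = ix$ids[p$nodes], moves = p$moves,
                   bonds = p$bonds, degree = p$degree),
              class = "relationship_path")
  })
}

#' Render a relationship path as a family code
#'
#' Parent steps become `1A`/`1a` atoms, child steps `1D`/`1d`, spouse steps
#' `0O`; a parent step immediately followed by a child step (a pivot through
#' a shared parent to another child) contracts to a sibling atom, `2A` when
#' the kin-side sibling was born earlier than the subject-side sibling, `2D`
#' when later, `2U` on ties or unknown birth years.  Gender letters are taken
#' from the persons reached (`X` when unknown).
#'
#' @param path a `relationship_path` from [enumerate_paths()].
#' @param graph the [pedigree()] it was computed on.
#' @return a [family_code()].
#' @export
path_to_code <- function(path, graph) {
  stopifnot(inherits(path, "relationship_path"), inherits(graph, "pedigree"))
  ix <- .expansion_index(graph)
  nodes <- match(path$person_ids, ix$ids)
  res <- .path_atoms(ix, nodes, path$moves, path$bonds)
  if (is.null(res)) {
    stop("subject sex unknown: cannot build a self atom", call. = FALSE)
  }
  family_code(res$atoms)
}

#' Select the canonical path among alternatives for one pair
#'
#' Deterministic minimum over (degree, number of spouse steps, number of step
#' bonds, code string).
#'
#' @param paths non-empty list of `relationship_path`s between the same pair.
#' @param graph the [pedigree()].
#' @return the single winning `relationship_path`.
#' @export
select_canonical <- function(paths, graph) {
  stopifnot(length(paths) >= 1L)
  if (length(paths) == 1L) return(paths[[1L]])
  key <- vapply(paths, function(p) {
    code <- format_code(path_to_code(p, graph))
    sprintf("%02d|%02d|%02d|%s", p$degree, sum(p$moves == "spouse"),
            sum(p$bonds == "step"), code)
  }, character(1))
  paths[[order(key)[1L]]]
}

#' Expand a pedigree into family-tree records
#'
#' For every unordered pair of persons within `max_degree` degrees of
#' kinship, selects one canonical relationship path and emits two directed
#' records (subject to family member and its inverse) in the standard family
#' tree layout.  `FMLY_DGR` is the degree of kinship (0 for spouses, 1-4
#' otherwise), `FMLY_TYPE` the family-type code (C1/C2 blood, A0 spouse,
#' A1/A2 affinal, R1 adoptive), and `HHRR_CD` the shared household /
#' insurance-unit history computed from `snapshots` when given (1 both
#' sources, 2 household only, 3 insurance unit only, `NA` never co-members).
#'
#' Persons of unknown sex cannot head a family code and are skipped as
#' subjects.
#'
#' @param graph a [pedigree()].
#' @param snapshots optional membership snapshot data.frame (see
#'   [membership_history()]).
#' @param max_degree maximum degree of kinship (default 4).
#' @param max_spouse_edges maximum spouse steps per path (default 1).
#' @param close_threshold degree boundary for close vs non-close family types
#'   (default 2).
#' @return a data.frame with columns `r FAMILY_TREE_COLUMNS`, sorted by
#'   `TG_ID`, `FMLY_ID`.
#' @export
expand_all <- function(graph, snapshots = NULL, max_degree = 4L,
                       max_spouse_edges = 1L, close_threshold = 2L) {
  stopifnot(inherits(graph, "pedigree"))
  ix <- .expansion_index(graph)
  hh <- if (!is.null(snapshots)) .hhrr_pair_table(snapshots) else NULL
  ord <- order(ix$ids)
  tg <- character(); fm <- character(); cd <- character(); dg <- integer()
  ft <- character()
  out <- vector("list", 4096L); n_out <- 0L
  emit <- function(subject, target, code, degree, ftype) {
    n_out <<- n_out + 1L
    if (n_out > length(out)) length(out) <<- 2L * n_out
    out[[n_out]] <<- c(subject, target, code, degree, ftype)
  }
  for (s in ord) {
    paths <- .paths_from(ix, s, max_degree, max_spouse_edges)
    if (length(paths) == 0L) next
    targets <- vapply(paths, function(p) p$nodes[length(p$nodes)], integer(1))
    keep <- ix$ids[targets] > ix$ids[s]      # canonical direction: lower id first
    paths <- paths[keep]; targets <- targets[keep]
    if (length(paths) == 0L) next
    for (t in unique(targets)) {
      cand <- paths[targets == t]
      best <- NULL; best_key <- NULL; best_fwd <- NULL
      for (p in cand) {
        fwd <- .path_atoms(ix, p$nodes, p$moves, p$bonds)
        if (is.null(fwd)) next
        key <- sprintf("%02d|%02d|%02d|%s", p$degree, p$n_spouse,
                       sum(p$bonds == "step"), paste0(fwd$atoms, collapse = ""))
        if (is.null(best_key) || key < best_key) {
          best <- p; best_key <- key; best_fwd <- fwd
        }
      }
      if (is.null(best)) next
      rp <- .reverse_path(best)
      rev_atoms <- .path_atoms(ix, rp$nodes, rp$moves, rp$bonds)
      fcode <- paste0(best_fwd$atoms, collapse = "")
      ftype <- classify_family_type(family_code(best_fwd$atoms),
                                    has_step = best_fwd$has_step,
                                    has_adoptive = best_fwd$has_adoptive,
                                    close_threshold = close_threshold)
      emit(s, t, fcode, best$degree, ftype)
      if (!is.null(rev_atoms)) {
        emit(t, s, paste0(rev_atoms$atoms, collapse = ""), best$degree, ftype)
      }
    }
  }
  if (n_out == 0L) {
    rec <- data.frame(TG_ID = character(), FMLY_ID = character(),
                      TG_SEX_TYPE = character(), TG_BYEAR = integer(),
                      FMLY_SEX_TYPE = character(), FMLY_BYEAR = integer(),
                      FMLY_CD = character(), FMLY_DGR = integer(),
                      FMLY_TYPE = character(), HHRR_CD = integer(),
                      stringsAsFactors = FALSE)
    return(rec)
  }
  m <- matrix(unlist(out[seq_len(n_out)]), ncol = 5L, byrow = TRUE)
  si <- as.integer(m[, 1L]); ti <- as.integer(m[, 2L])
  rec <- data.frame(
    TG_ID = ix$ids[si], FMLY_ID = ix$ids[ti],
    TG_SEX_TYPE = ix$sex[si], TG_BYEAR = ix$byear[si],
    FMLY_SEX_TYPE = ix$sex[ti], FMLY_BYEAR = ix$byear[ti],
    FMLY_CD = m[, 3L], FMLY_DGR = as.integer(m[, 4L]),
    FMLY_TYPE = m[, 5L], HHRR_CD = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (!is.null(hh) && nrow(hh) > 0L) {
    lo <- pmin(rec$TG_ID, rec$FMLY_ID); hi <- pmax(rec$TG_ID, rec$FMLY_ID)
    idx <- match(paste(lo, hi, sep = "\r"), paste(hh$lo, hh$hi, sep = "\r"))
    rec$HHRR_CD <- hh$hhrr_cd[idx]
  }
  rec <- rec[order(rec$TG_ID, rec$FMLY_ID), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Write family-tree records to CSV
#'
#' @param records data.frame from [expand_all()].
#' @param file output path.
#' @export
write_family_tree <- function(records, file) {
  stopifnot(all(FAMILY_TREE_COLUMNS %in% names(records)))
  utils::write.csv(records[FAMILY_TREE_COLUMNS], file, row.names = FALSE,
                   na = "")
  invisible(records)
}

#' Read family-tree records from CSV
#'
#' @param file path to a CSV written by [write_family_tree()].
#' @export
read_family_tree <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE,
                  colClasses = c(TG_ID = "character", FMLY_ID = "character",
                                 FMLY_CD = "character"))
}
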