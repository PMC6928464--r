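# Pedigree graph --------------------------------------------------------------
#
# Persons plus typed parent-child edges (biological / step / adoptive) and
# unordered spouse edges.  Sibling relationships are never stored; they are
# derived from shared biological parents.

.BONDS <- c("biological", "step", "adoptive")

#' Create an empty pedigree
#'
#' @param persons optional data.frame with columns `person_id`, `sex`
#'   (M/W/X), `birth_year` (integer or NA); extra columns (e.g. `death_year`)
#'   are kept.
#' @return an object of class `pedigree` with components `persons`,
#'   `parent_edges` (`parent_id`, `child_id`, `bond`) and `spouse_edges`
#'   (`a_id`, `b_id`).
#' @export
pedigree <- function(persons = NULL) {
  g <- structure(list(
    persons = data.frame(person_id = character(), sex = character(),
                         birth_year = integer(), stringsAsFactors = FALSE),
    parent_edges = data.frame(parent_id = character(), child_id = character(),
                              bond = character(), stringsAsFactors = FALSE),
    spouse_edges = data.frame(a_id = character(), b_id = character(),
                              stringsAsFactors = FALSE)
  ), class = "pedigree")
  if (!is.null(persons)) {
    stopifnot(all(c("person_id", "sex", "birth_year") %in% names(persons)))
    persons$person_id <- as.character(persons$person_id)
    if (anyDuplicated(persons$person_id)) {
      stop("duplicate person_id in persons", call. = FALSE)
    }
    if (!all(persons$sex %in% c("M", "W", "X"))) {
      stop("sex must be one of M/W/X", call. = FALSE)
    }
    g$persons <- as.data.frame(persons, stringsAsFactors = FALSE)
  }
  g
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d persons, %d parent edges, %d spouse edges\n",
              nrow(x$persons), nrow(x$parent_edges), nrow(x$spouse_edges)))
  invisible(x)
}

.check_person <- function(graph, id) {
  if (!id %in% graph$persons$person_id) {
    stop(sprintf("unknown person id '%s'", id), call. = FALSE)
  }
}

#' Add a person to a pedigree
#'
#' @param graph a `pedigree`.
#' @param person_id unique identifier.
#' @param sex one of `"M" "W" "X"`.
#' @param birth_year integer year or `NA`.
#' @param ... further person attributes stored as columns.
#' @return the updated `pedigree`.
#' @export
add_person <- function(graph, person_id, sex = "X", birth_year = NA_integer_, ...) {
  stopifnot(inherits(graph, "pedigree"), sex %in% c("M", "W", "X"))
  person_id <- as.character(person_id)
  if (person_id %in% graph$persons$person_id) {
    stop(sprintf("person '%s' already exists", person_id), call. = FALSE)
  }
  row <- data.frame(person_id = person_id, sex = sex,
                    birth_year = as.integer(birth_year), ...,
                    stringsAsFactors = FALSE)
  for (col in setdiff(names(graph$persons), names(row))) row[[col]] <- NA
  for (col in setdiff(names(row), names(graph$persons))) graph$persons[[col]] <- NA
  graph$persons <- rbind(graph$persons, row[names(graph$persons)])
  graph
}

# TRUE if `descendant` is reachable from `ancestor` going down biological edges
.is_bio_descendant <- function(edges, ancestor, descendant) {
  frontier <- ancestor
  seen <- character()
  while (length(frontier) > 0L) {
    kids <- edges$child_id[edges$parent_id %in% frontier &
                             edges$bond == "biological"]
    kids <- setdiff(kids, seen)
    if (descendant %in% kids) return(TRUE)
    seen <- c(seen, kids)
    frontier <- kids
  }
  FALSE
}

#' Add a parent-child edge
#'
#' Idempotent for duplicates.  Rejects self-edges, a third biological parent,
#' cycles in biological parentage, and a biological parent not born before
#' the child when both birth years are known.
#'
#' @param graph a `pedigree`.
#' @param parent_id,child_id existing person ids.
#' @param bond `"biological"` (default), `"step"` or `"adoptive"`.
#' @return the updated `pedigree`.
#' @export
add_parent_edge <- function(graph, parent_id, child_id, bond = "biological") {
  stopifnot(inherits(graph, "pedigree"), bond %in% .BONDS)
  parent_id <- as.character(parent_id); child_id <- as.character(child_id)
  .check_person(graph, parent_id); .check_person(graph, child_id)
  if (parent_id == child_id) stop("self parent edge", call. = FALSE)
  e <- graph$parent_edges
  if (any(e$parent_id == parent_id & e$child_id == child_id & e$bond == bond)) {
    return(graph)                       # duplicate: no-op
  }
  if (bond == "biological") {
    n_bio <- sum(e$child_id == child_id & e$bond == "biological")
    if (n_bio >= 2L) {
      stop(sprintf("'%s' already has two biological parents", child_id),
           call. = FALSE)
    }
    if (.is_bio_descendant(e, child_id, parent_id)) {
      stop(sprintf("edge %s -> %s would create a biological-parentage cycle",
                   parent_id, child_id), call. = FALSE)
    }
    by <- function(id) graph$persons$birth_year[graph$persons$person_id == id]
    bp <- by(parent_id); bc <- by(child_id)
    if (!is.na(bp) && !is.na(bc) && bp >= bc) {
      stop(sprintf("biological parent '%s' (born %d) not older than child '%s' (born %d)",
                   parent_id, bp, child_id, bc), call. = FALSE)
    }
  }
  graph$parent_edges <- rbind(e, data.frame(parent_id = parent_id,
                                            child_id = child_id, bond = bond,
                                            stringsAsFactors = FALSE))
  graph
}

#' Add a spouse edge (unordered)
#'
#' @param graph a `pedigree`.
#' @param a_id,b_id existing, distinct person ids.
#' @return the updated `pedigree`.
#' @export
add_spouse_edge <- function(graph, a_id, b_id) {
  stopifnot(inherits(graph, "pedigree"))
  a_id <- as.character(a_id); b_id <- as.character(b_id)
  .check_person(graph, a_id); .check_person(graph, b_id)
  if (a_id == b_id) stop("self spouse edge", call. = FALSE)
  lo <- pmin(a_id, b_id); hi <- pmax(a_id, b_id)
  e <- graph$spouse_edges
  if (any(e$a_id == lo & e$b_id == hi)) return(graph)
  graph$spouse_edges <- rbind(e, data.frame(a_id = lo, b_id = hi,
                                            stringsAsFactors = FALSE))
  graph
}

#' Siblings of a person
#'
#' Persons sharing at least one biological parent with `person_id`, excluding
#' the person themselves.  Full siblings share two parents, half siblings one.
#'
#' @param graph a `pedigree`.
#' @param person_id an existing person id.
#' @return data.frame with columns `person_id`, `shared_parent_count`.
#' @export
siblings_of <- function(graph, person_id) {
  stopifnot(inherits(graph, "pedigree"))
  person_id <- as.character(person_id)
  .check_person(graph, person_id)
  e <- graph$parent_edges[graph$parent_edges$bond == "biological", ]
  my_parents <- e$parent_id[e$child_id == person_id]
  sibs <- e[e$parent_id %in% my_parents & e$child_id != person_id, ]
  if (nrow(sibs) == 0L) {
    return(data.frame(person_id = character(), shared_parent_count = integer(),
                      stringsAsFactors = FALSE))
  }
  counts <- table(sibs$child_id)
  data.frame(person_id = names(counts),
             shared_parent_count = as.integer(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}

# undirected weighted adjacency used by the oracle only
.oracle_adjacency <- function(graph) {
  pe <- graph$parent_edges; se <- graph$spouse_edges
  from <- c(pe$parent_id, pe$child_id, se$a_id, se$b_id)
  to <- c(pe$child_id, pe$parent_id, se$b_id, se$a_id)
  w <- c(rep(1L, 2L * nrow(pe)), rep(0L, 2L * nrow(se)))
  split(data.frame(to = to, w = w, stringsAsFactors = FALSE), from)
}

#' Brute-force kinship distance oracle
#'
#' Exhaustive simple-path search between two persons, counting one degree per
#' parent-child edge and zero per spouse edge, returning the minimum total
#' weight if it does not exceed `max_degree` and `NA` otherwise.  This is an
#' intentionally naive reference computation, independent of the production
#' expansion code, meant for testing.
#'
#' @param graph a `pedigree`.
#' @param a_id,b_id existing person ids.
#' @param max_degree prune bound (default 4).
#' @return integer distance or `NA_integer_`.
#' @examples
#' g <- pedigree(data.frame(person_id = c("p", "c"), sex = c("M", "W"),
#'                          birth_year = c(1950L, 1980L)))
#' g <- add_parent_edge(g, "p", "c")
#' kinship_distance_oracle(g, "p", "c")  # 1
#' @export
kinship_distance_oracle <- function(graph, a_id, b_id, max_degree = 4L) {
  stopifnot(inherits(graph, "pedigree"))
  a_id <- as.character(a_id); b_id <- as.character(b_id)
  .check_person(graph, a_id); .check_person(graph, b_id)
  if (a_id == b_id) return(0L)
  adj <- .oracle_adjacency(graph)
  best <- Inf
  visit <- function(node, weight, visited) {
    nb <- adj[[node]]
    if (is.null(nb)) return(invisible(NULL))
    for (k in seq_len(nrow(nb))) {
      nxt <- nb$to[k]; w <- weight + nb$w[k]
      if (w > max_degree || w >= best || nxt %in% visited) next
      if (nxt == b_id) {
        best <<- w
      } else {
        visit(nxt, w, c(visited, nxt))
      }
    }
    invisible(NULL)
  }
  visit(a_id, 0L, a_id)
  if (is.infinite(best)) NA_integer_ else as.integer(best)
}

#' Read a pedigree from persons and edges CSV files
#'
#' Persons CSV: `person_id,sex,birth_year` (extra columns kept).  Edges CSV:
#' `type,parent_or_a,child_or_b,bond` where `type` is `parent` or `spouse`.
#'
#' @param persons_file,edges_file paths.
#' @return a `pedigree`.
#' @export
read_pedigree <- function(persons_file, edges_file) {
  persons <- utils::read.csv(persons_file, stringsAsFactors = FALSE,
                             colClasses = c(person_id = "character"))
  g <- pedigree(persons)
  edges <- utils::read.csv(edges_file, stringsAsFactors = FALSE,
                           colClasses = "character")
  for (k in seq_len(nrow(edges))) {
    if (edges$type[k] == "parent") {
      g <- add_parent_edge(g, edges$parent_or_a[k], edges$child_or_b[k],
                           bond = edges$bond[k])
    } else {
      g <- add_spouse_edge(g, edges$parent_or_a[k], edges$child_or_b[k])
    }
  }
  g
}

#' Write a pedigree to persons and edges CSV files
#'
#' @param graph a `pedigree`.
#' @param persons_file,edges_file output paths.
#' @export
write_pedigree <- function(graph, persons_file, edges_file) {
  stopifnot(inherits(graph, "pedigree"))
  utils::write.csv(graph$persons, persons_file, row.names = FALSE)
  pe <- graph$parent_edges; se <- graph$spouse_edges
  edges <- rbind(
    data.frame(type = rep("parent", nrow(pe)), parent_or_a = pe$parent_id,
               child_or_b = pe$child_id, bond = pe$bond,
               stringsAsFactors = FALSE),
    data.frame(type = rep("spouse", nrow(se)), parent_or_a = se$a_id,
               child_or_b = se$b_id, bond = NA_character_,
               stringsAsFactors = FALSE)
  )
  utils::write.csv(edges, edges_file, row.names = FALSE)
  invisible(graph)
}
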