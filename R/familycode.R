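# Family-code algebra ---------------------------------------------------------
#
# A family code is a sequence of three-character basic codes read left to right
# from a subject toward one of their kin.  Each atom is
#   <degree digit><relation letter><gender letter>
# where the degree digit counts degrees of kinship (chon) contributed by the
# step, the relation letter distinguishes self/spouse/parent/child/sibling
# (lowercase a/d mark step relations) and the gender letter is the sex of the
# person reached by the step.  Every code starts with a self atom (0IM / 0IW).

.VALID_PAIRS <- c("0I", "0O", "1A", "1D", "2A", "2D", "2U", "1a", "1d")
.VALID_SEX <- c("M", "W", "X")

.atom_pair <- function(a) substring(a, 1L, 2L)
.atom_deg <- function(a) as.integer(substring(a, 1L, 1L))
.atom_rel <- function(a) substring(a, 2L, 2L)
.atom_sex <- function(a) substring(a, 3L, 3L)

.sex_compatible <- function(s1, s2) s1 == s2 | s1 == "X" | s2 == "X"
.sex_merge <- function(s1, s2) ifelse(s1 == "X", s2, s1)

#' Construct a family code from basic-code atoms
#'
#' @param atoms character vector of three-character basic codes, the first of
#'   which must be a self atom (`"0IM"` or `"0IW"`).
#' @return an object of class `family_code` (a character vector of atoms).
#' @examples
#' family_code(c("0IM", "1AM"))   # a man's father
#' @export
family_code <- function(atoms) {
  code <- structure(as.character(atoms), class = "family_code")
  validate_family_code(code)
  code
}

validate_family_code <- function(code) {
  atoms <- unclass(code)
  if (length(atoms) < 1L) {
    stop("a family code needs at least the self atom", call. = FALSE)
  }
  for (i in seq_along(atoms)) {
    a <- atoms[i]
    off <- (i - 1L) * 3L
    if (nchar(a) != 3L || !(.atom_pair(a) %in% .VALID_PAIRS) ||
        !(.atom_sex(a) %in% .VALID_SEX)) {
      stop(sprintf("invalid basic code '%s' at offset %d", a, off),
           call. = FALSE)
    }
  }
  if (.atom_pair(atoms[1L]) != "0I" || !(.atom_sex(atoms[1L]) %in% c("M", "W"))) {
    stop(sprintf("family code must start with 0IM or 0IW, got '%s'", atoms[1L]),
         call. = FALSE)
  }
  if (length(atoms) > 1L && any(.atom_pair(atoms[-1L]) == "0I")) {
    i <- which(.atom_pair(atoms) == "0I")[2L]
    stop(sprintf("self atom '%s' at offset %d is only allowed in first position",
                 atoms[i], (i - 1L) * 3L), call. = FALSE)
  }
  invisible(code)
}

#' Coerce to a family code
#'
#' Strings are parsed with [parse_code()]; `family_code` objects pass through.
#' @param x a code string or `family_code`.
#' @export
as_family_code <- function(x) {
  if (inherits(x, "family_code")) return(x)
  parse_code(x)
}

#' Parse a family-code string
#'
#' Splits a concatenated code string such as `"0IM1AM1AW"` into its basic-code
#' atoms and validates it: every triple must be a known (degree, relation)
#' pair with gender M/W/X, the first atom must be a gendered self atom, and no
#' self atom may appear later.
#'
#' @param text a code string whose length is a positive multiple of 3.
#' @return a [family_code()].
#' @examples
#' parse_code("0IM1AM")      # father, seen from a man
#' parse_code("0IM1AM1AW")   # paternal grandmother
#' @export
parse_code <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("expected a single code string", call. = FALSE)
  }
  n <- nchar(text)
  if (n == 0L || n %% 3L != 0L) {
    stop(sprintf("code string length must be a positive multiple of 3, got %d", n),
         call. = FALSE)
  }
  atoms <- substring(text, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  family_code(atoms)
}

#' Format a family code as a string
#'
#' Inverse of [parse_code()]: `parse_code(format_code(x))` is identical to `x`.
#' @param code a `family_code` (or code string).
#' @return the concatenated code string.
#' @export
format_code <- function(code) {
  paste0(unclass(as_family_code(code)), collapse = "")
}

#' @export
format.family_code <- function(x, ...) format_code(x)

#' @export
print.family_code <- function(x, ...) {
  cat("<family_code> ", format_code(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.family_code <- function(x, ...) format_code(x)

# index (in full atom vector) of the first atom of the first contractible
# adjacent tail pair, or 0L if the code is reduced
.find_contractible <- function(atoms) {
  if (length(atoms) < 3L) return(0L)
  for (i in 2L:(length(atoms) - 1L)) {
    p <- .atom_pair(atoms[i]); q <- .atom_pair(atoms[i + 1L])
    if ((p == "1A" && q == "1D") || (p == "1D" && q == "1A") ||
        (p == "0O" && q == "0O") ||
        (.atom_deg(atoms[i]) == 2L && .atom_deg(atoms[i + 1L]) == 2L)) {
      return(i)
    }
  }
  0L
}

#' Degree of kinship of a family code
#'
#' Sums the degree digits of all atoms after the self prefix: parent/child
#' steps (including step relations) count one degree, sibling steps two,
#' spouse steps zero.  The code must be reduced; a code still containing a
#' contractible adjacent pair (such as parent-then-child) has no well-defined
#' degree and raises an error.
#'
#' @param code a `family_code` or code string.
#' @return integer degree of kinship (0 for self and spouse).
#' @examples
#' degree_of("0IM1AM")      # 1 (parent)
#' degree_of("0IW2AM")      # 2 (older brother)
#' degree_of("0IM0OW1AM")   # 1 (spouse's father; the spouse step adds 0)
#' @export
degree_of <- function(code) {
  code <- as_family_code(code)
  atoms <- unclass(code)
  i <- .find_contractible(atoms)
  if (i > 0L) {
    stop(sprintf("code '%s' contains contractible pair '%s%s'; reduce_code() it first",
                 format_code(code), atoms[i], atoms[i + 1L]), call. = FALSE)
  }
  if (length(atoms) == 1L) return(0L)
  sum(.atom_deg(atoms[-1L]))
}

.INVERT_REL <- c("1A" = "1D", "1D" = "1A", "1a" = "1d", "1d" = "1a",
                 "2A" = "2D", "2D" = "2A", "2U" = "2U", "0O" = "0O")

#' Invert a family code
#'
#' Returns the code naming the subject as seen from the family member: the
#' self prefix takes the family member's sex, the remaining atoms are the
#' original tail reversed with every relation inverted (parent and child
#' swap, older and younger sibling swap, spouse and undifferentiated sibling
#' are self-inverse) and gender letters reassigned so each atom carries the
#' sex of the person reached along the reversed chain.  Inversion is an
#' involution when both endpoint sexes are known.
#'
#' @param code a `family_code` or code string.
#' @param subject_sex sex of the subject, `"M"` or `"W"`; defaults to the
#'   code's own self atom.
#' @param family_sex sex of the family member, `"M"` or `"W"`; defaults to the
#'   code's terminal gender letter, which must then not be `"X"`.
#' @return the inverted `family_code`.
#' @examples
#' invert_code("0IM1AM")                 # "0IM1DM": my father sees me as a son
#' invert_code("0IM1AM1AW")              # grandmother's son's son
#' @export
invert_code <- function(code, subject_sex = NULL, family_sex = NULL) {
  code <- as_family_code(code)
  atoms <- unclass(code)
  if (is.null(subject_sex)) subject_sex <- .atom_sex(atoms[1L])
  if (!(subject_sex %in% c("M", "W"))) {
    stop("subject_sex must be 'M' or 'W'", call. = FALSE)
  }
  term_sex <- .atom_sex(atoms[length(atoms)])
  if (is.null(family_sex)) family_sex <- term_sex
  if (!(family_sex %in% c("M", "W"))) {
    stop("family_sex must be 'M' or 'W' (a self atom cannot carry X)",
         call. = FALSE)
  }
  if (!.sex_compatible(term_sex, family_sex)) {
    stop(sprintf("terminal gender '%s' of '%s' is incompatible with family_sex '%s'",
                 term_sex, format_code(code), family_sex), call. = FALSE)
  }
  n <- length(atoms) - 1L               # tail length
  if (n == 0L) return(family_code(paste0("0I", family_sex)))
  # sexes along the original chain: g[1] = subject, g[i + 1] = person after step i
  g <- c(subject_sex, .atom_sex(atoms[-1L]))
  g[n + 1L] <- family_sex
  out <- character(n + 1L)
  out[1L] <- paste0("0I", family_sex)
  for (j in seq_len(n)) {
    k <- n + 1L - j                     # original step being reversed
    out[j + 1L] <- paste0(.INVERT_REL[[.atom_pair(atoms[k + 1L])]], g[k])
  }
  family_code(out)
}

#' Reduction result
#'
#' @param code the canonical reduced `family_code`.
#' @param ambiguous logical; `TRUE` when the relationship cannot be determined
#'   uniquely from the code alone.
#' @param alternatives list of realizable reduced `family_code` alternatives;
#'   non-empty exactly when `ambiguous` is `TRUE`.
#' @export
reduction_result <- function(code, ambiguous, alternatives = list()) {
  stopifnot(is.logical(ambiguous), length(ambiguous) == 1L)
  if (!ambiguous && length(alternatives) > 0L) {
    stop("an unambiguous reduction cannot carry alternatives", call. = FALSE)
  }
  structure(list(code = code, ambiguous = ambiguous, alternatives = alternatives),
            class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  cat("<reduction_result> ", format_code(x$code),
      if (x$ambiguous) " (ambiguous)" else "", "\n", sep = "")
  if (x$ambiguous) {
    cat("  alternatives: ",
        paste(vapply(x$alternatives, format_code, character(1)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# One rewrite step on atoms at tail pair (i, i+1) (full-vector indices).
# Returns a list of candidate atom vectors; attribute "forced" marks branches
# created by the spouse-of-spouse rule, which stays ambiguous even when it
# leaves a single alternative (monogamy is not assumed).
.contract_branches <- function(atoms, i) {
  p <- .atom_pair(atoms[i]); q <- .atom_pair(atoms[i + 1L])
  s_before <- .atom_sex(atoms[i - 1L])
  s2 <- .atom_sex(atoms[i + 1L])
  out <- list()
  drop_pair <- function() {
    # collapsing the pair identifies the person after it with the person
    # before it; their sexes must be compatible
    if (!.sex_compatible(s_before, s2)) return(NULL)
    new <- atoms[-c(i, i + 1L)]
    merged <- .sex_merge(s_before, s2)
    new[i - 1L] <- paste0(.atom_pair(new[i - 1L]), merged)
    new
  }
  replace_pair <- function(pair) {
    c(atoms[seq_len(i - 1L)], paste0(pair, s2),
      if (i + 1L < length(atoms)) atoms[(i + 2L):length(atoms)])
  }
  forced <- FALSE
  if (p == "1A" && q == "1D") {                 # parent's child: self or sibling
    out <- list(drop_pair(), replace_pair("2U"))
  } else if (p == "1D" && q == "1A") {
    # child's other parent: the spouse atom is only a stand-in (co-parents
    # need not be married), so this contraction is never determinate
    out <- list(drop_pair(), replace_pair("0O"))
    forced <- TRUE
  } else if (p == "0O" && q == "0O") {          # spouse's spouse
    out <- list(drop_pair())
    forced <- TRUE
  } else {                                      # sibling's sibling
    out <- list(drop_pair(), replace_pair("2U"))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  attr(out, "forced") <- forced
  out
}

#' Reduce a family code
#'
#' Applies the identity-blind contraction rules exhaustively: a parent step
#' followed by a child step may collapse to self or contract to a sibling; a
#' child step followed by a parent step may collapse to self or name a
#' co-parent (spouse atom); a spouse step followed by a spouse step collapses
#' to self but remains flagged ambiguous (monogamy is not assumed); two
#' adjacent sibling steps collapse to self or contract to a sibling.  A
#' self-collapse alternative is kept only when it is realizable, i.e. the
#' sexes of the identified persons are compatible.  A code with no
#' contractible adjacent pair is returned unchanged and unambiguous.
#'
#' @param code a `family_code` or code string.
#' @return a [reduction_result()].
#' @examples
#' reduce_code("0IM1AM1AW")  # already reduced: unchanged, unambiguous
#' reduce_code("0IM1AM1DX")  # father's child: self or sibling (ambiguous)
#' @export
reduce_code <- function(code) {
  code <- as_family_code(code)
  terminals <- new.env(parent = emptyenv())
  recurse <- function(atoms, forced) {
    i <- .find_contractible(atoms)
    if (i == 0L) {
      key <- paste0(atoms, collapse = "")
      prev <- terminals[[key]]
      terminals[[key]] <- list(atoms = atoms,
                               forced = forced || isTRUE(prev$forced))
      return(invisible(NULL))
    }
    branches <- .contract_branches(atoms, i)
    f <- forced || attr(branches, "forced")
    for (b in branches) recurse(b, f)
    invisible(NULL)
  }
  recurse(unclass(code), FALSE)
  keys <- sort(ls(terminals))
  if (length(keys) == 0L) {
    # every branch unrealizable: degenerate; return the input flagged ambiguous
    return(reduction_result(code, TRUE, list(code)))
  }
  alts <- lapply(keys, function(k) family_code(terminals[[k]]$atoms))
  forced_any <- any(vapply(keys, function(k) terminals[[k]]$forced, logical(1)))
  ambiguous <- length(alts) > 1L || forced_any
  # canonical representative: fewest atoms, then lexicographic
  ord <- order(lengths(alts), vapply(alts, format_code, character(1)))
  canon <- alts[[ord[1L]]]
  if (!ambiguous) {
    reduction_result(canon, FALSE)
  } else {
    reduction_result(canon, TRUE, alts[ord])
  }
}

#' Compose two family codes
#'
#' Given a code from A to B and a code from B to C, concatenates A→B with the
#' tail of B→C and reduces the result, yielding the extended relationship
#' A→C.  The terminal gender of the first code must be compatible with the
#' self prefix of the second (they name the same person, B).
#'
#' @param code_ab,code_bc `family_code`s or code strings.
#' @return a [reduction_result()]; ambiguity from reduction is propagated.
#' @examples
#' compose_codes("0IM1AM", "0IM1AW")  # father's mother = paternal grandmother
#' @export
compose_codes <- function(code_ab, code_bc) {
  a <- unclass(as_family_code(code_ab))
  b <- unclass(as_family_code(code_bc))
  term <- .atom_sex(a[length(a)])
  self_b <- .atom_sex(b[1L])
  if (!.sex_compatible(term, self_b)) {
    stop(sprintf("terminal gender '%s' of '%s' does not match self prefix '%s' of '%s'",
                 term, paste0(a, collapse = ""), b[1L], paste0(b, collapse = "")),
         call. = FALSE)
  }
  if (term == "X" && length(a) > 1L) {
    # the pivot person is the same individual in both codes; adopt the
    # more specific sex
    a[length(a)] <- paste0(.atom_pair(a[length(a)]), self_b)
  }
  reduce_code(family_code(c(a, b[-1L])))
}

#' Classify the kinship category of a reduced code
#'
#' One of `SELF`, `SPOUSE` (tail is a single spouse atom), `AFFINAL` (any
#' other tail containing a spouse atom), `DIRECT_ANCESTOR` (all parent or
#' step-parent atoms), `DIRECT_DESCENDANT` (all child or step-child atoms),
#' or `COLLATERAL_BLOOD`.
#'
#' @param code a reduced `family_code` or code string.
#' @return a length-one character category.
#' @examples
#' classify_category("0IM1AM1AW")  # "DIRECT_ANCESTOR"
#' classify_category("0IM0OW")     # "SPOUSE"
#' @export
classify_category <- function(code) {
  code <- as_family_code(code)
  atoms <- unclass(code)
  if (.find_contractible(atoms) > 0L) {
    stop(sprintf("code '%s' is not reduced", format_code(code)), call. = FALSE)
  }
  tail <- .atom_pair(atoms[-1L])
  if (length(tail) == 0L) return("SELF")
  if (length(tail) == 1L && tail == "0O") return("SPOUSE")
  if (any(tail == "0O")) return("AFFINAL")
  if (all(tail %in% c("1A", "1a"))) return("DIRECT_ANCESTOR")
  if (all(tail %in% c("1D", "1d"))) return("DIRECT_DESCENDANT")
  "COLLATERAL_BLOOD"
}

#' Family type (FMLY_TYPE) of a relationship
#'
#' Maps a reduced code to the family-type code list of the family tree
#' database: `R1` adoptive parent or child; `A0` spouse; `A1`/`A2` close and
#' non-close relatives by affinity; `C1`/`C2` close and non-close blood
#' relatives.  "Close" means degree of kinship at most `close_threshold`.
#' `A3` (old-law affinity) is accepted in data but never produced.
#'
#' @param code a reduced `family_code` or code string.
#' @param has_step logical; the relationship path involves a step bond
#'   (carried as metadata; step relations classify with their blood analogue).
#' @param has_adoptive logical; the relationship path involves an adoptive
#'   bond.
#' @param close_threshold integer; degree boundary between close and
#'   non-close, default 2.
#' @return one of `"C1" "C2" "A0" "A1" "A2" "R1"`.
#' @export
classify_family_type <- function(code, has_step = FALSE, has_adoptive = FALSE,
                                 close_threshold = 2L) {
  stopifnot(close_threshold >= 1L)
  code <- as_family_code(code)
  if (has_adoptive) return("R1")
  cat <- classify_category(code)
  if (cat == "SELF") {
    stop("a self code has no family type", call. = FALSE)
  }
  if (cat == "SPOUSE") return("A0")
  deg <- degree_of(code)
  if (cat == "AFFINAL") {
    if (deg <= close_threshold) "A1" else "A2"
  } else {
    if (deg <= close_threshold) "C1" else "C2"
  }
}
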