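test_that("parsing splits code strings into validated atoms", {
  expect_equal(unclass(parse_code("0IM1AM")), c("0IM", "1AM"),
               ignore_attr = TRUE)
  expect_equal(unclass(parse_code("0IW")), "0IW", ignore_attr = TRUE)
  expect_equal(unclass(parse_code("0IM1AM1AW")), c("0IM", "1AM", "1AW"),
               ignore_attr = TRUE)
})

test_that("malformed codes are rejected with the offending triple and offset", {
  expect_error(parse_code("1AM0IM"), "0IM.*offset 3|start with 0IM")
  expect_error(parse_code("0IM1A"), "multiple of 3")
  expect_error(parse_code(""), "multiple of 3")
  expect_error(parse_code("0IM3AM"), "'3AM' at offset 3")
  expect_error(parse_code("0IM1AZ"), "'1AZ' at offset 3")
  expect_error(parse_code("0IX"), "0IM or 0IW")
  expect_error(parse_code("0IM0IW"), "offset 3")
})

test_that("parse and format are inverse over generated codes", {
  set.seed(11)
  pairs <- c("0O", "1A", "1D", "2A", "2D", "2U", "1a", "1d")
  for (k in 1:50) {
    n <- sample(0:4, 1)
    atoms <- c(paste0("0I", sample(c("M", "W"), 1)),
               if (n > 0) paste0(sample(pairs, n, replace = TRUE),
                                 sample(c("M", "W", "X"), n, replace = TRUE)))
    code <- family_code(atoms)
    expect_identical(parse_code(format_code(code)), code)
  }
})

test_that("degree of kinship sums the tail degree digits", {
  expect_equal(degree_of("0IM1AM"), 1L)       # parent: 1st degree
  expect_equal(degree_of("0IW2AM"), 2L)       # older sibling: 2nd degree
  expect_equal(degree_of("0IM1AM1AW"), 2L)    # grandparent
  expect_equal(degree_of("0IM0OW1AM"), 1L)    # spouse's father: spouse adds 0
  expect_equal(degree_of("0IW"), 0L)          # self
  expect_equal(degree_of("0IM0OW"), 0L)       # spouse: zero degree
  expect_equal(degree_of("0IM1aW"), 1L)       # step parent still 1st degree
})

test_that("degree refuses unreduced codes", {
  expect_error(degree_of("0IM1AM1DW"), "reduce_code")
  expect_error(degree_of("0IM0OW0OM"), "reduce_code")
})

test_that("grandparent degree matches a brute-force pedigree oracle", {
  g <- three_generations()
  expect_equal(degree_of("0IM1AM1AW"), kinship_distance_oracle(g, "C", "GM"))
  # spouse's father: mother M -> spouse F -> his father GF
  expect_equal(degree_of("0IW0OM1AM"), kinship_distance_oracle(g, "M", "GF"))
})

test_that("inversion reverses the code with relations and genders remapped", {
  expect_equal(format_code(invert_code("0IM1AM", "M", "M")), "0IM1DM")
  expect_equal(format_code(invert_code("0IM1AM1AW", "M", "W")), "0IW1DM1DM")
  expect_equal(format_code(invert_code("0IW", "W", "W")), "0IW")
  expect_equal(format_code(invert_code("0IM0OW", "M", "W")), "0IW0OM")
  expect_equal(format_code(invert_code("0IW2AM", "W", "M")), "0IM2DW")
})

test_that("inversion agrees with reading the reverse path off a pedigree", {
  g <- three_generations()
  # degree-2 ancestor path C -> F -> GF and its reverse
  anc <- Filter(function(p) identical(p$person_ids, c("C", "F", "GF")),
                enumerate_paths(g, "C", max_degree = 2))[[1]]
  rev <- Filter(function(p) identical(p$person_ids, c("GF", "F", "C")),
                enumerate_paths(g, "GF", max_degree = 2))[[1]]
  expect_equal(format_code(invert_code(path_to_code(anc, g))),
               format_code(path_to_code(rev, g)))
})

test_that("inversion is an involution and preserves degree", {
  set.seed(23)
  pairs <- c("0O", "1A", "1D", "2A", "2D", "2U", "1a", "1d")
  n_checked <- 0
  while (n_checked < 40) {
    n <- sample(1:4, 1)
    atoms <- c(paste0("0I", sample(c("M", "W"), 1)),
               paste0(sample(pairs, n, replace = TRUE),
                      sample(c("M", "W"), n, replace = TRUE)))
    code <- family_code(atoms)
    red <- reduce_code(code)
    if (red$ambiguous || length(unclass(red$code)) == 1L) next
    code <- red$code
    str <- format_code(code)
    s <- substr(str, 3, 3); f <- substr(str, nchar(str), nchar(str))
    inv <- invert_code(code, s, f)
    expect_identical(invert_code(inv, f, s), code)
    expect_equal(degree_of(inv), degree_of(code))
    n_checked <- n_checked + 1
  }
})

test_that("inversion requires a gendered family member for the new self atom", {
  expect_error(invert_code("0IM1DX"), "cannot carry X|family_sex")
  expect_error(invert_code("0IM1AM", family_sex = "W"), "incompatible")
})

test_that("composition concatenates through the shared person and reduces", {
  r <- compose_codes("0IM1AM", "0IM1AW")
  expect_false(r$ambiguous)
  expect_equal(format_code(r$code), "0IM1AM1AW")  # father's mother
  r2 <- compose_codes("0IM", "0IM1AW")            # self is a left identity
  expect_equal(format_code(r2$code), "0IM1AW")
  expect_error(compose_codes("0IM1AM", "0IW1AW"), "does not match")
})

test_that("composing father with his child is ambiguous between self and sibling", {
  r <- compose_codes("0IM1AM", "0IM1DX")
  expect_true(r$ambiguous)
  alts <- sort(vapply(r$alternatives, format_code, character(1)))
  expect_equal(alts, c("0IM", "0IM2UX"))
})

test_that("composition refines an unknown pivot sex from the second code", {
  r <- compose_codes("0IM1AX", "0IM1AW")   # parent of unknown sex, then his mother
  expect_equal(format_code(r$code), "0IM1AM1AW")
})

test_that("reduction keeps only realizable alternatives", {
  # mother's son seen by a man: self (sexes match) or brother
  r1 <- reduce_code("0IM1AW1DM")
  expect_true(r1$ambiguous)
  expect_setequal(vapply(r1$alternatives, format_code, character(1)),
                  c("0IM", "0IM2UM"))
  # mother's daughter seen by a man: self impossible, sibling certain
  r2 <- reduce_code("0IM1AW1DW")
  expect_false(r2$ambiguous)
  expect_equal(format_code(r2$code), "0IM2UW")
  # child's parent: self or co-parent
  r3 <- reduce_code("0IW1DM1AW")
  expect_true(r3$ambiguous)
  expect_setequal(vapply(r3$alternatives, format_code, character(1)),
                  c("0IW", "0IW0OW"))
})

test_that("spouse-of-spouse stays flagged ambiguous without monogamy", {
  r <- reduce_code("0IM0OW0OM")
  expect_true(r$ambiguous)
  expect_equal(vapply(r$alternatives, format_code, character(1)), "0IM")
})

test_that("reduced codes pass through unchanged", {
  for (s in c("0IM1AM1AW", "0IM0OW1AM", "0IW2AM1DW", "0IM")) {
    r <- reduce_code(s)
    expect_false(r$ambiguous)
    expect_equal(format_code(r$code), s)
    expect_length(r$alternatives, 0)
  }
})

test_that("every reduction alternative is realizable on a concrete pedigree", {
  # father's child (0IM1AM1DX): self on a 2-person pedigree, sibling on a
  # 3-person pedigree
  alts <- vapply(reduce_code("0IM1AM1DX")$alternatives, format_code,
                 character(1))
  g_self <- pedigree(data.frame(person_id = c("F", "A"), sex = c("M", "M"),
                                birth_year = c(1950L, 1980L)))
  g_self <- add_parent_edge(g_self, "F", "A")
  expect_equal(kinship_distance_oracle(g_self, "A", "A"), 0L)  # self branch
  g_sib <- nuclear_family()
  rec <- expand_all(g_sib)
  sib_cd <- rec$FMLY_CD[rec$TG_ID == "A" & rec$FMLY_ID == "B"]
  expect_equal(degree_of(sib_cd), degree_of(alts[alts != "0IM"]))
})

test_that("kinship categories follow the reduced tail structure", {
  expect_equal(classify_category("0IM"), "SELF")
  expect_equal(classify_category("0IM0OW"), "SPOUSE")
  expect_equal(classify_category("0IM1AM1AW"), "DIRECT_ANCESTOR")
  expect_equal(classify_category("0IW1DM1DW"), "DIRECT_DESCENDANT")
  expect_equal(classify_category("0IW2AM1DW"), "COLLATERAL_BLOOD")
  expect_equal(classify_category("0IM0OW1AM"), "AFFINAL")
  expect_equal(classify_category("0IM1DW0OM"), "AFFINAL")
  expect_equal(classify_category("0IM1aW"), "DIRECT_ANCESTOR")
})

test_that("family types split by category, adoption, and the close threshold", {
  expect_equal(classify_family_type("0IM1AM"), "C1")
  expect_equal(classify_family_type("0IM0OW"), "A0")
  expect_equal(classify_family_type("0IM1AM", has_adoptive = TRUE), "R1")
  expect_equal(classify_family_type("0IM1AM2AM1DM"), "C2")     # degree 4 blood
  expect_equal(classify_family_type("0IM0OW1AM"), "A1")        # spouse's father
  expect_equal(classify_family_type("0IM0OW1AM2AM"), "A2")     # spouse's uncle
  expect_equal(classify_family_type("0IM1AM1AM", close_threshold = 1L), "C2")
})
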