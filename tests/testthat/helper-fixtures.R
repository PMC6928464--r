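# programmatic fixtures shared across test files

# father F, mother M, son A (1980), daughter B (1983)
nuclear_family <- function() {
  g <- pedigree(data.frame(person_id = c("F", "M", "A", "B"),
                           sex = c("M", "W", "M", "W"),
                           birth_year = c(1950L, 1952L, 1980L, 1983L)))
  g <- add_parent_edge(g, "F", "A")
  g <- add_parent_edge(g, "F", "B")
  g <- add_parent_edge(g, "M", "A")
  g <- add_parent_edge(g, "M", "B")
  add_spouse_edge(g, "F", "M")
}

# paternal line: grandfather GF + grandmother GM -> father F (+ mother M) -> child C
three_generations <- function() {
  g <- pedigree(data.frame(person_id = c("GF", "GM", "F", "M", "C"),
                           sex = c("M", "W", "M", "W", "M"),
                           birth_year = c(1920L, 1922L, 1950L, 1952L, 1980L)))
  g <- add_parent_edge(g, "GF", "F")
  g <- add_parent_edge(g, "GM", "F")
  g <- add_spouse_edge(g, "GF", "GM")
  g <- add_parent_edge(g, "F", "C")
  g <- add_parent_edge(g, "M", "C")
  add_spouse_edge(g, "F", "M")
}

# two sibling parents -> first cousins X and Y
cousin_pedigree <- function() {
  df <- data.frame(
    person_id = c("GF", "GM", "P1", "P2", "S1", "S2", "X", "Y"),
    sex = c("M", "W", "M", "W", "W", "M", "M", "W"),
    birth_year = c(1920L, 1922L, 1950L, 1953L, 1951L, 1950L, 1980L, 1981L))
  g <- pedigree(df)
  g <- add_parent_edge(g, "GF", "P1"); g <- add_parent_edge(g, "GM", "P1")
  g <- add_parent_edge(g, "GF", "P2"); g <- add_parent_edge(g, "GM", "P2")
  g <- add_spouse_edge(g, "GF", "GM")
  g <- add_spouse_edge(g, "P1", "S1"); g <- add_spouse_edge(g, "P2", "S2")
  g <- add_parent_edge(g, "P1", "X"); g <- add_parent_edge(g, "S1", "X")
  g <- add_parent_edge(g, "P2", "Y"); g <- add_parent_edge(g, "S2", "Y")
  g
}

# single line of descent over n generations
chain_pedigree <- function(n = 6L) {
  ids <- paste0("G", seq_len(n))
  g <- pedigree(data.frame(person_id = ids,
                           sex = rep_len(c("M", "W"), n),
                           birth_year = seq(1900L, by = 25L, length.out = n)))
  for (k in seq_len(n - 1L)) g <- add_parent_edge(g, ids[k], ids[k + 1L])
  g
}

# random multi-generation pedigree with at most `max_persons` members;
# deterministic in `seed` (bumps the seed until the size bound holds)
random_pedigree <- function(seed, max_persons = 40L) {
  repeat {
    cfg <- sim_config(seed = seed, n_founder_couples = 2L, n_generations = 3L,
                      fertility = 2.0, marriage_prob = 0.7)
    sim <- simulate_population(cfg)
    if (nrow(sim$persons) <= max_persons) return(sim)
    seed <- seed + 10000L
  }
}
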