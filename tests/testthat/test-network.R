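# Candidate enumeration, stoichiometry and propensity conventions.

# Independent brute-force enumeration of the three candidate forms, written
# without reference to the package's enumeration code.
brute_force_candidates <- function(n) {
  out <- character(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) out <- c(out, paste0(i, ">", j))                    # conversion
    for (k in seq_len(n)) {
      if (i != j && i != k && j != k) {
        out <- c(out, paste0(i, ">", min(j, k), "+", max(j, k)))   # split
        if (i < j) out <- c(out, paste0(i, "+", j, ">", k))        # association
      }
    }
  }
  unique(out)
}

key_of <- function(r) paste0(paste(r$reactants, collapse = "+"), ">",
                             paste(r$products, collapse = "+"))

test_that("enumeration matches brute force for small species sets", {
  for (n in c(3, 4, 5)) {
    lib <- enumerate_candidates(paste0("X", seq_len(n)))
    got <- vapply(lib$network$reactions, key_of, "")
    want <- brute_force_candidates(n)
    expect_setequal(got, want)
    expect_equal(anyDuplicated(got), 0L)
  }
  # counts: 4 species -> 6 conversions + 12 splits + 12 associations
  lib4 <- enumerate_candidates(paste0("X", 1:4))
  expect_length(lib4$network$reactions, 30L)
  nre <- vapply(lib4$network$reactions, function(r)
    paste(length(r$reactants), length(r$products)), "")
  expect_equal(as.integer(table(nre)[c("1 1", "1 2", "2 1")]), c(6L, 12L, 12L))
})

test_that("library size follows the closed-form count and is deterministic", {
  for (n in 3:8) {
    lib <- enumerate_candidates(paste0("s", seq_len(n)))
    expect_length(lib$network$reactions,
                  choose(n, 2) + n * choose(n - 1, 2) + choose(n, 2) * (n - 2))
  }
  a <- enumerate_candidates(paste0("X", 1:6))
  b <- enumerate_candidates(paste0("X", 1:6))
  expect_identical(a, b)
  # two species: the single conversion pair
  expect_length(enumerate_candidates(c("A", "B"))$network$reactions, 1L)
  expect_error(enumerate_candidates("A"), "at least 2")
})

test_that("canonical ordering lists conversions, then splits, then associations", {
  lib <- enumerate_candidates(paste0("X", 1:4))
  sizes <- vapply(lib$network$reactions, function(r)
    c(length(r$reactants), length(r$products)), integer(2))
  expect_equal(sizes[1, 1:6], rep(1L, 6))
  expect_equal(sizes[2, 1:6], rep(1L, 6))
  expect_equal(sizes[2, 7:18], rep(2L, 12))
  expect_equal(sizes[1, 19:30], rep(2L, 12))
})

test_that("module constraints restrict enumeration and append cross reactions", {
  sp <- paste0("X", 1:6)
  mods <- list(a = sp[1:3], b = sp[4:6])
  cross <- list(reaction(1L, 4L), reaction(c(2L, 5L), 6L))
  lib <- enumerate_candidates(sp, modules = mods, cross_reactions = cross)
  per_mod <- choose(3, 2) + 3 * choose(2, 2) + choose(3, 2) * 1
  expect_length(lib$network$reactions, 2 * per_mod + 2L)
  within <- head(lib$network$reactions, 2 * per_mod)
  for (r in within) {
    idx <- c(r$reactants, r$products)
    expect_true(all(idx <= 3) || all(idx >= 4))
  }
  expect_error(enumerate_candidates(sp, modules = list(a = c("X1", "Z9"))),
               "unknown species")
})

test_that("stoichiometry vectors follow product-minus-reactant multiplicity", {
  expect_equal(stoichiometry_vector(reaction(c(1L, 2L), 3L), 4L),
               c(-1L, -1L, 1L, 0L))
  expect_equal(stoichiometry_vector(reaction(c(1L, 1L), 2L), 2L), c(-2L, 1L))
  expect_equal(stoichiometry_vector(reaction(1L, 2L), 3L), c(-1L, 1L, 0L))
  # every candidate stoichiometry is within -2..2 and nonzero
  lib <- enumerate_candidates(paste0("X", 1:5))
  for (r in lib$network$reactions) {
    s <- stoichiometry_vector(r, 5L)
    expect_true(all(abs(s) <= 2) && any(s != 0))
  }
})

test_that("mass-action propensity factors follow stochastic combinatorics", {
  x <- c(5, 3, 2)
  expect_equal(mass_action_propensity(reaction(c(1L, 2L), 3L))(x), 15)
  expect_equal(mass_action_propensity(reaction(1L, c(2L, 3L)))(x), 5)
  expect_equal(mass_action_propensity(reaction(c(1L, 1L), 2L))(x), 20)
  expect_equal(mass_action_propensity(reaction(integer(0), 1L))(x), 1)
})

test_that("reaction validation rejects malformed reactions", {
  expect_error(reaction(c(1L, 2L, 3L), 4L), "at most 2")
  expect_error(reaction(1L, 1L), "must differ")
  expect_error(reaction(1L, 2L, -0.5), "nonnegative")
  expect_error(reaction_network("A", list(reaction(1L, 2L))), "outside")
})

test_that("fixture networks are reproducible and drawn from the library", {
  enz <- fixture_network("enzymatic")
  expect_length(enz$species, 4L)
  expect_length(enz$reactions, 3L)
  expect_equal(vapply(enz$reactions, `[[`, numeric(1), "rate"),
               c(0.002, 0.1, 0.3))

  r1 <- fixture_network("random_sparse", n_species = 14L, n_reactions = 13L,
                        seed = 42L)
  r2 <- fixture_network("random_sparse", n_species = 14L, n_reactions = 13L,
                        seed = 42L)
  expect_identical(r1, r2)
  lib_keys <- vapply(enumerate_candidates(paste0("X", 1:14))$network$reactions,
                     key_of, "")
  expect_true(all(vapply(r1$reactions, key_of, "") %in% lib_keys))
  expect_error(fixture_network("random_sparse", n_species = 3L,
                               n_reactions = 100L), "library has only")
})

test_that("network specs round-trip through YAML", {
  net <- enz_network()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_network_spec(net, path, modules = list(m1 = c("E", "S", "ES", "P")))
  spec <- read_network_spec(path)
  expect_equal(spec$network$species, net$species)
  expect_equal(lapply(spec$network$reactions, unclass),
               lapply(net$reactions, unclass))
  expect_equal(unlist(spec$modules$m1), c("E", "S", "ES", "P"))
})
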