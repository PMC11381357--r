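# Secondary-structure engine: enumeration oracle, partition function,
# MFE, intermediate state, ppairs adapter.

test_that("reverse complement is correct and involutive", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAAA"), "TTTT")
  expect_error(reverse_complement("ACGX"), "invalid")
  set.seed(11)
  for (i in 1:20) {
    s <- random_dna(sample(4:30, 1))
    expect_equal(reverse_complement(reverse_complement(s)), s)
    # independent cross-check against Biostrings
    expect_equal(reverse_complement(s),
                 as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))))
  }
})

test_that("enumeration counts match hand enumeration", {
  m <- energy_model()
  expect_length(enumerate_structures("AAAAAA", m), 1L)    # no WC pairs
  expect_length(enumerate_structures("GAAAC", m), 2L)     # empty + (1,5)
  expect_length(enumerate_structures("GGAAACC", m), 6L)
  ss <- enumerate_structures("GAAAC", m)
  np <- sort(vapply(ss, function(s) nrow(s$pairs), integer(1)))
  expect_identical(np, c(0L, 1L))
  expect_error(enumerate_structures(random_dna(25), m), "capped")
})

test_that("hairpin loops respect the minimum loop length", {
  m <- energy_model(min_loop = 3L)
  # GAAC: closing pair would enclose only 2 bases -> no structure beyond empty
  expect_length(enumerate_structures("GAAC", m), 1L)
  m0 <- energy_model(min_loop = 0L)
  expect_gt(length(enumerate_structures("GAAC", m0)), 1L)
})

test_that("two-state pair probability has its closed form", {
  # single admissible pair with Boltzmann weight e gives p = e / (1 + e)
  m1 <- energy_model(pair_penalty = -1, stacks = 0, kT = 1)
  ppm <- partition_pair_probabilities("GAAAC", m1)
  expect_equal(ppm$p[1, 5], exp(1) / (1 + exp(1)), tolerance = 1e-12)
  expect_equal(ppm$free_energy, -log(1 + exp(1)), tolerance = 1e-12)
})

test_that("unpairable strands have an empty ensemble", {
  ppm <- partition_pair_probabilities("AAAAAAAAAA", energy_model())
  expect_equal(ppm$p_unpaired, rep(1, 10))
  expect_equal(ppm$free_energy, 0)
  expect_true(all(ppm$p == 0))
})

test_that("DP pair probabilities match exhaustive enumeration", {
  m <- energy_model()
  set.seed(101)
  worst <- 0
  for (i in 1:40) {
    s <- random_dna(sample(6:12, 1))
    oracle <- enum_pair_probs(s, m)
    dp <- partition_pair_probabilities(s, m)
    worst <- max(worst, max(abs(dp$p - oracle$p)),
                 abs(dp$free_energy - oracle$free_energy))
  }
  expect_lt(worst, 1e-9)
})

test_that("pair-probability matrices satisfy their invariants", {
  m <- energy_model()
  set.seed(7)
  for (i in 1:20) {
    ppm <- partition_pair_probabilities(random_dna(22), m)
    expect_true(all(ppm$p >= 0 & ppm$p <= 1))
    expect_equal(ppm$p, t(ppm$p))
    expect_true(all(abs(ppm$p_unpaired - (1 - rowSums(ppm$p))) < 1e-9))
    expect_true(all(ppm$p_unpaired >= 0 & ppm$p_unpaired <= 1))
  }
})

test_that("MFE equals the enumeration argmin with the tie-break", {
  m <- energy_model()
  mf <- mfe_structure("AAAAAAAAAA", m)
  expect_identical(nrow(mf$pairs), 0L)
  expect_equal(mf$energy, 0)
  mf <- mfe_structure("GGGAAAACCC", m)
  expect_equal(unname(mf$pairs), cbind(c(1L, 2L, 3L), c(10L, 9L, 8L)),
               ignore_attr = TRUE)
  set.seed(23)
  for (i in 1:40) {
    s <- random_dna(sample(6:12, 1))
    oracle <- enum_mfe(s, m)
    mf <- mfe_structure(s, m)
    expect_equal(mf$energy, oracle$energy, tolerance = 1e-9)
    expect_identical(nrow(mf$pairs), oracle$min_pairs)
    # MFE energy bounds every enumerated structure
    expect_true(all(vapply(enumerate_structures(s, m),
                           function(x) x$energy >= mf$energy - 1e-12,
                           logical(1))))
  }
})

test_that("a hairpin with contiguous paired toehold bases is found by MFE", {
  # invader whose toehold bases 3-5 pair with a downstream CCC run,
  # verified by enumeration on the 12-nt core
  core <- "AGGGAAAACCCA"
  m <- energy_model()
  oracle <- enum_mfe(core, m)
  mf <- mfe_structure(core, m)
  expect_equal(mf$energy, oracle$energy, tolerance = 1e-12)
  expect_identical(unname(mf$pairs[, 1]), c(2L, 3L, 4L))
})

test_that("intermediate state follows the mass-action quadratic", {
  sys <- displacement_system(paste0("GCGATC", "TCATTCAATACCCTAC"))
  m <- energy_model()
  # forced K = 0 emulates a non-complementary toehold/overhang
  i0 <- intermediate_state(sys, m, c0 = 5e-8, K = 0)
  expect_equal(i0$theta, 0)
  expect_equal(i0$complex_conc, 0)
  i1 <- intermediate_state(sys, m, c0 = 5e-8, K = 1e9)
  expect_equal(i1$theta, (101 - sqrt(201)) / 100, tolerance = 1e-12)
  expect_equal(i1$complex_conc, i1$theta * 5e-8)
  # theta monotone increasing in K at fixed c0
  Ks <- 10^seq(3, 12, by = 0.5)
  thetas <- vapply(Ks, theta_two_state, numeric(1), c0 = 5e-8)
  expect_true(all(diff(thetas) > 0))
  expect_true(all(thetas >= 0 & thetas <= 1))
  expect_error(intermediate_state(sys, m, c0 = 0), "c0")
})

test_that("ppairs files parse, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".ppairs")
  writeLines(c("2", "1 2 0.5"), f)
  ppm <- read_pair_probabilities(f)
  expect_equal(ppm$p[1, 2], 0.5)
  expect_equal(ppm$p_unpaired, c(0.5, 0.5))
  # empty body -> all unpaired
  writeLines("4", f)
  ppm <- read_pair_probabilities(f)
  expect_true(all(ppm$p == 0))
  expect_equal(ppm$p_unpaired, rep(1, 4))
  # malformed and out-of-range input
  writeLines(c("2", "1 2"), f)
  expect_error(read_pair_probabilities(f), "malformed")
  writeLines(c("2", "1 2 1.5"), f)
  expect_error(read_pair_probabilities(f), "outside")
  writeLines(c("3", "1 2 0.8", "1 3 0.8"), f)
  expect_error(read_pair_probabilities(f), "sum")
  # round trip of a computed matrix
  ppm0 <- partition_pair_probabilities("GGGCAAAAGCCC", energy_model())
  write_pair_probabilities(ppm0, f)
  back <- read_pair_probabilities(f)
  expect_lt(max(abs(back$p - ppm0$p)), 1e-12)
  expect_lt(max(abs(back$p_unpaired - ppm0$p_unpaired)), 1e-12)
})
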