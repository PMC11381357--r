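# Synthetic study generator: systems, planted rates, traces, temperature
# series.

test_that("config validation rejects bad inputs", {
  expect_error(synthetic_config(n_systems = -1), "n_systems")
  expect_error(synthetic_config(branch_seq = "ACGTN"), "invalid")
  expect_error(synthetic_config(planted_coeffs = c(X99 = 1)), "unknown feature")
  expect_error(synthetic_config(c0 = 0), "c0")
  expect_error(synthetic_config(dt = 0), "dt")
  expect_error(synthetic_config(temps_C = numeric(0)), "temps_C")
})

test_that("system generation is deterministic, extendable and complementary", {
  cfg <- synthetic_config(n_systems = 12, seed = 42)
  expect_length(gen_systems(synthetic_config(n_systems = 0)), 0)
  s1 <- gen_systems(cfg)
  s2 <- gen_systems(cfg)
  expect_identical(lapply(s1, function(s) s$invader$sequence),
                   lapply(s2, function(s) s$invader$sequence))
  # adding systems never perturbs earlier ones
  s3 <- gen_systems(synthetic_config(n_systems = 20, seed = 42))
  expect_identical(vapply(s3[1:12], function(s) s$invader$sequence, character(1)),
                   vapply(s1, function(s) s$invader$sequence, character(1)))
  for (s in s1) {
    expect_equal(s$substrate$sequence, reverse_complement(s$invader$sequence))
    expect_equal(s$incumbent$sequence,
                 reverse_complement(substr(s$invader$sequence, 7, 22)))
    expect_equal(substr(s$invader$sequence, 7, 22), cfg$branch_seq)
  }
})

test_that("toehold base composition is uniform", {
  cfg <- synthetic_config(n_systems = 4000, seed = 99)
  toeholds <- vapply(gen_systems(cfg), toehold_seq, character(1))
  mat <- do.call(rbind, strsplit(toeholds, ""))
  n <- nrow(mat)
  # per-position binomial 4-sigma bounds around 1/4, and a chi-square check
  for (pos in 1:6) {
    freq <- table(factor(mat[, pos], levels = c("A", "C", "G", "T"))) / n
    expect_true(all(abs(freq - 0.25) < 4 * sqrt(0.25 * 0.75 / n)))
    expect_gt(chisq.test(table(factor(mat[, pos],
                                      levels = c("A", "C", "G", "T"))))$p.value,
              1e-4)
  }
})

test_that("planted log-rate follows its closed form and noise model", {
  cfg0 <- synthetic_config(planted_coeffs = NULL, planted_intercept = 5,
                           noise_sd_log10k = 0)
  fv <- featurize_system(displacement_system(paste0("GCGATC", cfg0$branch_seq)))
  expect_equal(planted_log_rate(fv, cfg0), 1e5)
  # with coefficients, the linear model in the features
  cfg1 <- synthetic_config(planted_coeffs = c(X3 = 0.5), planted_intercept = 2,
                           noise_sd_log10k = 0)
  expect_equal(planted_log_rate(fv, cfg1), 10^(2 + 0.5 * unname(fv["X3"])))
  # Monte-Carlo recovery of (mean, sd) of log10 k
  cfgn <- synthetic_config(planted_coeffs = NULL, planted_intercept = 5,
                           noise_sd_log10k = 0.3)
  draws <- withr::with_seed(8,
    replicate(1000, log10(planted_log_rate(fv, cfgn))))
  expect_lt(abs(mean(draws) - 5) / (0.3 / sqrt(1000)), 4)
  expect_equal(sd(draws), 0.3, tolerance = 0.05)
  # determinism given a seed
  expect_identical(planted_log_rate(fv, cfgn, seed = 12),
                   planted_log_rate(fv, cfgn, seed = 12))
})

test_that("simulated traces follow the second-order law with calibration", {
  cfg <- synthetic_config(trace_noise_sd = 0, dt = 10, duration = 1000)
  flat <- simulate_trace(0, cfg)
  expect_true(all(flat$intensities ==
                    cfg$calibration$intercept + cfg$background))
  tr <- simulate_trace(1e5, cfg)  # half completion at exactly 200 s
  c_nM <- (tr$intensities - cfg$calibration$intercept - cfg$background) /
    cfg$calibration$slope
  expect_equal(c_nM[tr$times == 200], 25, tolerance = 1e-9)
  expect_true(all(diff(c_nM) > 0))       # nondecreasing
  expect_true(all(c_nM <= 50 + 1e-9))    # bounded by c0
  expect_error(simulate_trace(-1, cfg), "k")
})

test_that("trace noise is additive, zero-mean and seed-reproducible", {
  cfg <- synthetic_config(trace_noise_sd = 6, dt = 100, duration = 2000)
  cfg0 <- synthetic_config(trace_noise_sd = 0, dt = 100, duration = 2000)
  clean <- simulate_trace(1e5, cfg0)$intensities
  resid <- vapply(1:100, function(s)
    mean(simulate_trace(1e5, cfg, seed = s)$intensities - clean), numeric(1))
  se <- 6 / sqrt(length(clean) * 100)
  expect_lt(abs(mean(resid)), 4 * se)
  expect_identical(simulate_trace(1e5, cfg, seed = 3)$intensities,
                   simulate_trace(1e5, cfg, seed = 3)$intensities)
})

test_that("temperature series obey the Arrhenius ratio", {
  cfg <- synthetic_config(trace_noise_sd = 0, Ea = 0, dt = 50, duration = 1000)
  ser <- simulate_temperature_series(cfg)
  expect_named(ser, c("15", "20", "25", "30"))
  # Ea = 0: identical kinetics at all temperatures
  for (t in ser) expect_identical(t$intensities, ser[[1]]$intensities)
  cfg2 <- synthetic_config(trace_noise_sd = 0, Ea = 6e4)
  r <- arrhenius_k(30, 6e4, cfg2$lnA) / arrhenius_k(15, 6e4, cfg2$lnA)
  expect_equal(r, exp(6e4 / 8.314 * (1 / 288.15 - 1 / 303.15)),
               tolerance = 1e-12)
  # fixed seed -> reproducible series
  cfg3 <- synthetic_config(trace_noise_sd = 6, dt = 100, duration = 1000)
  a <- simulate_temperature_series(cfg3, seed = 5)
  b <- simulate_temperature_series(cfg3, seed = 5)
  expect_identical(lapply(a, `[[`, "intensities"),
                   lapply(b, `[[`, "intensities"))
})

test_that("the planted study is internally consistent", {
  st <- simulate_study(synthetic_config(n_systems = 25, seed = 2))
  expect_identical(nrow(st$features), 25L)
  expect_identical(st$rates$rate_class,
                   classify_rate(st$rates$t_eq))
  # classes are monotone in k
  ord <- order(st$rates$k)
  expect_true(all(diff(st$rates$rate_class[ord]) <= 0))
})
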