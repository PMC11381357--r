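# Shared test oracles and fixture builders. Everything here is independent of
# the dynamic-programming code paths it is used to check.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Boltzmann pair probabilities by exhaustive enumeration (brute-force oracle).
enum_pair_probs <- function(seq, model) {
  ss <- enumerate_structures(seq, model)
  wts <- exp(-vapply(ss, function(s) s$energy, numeric(1)) / model$kT)
  Z <- sum(wts)
  n <- nchar(seq)
  P <- matrix(0, n, n)
  for (k in seq_along(ss)) {
    p <- ss[[k]]$pairs
    if (nrow(p) > 0) for (r in seq_len(nrow(p)))
      P[p[r, 1], p[r, 2]] <- P[p[r, 1], p[r, 2]] + wts[k] / Z
  }
  list(p = P + t(P), Z = Z, free_energy = -model$kT * log(Z))
}

# Enumeration argmin with the package's tie-break (fewest pairs first).
enum_mfe <- function(seq, model) {
  ss <- enumerate_structures(seq, model)
  es <- vapply(ss, function(s) s$energy, numeric(1))
  np <- vapply(ss, function(s) nrow(s$pairs), integer(1))
  best <- which(es <= min(es) + 1e-12)
  best[which.min(np[best])]
  list(energy = min(es), min_pairs = min(np[best]), all = ss[best])
}

# A small planted labeled dataset for ml tests: class is a noiseless monotone
# function of the features via the planted log-rate model.
planted_dataset <- function(n, seed, noise = 0) {
  cfg <- synthetic_config(n_systems = n, seed = seed, noise_sd_log10k = noise)
  st <- simulate_study(cfg)
  assemble_dataset(st$features, st$rates)
}
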