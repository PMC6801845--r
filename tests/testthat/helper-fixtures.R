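# Shared fixtures (memoized so expensive simulations run once per session)
# and independent oracles used across test files.

.fixture_cache <- new.env(parent = emptyenv())

# Default-condition simulated experiment with normalization and factors.
cached_default_sim <- function(seed = 1) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_cache[[key]])) {
    sim <- simulate_counts(sim_config(seed = seed))
    f <- tmm_factors(sim$counts)
    .fixture_cache[[key]] <- list(sim = sim, factors = f,
                                  normalized = normalize_counts(sim$counts, f))
  }
  .fixture_cache[[key]]
}

# Effect-free simulation (pure null) at a given dispersion.
cached_null_sim <- function(seed = 11, dispersion = 0.2) {
  key <- paste0("null", seed, "_", dispersion)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- sim_config(seed = seed, dispersion = dispersion,
                      effect_log2fc_radiation = 0,
                      effect_log2fc_microgravity = 0,
                      effect_log2fc_synergy = 0)
    sim <- simulate_counts(cfg)
    f <- tmm_factors(sim$counts)
    .fixture_cache[[key]] <- list(sim = sim, factors = f,
                                  normalized = normalize_counts(sim$counts, f))
  }
  .fixture_cache[[key]]
}

# Independent brute-force oracle for the conditional exact test: direct
# enumeration of the joint probabilities of every split of the total, with
# plain density calls and no truncation or log-space shortcuts.
oracle_exact_p <- function(sum_a, sum_b, n_a, n_b, phi) {
  s <- sum_a + sum_b
  if (s == 0) return(1)
  mu <- s / (n_a + n_b)
  k <- 0:s
  if (phi <= 0) {
    pr <- dpois(k, lambda = n_a * mu) * dpois(s - k, lambda = n_b * mu)
  } else {
    pr <- dnbinom(k, mu = n_a * mu, size = n_a / phi) *
      dnbinom(s - k, mu = n_b * mu, size = n_b / phi)
  }
  obs <- pr[sum_a + 1]
  sum(pr[pr <= obs * (1 + 1e-10)]) / sum(pr)
}

# Tiny deterministic count matrix used by several IO / normalization tests.
toy_counts <- function() {
  m <- matrix(c(100, 200, 300, 400, 500,
                110, 190, 310, 390, 510,
                205, 395, 610, 800, 990), ncol = 3,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  storage.mode(m) <- "integer"
  m
}
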