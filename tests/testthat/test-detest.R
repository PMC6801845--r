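test_that("a perfectly balanced split is never significant", {
  expect_equal(exact_nb_test(25, 25, 3, 3, 0.1), 1)
  expect_equal(exact_nb_test(0, 0, 3, 3, 0.1), 1)  # untestable convention
  expect_equal(exact_nb_test(7, 7, 2, 2, 0), 1)
})

test_that("truncated p equals brute-force enumeration on a dense grid", {
  sizes <- list(c(1, 1), c(1, 3), c(2, 3), c(3, 3), c(6, 6), c(1, 6))
  for (phi in c(0, 0.1, 0.5)) {
    for (ns in sizes) {
      for (s in c(1, 2, 5, 13, 27, 50)) {
        for (ka in unique(c(0, s %/% 4, s %/% 2, s))) {
          p_impl <- exact_nb_test(ka, s - ka, ns[1], ns[2], phi)
          p_oracle <- oracle_exact_p(ka, s - ka, ns[1], ns[2], phi)
          expect_equal(p_impl, p_oracle, tolerance = 1e-9,
                       label = sprintf("s=%d ka=%d n=(%d,%d) phi=%g",
                                       s, ka, ns[1], ns[2], phi))
        }
      }
    }
  }
})

test_that("the phi -> 0 limit converges to the exact binomial split test", {
  for (ka in c(3, 10, 17)) {
    p_small_phi <- exact_nb_test(ka, 20 - ka, 2, 3, 1e-9)
    p_binom <- exact_nb_test(ka, 20 - ka, 2, 3, 0)
    expect_equal(p_small_phi, p_binom, tolerance = 1e-4)
  }
})

test_that("p decreases monotonically as the split grows more extreme", {
  s <- 60
  p <- vapply(30:60, function(k) exact_nb_test(k, s - k, 3, 3, 0.1),
              numeric(1))
  expect_true(all(diff(p) <= 1e-12))
})

test_that("swapping groups preserves p and inverts the fold change", {
  expect_equal(exact_nb_test(40, 12, 3, 3, 0.2),
               exact_nb_test(12, 40, 3, 3, 0.2))
  expect_equal(exact_nb_test(40, 12, 2, 4, 0.2),
               exact_nb_test(12, 40, 4, 2, 0.2))

  fx <- cached_default_sim()
  d <- fx$sim$design
  a <- contrast("fwd", d$sample_id[d$condition == "ST-X3"],
                d$sample_id[d$condition == "RO-X3"])
  b <- contrast("rev", d$sample_id[d$condition == "RO-X3"],
                d$sample_id[d$condition == "ST-X3"])
  genes <- rownames(fx$sim$counts)[1:50]
  ra <- run_contrast(fx$sim$counts, fx$normalized, a, phi = 0.1,
                     genes = genes, factors = fx$factors)
  rb <- run_contrast(fx$sim$counts, fx$normalized, b, phi = 0.1,
                     genes = genes, factors = fx$factors)
  expect_equal(ra$p_value, rb$p_value, tolerance = 1e-12)
  expect_equal(ra$log2_fc, -rb$log2_fc, tolerance = 1e-12)
})

test_that("equal group means give zero log2 fold change", {
  m <- matrix(rep(c(100L, 50L), each = 6), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  norm <- normalize_counts(m, rep(1, 6))
  ct <- contrast("x", paste0("s", 1:3), paste0("s", 4:6))
  res <- run_contrast(m, norm, ct, phi = 0.1)
  expect_equal(res$log2_fc, c(0, 0))
  expect_equal(res$p_value, c(1, 1))
  expect_false(any(res$significant))
})

test_that("significance flag combines p and two-sided fold-change thresholds", {
  fx <- cached_default_sim()
  d <- fx$sim$design
  ct <- contrast("st_vs_roC3", d$sample_id[d$condition == "ST-C3"],
                 d$sample_id[d$condition == "RO-C3"])
  res <- run_contrast(fx$sim$counts, fx$normalized, ct, phi = 0.1,
                      factors = fx$factors)
  manual <- res$p_value < 0.05 & (res$fold_change > 2 | res$fold_change < 0.5)
  expect_identical(res$significant, manual)
})

test_that("null type-I error is near nominal and planted effects are powered", {
  fx <- cached_null_sim()
  d <- fx$sim$design
  ct <- contrast("null", d$sample_id[d$condition == "ST-X3"],
                 d$sample_id[d$condition == "RO-X3"])
  res <- run_contrast(fx$sim$counts, fx$normalized, ct, phi = 0.2,
                      factors = fx$factors)
  expect_gt(mean(res$p_value < 0.05), 0.03)
  expect_lt(mean(res$p_value < 0.05), 0.07)

  # power: log2FC = 3 at mu = 500, phi = 0.1, 3 vs 3
  set.seed(202)
  hits <- vapply(1:200, function(i) {
    a <- rnbinom(3, mu = 500, size = 10)
    b <- rnbinom(3, mu = 4000, size = 10)
    exact_nb_test(sum(a), sum(b), 3, 3, 0.1) < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("common dispersion is recovered by conditional maximum likelihood", {
  fx <- cached_null_sim()  # phi_true = 0.2
  d <- fx$sim$design
  st <- d$sample_id[d$condition %in% c("ST", "RO")]
  est <- estimate_common_dispersion(
    fx$sim$counts[, st], rep(c("ST", "RO"), each = 6),
    lib_sizes = (colSums(fx$sim$counts) * fx$factors)[st])
  expect_equal(est$method, "cml")
  expect_lt(abs(est$phi - 0.2) / 0.2, 0.25)
})

test_that("Poisson data yields a near-zero dispersion estimate", {
  cfg <- sim_config(seed = 3, dispersion = 0, effect_log2fc_radiation = 0,
                    effect_log2fc_microgravity = 0, effect_log2fc_synergy = 0)
  sim <- simulate_counts(cfg)
  est <- estimate_common_dispersion(sim$counts, sim$design$condition)
  expect_lt(est$phi, 0.02)
})

test_that("identical constant replicates give phi = 0", {
  m <- matrix(rep(c(50L, 200L, 10L), 4), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  est <- estimate_common_dispersion(m, rep("g1", 4))
  expect_equal(est$phi, 0)
})

test_that("dispersion estimation agrees with the independent edgeR qCML route", {
  skip_if_not_installed("edgeR")
  fx <- cached_null_sim()
  d <- fx$sim$design
  st <- d$sample_id[d$condition %in% c("ST", "RO")]
  est <- estimate_common_dispersion(fx$sim$counts[, st],
                                    rep(c("ST", "RO"), each = 6))
  y <- edgeR::DGEList(counts = fx$sim$counts[, st],
                      group = rep(c("ST", "RO"), each = 6))
  y <- edgeR::estimateCommonDisp(y)
  expect_equal(est$phi, y$common.dispersion, tolerance = 0.1)
})

test_that("degenerate designs are rejected with guidance", {
  m <- toy_counts()
  expect_error(estimate_common_dispersion(m, c("a", "b", "c")),
               "supply a dispersion")
  ct <- contrast("bad", "s1", "s2")
  expect_error(run_contrast(m, normalize_counts(m),
                            contrast("missing", "s1", "zz"), phi = 0.1),
               "zz")
  expect_error(contrast("overlap", c("s1", "s2"), c("s2", "s3")), "overlap")
  expect_error(contrast("empty", character(0), "s1"), "nonempty")
})
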