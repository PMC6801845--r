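test_that("Step 1 intersects the panel with detected genes", {
  m <- matrix(c(5L, 2L, 3L, 0L), ncol = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  m <- rbind(m, c = c(0L, 0L))
  expect_equal(step1_panel_filter(m, c("a", "c")), "a")
  expect_warning(out <- step1_panel_filter(m, c("zz")), "no panel gene")
  expect_length(out, 0)
  expect_equal(step1_panel_filter(m, c("a", "b")), c("a", "b"))

  fx <- cached_default_sim()
  panel <- fx$sim$truth$gene_id[fx$sim$truth$in_panel]
  expect_length(step1_panel_filter(fx$sim$counts, panel), 82L)
})

test_that("Step 2 keeps genes at or above the standing-expression threshold", {
  norm <- matrix(c(1500, 999.9, 1000, 120, 80, 400), ncol = 2,
                 dimnames = list(c("hi", "lo", "edge"), c("s1", "s2")))
  kept <- step2_expression_filter(norm, rownames(norm), c("s1", "s2"),
                                  threshold = 1000)
  expect_setequal(kept, c("hi", "edge"))

  fx <- cached_default_sim()
  g1 <- step1_panel_filter(fx$sim$counts,
                           fx$sim$truth$gene_id[fx$sim$truth$in_panel])
  standing <- fx$sim$design$sample_id[fx$sim$design$gravity == "ST"]
  g2 <- step2_expression_filter(fx$normalized, g1, standing)
  expect_length(g2, 13L)  # the planted high-expression panel genes
})

test_that("Step 3 finds the gravity effect only where planted", {
  fx <- cached_default_sim()
  truth <- fx$sim$truth
  genes <- truth$gene_id[truth$in_panel & truth$detected][1:13]
  s3 <- step3_gravity_contrasts(fx$sim$counts, fx$normalized, fx$sim$design,
                                genes, phi = 0.1, factors = fx$factors)
  expect_equal(dim(s3$p), c(13L, 4L))
  expect_true(all(s3$p >= 0 & s3$p <= 1))
  syn <- truth$gene_id[truth$synergy_class_truth != "none"]
  expect_true(all(s3$pass[syn]))
})

test_that("identical replicate values across gravity give p = 1 and fail", {
  m <- matrix(rep(c(120L, 45L), each = 36), nrow = 2, byrow = TRUE)
  d <- build_design()
  dimnames(m) <- list(c("g1", "g2"), d$sample_id)
  norm <- normalize_counts(m, rep(1, 36))
  s3 <- step3_gravity_contrasts(m, norm, d, c("g1", "g2"), phi = 0.1)
  expect_true(all(s3$p == 1))
  expect_false(any(s3$pass))
  s4 <- step4_microgravity_alone(m, norm, d, c("g1", "g2"), phi = 0.1)
  expect_false(any(s4$pass))
})

test_that("Step 4 detects a planted microgravity-alone effect", {
  fx <- cached_default_sim()
  truth <- fx$sim$truth
  mug <- truth$gene_id[truth$mug_program][1:10]
  quiet <- truth$gene_id[truth$in_panel & truth$detected &
                           truth$synergy_class_truth == "none"][1:4]
  s4 <- step4_microgravity_alone(fx$sim$counts, fx$normalized, fx$sim$design,
                                 c(mug, quiet), phi = 0.1,
                                 factors = fx$factors)
  expect_true(all(s4$pass[mug]))      # log2FC 1.5 at N = 6 vs 6 is powered
  expect_false(any(s4$pass[quiet]))   # no gravity response planted
})

test_that("Step 5 conversion follows the defined arithmetic", {
  d <- build_design()
  # gene with ST = 2000, RO = 1000, ST-C3 = 3200, RO-C3 = 800, rest 1000
  norm <- matrix(1000, nrow = 1, ncol = 36,
                 dimnames = list("g1", d$sample_id))
  norm[1, d$condition == "ST"] <- 2000
  norm[1, d$condition == "RO"] <- 1000
  norm[1, d$condition == "ST-C3"] <- 3200
  norm[1, d$condition == "RO-C3"] <- 800
  s5 <- step5_convert_and_classify(norm, d, "g1")
  expect_equal(s5$ratio_r, 2)
  expect_equal(s5$converted_C3, 1600)
  expect_equal(s5$adjusted_fc_C3, 0.5)
  expect_equal(s5$class_C3, "enhanced_decrease")
  # r = 1 with equal irradiated means is the identity: class none
  norm2 <- matrix(1000, nrow = 1, ncol = 36,
                  dimnames = list("g1", d$sample_id))
  s5b <- step5_convert_and_classify(norm2, d, "g1")
  expect_equal(s5b$adjusted_fc_X3, 1)
  expect_equal(s5b$class_X3, "none")
  # zero non-irradiated RO mean: unclassifiable
  norm3 <- norm
  norm3[1, d$condition == "RO"] <- 0
  s5c <- step5_convert_and_classify(norm3, d, "g1")
  expect_false(s5c$classifiable)
})

test_that("conversion equals the plain irradiated ratio when r = 1", {
  fx <- cached_default_sim()
  d <- fx$sim$design
  genes <- fx$sim$truth$gene_id[1:13]
  norm <- fx$normalized
  # force equal non-irradiated means so r = 1 exactly
  norm[genes, d$sample_id[d$condition == "RO"]] <-
    rowMeans(norm[genes, d$sample_id[d$condition == "ST"], drop = FALSE])
  norm[genes, d$sample_id[d$condition == "ST"]] <-
    rowMeans(norm[genes, d$sample_id[d$condition == "ST"], drop = FALSE])
  s5 <- step5_convert_and_classify(norm, d, genes)
  plain <- rowMeans(norm[genes, d$sample_id[d$condition == "RO-X24"],
                         drop = FALSE]) /
    rowMeans(norm[genes, d$sample_id[d$condition == "ST-X24"], drop = FALSE])
  expect_equal(s5$adjusted_fc_X24, unname(plain), tolerance = 1e-12)
})

test_that("the funnel is monotone and the full screen recovers planted genes", {
  fp_counts <- integer(0)
  sens <- integer(0)
  dir_ok <- integer(0)
  for (seed in 1:3) {
    fx <- cached_default_sim(seed)
    truth <- fx$sim$truth
    cfg <- screen_config(truth$gene_id[truth$in_panel])
    scr <- run_screen(fx$sim$counts, fx$normalized, fx$sim$design, cfg,
                      factors = fx$factors)
    r <- scr$records
    # funnel: step1 >= step2 >= (step3 | step4) >= selected
    expect_true(all(r$step2_pass <= r$step1_pass))
    gate <- r$step3_pass | (!is.na(r$step4_pass) & r$step4_pass)
    expect_true(all(gate <= r$step2_pass))
    expect_true(all(r$selected <= gate))
    # step 4 is only evaluated for step-3 failures
    expect_true(all(is.na(r$step4_p[r$step3_pass])))

    syn <- truth$gene_id[truth$synergy_class_truth != "none"]
    tp <- intersect(scr$selected, syn)
    sens <- c(sens, length(tp))
    fp_counts <- c(fp_counts, length(setdiff(scr$selected, syn)))
    dir_ok <- c(dir_ok,
                sum(r$synergy_class[match(tp, r$gene_id)] ==
                      truth$synergy_class_truth[match(tp, truth$gene_id)]))
  }
  expect_gte(median(sens), 8)
  expect_lte(median(fp_counts), 1)
  expect_gte(median(dir_ok), 8)
})

test_that("screen conclusions are invariant to a global normalized rescale", {
  fx <- cached_default_sim()
  d <- fx$sim$design
  genes <- fx$sim$truth$gene_id[1:13]
  s5a <- step5_convert_and_classify(fx$normalized, d, genes)
  s5b <- step5_convert_and_classify(fx$normalized * 7.3, d, genes)
  expect_equal(s5a$ratio_r, s5b$ratio_r, tolerance = 1e-12)
  expect_equal(s5a$adjusted_fc_C24, s5b$adjusted_fc_C24, tolerance = 1e-12)
  expect_identical(s5a$class_X3, s5b$class_X3)

  rel_a <- relative_expression(fx$normalized, d, genes)
  rel_b <- relative_expression(fx$normalized * 7.3, d, genes)
  expect_equal(rel_a$relative, rel_b$relative, tolerance = 1e-12)
})

test_that("relative expression is max-scaled with replicate standard errors", {
  fx <- cached_default_sim()
  d <- fx$sim$design
  genes <- fx$sim$truth$gene_id[1:5]
  rel <- relative_expression(fx$normalized, d, genes)
  for (g in genes) {
    expect_equal(max(rel$relative[rel$gene_id == g]), 1)
  }
  # flat gene: all relative values 1, directions ns
  m <- matrix(500, nrow = 1, ncol = 36,
              dimnames = list("flat", d$sample_id))
  counts_flat <- matrix(500L, nrow = 1, ncol = 36,
                        dimnames = list("flat", d$sample_id))
  rel_flat <- relative_expression(m, d, "flat", counts = counts_flat,
                                  phi = 0.1)
  expect_true(all(rel_flat$relative == 1))
  dirs <- attr(rel_flat, "directions")
  expect_true(all(unlist(dirs[, -1]) == "ns"))
  # SE definition: sd of max-scaled replicates / sqrt(N)
  g <- genes[1]
  st_cols <- d$sample_id[d$condition == "ST"]
  cond_means <- sapply(unique(d$condition), function(cc) {
    mean(fx$normalized[g, d$sample_id[d$condition == cc]])
  })
  manual_se <- sd(fx$normalized[g, st_cols] / max(cond_means)) /
    sqrt(length(st_cols))
  expect_equal(rel$se[rel$gene_id == g & rel$condition == "ST"], manual_se)
})

test_that("planted enhanced_increase genes show the up direction under rotation", {
  fx <- cached_default_sim()
  truth <- fx$sim$truth
  up_genes <- truth$gene_id[truth$synergy_class_truth == "enhanced_increase"]
  rel <- relative_expression(fx$normalized, fx$sim$design, up_genes,
                             counts = fx$sim$counts, phi = 0.1,
                             factors = fx$factors)
  dirs <- attr(rel, "directions")
  calls <- unlist(dirs[, c("X3", "X24", "C3", "C24")])
  expect_gt(mean(calls == "up"), 0.9)
})
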