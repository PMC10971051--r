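test_that("subgroup pooling matches direct computation on patient-level data", {
  # identical subgroups leave the mean unchanged; the pooled sample SD is
  # sqrt(((m-1)V + (n-1)V) / (m+n-1)), slightly below sqrt(V) because the
  # two subgroup means coincide exactly
  z <- pool_subgroup_summaries(subgroup_summary("a", 10, 5, 4),
                               subgroup_summary("b", 10, 5, 4))
  expect_equal(z$mean, 5)
  expect_equal(z$sd, sqrt(18 * 4 / 19))
  expect_equal(z$n, 20)

  # two-point sample: SD = |3 - 5| / sqrt(2)
  z2 <- pool_subgroup_summaries(subgroup_summary("a", 1, 3, 0),
                                subgroup_summary("b", 1, 5, 0))
  expect_equal(z2$mean, 4)
  expect_equal(z2$sd, sqrt(2))

  # algebraic identity: pooled summary equals mean/sd of the concatenated
  # synthetic per-patient values, to machine precision
  spec <- study_spec("s", data.frame(label = c("chl_mhl", "ssd"),
                                     n = c(39, 15)),
                     data.frame(subgroup = c("chl_mhl", "ssd"),
                                endpoint = "pta4", timepoint = 6,
                                measure = "change",
                                mean = c(22.5, 17.2), sd = c(9.8, 10.9)))
  rec <- generate_study(spec, seed = 101)
  by_sub <- summarize_records(rec, by_subgroup = TRUE)
  a <- by_sub[by_sub$subgroup == "chl_mhl", ]
  b <- by_sub[by_sub$subgroup == "ssd", ]
  pooled <- pool_subgroup_summaries(
    subgroup_summary("chl_mhl", a$n, a$mean, a$sd^2),
    subgroup_summary("ssd", b$n, b$mean, b$sd^2))
  expect_equal(pooled$mean, mean(rec$value), tolerance = 1e-12)
  expect_equal(pooled$sd, sd(rec$value), tolerance = 1e-12)
})

test_that("subgroup pooling validates its inputs", {
  a <- subgroup_summary("a", 5, 1, 1, endpoint = "pta4")
  b <- subgroup_summary("b", 5, 1, 1, endpoint = "hui3")
  expect_error(pool_subgroup_summaries(a, b), "endpoints")
  expect_error(subgroup_summary("a", 0, 1, 1), "n must be")
  expect_error(subgroup_summary("a", 5, 1, -1), "variance")
})

test_that("DerSimonian-Laird pooling reproduces the published arm metas", {
  pta <- meta_analyze(osia_pta4_arms())
  expect_equal(round(pta$mean, 2), 28.07)
  expect_equal(round(c(pta$ci_low, pta$ci_high), 2), c(26.00, 30.14))
  expect_equal(pta$tau2, 0)  # Q = 0.05 < k - 1 here

  sq <- meta_analyze(list(
    study_arm_summary("osia1", "speech_quiet", 6, "change", 48, 61.50, 27.70),
    study_arm_summary("osia2", "speech_quiet", 6, "change", 28, 54.00, 29.80)))
  expect_gt(sq$tau2, 0)
  expect_equal(round(sq$mean, 2), 58.80)
  expect_equal(round(c(sq$ci_low, sq$ci_high), 2), c(51.74, 65.86))

  # single arm passes through with se = sd / sqrt(n)
  single <- meta_analyze(list(
    study_arm_summary("osia1", "speech_noise", 6, "change", 48, 13.70, 8.10)))
  expect_equal(single$mean, 13.70)
  expect_equal(single$se, 8.10 / sqrt(48))
  expect_equal(round(c(single$ci_low, single$ci_high), 2), c(11.41, 15.99))
})

test_that("meta-analysis invariants hold", {
  arm <- function(m, sd = 4, n = 25)
    study_arm_summary("s", "e", 6, "change", n, m, sd)

  # identical arms return the common mean; se decreases as arms are added
  prev_se <- Inf
  for (k in 2:5) {
    eff <- meta_analyze(rep(list(arm(10)), k))
    expect_equal(eff$mean, 10)
    expect_lt(eff$se, prev_se)
    prev_se <- eff$se
  }

  # Q <= k - 1 implies tau2 = 0 and equality with fixed-effect pooling
  low_het <- list(arm(10.0), arm(10.1))
  eff <- meta_analyze(low_het)
  expect_lte(eff$q, 1)
  expect_equal(eff$tau2, 0)
  v <- 16 / 25
  expect_equal(eff$mean, (10.0 / v + 10.1 / v) / (2 / v))

  # weights sum to 1 / se^2
  sq <- meta_analyze(list(arm(10, 4), arm(30, 8, 10)))
  expect_equal(sum(sq$weights), 1 / sq$se^2)

  expect_error(meta_analyze(list()), "at least one")
  expect_error(meta_analyze(list(arm(1),
    study_arm_summary("s", "other", 6, "change", 5, 1, 1))), "mixed endpoints")
})

test_that("indirect comparison reproduces the published differences", {
  pta <- itc_difference(meta_analyze(osia_pta4_arms()),
                        meta_analyze(list(baha_pta4_arm())))
  # published values carry the rounding of their 2-dp inputs: +/- 0.01
  expect_equal(pta$difference, 7.05, tolerance = 0.01)
  expect_equal(pta$ci_low, 3.58, tolerance = 0.01)
  expect_equal(pta$ci_high, 10.51, tolerance = 0.01)
  expect_true(pta$significant)

  noise <- itc_difference(
    study_arm_summary("osia1", "speech_noise", 6, "change", 48, 13.70, 8.10),
    study_arm_summary("baha1", "speech_noise", 6, "change", 36, 4.26, 5.66))
  expect_equal(noise$difference, 9.44, tolerance = 1e-12)
  expect_equal(noise$ci_low, 6.50, tolerance = 0.01)
  expect_equal(noise$ci_high, 12.39, tolerance = 0.01)
})

test_that("indirect comparison invariants hold", {
  o <- meta_analyze(osia_pta4_arms())
  b <- meta_analyze(list(baha_pta4_arm()))
  fwd <- itc_difference(o, b)
  rev <- itc_difference(b, o)
  expect_equal(rev$difference, -fwd$difference)
  expect_equal(rev$se, fwd$se)
  # se^2 is the sum of the two arm variances
  expect_equal(fwd$se^2, o$se^2 + b$se^2)
  # significance flag is exactly |d| / se > z
  expect_identical(fwd$significant,
                   abs(fwd$difference) / fwd$se > qnorm(0.975))

  same <- itc_difference(o, o)
  expect_equal(same$difference, 0)
  expect_false(same$significant)

  mism <- meta_analyze(list(study_arm_summary("x", "hui3", 6, "change",
                                              10, 0.1, 0.2)))
  expect_error(itc_difference(o, mism), "endpoints")
})

test_that("confidence intervals use the normal quantile", {
  expect_equal(confidence_interval(0, 1, 0.95),
               c(-1, 1) * qnorm(0.975))
  # published single-study interval back-calculates with z, not t
  ci <- confidence_interval(21.02, 10.41 / sqrt(54), 0.95)
  # published bounds carry the rounding of their 2-dp inputs: +/- 0.01
  expect_equal(ci[1], 18.25, tolerance = 0.01)
  expect_equal(ci[2], 23.80, tolerance = 0.01)
  expect_equal(confidence_interval(3, 0), c(3, 3))
  expect_error(confidence_interval(0, -1), "se must be")
  expect_error(confidence_interval(0, 1, 1.2), "level")
})
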