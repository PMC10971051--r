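test_that("study generation is deterministic and honours its spec", {
  spec <- example_study_spec()
  r1 <- generate_study(spec, seed = 3)
  r2 <- generate_study(spec, seed = 3)
  expect_identical(r1, r2)
  r3 <- generate_study(spec, seed = 4)
  expect_false(identical(r1$value, r3$value))

  # sizes and labels follow the spec
  expect_equal(nrow(r1), 2 * (39 + 15))
  expect_setequal(unique(r1$subgroup), c("chl_mhl", "ssd"))

  # zero-SD spec: every record equals the mean
  const <- study_spec("c", data.frame(label = "g", n = 8),
                      data.frame(subgroup = "g", endpoint = "e",
                                 timepoint = 6, measure = "change",
                                 mean = 2.5, sd = 0))
  rc <- generate_study(const, seed = 1)
  expect_true(all(rc$value == 2.5))
  expect_equal(summarize_records(rc)$sd, 0)

  expect_error(generate_study(spec), "seed")
})

test_that("summaries use the n-1 denominator and flag degenerate groups", {
  rec <- data.frame(patient_id = c("p1", "p2", "p3"), study_id = "s",
                    subgroup = "g", endpoint = "e", timepoint = 6,
                    measure = "change", value = c(1, 2, 4))
  s <- summarize_records(rec, by_subgroup = FALSE)
  expect_equal(s$mean, 7 / 3)
  expect_equal(s$sd, sd(c(1, 2, 4)))
  single <- summarize_records(rec[1, ], by_subgroup = FALSE)
  expect_true(is.na(single$sd))
  expect_error(summarize_records(rec[0, ]), "no records")
})

test_that("parameter recovery within 3 standard errors at n = 500", {
  spec <- study_spec("big", data.frame(label = c("a", "b"), n = c(500, 500)),
                     data.frame(subgroup = c("a", "b"), endpoint = "e",
                                timepoint = 6, measure = "change",
                                mean = c(10, 20), sd = c(4, 6)))
  s <- summarize_records(generate_study(spec, seed = 2024))
  for (i in 1:2) {
    target <- spec$measures[spec$measures$subgroup == s$subgroup[i], ]
    se_mean <- target$sd / sqrt(500)
    expect_lt(abs(s$mean[i] - target$mean), 3 * se_mean)
    se_sd <- target$sd / sqrt(2 * (500 - 1))
    expect_lt(abs(s$sd[i] - target$sd), 3 * se_sd)
  }
})

test_that("generated data round-trips through the pooling identity", {
  spec <- study_spec("rt", data.frame(label = c("x", "y"), n = c(13, 7)),
                     data.frame(subgroup = c("x", "y"), endpoint = "e",
                                timepoint = 6, measure = "change",
                                mean = c(5, 9), sd = c(2, 3)))
  rec <- generate_study(spec, seed = 8)
  sub <- summarize_records(rec, by_subgroup = TRUE)
  whole <- summarize_records(rec, by_subgroup = FALSE)
  pooled <- pool_subgroup_summaries(
    subgroup_summary("x", sub$n[sub$subgroup == "x"],
                     sub$mean[sub$subgroup == "x"],
                     sub$sd[sub$subgroup == "x"]^2),
    subgroup_summary("y", sub$n[sub$subgroup == "y"],
                     sub$mean[sub$subgroup == "y"],
                     sub$sd[sub$subgroup == "y"]^2))
  expect_equal(pooled$mean, whole$mean, tolerance = 1e-12)
  expect_equal(pooled$sd, whole$sd, tolerance = 1e-12)
  expect_equal(pooled$n, whole$n)
})

test_that("life table constructors cover the three models", {
  immortal <- make_life_table("constant", q = 0)
  tr <- run_cohort(toy_arm(), toy_config(horizon_years = 3), immortal)
  expect_true(all(rowSums(tr$occupancy[, model_states() != "dead"]) == 1))

  # q = 1: the cohort is dead after the first year of cycles
  certain <- make_life_table("constant", q = 1)
  tr1 <- run_cohort(toy_arm(), toy_config(horizon_years = 2), certain)
  expect_equal(unname(tr1$occupancy[5, "dead"]), 1)

  gomp <- make_life_table("gompertz")
  expect_true(all(diff(gomp$qx) >= 0))
  expect_true(all(gomp$qx >= 0 & gomp$qx <= 1))
  expect_equal(gomp$age, 0:100)

  fix <- make_life_table("fixture")
  expect_equal(names(fix), c("age", "qx"))
  expect_error(make_life_table("constant", q = 2), "q must be")
})
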