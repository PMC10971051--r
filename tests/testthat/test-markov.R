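test_that("transition matrix structure is correct", {
  # zero rates, zero mortality: cohort stays in the first aided state
  M <- build_transition_matrix(0, reoperation_split(0, 1, 0), 0)
  expect_equal(M["aided_first", "aided_first"], 1)
  expect_equal(unname(M["dead", ]), c(rep(0, 8), 1))  # absorbing
  expect_equal(unname(rowSums(M)), rep(1, 9))

  # even explant/reimplant split produces equal off-diagonal entries
  p <- rate_to_cycle_probability(4 / 1296, 3)
  M2 <- build_transition_matrix(p, reoperation_split(0, 0.5, 0.5), 0.002)
  expect_equal(M2["aided_first", "unaided"], M2["aided_first", "tunnel_q1"])
  expect_equal(unname(rowSums(M2)), rep(1, 9))

  # hand-built oracle for the first-device row
  s <- 1 - 0.002
  expect_equal(M2["aided_first", "aided_first"], s * (1 - p))
  expect_equal(M2["aided_first", "unaided"], s * p * 0.5)
  expect_equal(M2["aided_first", "dead"], 0.002)

  # no third device: non-revision reoperation of a second device is terminal
  expect_equal(M2["aided_second", "unaided"], s * p)
  # tunnel advances deterministically
  expect_equal(M2["tunnel_q1", "tunnel_q2"], s)
  expect_equal(M2["tunnel_q4", "aided_second"], s)

  expect_error(build_transition_matrix(1.5, reoperation_split(0, 1, 0), 0),
               "probabilities")
})

test_that("cohort trace conserves occupancy and mortality matches closed form", {
  # property-style: random configurations under a fixed seed
  set.seed(7)
  for (i in 1:5) {
    arm <- toy_arm(monthly_reop = runif(1, 0, 0.02),
                   monthly_ae = runif(1, 0, 0.02),
                   split = reoperation_split(0.2, 0.4, 0.4))
    lt <- make_life_table("constant", q = runif(1, 0, 0.05))
    tr <- run_cohort(arm, toy_config(), lt)
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-12))
    expect_true(all(diff(tr$occupancy[, "dead"]) >= 0))
    expect_true(all(tr$occupancy >= -1e-15))
  }

  # with only mortality (constant q), survival after y years is (1-q)^y
  lt <- make_life_table("constant", q = 0.03)
  tr <- run_cohort(toy_arm(), toy_config(horizon_years = 10), lt)
  y <- tr$times
  alive <- rowSums(tr$occupancy[, model_states() != "dead"])
  expect_equal(alive, (1 - 0.03)^y, tolerance = 1e-12)

  # zero mortality, zero events: all mass stays in aided_first
  tr0 <- run_cohort(toy_arm(), toy_config(), immortal_lt())
  expect_true(all(tr0$occupancy[, "aided_first"] == 1))
})

test_that("engine survival matches the continuous Gompertz-Makeham solution", {
  a <- 1.72e-5; b <- 0.0977; mk <- 4e-4
  lt <- make_life_table("gompertz", a = a, b = b, makeham = mk)
  cfg <- toy_config(start_age = 47, horizon_years = 10)
  tr <- run_cohort(toy_arm(), cfg, lt)
  alive <- rowSums(tr$occupancy[, model_states() != "dead"])
  # S(t) = exp(-mk t - a/b (e^{b (x0+t)} - e^{b x0})) with hazard h(x) ~ q(x)
  t <- tr$times
  surv <- exp(-mk * t - a / b * (exp(b * (47 + t)) - exp(b * 47)))
  # annual discretisation of q vs continuous hazard: small but nonzero
  expect_equal(alive, surv, tolerance = 0.005)
})

test_that("explanted fraction follows the scalar recursion oracle", {
  # all-explant split: cumulative explanted mass after k cycles is
  # 1 - (1 - p)^k when mortality is zero
  r <- 1 / 786
  arm <- toy_arm(monthly_reop = r, split = reoperation_split(0, 1, 0))
  tr <- run_cohort(arm, toy_config(horizon_years = 2), immortal_lt())
  p <- rate_to_cycle_probability(r, 3)
  expect_equal(unname(tr$occupancy[9, "unaided"]), 1 - (1 - p)^8,
               tolerance = 1e-12)
  expect_lt(tr$occupancy[9, "unaided"], 0.04)  # a few per cent at 24 months
})

test_that("utility schedule follows the rehabilitation phases", {
  u <- utility_schedule(0.67, 0.09, 0.09)
  expect_equal(utility_for("aided_first", 0, u), 0.67)
  expect_equal(utility_for("aided_first", 1, u), 0.76)
  expect_equal(utility_for("aided_first", 10, u), 0.76)
  expect_equal(utility_for("tunnel_q1", 5, u), 0.67)
  expect_equal(utility_for("tunnel_q2", 5, u), 0.76)
  expect_equal(utility_for("tunnel_q4", 5, u), 0.76)
  expect_equal(utility_for("unaided", 5, u), 0.67)   # reverts to baseline
  expect_equal(utility_for("dead", 5, u), 0)
  b <- utility_schedule(0.67, 0.06, 0.06)
  expect_equal(utility_for("aided_second", 2, b), 0.73)
  expect_error(utility_schedule(0.9, 0.2, 0.2), "within")
})

test_that("zero-everything configuration reproduces closed-form accruals", {
  # discount 0, no mortality, no events, 10 years: QALYs are the exact
  # schedule integral and costs are upfront + the two processor upgrades
  arm <- toy_arm(baseline = 0.67, gain_3m = 0.09, gain_6m = 0.09)
  cfg <- toy_config(horizon_years = 10)
  tot <- run_arm(arm, cfg, immortal_lt())
  q_expected <- 0.25 * (0.67 + 0.76 + 38 * 0.76)
  expect_equal(unname(tot$qalys["undiscounted"]), q_expected, tolerance = 1e-12)
  expect_equal(unname(tot$qalys["discounted"]), q_expected, tolerance = 1e-12)
  c_expected <- (1000 + 10 + 20) + 2 * 100
  expect_equal(unname(tot$cost["undiscounted"]), c_expected, tolerance = 1e-12)
  expect_equal(unname(tot$life_years["undiscounted"]), 10)

  # constant utility of 0.76 from surgery onwards gives exactly 7.6 QALYs
  flat <- toy_arm(baseline = 0.76, gain_3m = 0, gain_6m = 0)
  tot_flat <- run_arm(flat, cfg, immortal_lt())
  expect_equal(unname(tot_flat$qalys["undiscounted"]), 7.6, tolerance = 1e-12)
})

test_that("discounting matches the geometric-series oracle", {
  r <- 0.05
  arm <- toy_arm(baseline = 0.76, gain_3m = 0, gain_6m = 0)
  cfg <- model_config(start_age = 47, horizon_years = 10,
                      discount_annual = r)
  tot <- run_arm(arm, cfg, immortal_lt())
  k <- 1:40
  annuity <- sum((1 + r)^(-(k - 0.5) * 0.25)) * 0.25
  expect_equal(unname(tot$qalys["discounted"]), 0.76 * annuity,
               tolerance = 1e-12)
  # discounted strictly below undiscounted once accruals extend past cycle 1
  expect_lt(tot$qalys["discounted"], tot$qalys["undiscounted"])
  expect_lt(tot$cost["discounted"], tot$cost["undiscounted"])
})

test_that("half-cycle corrected QALYs lie between rectangle estimates", {
  lt <- make_life_table("constant", q = 0.05)
  arm <- toy_arm(baseline = 0.7, gain_3m = 0, gain_6m = 0)
  cfg <- toy_config(horizon_years = 10)
  tr <- run_cohort(arm, cfg, lt)
  tot <- accrue_outcomes(tr, arm, cfg)
  occ <- tr$occupancy
  alive <- rowSums(occ[, model_states() != "dead"])
  start_rect <- sum(0.7 * alive[1:40]) * 0.25
  end_rect <- sum(0.7 * alive[2:41]) * 0.25
  q <- unname(tot$qalys["undiscounted"])
  expect_gte(q, end_rect)
  expect_lte(q, start_rect)
})

test_that("ICER algebra behaves", {
  cfg <- toy_config(horizon_years = 10)
  a <- run_arm(toy_arm(baseline = 0.6, gain_3m = 0.1, gain_6m = 0.1,
                       device = 2000), cfg, immortal_lt())
  b <- run_arm(toy_arm(baseline = 0.6, gain_3m = 0.05, gain_6m = 0.05,
                       device = 1000), cfg, immortal_lt())
  res <- compute_icer(a, b, cfg)
  expect_true(res$icer_defined)
  expect_equal(unname(res$icer["undiscounted"]),
               unname((a$cost["undiscounted"] - b$cost["undiscounted"]) /
                        (a$qalys["undiscounted"] - b$qalys["undiscounted"])))

  # identical arms: delta 0, ICER undefined
  same <- compute_icer(a, a, cfg)
  expect_false(same$icer_defined)
  expect_true(is.na(same$icer["discounted"]))

  # doubling both arms' costs doubles the incremental cost and the ICER
  dbl <- function(t) { t$cost <- 2 * t$cost; t }
  res2 <- compute_icer(dbl(a), dbl(b), cfg)
  expect_equal(unname(res2$incremental_cost), unname(2 * res$incremental_cost))
  expect_equal(unname(res2$icer), unname(2 * res$icer))
  expect_equal(res2$incremental_qalys, res$incremental_qalys)
})
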