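#' Linearly converge one arm's monthly rate towards another's
#'
#' The constant-risk assumption is relaxed by converging the comparator's
#' event rates to the intervention's over months 12-24 after surgery:
#' before month 12 the arm keeps its own rate, between months 12 and 24 the
#' rate is interpolated linearly, and from month 24 both arms share the
#' target rate.
#'
#' @param own Arm-specific monthly rate.
#' @param target Monthly rate converged to.
#' @param month Months since surgery (cycle start).
#' @param window Numeric length-2: start and end month of convergence.
#' @return Monthly rate at `month`.
#' @export
converge_transition_probabilities <- function(own, target, month,
                                              window = c(12, 24)) {
  if (month <= window[1]) return(own)
  if (month >= window[2]) return(target)
  f <- (month - window[1]) / (window[2] - window[1])
  own + f * (target - own)
}

#' Define a univariate scenario
#'
#' A scenario changes exactly one parameter dimension of a
#' [model_parameters()] bundle.
#'
#' @param name Scenario label.
#' @param modify Function `model_parameters -> model_parameters`.
#' @param converge If `TRUE`, the scenario is solved with converging
#'   transition probabilities.
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, modify = identity, converge = FALSE) {
  stopifnot(is.character(name), is.function(modify))
  structure(list(name = name, modify = modify, converge = converge),
            class = "scenario")
}

scale_costs <- function(params, items, factor) {
  for (side in c("intervention", "comparator"))
    for (it in items)
      params[[side]]$costs[[it]] <- params[[side]]$costs[[it]] * factor
  params
}

set_horizon <- function(params, years) {
  params$config$horizon_years <- years
  params
}

lifetime_horizon_years <- function(params, max_age = 100) {
  cyc_y <- params$config$cycle_months / 12
  ceiling((max_age - params$config$start_age) / cyc_y) * cyc_y
}

#' The published univariate scenario set
#'
#' Time horizon 5 years and lifetime (run to age 100), discounting 2.5% and
#' 7.5%, procedure (surgery + hospitalisation) costs +/-10%, soft-tissue
#' management cost +/-10%, converging transition probabilities (months
#' 12-24), and the CHL/MHL-only utility inputs.
#'
#' @param params Base-case [model_parameters()] (used to size the lifetime
#'   horizon).
#' @return Named list of [scenario()] objects.
#' @export
default_scenarios <- function(params) {
  chl <- function(p) {
    alt <- default_parameters(subgroup = "chl_mhl", config = p$config,
                              life_table = p$life_table)
    p$intervention$utilities <- alt$intervention$utilities
    p$comparator$utilities <- alt$comparator$utilities
    p
  }
  list(
    horizon_5y = scenario("horizon_5y", function(p) set_horizon(p, 5)),
    horizon_lifetime = scenario("horizon_lifetime", function(p)
      set_horizon(p, lifetime_horizon_years(p))),
    discount_2.5 = scenario("discount_2.5", function(p) {
      p$config$discount_annual <- 0.025; p
    }),
    discount_7.5 = scenario("discount_7.5", function(p) {
      p$config$discount_annual <- 0.075; p
    }),
    procedure_costs_minus10 = scenario("procedure_costs_minus10", function(p)
      scale_costs(p, c("surgery", "hospitalisation"), 0.9)),
    procedure_costs_plus10 = scenario("procedure_costs_plus10", function(p)
      scale_costs(p, c("surgery", "hospitalisation"), 1.1)),
    ae_cost_minus10 = scenario("ae_cost_minus10", function(p)
      scale_costs(p, "ae_management", 0.9)),
    ae_cost_plus10 = scenario("ae_cost_plus10", function(p)
      scale_costs(p, "ae_management", 1.1)),
    converging_tp = scenario("converging_tp", identity, converge = TRUE),
    chl_mhl_utilities = scenario("chl_mhl_utilities", chl))
}

#' Univariate (tornado) sensitivity analysis
#'
#' Solves the base case, then one run per scenario, and returns the table
#' sorted by absolute deviation from the base-case discounted ICER
#' (tornado order).
#'
#' @param params Base-case [model_parameters()].
#' @param scenarios List of [scenario()] objects; defaults to
#'   [default_scenarios()].
#' @return A data.frame of class `tornado_table` with columns `scenario`,
#'   `icer`, `icer_undiscounted`, `incremental_cost`, `incremental_qalys`,
#'   `delta_vs_base`; the base-case ICER is attached as attribute
#'   `"base_icer"`.
#' @export
run_univariate <- function(params, scenarios = default_scenarios(params)) {
  base <- run_base_case(params)
  rows <- lapply(scenarios, function(sc) {
    stopifnot(inherits(sc, "scenario"))
    p <- sc$modify(params)
    res <- run_base_case(p, converge = sc$converge)
    data.frame(scenario = sc$name,
               icer = res$icer[["discounted"]],
               icer_undiscounted = res$icer[["undiscounted"]],
               incremental_cost = res$incremental_cost[["discounted"]],
               incremental_qalys = res$incremental_qalys[["discounted"]])
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$delta_vs_base <- out$icer - base$icer[["discounted"]]
  out <- out[order(-abs(out$delta_vs_base)), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$icer[["discounted"]]
  attr(out, "base") <- base
  class(out) <- c("tornado_table", class(out))
  out
}

# ---- probabilistic sensitivity analysis -------------------------------------

# method-of-moments beta from mean and standard error
beta_moments <- function(mean, se) {
  if (is.na(se) || se < 0) stop("beta_moments: se must be >= 0")
  nu <- mean * (1 - mean) / se^2 - 1
  if (nu <= 0) stop("beta_moments: se too large for a beta distribution")
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

# method-of-moments gamma from mean and standard error
gamma_moments <- function(mean, se) {
  if (is.na(se) || se < 0) stop("gamma_moments: se must be >= 0")
  shape <- (mean / se)^2
  c(shape = shape, rate = shape / mean)
}

#' Probabilistic sensitivity analysis by Monte Carlo simulation
#'
#' Per draw, every model input is sampled and the deterministic engine is
#' solved for both arms.  Distributions (all method-of-moments):
#' * baseline utility: beta with the pooled pre-operative mean and its
#'   meta-analysis standard error (one draw applied to both arms);
#' * utility gains: normal with the arm means and standard errors.  With
#'   the default `gain_model = "common"` a single standard-normal deviate
#'   scales all gain draws, so each gain keeps its marginal distribution
#'   while the between-arm increment stays at its evidence-based value;
#'   `gain_model = "independent"` draws each gain independently (see the
#'   methods vignette for why the common-deviate model is the default);
#' * start age: normal;
#' * costs: gamma with SE equal to `cost_se_frac` (default 10%) of the
#'   mean; arm-specific tariffs (device, sound processor) are drawn per
#'   arm, shared tariffs (surgery, hospitalisation, AE management) once;
#' * monthly event rates: beta(events, exposure - events);
#' * comparator reoperation split: beta from the observed
#'   explantation/reimplantation counts (revision fraction fixed at its
#'   point value of zero).
#'
#' Draws are consumed in a fixed documented order from one RNG stream, so a
#' given seed reproduces the sample list exactly.
#'
#' @param params [model_parameters()] with a populated `psa` element
#'   (see [default_parameters()]).
#' @param n_draws Number of Monte Carlo iterations (>= 1); the published
#'   analysis used 1000.
#' @param seed Integer seed (mandatory).
#' @param gain_model `"common"` (default, from `params$psa`) or
#'   `"independent"`.
#' @return An object of class `psa_result`: data.frame with one row per
#'   draw (`draw`, `inc_cost`, `inc_qalys`, `icer`, `dominant`,
#'   `dominated`), the base-case `ce_result` attached as attribute
#'   `"base"`, plus `"seed"` and `"n_draws"`.
#' @export
run_psa <- function(params, n_draws = 1000, seed,
                    gain_model = NULL) {
  stopifnot(inherits(params, "model_parameters"), n_draws >= 1)
  if (missing(seed)) stop("run_psa: a seed is required for reproducibility")
  psa <- params$psa
  if (is.null(psa)) stop("run_psa: params carries no psa hyperparameters")
  if (is.null(gain_model)) gain_model <- psa$gain_model %||% "common"
  gain_model <- match.arg(gain_model, c("common", "independent"))

  base <- run_base_case(params)
  int0 <- params$intervention; cmp0 <- params$comparator
  u_int <- int0$utilities; u_cmp <- cmp0$utilities
  cfg0 <- params$config

  # a standard error of exactly zero means a degenerate (fixed) parameter;
  # NA or negative standard errors are configuration errors
  se_chk <- function(se, what) {
    if (is.null(se) || is.na(se) || se < 0)
      stop("run_psa: invalid standard error for ", what)
    se
  }
  se_b <- se_chk(u_int$se_baseline, "baseline utility")
  for (nm in c("se_3m", "se_6m")) {
    se_chk(u_int[[nm]], paste("intervention", nm))
    se_chk(u_cmp[[nm]], paste("comparator", nm))
  }
  base_beta <- if (se_b > 0) beta_moments(u_int$baseline, se_b)
  split_ab <- if (!is.null(psa$split_events))
    c(psa$split_events[["explant"]], psa$split_events[["reimplant"]])

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  draw_gain <- function(mean, se, z) mean + z * se
  clamp_u <- function(u, b) min(u, 1 - b)  # keep aided utility <= 1

  out <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    # 1. utility gains (common deviate or independent draws)
    if (gain_model == "common") {
      z <- stats::rnorm(1)
      z4 <- rep(z, 4)
    } else {
      z4 <- stats::rnorm(4)
    }
    g3_i <- draw_gain(u_int$gain_3m, u_int$se_3m, z4[1])
    g6_i <- draw_gain(u_int$gain_6m, u_int$se_6m, z4[2])
    g3_c <- draw_gain(u_cmp$gain_3m, u_cmp$se_3m, z4[3])
    g6_c <- draw_gain(u_cmp$gain_6m, u_cmp$se_6m, z4[4])
    # 2. baseline utility (common to both arms)
    b <- if (is.null(base_beta)) u_int$baseline
         else stats::rbeta(1, base_beta[1], base_beta[2])
    # 3. start age
    age <- if (psa$start_age_se > 0)
      stats::rnorm(1, cfg0$start_age, psa$start_age_se) else cfg0$start_age
    age <- min(max(age, 18), 90)
    # 4. costs
    gdraw <- function(mean) {
      if (mean <= 0 || psa$cost_se_frac == 0) return(mean)
      g <- gamma_moments(mean, psa$cost_se_frac * mean)
      stats::rgamma(1, shape = g["shape"], rate = g["rate"])
    }
    dev_i <- gdraw(int0$costs$device); dev_c <- gdraw(cmp0$costs$device)
    sp_i <- gdraw(int0$costs$replacement_sound_processor)
    sp_c <- gdraw(cmp0$costs$replacement_sound_processor)
    surg <- gdraw(int0$costs$surgery)
    hosp <- gdraw(int0$costs$hospitalisation)
    aec <- gdraw(int0$costs$ae_management)
    # 5. monthly event rates (beta from events / exposure-months; fixed at
    #    the point rates when no counts are supplied)
    if (!is.null(psa$events)) {
      rdraw <- function(ev) {
        stats::rbeta(1, max(ev[1], 0.5), max(ev[2] - ev[1], 0.5))
      }
      r_reop_i <- rdraw(psa$events$osia_reop)
      r_reop_c <- rdraw(psa$events$baha_reop)
      r_ae_i <- rdraw(psa$events$osia_ae)
      r_ae_c <- rdraw(psa$events$baha_ae)
    } else {
      r_reop_i <- int0$monthly_reop_rate; r_reop_c <- cmp0$monthly_reop_rate
      r_ae_i <- int0$monthly_ae_rate; r_ae_c <- cmp0$monthly_ae_rate
    }
    # 6. comparator reoperation split (explant fraction)
    f_expl <- if (is.null(split_ab)) cmp0$reop_split$explant
              else stats::rbeta(1, split_ab[1], split_ab[2])

    mk_util <- function(g3, g6) {
      utility_schedule(b, clamp_u(g3, b), clamp_u(g6, b))
    }
    int <- arm_parameters(int0$name,
      cost_set(dev_i, sp_i, surg, hosp, aec),
      mk_util(g3_i, g6_i), r_reop_i, int0$reop_split, r_ae_i,
      int0$reimplant_includes_device)
    cmp_split <- if (is.null(split_ab)) cmp0$reop_split
                 else reoperation_split(0, f_expl, 1 - f_expl)
    cmp <- arm_parameters(cmp0$name,
      cost_set(dev_c, sp_c, surg, hosp, aec),
      mk_util(g3_c, g6_c), r_reop_c, cmp_split, r_ae_c,
      cmp0$reimplant_includes_device)
    cfg <- cfg0; cfg$start_age <- age

    res <- compute_icer(run_arm(int, cfg, params$life_table),
                        run_arm(cmp, cfg, params$life_table), cfg)
    dc <- res$incremental_cost[["discounted"]]
    dq <- res$incremental_qalys[["discounted"]]
    out[[i]] <- c(dc, dq)
  }
  m <- do.call(rbind, out)
  df <- data.frame(draw = seq_len(n_draws), inc_cost = m[, 1],
                   inc_qalys = m[, 2])
  df$icer <- ifelse(df$inc_qalys != 0, df$inc_cost / df$inc_qalys, NA_real_)
  df$dominant <- df$inc_cost < 0 & df$inc_qalys > 0
  df$dominated <- df$inc_cost > 0 & df$inc_qalys < 0
  structure(df, class = c("psa_result", "data.frame"),
            base = base, seed = seed, n_draws = n_draws,
            gain_model = gain_model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of Monte Carlo draws
#' with positive net monetary benefit `wtp * dQ - dC`.  The empirical curve
#' is reported as-is (monotonicity is not enforced).
#'
#' @param samples A [run_psa()] result (or data.frame with `inc_cost` and
#'   `inc_qalys`).
#' @param wtp_grid Thresholds in AUD/QALY; the default grid covers 0 to
#'   100,000 in steps of 5,000 (including the 50,000 benchmark).
#' @return Data.frame with columns `wtp`, `probability`.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 100000, by = 5000)) {
  if (NROW(samples) == 0) stop("ceac: no samples")
  stopifnot(all(c("inc_cost", "inc_qalys") %in% names(samples)))
  prob <- vapply(wtp_grid, function(l)
    mean(l * samples$inc_qalys - samples$inc_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}
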