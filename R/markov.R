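# Health states of the cohort model.  The four tunnel quarters force a
# reimplanted cohort through the one-year rehabilitation phase with
# time-dependent utilities before it reaches the steady aided-second state.
MODEL_STATES <- c("aided_first", "aided_revised",
                  "tunnel_q1", "tunnel_q2", "tunnel_q3", "tunnel_q4",
                  "aided_second", "unaided", "dead")
AIDED_STATES <- c("aided_first", "aided_revised",
                  "tunnel_q1", "tunnel_q2", "tunnel_q3", "tunnel_q4",
                  "aided_second")

#' Health state names of the cohort model
#'
#' @return Character vector of the nine state identifiers in model order.
#' @export
model_states <- function() MODEL_STATES

#' Build the one-cycle transition matrix
#'
#' Transitions out of the aided states combine background mortality with the
#' per-cycle reoperation risk.  Mortality applies first; conditional on
#' survival, a reoperation sends the cohort to a revision (stay aided),
#' explantation (permanently unaided) or reimplantation (enter the one-year
#' tunnel) destination per the reoperation split.  Tunnel states advance
#' deterministically (mortality aside) one quarter per cycle into the
#' aided-second state.  Holders of a second device face the same
#' reoperation risk, but with no third device offered: any non-revision
#' reoperation of a second device leads to the unaided state.  The dead
#' state is absorbing.
#'
#' @param p_reop Per-cycle reoperation probability in \[0, 1\].
#' @param split A [reoperation_split()].
#' @param p_die Per-cycle death probability in \[0, 1\].
#' @return A 9 x 9 row-stochastic matrix with dimnames [model_states()].
#' @export
build_transition_matrix <- function(p_reop, split, p_die) {
  stopifnot(inherits(split, "reoperation_split"))
  if (p_reop < 0 || p_reop > 1 || p_die < 0 || p_die > 1)
    stop("build_transition_matrix: probabilities must be in [0, 1]")
  n <- length(MODEL_STATES)
  M <- matrix(0, n, n, dimnames = list(MODEL_STATES, MODEL_STATES))
  s <- 1 - p_die
  d <- split_reoperation(p_reop, split)

  M["aided_first", "dead"] <- p_die
  M["aided_first", "aided_revised"] <- s * d[["revision"]]
  M["aided_first", "unaided"] <- s * d[["explant"]]
  M["aided_first", "tunnel_q1"] <- s * d[["reimplant"]]
  M["aided_first", "aided_first"] <- s * (1 - p_reop)

  M["aided_revised", "dead"] <- p_die
  M["aided_revised", "aided_revised"] <- s * (1 - p_reop) + s * d[["revision"]]
  M["aided_revised", "unaided"] <- s * d[["explant"]]
  M["aided_revised", "tunnel_q1"] <- s * d[["reimplant"]]

  tun <- c("tunnel_q1", "tunnel_q2", "tunnel_q3", "tunnel_q4")
  nxt <- c("tunnel_q2", "tunnel_q3", "tunnel_q4", "aided_second")
  for (i in seq_along(tun)) {
    M[tun[i], "dead"] <- p_die
    M[tun[i], nxt[i]] <- s
  }

  M["aided_second", "dead"] <- p_die
  M["aided_second", "aided_second"] <- s * (1 - p_reop) + s * d[["revision"]]
  M["aided_second", "unaided"] <- s * (d[["explant"]] + d[["reimplant"]])

  M["unaided", "dead"] <- p_die
  M["unaided", "unaided"] <- s
  M["dead", "dead"] <- 1

  if (any(abs(rowSums(M) - 1) > 1e-9))
    stop("build_transition_matrix: rows do not sum to 1")
  M
}

#' Utility for a state at a given time since (re)implantation
#'
#' First post-operative quarter: baseline; second quarter: baseline plus the
#' 3-month gain; third quarter onwards: baseline plus the 6-month gain, held
#' constant.  The unaided (explanted) state reverts to baseline; death
#' carries zero utility.  The tunnel quarters encode the same schedule for a
#' replacement device.
#'
#' @param state One of [model_states()].
#' @param cycles_since_implant Completed quarterly cycles since the current
#'   device was (re)implanted; 0 during the first post-operative quarter.
#'   Only used for `aided_first`.
#' @param utilities A [utility_schedule()].
#' @return Utility value.
#' @export
utility_for <- function(state, cycles_since_implant, utilities) {
  stopifnot(inherits(utilities, "utility_schedule"))
  b <- utilities$baseline
  switch(state,
    aided_first = b + if (cycles_since_implant <= 0) 0
                      else if (cycles_since_implant == 1) utilities$gain_3m
                      else utilities$gain_6m,
    aided_revised = b + utilities$gain_6m,
    tunnel_q1 = b,
    tunnel_q2 = b + utilities$gain_3m,
    tunnel_q3 = b + utilities$gain_6m,
    tunnel_q4 = b + utilities$gain_6m,
    aided_second = b + utilities$gain_6m,
    unaided = b,
    dead = 0,
    stop("utility_for: unknown state ", state))
}

#' Run the cohort through the Markov model
#'
#' The cohort starts fully in `aided_first` at surgery.  Each cycle the
#' transition matrix is rebuilt with the age-specific quarterly death
#' probability `1 - (1 - qx)^(cycle_years)` and the (possibly converged)
#' per-cycle event probabilities.  Expected reoperation events by type are
#' recorded per cycle for costing.
#'
#' @param arm An [arm_parameters()] object.
#' @param config A [model_config()].
#' @param life_table Life table data.frame (`age`, `qx`).
#' @param converge_to Optional second [arm_parameters()]: when given, this
#'   arm's monthly reoperation and complication rates are linearly
#'   interpolated towards `converge_to`'s rates between months 12 and 24
#'   post-surgery and equal thereafter (the converging-transition-
#'   probability scenario).
#' @return An object of class `cohort_trace`: list with `occupancy`
#'   ((cycles+1) x 9 matrix), `times` (years at each row), `ages`,
#'   `p_die`, `p_reop`, `p_ae` (per cycle) and per-cycle expected event
#'   counts `n_revision`, `n_explant`, `n_reimplant`.
#' @export
run_cohort <- function(arm, config, life_table, converge_to = NULL) {
  stopifnot(inherits(arm, "arm_parameters"), inherits(config, "model_config"))
  validate_life_table(life_table)
  cyc_y <- config$cycle_months / 12
  n_cyc <- as.integer(round(config$horizon_years / cyc_y))
  occ <- matrix(0, n_cyc + 1, length(MODEL_STATES),
                dimnames = list(NULL, MODEL_STATES))
  occ[1, "aided_first"] <- 1

  p_die <- p_reop <- p_ae <- numeric(n_cyc)
  n_rev <- n_expl <- n_reimp <- numeric(n_cyc)
  aided_risk <- c("aided_first", "aided_revised", "aided_second")

  for (k in seq_len(n_cyc)) {
    age <- config$start_age + (k - 1) * cyc_y
    qx <- lookup_qx(life_table, age)
    p_die[k] <- 1 - (1 - qx)^cyc_y

    month <- (k - 1) * config$cycle_months
    rates <- c(reop = arm$monthly_reop_rate, ae = arm$monthly_ae_rate)
    if (!is.null(converge_to)) {
      rates["reop"] <- converge_transition_probabilities(
        arm$monthly_reop_rate, converge_to$monthly_reop_rate, month)
      rates["ae"] <- converge_transition_probabilities(
        arm$monthly_ae_rate, converge_to$monthly_ae_rate, month)
    }
    p_reop[k] <- rate_to_cycle_probability(rates[["reop"]], config$cycle_months)
    p_ae[k] <- rate_to_cycle_probability(rates[["ae"]], config$cycle_months)

    M <- build_transition_matrix(p_reop[k], arm$reop_split, p_die[k])
    cur <- occ[k, ]
    occ[k + 1, ] <- as.numeric(cur %*% M)

    # expected reoperation events by type (revisions include the self-loop
    # revisions of already-revised/second devices)
    surv_reop <- (1 - p_die[k]) * p_reop[k]
    at_risk <- sum(cur[aided_risk])
    n_rev[k] <- at_risk * surv_reop * arm$reop_split$revision
    first_tier <- sum(cur[c("aided_first", "aided_revised")])
    n_reimp[k] <- first_tier * surv_reop * arm$reop_split$reimplant
    n_expl[k] <- first_tier * surv_reop * arm$reop_split$explant +
      cur[["aided_second"]] * surv_reop *
        (arm$reop_split$explant + arm$reop_split$reimplant)

    if (any(occ[k + 1, ] < -1e-12) ||
        abs(sum(occ[k + 1, ]) - 1) > 1e-9)
      stop("run_cohort: occupancy left the simplex at cycle ", k)
  }

  structure(list(occupancy = occ, times = (0:n_cyc) * cyc_y,
                 ages = config$start_age + (0:n_cyc) * cyc_y,
                 p_die = p_die, p_reop = p_reop, p_ae = p_ae,
                 n_revision = n_rev, n_explant = n_expl,
                 n_reimplant = n_reimp, cycle_years = cyc_y,
                 arm = arm$name),
            class = "cohort_trace")
}

#' Accrue costs and QALYs along a cohort trace
#'
#' Continuous accruals (utilities, soft-tissue management costs) use
#' half-cycle-corrected occupancy (mean of start- and end-of-cycle
#' occupancy) and are discounted at the cycle midpoint with
#' `(1 + r)^(-t)`.  One-off costs are discounted at event time: the initial
#' device, surgery and hospitalisation at t = 0; reoperation procedure
#' costs at the midpoint of the cycle in which the transition occurs
#' (surgery + hospitalisation for every reoperation type; a reimplantation
#' additionally incurs the device tariff only when the arm sets
#' `reimplant_includes_device`); and sound-processor upgrades at every
#' upgrade anniversary from year `sp_upgrade_interval_years` up to and
#' including the horizon boundary, weighted by the occupancy of the aided
#' (implanted) states at that time.
#'
#' @param trace A [run_cohort()] result.
#' @param arm The [arm_parameters()] used to produce it.
#' @param config The [model_config()] used to produce it.
#' @return An object of class `arm_totals`: list with `cost`, `qalys`,
#'   `life_years` (each `c(discounted, undiscounted)`) and a cost
#'   `breakdown`.
#' @export
accrue_outcomes <- function(trace, arm, config) {
  stopifnot(inherits(trace, "cohort_trace"),
            inherits(arm, "arm_parameters"))
  occ <- trace$occupancy
  n_cyc <- nrow(occ) - 1L
  cyc_y <- trace$cycle_years
  r <- config$discount_annual
  cs <- arm$costs
  ut <- arm$utilities

  # per-cycle utility vectors (time-dependent only through aided_first)
  k <- seq_len(n_cyc)
  u_first <- ut$baseline + ifelse(k == 1, 0,
                                  ifelse(k == 2, ut$gain_3m, ut$gain_6m))
  u_static <- vapply(MODEL_STATES, utility_for, numeric(1),
                     cycles_since_implant = 2L, utilities = ut)

  occ_h <- (occ[k, , drop = FALSE] + occ[k + 1, , drop = FALSE]) / 2
  t_mid <- (k - 0.5) * cyc_y
  df_mid <- (1 + r)^(-t_mid)

  u_mat <- matrix(u_static, n_cyc, length(MODEL_STATES), byrow = TRUE,
                  dimnames = list(NULL, MODEL_STATES))
  u_mat[, "aided_first"] <- u_first
  q_cycle <- rowSums(u_mat * occ_h) * cyc_y
  ly_cycle <- rowSums(occ_h[, MODEL_STATES != "dead", drop = FALSE]) * cyc_y

  ae_cycle <- cs$ae_management * trace$p_ae *
    rowSums(occ_h[, AIDED_STATES, drop = FALSE])
  reop_proc <- cs$surgery + cs$hospitalisation
  reimp_cost <- reop_proc +
    if (isTRUE(arm$reimplant_includes_device)) cs$device else 0
  reop_cycle <- (trace$n_revision + trace$n_explant) * reop_proc +
    trace$n_reimplant * reimp_cost

  upfront <- cs$device + cs$surgery + cs$hospitalisation
  horizon <- n_cyc * cyc_y
  up_t <- seq(config$sp_upgrade_interval_years, horizon,
              by = config$sp_upgrade_interval_years)
  up_t <- up_t[up_t > 0]
  sp_undisc <- sp_disc <- 0
  for (t in up_t) {
    row <- as.integer(round(t / cyc_y)) + 1L
    aided <- sum(occ[row, AIDED_STATES])
    sp_undisc <- sp_undisc + cs$replacement_sound_processor * aided
    sp_disc <- sp_disc + cs$replacement_sound_processor * aided * (1 + r)^(-t)
  }

  cost_undisc <- upfront + sum(ae_cycle) + sum(reop_cycle) + sp_undisc
  cost_disc <- upfront + sum((ae_cycle + reop_cycle) * df_mid) + sp_disc
  structure(list(
    cost = c(discounted = cost_disc, undiscounted = cost_undisc),
    qalys = c(discounted = sum(q_cycle * df_mid),
              undiscounted = sum(q_cycle)),
    life_years = c(discounted = sum(ly_cycle * df_mid),
                   undiscounted = sum(ly_cycle)),
    breakdown = list(upfront = upfront,
                     sound_processor = c(discounted = sp_disc,
                                         undiscounted = sp_undisc),
                     reoperations = c(discounted = sum(reop_cycle * df_mid),
                                      undiscounted = sum(reop_cycle)),
                     ae_management = c(discounted = sum(ae_cycle * df_mid),
                                       undiscounted = sum(ae_cycle))),
    arm = arm$name), class = "arm_totals")
}

#' Run one arm end to end
#'
#' @inheritParams run_cohort
#' @return An `arm_totals` object with the `cohort_trace` attached as
#'   attribute `"trace"`.
#' @export
run_arm <- function(arm, config, life_table, converge_to = NULL) {
  trace <- run_cohort(arm, config, life_table, converge_to)
  out <- accrue_outcomes(trace, arm, config)
  attr(out, "trace") <- trace
  out
}

#' Incremental cost-effectiveness of intervention versus comparator
#'
#' @param intervention,comparator `arm_totals` from [run_arm()] /
#'   [accrue_outcomes()], computed under the same configuration.
#' @param config The shared [model_config()] (supplies the
#'   willingness-to-pay threshold).
#' @return An object of class `ce_result` with per-arm totals, incremental
#'   discounted/undiscounted costs and QALYs, ICERs (AUD per QALY), an
#'   `icer_defined` flag (FALSE when incremental QALYs are zero) and a
#'   `cost_effective` flag (discounted ICER at or below `wtp` with positive
#'   incremental QALYs).
#' @export
compute_icer <- function(intervention, comparator, config) {
  stopifnot(inherits(intervention, "arm_totals"),
            inherits(comparator, "arm_totals"),
            inherits(config, "model_config"))
  dc <- intervention$cost - comparator$cost
  dq <- intervention$qalys - comparator$qalys
  defined <- dq["discounted"] != 0
  icer <- ifelse(dq != 0, dc / dq, NA_real_)
  structure(list(intervention = intervention, comparator = comparator,
                 incremental_cost = dc, incremental_qalys = dq,
                 icer = icer,
                 icer_defined = unname(defined),
                 cost_effective = unname(defined && dq["discounted"] > 0 &&
                                           icer["discounted"] <= config$wtp),
                 wtp = config$wtp),
            class = "ce_result")
}

#' Run the deterministic two-arm base case
#'
#' @param params A [model_parameters()] bundle (see
#'   [default_parameters()]).
#' @param converge If `TRUE`, the comparator's event rates converge to the
#'   intervention's between months 12 and 24 (scenario analysis).
#' @return A `ce_result`.
#' @export
run_base_case <- function(params, converge = FALSE) {
  stopifnot(inherits(params, "model_parameters"))
  int <- run_arm(params$intervention, params$config, params$life_table)
  cmp <- run_arm(params$comparator, params$config, params$life_table,
                 converge_to = if (converge) params$intervention else NULL)
  compute_icer(int, cmp, params$config)
}

#' @export
print.ce_result <- function(x, ...) {
  fmt <- function(v) formatC(v, format = "f", digits = 2, big.mark = ",")
  cat("Cost-utility result (intervention vs comparator)\n")
  for (w in c("undiscounted", "discounted")) {
    cat(sprintf("  %-12s costs: %s vs %s (delta %s); QALYs: %s vs %s (delta %s)\n",
                w, fmt(x$intervention$cost[w]), fmt(x$comparator$cost[w]),
                fmt(x$incremental_cost[w]), fmt(x$intervention$qalys[w]),
                fmt(x$comparator$qalys[w]), fmt(x$incremental_qalys[w])))
    cat(sprintf("  %-12s ICER: %s AUD/QALY\n", w,
                if (x$icer_defined) fmt(x$icer[w]) else "undefined"))
  }
  cat(sprintf("  cost-effective at WTP %s: %s\n", fmt(x$wtp),
              x$cost_effective))
  invisible(x)
}
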