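#' Summary statistics for one study subgroup
#'
#' Container for the per-subgroup summaries (count, mean, variance) that
#' BCHI studies report separately for the conductive/mixed hearing loss
#' (CHL/MHL) and single-sided deafness (SSD) populations.
#'
#' @param label Subgroup identifier, e.g. `"chl_mhl"` or `"ssd"`.
#' @param n Number of observations (>= 1).
#' @param mean Subgroup mean, in endpoint units (dB, %, or utility).
#' @param variance Subgroup variance (>= 0), i.e. SD squared.
#' @param endpoint,timepoint Optional endpoint identifier and months since
#'   surgery; when present on both arguments of
#'   [pool_subgroup_summaries()] they must match.
#' @return An object of class `subgroup_summary`.
#' @export
subgroup_summary <- function(label, n, mean, variance,
                             endpoint = NA_character_, timepoint = NA_real_) {
  stopifnot(length(label) == 1L, length(n) == 1L, length(mean) == 1L,
            length(variance) == 1L)
  if (!is.numeric(n) || !is.finite(n) || n < 1)
    stop("subgroup_summary: n must be a number >= 1")
  if (!is.numeric(variance) || !is.finite(variance) || variance < 0)
    stop("subgroup_summary: variance must be >= 0")
  structure(list(label = as.character(label), n = as.numeric(n),
                 mean = as.numeric(mean), variance = as.numeric(variance),
                 endpoint = as.character(endpoint),
                 timepoint = as.numeric(timepoint)),
            class = "subgroup_summary")
}

#' Summary statistics for one study arm
#'
#' One endpoint at one timepoint for one study arm: the unit consumed by
#' [meta_analyze()]. `measure` distinguishes a pre-operative baseline level
#' from a change-from-baseline.
#'
#' @param study_id Source study identifier.
#' @param endpoint Endpoint identifier (`"pta4"`, `"speech_quiet"`,
#'   `"speech_noise"`, `"hui3"`, ...).
#' @param timepoint Months since surgery (0 for baseline).
#' @param measure `"baseline"` or `"change"`.
#' @param n Number of patients contributing (>= 1).
#' @param mean Arm mean in endpoint units.
#' @param sd Arm standard deviation (>= 0).
#' @return An object of class `study_arm_summary`.
#' @export
study_arm_summary <- function(study_id, endpoint, timepoint, measure, n,
                              mean, sd) {
  if (!is.numeric(n) || n < 1) stop("study_arm_summary: n must be >= 1")
  if (!is.numeric(sd) || sd < 0) stop("study_arm_summary: sd must be >= 0")
  measure <- match.arg(measure, c("baseline", "change"))
  structure(list(study_id = as.character(study_id),
                 endpoint = as.character(endpoint),
                 timepoint = as.numeric(timepoint),
                 measure = measure, n = as.numeric(n),
                 mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "study_arm_summary")
}

#' Pool two subgroup summaries into a whole-cohort summary
#'
#' Combines subgroup counts, means and variances into the mean and SD of the
#' concatenated cohort from first principles.  With `m`, `x`, `VAR(X)` for
#' the first subgroup and `n`, `y`, `VAR(Y)` for the second:
#' \deqn{\bar Z = (m \bar X + n \bar Y)/(m+n)}
#' \deqn{SD(Z)^2 = \frac{(m-1)VAR(X) + (n-1)VAR(Y) +
#'   m(\bar X-\bar Z)^2 + n(\bar Y-\bar Z)^2}{m+n-1}}
#' This is an exact algebraic identity: the result equals the sample mean
#' and (n-1 denominator) SD of the pooled individual observations.
#'
#' @param a,b `subgroup_summary` objects on the same endpoint/timepoint.
#' @param study_id,measure Metadata attached to the returned arm summary.
#' @return A `study_arm_summary` for the combined cohort.
#' @export
pool_subgroup_summaries <- function(a, b, study_id = "pooled",
                                    measure = "change") {
  stopifnot(inherits(a, "subgroup_summary"), inherits(b, "subgroup_summary"))
  if (!is.na(a$endpoint) && !is.na(b$endpoint) && a$endpoint != b$endpoint)
    stop("pool_subgroup_summaries: endpoints do not match (",
         a$endpoint, " vs ", b$endpoint, ")")
  if (!is.na(a$timepoint) && !is.na(b$timepoint) &&
      a$timepoint != b$timepoint)
    stop("pool_subgroup_summaries: timepoints do not match")
  m <- a$n; n <- b$n
  if (m + n < 2) stop("pool_subgroup_summaries: need at least 2 observations")
  z <- (m * a$mean + n * b$mean) / (m + n)
  ss <- (m - 1) * a$variance + (n - 1) * b$variance +
    m * (a$mean - z)^2 + n * (b$mean - z)^2
  study_arm_summary(study_id = study_id,
                    endpoint = if (is.na(a$endpoint)) b$endpoint else a$endpoint,
                    timepoint = if (is.na(a$timepoint)) b$timepoint else a$timepoint,
                    measure = measure, n = m + n, mean = z,
                    sd = sqrt(ss / (m + n - 1)))
}

#' Normal-quantile confidence interval
#'
#' Symmetric interval `estimate +/- z * se` with `z` the standard normal
#' quantile for the requested coverage (1.959964 at 95%).  Back-calculation
#' of the published single-study intervals matches the normal quantile, not
#' Student's t, so z is used throughout the package.
#'
#' @param estimate Point estimate.
#' @param se Standard error (>= 0).
#' @param level Coverage as a fraction in (0, 1); default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
confidence_interval <- function(estimate, se, level = 0.95) {
  if (!is.numeric(se) || any(se < 0)) stop("confidence_interval: se must be >= 0")
  if (level <= 0 || level >= 1) stop("confidence_interval: level must be in (0, 1)")
  z <- stats::qnorm((1 + level) / 2)
  c(estimate - z * se, estimate + z * se)
}

#' Random-effects inverse-variance meta-analysis of study arms
#'
#' Pools the arm means of `k` study arms sharing an endpoint, timepoint and
#' measure.  The variance of each arm mean is `sd^2 / n`.  Between-study
#' variance tau^2 is estimated by the DerSimonian-Laird moment estimator,
#' truncated at zero:
#' \deqn{\tau^2 = \max\left(0, \frac{Q - (k-1)}
#'   {\sum w_i - \sum w_i^2 / \sum w_i}\right)}
#' with fixed-effect weights \eqn{w_i = n_i / sd_i^2} and Cochran's
#' \eqn{Q = \sum w_i (\bar x_i - \bar x_{FE})^2}.  Random-effects weights
#' are \eqn{w_i^* = 1/(sd_i^2/n_i + \tau^2)}; the pooled mean is their
#' weighted average with standard error \eqn{\sqrt{1/\sum w_i^*}}.
#' A single arm is passed through unchanged (`se = sd/sqrt(n)`).
#'
#' @param arms List of [study_arm_summary()] objects (k >= 1), or a
#'   data.frame with columns `n`, `mean`, `sd` (and optionally `study_id`,
#'   `endpoint`, `timepoint`, `measure`).
#' @param level Confidence level for the reported interval.
#' @return An object of class `pooled_effect` with elements `mean`, `se`,
#'   `ci_low`, `ci_high`, `tau2`, `q`, `weights` (random-effects weights,
#'   summing to `1/se^2`), `k`, and the shared `endpoint`/`timepoint`/
#'   `measure`.
#' @export
meta_analyze <- function(arms, level = 0.95) {
  if (is.data.frame(arms)) arms <- arms_from_frame(arms)
  if (!is.list(arms) || length(arms) == 0)
    stop("meta_analyze: need at least one study arm")
  if (inherits(arms, "study_arm_summary")) arms <- list(arms)
  ok <- vapply(arms, inherits, logical(1), what = "study_arm_summary")
  if (!all(ok)) stop("meta_analyze: inputs must be study_arm_summary objects")
  ep <- unique(vapply(arms, `[[`, character(1), "endpoint"))
  tp <- unique(vapply(arms, `[[`, numeric(1), "timepoint"))
  ms <- unique(vapply(arms, `[[`, character(1), "measure"))
  if (length(ep) > 1) stop("meta_analyze: mixed endpoints: ",
                           paste(ep, collapse = ", "))
  if (length(tp) > 1) stop("meta_analyze: mixed timepoints")
  if (length(ms) > 1) stop("meta_analyze: mixed measures")
  k <- length(arms)
  m <- vapply(arms, `[[`, numeric(1), "mean")
  v <- vapply(arms, function(a) a$sd^2 / a$n, numeric(1))
  if (any(v <= 0) && k > 1)
    stop("meta_analyze: zero-variance arm cannot be weighted with others")

  if (k == 1L) {
    se <- sqrt(v)
    tau2 <- 0; q <- 0; w <- if (v > 0) 1 / v else Inf
    mu <- m
  } else {
    wf <- 1 / v
    mu_fe <- sum(wf * m) / sum(wf)
    q <- sum(wf * (m - mu_fe)^2)
    cc <- sum(wf) - sum(wf^2) / sum(wf)
    tau2 <- max(0, (q - (k - 1)) / cc)
    w <- 1 / (v + tau2)
    mu <- sum(w * m) / sum(w)
    se <- sqrt(1 / sum(w))
  }
  ci <- confidence_interval(mu, se, level)
  structure(list(mean = mu, se = se, ci_low = ci[1], ci_high = ci[2],
                 tau2 = tau2, q = q, weights = w, k = k,
                 endpoint = ep, timepoint = tp, measure = ms,
                 level = level,
                 studies = vapply(arms, `[[`, character(1), "study_id")),
            class = "pooled_effect")
}

arms_from_frame <- function(df) {
  need <- c("n", "mean", "sd")
  if (!all(need %in% names(df)))
    stop("meta_analyze: data.frame needs columns n, mean, sd")
  lapply(seq_len(nrow(df)), function(i) {
    study_arm_summary(
      study_id = if ("study_id" %in% names(df)) df$study_id[i] else paste0("s", i),
      endpoint = if ("endpoint" %in% names(df)) df$endpoint[i] else NA_character_,
      timepoint = if ("timepoint_months" %in% names(df)) df$timepoint_months[i]
                  else if ("timepoint" %in% names(df)) df$timepoint[i] else NA_real_,
      measure = if ("measure" %in% names(df)) df$measure[i] else "change",
      n = df$n[i], mean = df$mean[i], sd = df$sd[i])
  })
}

#' Anchored indirect treatment comparison of two pooled effects
#'
#' Difference between two change-from-baseline effects, each anchored on its
#' own unaided baseline, with no head-to-head data:
#' `D = mean(intervention) - mean(comparator)`,
#' `SE(D) = sqrt(VAR(intervention) + VAR(comparator))`.  Significance is
#' assessed at the complement of `level` with no multiplicity correction.
#'
#' @param intervention,comparator `pooled_effect` objects (single arms can be
#'   wrapped via `meta_analyze(list(arm))`) on the same endpoint, timepoint
#'   and measure.
#' @param level Confidence level, default 0.95.
#' @return An object of class `itc_result` with `difference`, `se`,
#'   `ci_low`, `ci_high` and logical `significant`.
#' @export
itc_difference <- function(intervention, comparator, level = 0.95) {
  if (inherits(intervention, "study_arm_summary"))
    intervention <- meta_analyze(list(intervention), level)
  if (inherits(comparator, "study_arm_summary"))
    comparator <- meta_analyze(list(comparator), level)
  stopifnot(inherits(intervention, "pooled_effect"),
            inherits(comparator, "pooled_effect"))
  if (!is.na(intervention$endpoint) && !is.na(comparator$endpoint) &&
      intervention$endpoint != comparator$endpoint)
    stop("itc_difference: endpoints do not match (",
         intervention$endpoint, " vs ", comparator$endpoint, ")")
  if (!is.na(intervention$timepoint) && !is.na(comparator$timepoint) &&
      intervention$timepoint != comparator$timepoint)
    stop("itc_difference: timepoints do not match")
  d <- intervention$mean - comparator$mean
  se <- sqrt(intervention$se^2 + comparator$se^2)
  ci <- confidence_interval(d, se, level)
  z <- stats::qnorm((1 + level) / 2)
  structure(list(difference = d, se = se, ci_low = ci[1], ci_high = ci[2],
                 significant = se > 0 && abs(d) / se > z,
                 endpoint = intervention$endpoint,
                 timepoint = intervention$timepoint, level = level),
            class = "itc_result")
}

#' @export
print.pooled_effect <- function(x, digits = 2, ...) {
  cat(sprintf("Pooled effect (%s, %g mo, %s): %.*f  [%.*f, %.*f]\n",
              x$endpoint, x$timepoint, x$measure,
              digits, x$mean, digits, x$ci_low, digits, x$ci_high))
  cat(sprintf("  k = %d, se = %.4f, tau2 = %.4f, Q = %.4f\n",
              x$k, x$se, x$tau2, x$q))
  invisible(x)
}

#' @export
print.itc_result <- function(x, digits = 2, ...) {
  cat(sprintf("Indirect comparison (%s, %g mo): %.*f  [%.*f, %.*f]%s\n",
              x$endpoint, x$timepoint, digits, x$difference,
              digits, x$ci_low, digits, x$ci_high,
              if (isTRUE(x$significant)) "  *" else ""))
  invisible(x)
}
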