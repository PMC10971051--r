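#' Specification for a synthetic before/after hearing study
#'
#' Describes one study with subgroup sizes and, per subgroup, normal
#' generating parameters for any number of endpoint measures (baseline
#' levels and follow-up changes).  The normal generative model matches the
#' moment-based pooling and meta-analysis formulas the package implements.
#'
#' @param study_id Study label.
#' @param subgroups Data.frame with columns `label`, `n` (patients per
#'   subgroup, e.g. CHL/MHL and SSD).
#' @param measures Data.frame with columns `subgroup`, `endpoint`,
#'   `timepoint` (months), `measure` (`"baseline"`/`"change"`), `mean`,
#'   `sd`.
#' @return An object of class `study_spec`.
#' @export
study_spec <- function(study_id, subgroups, measures) {
  stopifnot(is.data.frame(subgroups), is.data.frame(measures),
            all(c("label", "n") %in% names(subgroups)),
            all(c("subgroup", "endpoint", "timepoint", "measure",
                  "mean", "sd") %in% names(measures)))
  if (any(subgroups$n < 1)) stop("study_spec: subgroup n must be >= 1")
  if (any(measures$sd < 0)) stop("study_spec: sd must be >= 0")
  if (!all(measures$subgroup %in% subgroups$label))
    stop("study_spec: measures reference unknown subgroups")
  structure(list(study_id = study_id, subgroups = subgroups,
                 measures = measures), class = "study_spec")
}

#' Generate patient-level records from a study specification
#'
#' Values are drawn independently from normal distributions with the
#' specified per-subgroup parameters.  Deterministic given the seed; the
#' caller's RNG state is left untouched.
#'
#' @param spec A [study_spec()].
#' @param seed Integer seed (mandatory).
#' @return Long-format data.frame with columns `patient_id`, `study_id`,
#'   `subgroup`, `endpoint`, `timepoint`, `measure`, `value`.
#' @export
generate_study <- function(spec, seed) {
  stopifnot(inherits(spec, "study_spec"))
  if (missing(seed)) stop("generate_study: a seed is required")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  offsets <- c(0, cumsum(spec$subgroups$n))
  names(offsets) <- c(spec$subgroups$label, "")
  rows <- lapply(seq_len(nrow(spec$measures)), function(i) {
    m <- spec$measures[i, ]
    n <- spec$subgroups$n[spec$subgroups$label == m$subgroup]
    data.frame(
      patient_id = sprintf("%s_p%03d", m$subgroup,
                           offsets[[m$subgroup]] + seq_len(n)),
      study_id = spec$study_id, subgroup = m$subgroup,
      endpoint = m$endpoint, timepoint = m$timepoint, measure = m$measure,
      value = stats::rnorm(n, m$mean, m$sd))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Summarise patient-level records
#'
#' Sample mean, sample SD (n - 1 denominator) and count per endpoint /
#' timepoint / measure, optionally split by subgroup.
#'
#' @param records Output of [generate_study()] (or any data.frame with the
#'   same columns).
#' @param by_subgroup Keep subgroups separate (`TRUE`) or summarise the
#'   whole cohort (`FALSE`).
#' @return Data.frame with columns `endpoint`, `timepoint`, `measure`,
#'   (`subgroup`,) `n`, `mean`, `sd`.  `sd` is `NA` for single-record
#'   groups (degenerate).
#' @export
summarize_records <- function(records, by_subgroup = TRUE) {
  if (NROW(records) == 0) stop("summarize_records: no records")
  keys <- c("endpoint", "timepoint", "measure",
            if (by_subgroup) "subgroup")
  split_idx <- interaction(records[keys], drop = TRUE)
  parts <- split(records, split_idx)
  out <- lapply(parts, function(p) {
    cbind(p[1, keys, drop = FALSE],
          data.frame(n = nrow(p), mean = mean(p$value),
                     sd = if (nrow(p) > 1) stats::sd(p$value) else NA_real_))
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$endpoint, res$timepoint, res$measure), , drop = FALSE]
}

#' Construct a life table
#'
#' Three generating models:
#' * `"constant"`: the same annual death probability `q` at every age;
#' * `"gompertz"`: Gompertz-Makeham hazard `q_x = makeham + a * exp(b * x)`
#'   capped at 1 (monotone in age);
#' * `"fixture"`: read a CSV with columns `age`, `qx`.
#'
#' @param model `"constant"`, `"gompertz"` or `"fixture"`.
#' @param q Annual death probability for the constant model.
#' @param a,b,makeham Gompertz-Makeham parameters.
#' @param path CSV path for the fixture model.
#' @param max_age Last tabulated age (default 100).
#' @return Data.frame with columns `age` (0..`max_age`), `qx`.
#' @export
make_life_table <- function(model = c("constant", "gompertz", "fixture"),
                            q = 0, a = 1.72e-5, b = 0.0977, makeham = 4e-4,
                            path = NULL, max_age = 100) {
  model <- match.arg(model)
  ages <- 0:max_age
  lt <- switch(model,
    constant = {
      if (q < 0 || q > 1) stop("make_life_table: q must be in [0, 1]")
      data.frame(age = ages, qx = rep(q, length(ages)))
    },
    gompertz = {
      qx <- pmin(1, makeham + a * exp(b * ages))
      if (any(qx < 0)) stop("make_life_table: negative qx")
      data.frame(age = ages, qx = qx)
    },
    fixture = if (is.null(path)) read_life_table() else read_life_table(path))
  validate_life_table(lt)
  lt
}
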