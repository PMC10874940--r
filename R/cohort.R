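#' Columns required of a cohort table
#'
#' One row per at-risk observation (a patient with two bleeds contributes two
#' rows). Times are stored in months on disk and converted to years
#' (`time_months / 12`) for person-year analytics.
#' @keywords internal
cohort_columns <- function() {
  c("patient_id", "time_months", "event", "volume_cm3", "margin_dose_gy",
    "compactness_index", "morphology", "sm_grade", "eloquent",
    "deep_drainage", "deep_location", "aneurysm", "sex", "age_years",
    "target_coverage", "stratum")
}

#' Configure a simulated bAVM cohort
#'
#' Patients are assigned to strata with exponential hemorrhage hazards
#' derived from annual event probabilities via `lambda = -log(1 - p)`, which
#' makes "p per year" exact under exponential waiting times. Follow-up
#' (censoring) times are drawn from `followup` and the observed time is the
#' minimum of the event and censoring time.
#'
#' @param n_patients Number of patients (>= 1).
#' @param followup Named list describing the censoring distribution in
#'   months: `list(dist = "uniform", min = , max = )` or
#'   `list(dist = "fixed", value = )` or
#'   `list(dist = "exponential", mean = )`.
#' @param stratum_hazards Named numeric vector: annual event probability per
#'   stratum label, each in `[0, 1)`.
#' @param stratum_probs Optional named probabilities of stratum membership
#'   (defaults to uniform over `names(stratum_hazards)`).
#' @param covariate_model Optional named list of generator functions, each
#'   taking `n` and returning a length-`n` vector, used to fill covariate
#'   columns; sensible defaults emulate the published cohort ranges.
#' @param annual_natural_rate Annual natural-course bleeding probability
#'   (default 0.022), recorded for downstream comparisons.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          followup = list(dist = "uniform", min = 6, max = 240),
                          stratum_hazards = c(all = 0.022),
                          stratum_probs = NULL,
                          covariate_model = NULL,
                          annual_natural_rate = 0.022,
                          seed = 1L) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (is.null(names(stratum_hazards)) || any(!nzchar(names(stratum_hazards))))
    stop("stratum_hazards must be a named vector", call. = FALSE)
  if (any(stratum_hazards < 0 | stratum_hazards >= 1))
    stop("annual probabilities must lie in [0, 1)", call. = FALSE)
  if (is.null(stratum_probs)) {
    stratum_probs <- stats::setNames(
      rep(1 / length(stratum_hazards), length(stratum_hazards)),
      names(stratum_hazards))
  }
  if (!setequal(names(stratum_probs), names(stratum_hazards)))
    stop("stratum referenced without a hazard: ",
         paste(setdiff(names(stratum_probs), names(stratum_hazards)),
               collapse = ", "), call. = FALSE)
  if (annual_natural_rate < 0 || annual_natural_rate >= 1)
    stop("annual_natural_rate must lie in [0, 1)", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients), followup = followup,
                 stratum_hazards = stratum_hazards,
                 stratum_probs = stratum_probs[names(stratum_hazards)],
                 covariate_model = covariate_model,
                 annual_natural_rate = annual_natural_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

draw_followup_months <- function(followup, n) {
  out <- switch(followup$dist,
    uniform = stats::runif(n, followup$min, followup$max),
    fixed = rep(followup$value, n),
    exponential = stats::rexp(n, rate = 1 / followup$mean),
    stop("unknown follow-up distribution: ", followup$dist, call. = FALSE))
  if (any(out <= 0)) stop("follow-up times must be strictly positive",
                          call. = FALSE)
  out
}

default_covariate_model <- function() {
  list(
    volume_cm3 = function(n) stats::runif(n, 1.4, 71.6),
    margin_dose_gy = function(n) stats::runif(n, 14.5, 20),
    compactness_index = function(n) exp(stats::rnorm(n, log(0.6), 0.5)),
    sm_grade = function(n) sample(1:5, n, TRUE,
                                  prob = c(.126, .286, .328, .202, .057)),
    eloquent = function(n) stats::rbinom(n, 1, 0.672),
    deep_drainage = function(n) stats::rbinom(n, 1, 0.408),
    deep_location = function(n) stats::rbinom(n, 1, 0.069),
    aneurysm = function(n) stats::rbinom(n, 1, 0.107),
    sex = function(n) sample(c("M", "F"), n, TRUE, prob = c(.546, .454)),
    age_years = function(n) stats::runif(n, 18.9, 80.1),
    target_coverage = function(n) stats::runif(n, 85.6, 99.8)
  )
}

#' Simulate a bAVM cohort
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` with the columns of [cohort_columns()], one row per
#'   at-risk observation.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  stratum <- sample(names(config$stratum_hazards), n, replace = TRUE,
                    prob = config$stratum_probs)
  p_annual <- config$stratum_hazards[stratum]
  lambda <- -log(1 - p_annual)          # per-year hazard
  censor_years <- draw_followup_months(config$followup, n) / 12
  event_years <- ifelse(lambda > 0, stats::rexp(n, rate = pmax(lambda, 1e-300)),
                        Inf)
  event <- as.integer(event_years <= censor_years)
  time_years <- pmin(event_years, censor_years)

  cm <- utils::modifyList(default_covariate_model(),
                          config$covariate_model %||% list())
  covs <- lapply(cm, function(f) f(n))
  df <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                   time_months = time_years * 12,
                   event = event,
                   stringsAsFactors = FALSE)
  for (nm in names(covs)) df[[nm]] <- covs[[nm]]
  df$morphology <- ifelse(df$compactness_index >= 0.63, "compact", "diffuse")
  df$stratum <- stratum
  df[, cohort_columns()]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a cohort table as CSV
#'
#' `read_cohort()` validates that the required columns are present and
#' numeric columns parse as numbers, reporting any missing column by name.
#'
#' @param cohort A cohort `data.frame`.
#' @param path CSV file path.
#' @param required Columns that must be present on read (default: the
#'   identifier, time and event columns).
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a
#'   `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path,
                        required = c("patient_id", "time_months", "event")) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cohort CSV missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  num_cols <- intersect(
    c("time_months", "event", "volume_cm3", "margin_dose_gy",
      "compactness_index", "sm_grade", "eloquent", "deep_drainage",
      "deep_location", "aneurysm", "age_years", "target_coverage"),
    names(df))
  for (nm in num_cols) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (anyNA(v) && !anyNA(df[[nm]]))
      stop("cohort column ", nm, " is not numeric", call. = FALSE)
    df[[nm]] <- v
  }
  if (any(df$time_months <= 0))
    stop("time_months must be strictly positive", call. = FALSE)
  df
}

#' Follow-up time in years for a cohort table
#' @param cohort A cohort `data.frame` with `time_months`.
#' @return Numeric vector of years.
#' @export
time_years <- function(cohort) cohort$time_months / 12
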