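#' Half-up decimal rounding
#'
#' Rounds halves away from zero at `digits` decimals, matching the table
#' formatting convention for reported rates (base `round()` is half-even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Person-year incidence rate
#'
#' Number of events divided by the person-years at risk, reported per 1000
#' person-years. Rounding (half-up, one decimal) is applied only at report
#' time; the stored rate is unrounded.
#'
#' @param events Non-negative event count.
#' @param person_years Person-years at risk (> 0).
#' @return An object of class `rate_cell`: `events`, `person_years`,
#'   `rate_per_1000py` (unrounded), `annual_pct` (100 * events / PY).
#' @export
person_year_rate <- function(events, person_years) {
  if (person_years <= 0) stop("person_years must be positive", call. = FALSE)
  if (events < 0) stop("events must be non-negative", call. = FALSE)
  structure(list(events = events, person_years = person_years,
                 rate_per_1000py = 1000 * events / person_years,
                 annual_pct = 100 * events / person_years),
            class = "rate_cell")
}

#' @export
print.rate_cell <- function(x, ...) {
  cat(sprintf("%d/%.1f (%.1f per 1000 PY)\n", x$events, x$person_years,
              round_half_up(x$rate_per_1000py, 1)))
  invisible(x)
}

#' Bin bAVM volumes into the reported size groups
#'
#' Groups are `< 20`, `20-40` (inclusive at both ends) and `> 40` cm^3.
#'
#' @param volume_cm3 Numeric volumes.
#' @param edges Two bin edges (default `c(20, 40)`).
#' @return Factor with levels `"<20"`, `"20-40"`, `">40"` (labels follow
#'   `edges`).
#' @export
bin_volume <- function(volume_cm3, edges = c(20, 40)) {
  labs <- c(paste0("<", edges[1]), paste0(edges[1], "-", edges[2]),
            paste0(">", edges[2]))
  out <- ifelse(volume_cm3 < edges[1], labs[1],
                ifelse(volume_cm3 <= edges[2], labs[2], labs[3]))
  factor(out, levels = labs)
}

#' Stratified person-year rate table
#'
#' Events and person-years summed per cell of `rows x cols`, with marginal
#' totals. Strata must partition the cohort (every observation falls in
#' exactly one cell).
#'
#' @param time_years Follow-up in years per at-risk observation.
#' @param event 0/1 event indicator per observation.
#' @param rows Factor/character stratum per observation (or `NULL` for a
#'   single row).
#' @param cols As `rows`, for columns (or `NULL`).
#' @return A `data.frame` of class `rate_table` with columns `row`, `col`,
#'   `events`, `person_years`, `rate_per_1000py` (NA where PY = 0), including
#'   `"All"` marginals.
#' @export
rate_table <- function(time_years, event, rows = NULL, cols = NULL) {
  n <- length(time_years)
  if (any(time_years <= 0)) stop("time_years must be positive", call. = FALSE)
  rows <- if (is.null(rows)) factor(rep("All", n)) else as.factor(rows)
  cols <- if (is.null(cols)) factor(rep("All", n)) else as.factor(cols)
  if (anyNA(rows) || anyNA(cols))
    stop("strata must partition the cohort: NA stratum found", call. = FALSE)
  lev_r <- unique(c(levels(rows), "All"))   # declared-but-empty strata kept
  lev_c <- unique(c(levels(cols), "All"))
  cells <- expand.grid(row = lev_r, col = lev_c, stringsAsFactors = FALSE)
  agg <- function(r, c) {
    in_cell <- (r == "All" | rows == r) & (c == "All" | cols == c)
    c(events = sum(event[in_cell]), person_years = sum(time_years[in_cell]))
  }
  m <- t(mapply(agg, cells$row, cells$col))
  out <- data.frame(cells, events = m[, "events"],
                    person_years = m[, "person_years"])
  out$rate_per_1000py <- ifelse(out$person_years > 0,
                                1000 * out$events / out$person_years, NA_real_)
  rownames(out) <- NULL
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Look up one cell of a rate table
#' @param tab A [rate_table()].
#' @param row,col Stratum labels (`"All"` for marginals).
#' @return The matching one-row `data.frame`.
#' @export
rate_cell <- function(tab, row = "All", col = "All") {
  hit <- tab[tab$row == row & tab$col == col, , drop = FALSE]
  if (nrow(hit) != 1L)
    stop("no unique cell (", row, ", ", col, ") in rate table", call. = FALSE)
  hit
}

#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over [survival::survfit()] returning the curve as plain
#' vectors. At tied times events are handled before censorings, per the
#' product-limit convention.
#'
#' @param time Follow-up times (years), non-negative.
#' @param event 0/1 event indicators.
#' @return An object of class `km_curve`: `time` (distinct observed times),
#'   `n_risk`, `n_event`, `surv` (S(t)), `std_err` (Greenwood), and the
#'   underlying `survfit` object as attribute `fit`.
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0)) stop("negative follow-up times", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 surv = fit$surv, std_err = fit$std.err),
            class = "km_curve", fit = fit)
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#' @param km A [km_estimate()] result.
#' @param t Times at which to evaluate S(t) (right-continuous step function;
#'   S = 1 before the first event).
#' @return Numeric vector of survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  ev <- km$time[km$n_event > 0]
  sv <- km$surv[km$n_event > 0]
  vapply(t, function(tt) {
    i <- findInterval(tt, ev)
    if (i == 0L) 1 else sv[i]
  }, numeric(1))
}

#' K-sample log-rank test
#'
#' Observed-minus-expected statistic with hypergeometric variance, summed
#' over distinct event times ([survival::survdiff()], rho = 0).
#'
#' @param time Follow-up times.
#' @param event 0/1 event indicators; at least one event overall.
#' @param group Group labels (K >= 2 groups).
#' @return List with `chisq`, `df` (K - 1), `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L)
    stop("log-rank requires at least two groups", call. = FALSE)
  if (sum(event) == 0L)
    stop("log-rank undefined: no events observed", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Simulate the untreated natural course of hemorrhage
#'
#' Event times are exponential with hazard `lambda = -log(1 - annual_rate)`,
#' so the annual event probability is exactly `annual_rate`; each subject is
#' censored at its supplied follow-up time. The closed-form survival curve
#' `S(t) = (1 - annual_rate)^t` is returned for overlay.
#'
#' @param followup_years Per-subject follow-up (censoring) times in years.
#' @param annual_rate Annual bleeding probability in `[0, 1)`; default 0.022.
#' @param seed Integer seed.
#' @return List with `time`, `event`, `annual_rate`, and `surv_fn`, a
#'   function of `t` returning the analytic survival.
#' @export
simulate_natural_course <- function(followup_years, annual_rate = 0.022,
                                    seed = 1L) {
  if (annual_rate < 0 || annual_rate >= 1)
    stop("annual_rate must lie in [0, 1)", call. = FALSE)
  set.seed(seed)
  n <- length(followup_years)
  if (annual_rate == 0) {
    tt <- followup_years
    ev <- integer(n)
  } else {
    lambda <- -log(1 - annual_rate)
    et <- stats::rexp(n, rate = lambda)
    ev <- as.integer(et <= followup_years)
    tt <- pmin(et, followup_years)
  }
  list(time = tt, event = ev, annual_rate = annual_rate,
       surv_fn = function(t) (1 - annual_rate)^t)
}

#' Cox proportional-hazards fit
#'
#' Wrapper over [survival::coxph()] maximising the partial likelihood
#' (Breslow ties by default) with Newton-Raphson; returns coefficients,
#' hazard ratios with Wald 95% CIs and p-values, and convergence
#' diagnostics. Interaction terms are written `"a:b"`; [backward_select()]
#' preserves main effects of retained interactions.
#'
#' @param data A `data.frame` of at-risk observations.
#' @param covariates Character vector of column names and optional `a:b`
#'   product terms.
#' @param time,event Column names of follow-up (years) and event indicator.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return An object of class `cox_fit`: `coef`, `hr`, `se`, `ci_lower`,
#'   `ci_upper`, `p` (named per term), `loglik` (final log partial
#'   likelihood), `iterations`, `converged`, `covariates`, and the
#'   underlying `coxph` object as `fit`.
#' @export
cox_fit <- function(data, covariates, time = "time_years", event = "event",
                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (sum(data[[event]]) < 1) stop("at least one event required", call. = FALSE)
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = ties)
  # rank deficiency shows up as NA coefficients
  if (anyNA(stats::coef(fit)))
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  s <- summary(fit)
  co <- s$coefficients
  se <- co[, "se(coef)"]
  beta <- co[, "coef"]
  if (any(!is.finite(se)) || any(abs(beta) > 15))
    warning("possible monotone likelihood (non-identifiable covariate): ",
            paste(rownames(co)[!is.finite(se) | abs(beta) > 15],
                  collapse = ", "), call. = FALSE)
  structure(list(
    coef = stats::setNames(beta, rownames(co)),
    hr = stats::setNames(exp(beta), rownames(co)),
    se = stats::setNames(se, rownames(co)),
    ci_lower = stats::setNames(exp(beta - 1.96 * se), rownames(co)),
    ci_upper = stats::setNames(exp(beta + 1.96 * se), rownames(co)),
    p = stats::setNames(co[, "Pr(>|z|)"], rownames(co)),
    loglik = fit$loglik[length(fit$loglik)],
    iterations = fit$iter,
    converged = is.null(fit$info) || fit$iter < fit$control$iter.max,
    covariates = covariates, fit = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (", length(x$coef), " terms, ",
      x$iterations, " iterations)\n", sep = "")
  tab <- data.frame(HR = round(x$hr, 3),
                    `95% CI` = sprintf("%.2f-%.2f", x$ci_lower, x$ci_upper),
                    p = signif(x$p, 3), check.names = FALSE)
  print(tab)
  invisible(x)
}

# main-effect names referenced by an interaction term like "a:b"
interaction_parents <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

#' Backward stepwise selection for the Cox model
#'
#' Iteratively refits the model after dropping the covariate with the
#' largest Wald p-value above `alpha`, preserving model hierarchy: a main
#' effect is never dropped while an interaction containing it is retained.
#' Stops when every droppable term has p <= alpha.
#'
#' @param data,time,event,ties As in [cox_fit()].
#' @param covariates Full starting model (column names and `a:b` terms).
#' @param alpha Stopping criterion on the Wald p-value (default 0.157).
#' @return A `cox_fit` for the final model, with `retained` (term list) and
#'   `path` (a `data.frame` logging each elimination step).
#' @export
backward_select <- function(data, covariates, alpha = 0.157,
                            time = "time_years", event = "event",
                            ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  current <- covariates
  path <- data.frame(step = integer(0), dropped = character(0),
                     p = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    fit <- cox_fit(data, current, time = time, event = event, ties = ties)
    # map fitted coefficient names back to requested terms (factors expand
    # to term-prefixed names; interactions keep their own ":" names)
    term_p <- vapply(current, function(tm) {
      nm <- names(fit$p)
      hits <- which(nm == tm)
      if (!length(hits)) {
        cand <- startsWith(nm, tm)
        if (!grepl(":", tm, fixed = TRUE))
          cand <- cand & !grepl(":", nm, fixed = TRUE)
        hits <- which(cand)
      }
      if (!length(hits))
        stop("cannot locate coefficient for term ", tm, call. = FALSE)
      max(fit$p[hits])
    }, numeric(1))
    in_interaction <- unique(unlist(lapply(
      current[grepl(":", current, fixed = TRUE)], interaction_parents)))
    droppable <- !(current %in% in_interaction)
    cand <- which(droppable & term_p > alpha)
    if (!length(cand)) {
      fit$retained <- current
      fit$path <- path
      return(fit)
    }
    worst <- cand[which.max(term_p[cand])]
    step <- step + 1L
    path <- rbind(path, data.frame(step = step, dropped = current[worst],
                                   p = term_p[worst]))
    current <- current[-worst]
    if (!length(current))
      stop("backward selection eliminated every covariate", call. = FALSE)
  }
}
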