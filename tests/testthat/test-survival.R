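test_that("person-year rates reproduce the published cell arithmetic", {
  r <- person_year_rate(5, 163.4)
  expect_equal(round_half_up(r$rate_per_1000py, 1), 30.6)
  expect_equal(person_year_rate(0, 168.4)$rate_per_1000py, 0)
  total <- person_year_rate(14, 1718)
  expect_equal(round_half_up(total$annual_pct, 1), 0.8)
  expect_error(person_year_rate(3, 0), "positive")
  # linear in events, inversely proportional to person-years
  expect_equal(person_year_rate(10, 163.4)$rate_per_1000py,
               2 * r$rate_per_1000py)
  expect_equal(person_year_rate(5, 326.8)$rate_per_1000py,
               r$rate_per_1000py / 2)
})

test_that("half-up rounding differs from banker's rounding where it must", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(2.05, 1), 2.1)
  expect_equal(round_half_up(14.85, 1), 14.9)
})

test_that("rate tables equal a brute-force filter-and-sum oracle, with consistent totals", {
  set.seed(41)
  n <- 400
  ty <- runif(n, 0.1, 15)
  ev <- rbinom(n, 1, 0.1)
  morph <- sample(c("compact", "diffuse"), n, TRUE)
  vol <- runif(n, 2, 70)
  tab <- rate_table(ty, ev, morph, bin_volume(vol))
  vb <- bin_volume(vol)
  for (i in seq_len(nrow(tab))) {
    keep <- (tab$row[i] == "All" | morph == tab$row[i]) &
      (tab$col[i] == "All" | vb == tab$col[i])
    expect_equal(tab$events[i], sum(ev[keep]))
    expect_equal(tab$person_years[i], sum(ty[keep]))
  }
  # totals row equals the sum of its cells
  for (cl in levels(vb)) {
    cells <- tab[tab$col == cl & tab$row != "All", ]
    expect_equal(sum(cells$events), rate_cell(tab, "All", cl)$events)
    expect_equal(sum(cells$person_years),
                 rate_cell(tab, "All", cl)$person_years)
  }
})

test_that("an empty stratum is reported with zero person-years and no rate", {
  tab <- rate_table(c(1, 2), c(1, 0),
                    rows = factor(c("a", "a"), levels = c("a", "b")))
  cell <- rate_cell(tab, "b", "All")
  expect_equal(cell$events, 0)
  expect_equal(cell$person_years, 0)
  expect_true(is.na(cell$rate_per_1000py))
})

test_that("the Kaplan-Meier estimate matches hand-computed product limits", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km_surv_at(km, c(0.5, 1, 1.9, 2, 3)),
               c(1, 2 / 3, 2 / 3, 1 / 3, 1 / 3))
  # no events: survival stays at 1
  km0 <- km_estimate(c(1, 5, 9), c(0, 0, 0))
  expect_true(all(km_surv_at(km0, c(1, 5, 9, 20)) == 1))
  expect_error(km_estimate(c(-1, 2), c(1, 0)), "negative")
})

test_that("without censoring the Kaplan-Meier curve is the empirical survival function", {
  set.seed(43)
  tt <- rexp(500, 0.3)
  km <- km_estimate(tt, rep(1, 500))
  for (q in c(0.5, 1, 2, 5))
    expect_equal(km_surv_at(km, q), mean(tt > q))
})

test_that("a large uncensored exponential sample matches the closed form", {
  set.seed(47)
  lambda <- 0.25
  tt <- rexp(10000, lambda)
  km <- km_estimate(tt, rep(1, 10000))
  grid <- seq(0.1, 12, by = 0.1)
  expect_lt(max(abs(km_surv_at(km, grid) - exp(-lambda * grid))), 0.02)
})

test_that("log-rank is null on identical groups and matches the hand oracle", {
  tt <- c(1, 3, 5, 7); ev <- c(1, 0, 1, 1)
  lr <- logrank_test(c(tt, tt), c(ev, ev), rep(c("a", "b"), each = 4))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)

  set.seed(53)
  time <- c(2, 4, 4, 7, 1, 3, 5, 9)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1)
  group <- rep(c("a", "b"), each = 4)
  lr2 <- logrank_test(time, event, group)
  expect_equal(lr2$chisq, logrank_oracle(time, event, group),
               tolerance = 1e-10)
  expect_equal(lr2$df, 1)

  # invariance to group relabeling and to equal event-free extension
  lr_swap <- logrank_test(time, event, rev(group))
  expect_equal(logrank_test(time, event, ifelse(group == "a", "x", "y"))$chisq,
               lr2$chisq)
  # extending event-free follow-up beyond the last event changes nothing
  time2 <- c(2, 4, 4, 20, 1, 3, 5, 21)
  event2 <- c(1, 1, 0, 0, 1, 1, 0, 0)
  lr_base <- logrank_test(time2, event2, group)
  lr_ext <- logrank_test(time2 + ifelse(event2 == 0 & time2 > 5, 7, 0),
                         event2, group)
  expect_equal(lr_ext$chisq, lr_base$chisq, tolerance = 1e-12)

  expect_error(logrank_test(tt, rep(0, 4), rep(c("a", "b"), 2)),
               "no events")
  expect_error(logrank_test(tt, ev, rep("a", 4)), "two groups")
})

test_that("the natural-course simulator reproduces its closed form", {
  nat0 <- simulate_natural_course(runif(100, 1, 10), annual_rate = 0,
                                  seed = 1)
  expect_true(all(nat0$event == 0))
  nat <- simulate_natural_course(rep(10, 2000), annual_rate = 0.022, seed = 2)
  expect_equal(nat$surv_fn(1), 0.978)
  km <- km_estimate(nat$time, nat$event)
  expect_lt(max(abs(km_surv_at(km, 1:9) - 0.978^(1:9))), 0.03)
  # empirical first-year event probability (all 2000 followed past 1 year)
  expect_lt(abs(mean(nat$event == 1 & nat$time <= 1) - 0.022), 0.01)
})

test_that("a symmetric binary covariate has zero log hazard ratio", {
  tt <- c(1, 2, 3, 4); ev <- c(1, 1, 0, 1)
  df <- data.frame(time_years = c(tt, tt), event = c(ev, ev),
                   arm = rep(0:1, each = 4))
  fit <- cox_fit(df, "arm")
  expect_lt(abs(fit$coef[["arm"]]), 1e-6)
  expect_equal(fit$hr[["arm"]], 1, tolerance = 1e-5)
})

test_that("a 6-subject fit matches a dense grid search of the Breslow partial likelihood", {
  df <- data.frame(time_years = c(2, 3, 5, 6, 8, 9),
                   event = c(1, 1, 0, 1, 1, 0),
                   x = c(1, 0, 1, 1, 0, 0))
  fit <- cox_fit(df, "x")
  grid <- seq(-3, 3, by = 5e-4)
  ll <- vapply(grid, breslow_loglik, numeric(1),
               time = df$time_years, event = df$event, x = df$x)
  expect_equal(fit$coef[["x"]], grid[which.max(ll)], tolerance = 1e-3)
  expect_equal(fit$loglik,
               breslow_loglik(fit$coef[["x"]], df$time_years, df$event, df$x),
               tolerance = 1e-6)
})

test_that("the Cox model recovers a planted hazard ratio of 2", {
  set.seed(59)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, rate = 0.05 * 2^x)
  cens <- runif(n, 0, 25)
  df <- data.frame(time_years = pmin(tt, cens),
                   event = as.integer(tt <= cens), x = x)
  expect_gt(mean(df$event), 0.3)
  fit <- cox_fit(df, "x")
  hr <- fit$hr[["x"]]
  expect_gt(hr, fit$ci_lower[["x"]]); expect_lt(hr, fit$ci_upper[["x"]])
  expect_true(fit$ci_lower[["x"]] < 2 && 2 < fit$ci_upper[["x"]])
  expect_gt(hr, 1.7); expect_lt(hr, 2.35)
  # coefficient invariant to covariate centering
  df$xc <- df$x - mean(df$x)
  expect_equal(cox_fit(df, "xc")$coef[["xc"]], fit$coef[["x"]],
               tolerance = 1e-6)
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  set.seed(61)
  df <- data.frame(time_years = rexp(50, 0.2), event = rbinom(50, 1, 0.5),
                   a = rnorm(50))
  df$b <- 2 * df$a
  expect_error(cox_fit(df, c("a", "b")), "collinear")
})

test_that("backward selection respects alpha, hierarchy, and trivial cases", {
  set.seed(67)
  n <- 600
  x <- rbinom(n, 1, 0.5)
  z <- rnorm(n)
  tt <- rexp(n, rate = 0.08 * exp(log(2) * x))
  cens <- runif(n, 0, 20)
  df <- data.frame(time_years = pmin(tt, cens),
                   event = as.integer(tt <= cens), x = x, z = z)
  # single strong covariate is retained unchanged
  sel <- backward_select(df, "x")
  expect_equal(sel$retained, "x")
  # alpha = 1 returns the full model
  sel_full <- backward_select(df, c("x", "z"), alpha = 1)
  expect_equal(sel_full$retained, c("x", "z"))
  # hierarchy: main effects survive while their interaction is retained
  df$w <- rnorm(n)
  sel_int <- backward_select(df, c("x", "w", "x:w"), alpha = 1)
  expect_true(all(c("x", "w", "x:w") %in% sel_int$retained))
})

test_that("backward selection keeps true effects and prunes null covariates", {
  set.seed(71)
  keep_true <- 0; keep_null <- 0
  reps <- 100
  for (r in 1:reps) {
    n <- 400
    x <- rbinom(n, 1, 0.5)
    nulls <- matrix(rnorm(n * 5), ncol = 5,
                    dimnames = list(NULL, paste0("n", 1:5)))
    tt <- rexp(n, rate = 0.08 * exp(log(2) * x))
    cens <- runif(n, 0, 20)
    df <- data.frame(time_years = pmin(tt, cens),
                     event = as.integer(tt <= cens), x = x, nulls)
    sel <- backward_select(df, c("x", paste0("n", 1:5)))
    keep_true <- keep_true + ("x" %in% sel$retained)
    keep_null <- keep_null + sum(paste0("n", 1:5) %in% sel$retained)
  }
  expect_gte(keep_true / reps, 0.95)
  expect_lte(keep_null / (5 * reps), 0.35)
})
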