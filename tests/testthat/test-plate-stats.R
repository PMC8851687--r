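test_that("control pooling follows the Welch comparison", {
  # identical constant groups: t = 0, p = 1, pooled
  p <- pool_controls(c(10, 10, 10, 10), c(10, 10, 10, 10))
  expect_true(p$pooled)
  expect_equal(p$p_value, 1)
  expect_length(p$values, 8)
  # extreme separation: not pooled, vehicle kept, warning raised
  expect_warning(q <- pool_controls(c(10, 10, 10, 10), c(50, 50, 50, 50)),
                 "differ")
  expect_false(q$pooled)
  expect_equal(q$values, c(50, 50, 50, 50))
  # hand-worked pair agrees with the textbook Welch computation
  a <- c(12, 14, 11, 13); b <- c(15, 18, 16, 17)
  r <- pool_controls(a, b, alpha = 1e-6) # alpha tiny so it pools
  tt <- t.test(a, b)
  expect_equal(r$p_value, unname(tt$p.value))
  expect_equal(r$t, unname(tt$statistic))
  expect_error(pool_controls(1, c(2, 3)), ">= 2 values")
})

test_that("LOD is mean + 3 sample SDs of pooled controls", {
  lod <- compute_lod(c(10, 12, 14, 10, 14), "droplet_count", "E1")
  expect_equal(lod$control_mean, 12)
  expect_equal(lod$control_sd, 2)
  expect_equal(lod$lod_threshold, 18)
  expect_false(lod$degenerate)
  deg <- compute_lod(rep(12, 5))
  expect_equal(deg$lod_threshold, 12)
  expect_true(deg$degenerate)
  expect_error(compute_lod(c(1, 2)), ">= 3 pooled control values")
})

test_that("cytotoxicity gate uses the strict >20% rule", {
  veh <- rep(100, 4)
  mk <- function(means) {
    data.frame(dose = rep(c(0.75, 1.5, 3), each = 2),
               value = rep(means, each = 2))
  }
  # 21% loss is cytotoxic, exactly 20% is not
  r <- assess_cytotoxicity(mk(c(100, 80, 79)), veh)
  expect_equal(r$by_dose$cytotoxic, c(FALSE, FALSE, TRUE))
  expect_equal(r$hnc, 1.5)
  expect_false(r$at_max)
  # all clean: hnc at the top dose
  r2 <- assess_cytotoxicity(mk(c(100, 95, 81)), veh)
  expect_equal(r2$hnc, 3)
  expect_true(r2$at_max)
  # lowest dose already toxic: no HNC
  r3 <- assess_cytotoxicity(mk(c(70, 70, 70)), veh)
  expect_true(is.na(r3$hnc))
  # a toxic dose interrupts the run even if higher doses look clean
  r4 <- assess_cytotoxicity(mk(c(100, 70, 100)), veh)
  expect_equal(r4$hnc, 0.75)
  expect_error(assess_cytotoxicity(mk(c(1, 1, 1)), c(0, 0)), "vehicle mean")
})

test_that("making a dose more cytotoxic never raises the HNC", {
  veh <- rep(100, 4)
  withr::with_seed(13, {
    for (rep in 1:20) {
      means <- runif(5, 60, 110)
      df <- data.frame(dose = dose_series(3, 5), value = means)
      h1 <- assess_cytotoxicity(df, veh)$hnc
      k <- sample(5, 1)
      df2 <- df; df2$value[k] <- df2$value[k] * runif(1, 0.3, 0.95)
      h2 <- assess_cytotoxicity(df2, veh)$hnc
      expect_true(is.na(h2) || (!is.na(h1) && h2 <= h1))
    }
  })
})

test_that("4PL fitting recovers noiseless parameters", {
  d <- rep(c(0.1, 0.3, 1, 3, 10, 30, 100, 300), each = 1)
  y <- 0 + (100 - 0) * d / (d + 10) # bottom 0, top 100, ec50 10, hill 1
  f <- fit_4pl(d, y)
  expect_true(f$converged)
  expect_false(f$degenerate)
  expect_lt(abs(f$bottom - 0), 1e-3 * 100)
  expect_lt(abs(f$top - 100) / 100, 1e-3)
  expect_lt(abs(f$ec50 - 10) / 10, 1e-3)
  expect_lt(abs(f$hill - 1), 1e-3)
  # permutation invariance
  perm <- withr::with_seed(3, sample(length(d)))
  f2 <- fit_4pl(d[perm], y[perm])
  expect_equal(f2$ec50, f$ec50, tolerance = 1e-6)
  # flat data: degenerate, top == bottom == c
  g <- fit_4pl(d, rep(5, length(d)))
  expect_true(g$degenerate)
  expect_equal(g$bottom, 5)
  expect_equal(g$top, 5)
  # decreasing data: canonical bottom <= top with negative hill
  ydec <- 100 - 90 * d / (d + 10)
  h <- fit_4pl(d, ydec)
  expect_lte(h$bottom, h$top)
  expect_lt(h$hill, 0)
  expect_error(fit_4pl(c(1, 1), c(2, 3)), ">= 2 dose levels")
  expect_error(fit_4pl(c(0, 1), c(2, 3)), "positive")
})

test_that("EC interpolation matches the closed form and a root oracle", {
  f <- structure(list(bottom = 0, top = 100, ec50 = 10, hill = 1,
                      rss = 0, converged = TRUE, degenerate = FALSE, n = 8),
                 class = "fourpl_fit")
  expect_equal(interpolate_ec(f, 50), 10) # EC50 identity
  expect_equal(interpolate_ec(f, 10), 10 * (10 / 90)) # 1.111...
  # numeric root of the response curve at the f% level
  for (lev in c(10, 20, 50, 80)) {
    for (hill in c(0.7, 1, 2.3)) {
      fh <- f; fh$hill <- hill
      target <- fh$bottom + lev / 100 * (fh$top - fh$bottom)
      root <- uniroot(function(d) predict(fh, d) - target,
                      interval = c(1e-8, 1e8), tol = 1e-12)$root
      expect_equal(interpolate_ec(fh, lev), root, tolerance = 1e-9)
    }
  }
  expect_error(interpolate_ec(f, 0), "level")
  deg <- f; deg$degenerate <- TRUE
  expect_true(is.na(interpolate_ec(deg, 10)))
})

test_that("activity calling needs two endpoints at or above the LOD", {
  doses <- dose_series(3, 5)
  mk_series <- function(level) data.frame(dose = rep(doses, each = 4),
                                          value = rep(level, 20))
  lod <- compute_lod(c(98, 100, 102, 99, 101)) # mean 100, threshold ~104.3
  eps <- paste0("ep", 1:6)
  lods <- setNames(rep(list(lod), 6), eps)
  # exactly one endpoint above: not active
  series <- setNames(c(list(mk_series(150)), rep(list(mk_series(100)), 5)), eps)
  call1 <- call_activity(series, lods, hnc = 3, sample_id = "X")
  expect_false(call1$active)
  expect_equal(call1$n_active_endpoints, 1)
  # zero above: not active; all six above: active
  call0 <- call_activity(setNames(rep(list(mk_series(100)), 6), eps), lods, 3)
  expect_false(call0$active)
  call6 <- call_activity(setNames(rep(list(mk_series(150)), 6), eps), lods, 3)
  expect_true(call6$active)
  expect_equal(call6$n_active_endpoints, 6)
  # two endpoints: boundary of the rule, and responses at the LOD count (>=)
  series2 <- setNames(c(rep(list(mk_series(lod$lod_threshold)), 2),
                        rep(list(mk_series(100)), 4)), eps)
  expect_true(call_activity(series2, lods, 3)$active)
  # missing endpoint data: skipped with a warning, never counted active
  series_na <- series2; series_na[["ep1"]] <- NULL
  expect_warning(cm <- call_activity(series_na, lods[-1][c(1:5)], 3),
                 regexp = NA) # complete list minus ep1: no warning
  series_missing <- c(series2[1:5], list(ep6 = NULL))
  expect_warning(cx <- call_activity(series_missing, lods, 3), "skipped")
  expect_equal(nrow(cx$per_endpoint), 5)
  # cytotoxic top doses are excluded from the comparison
  grad <- data.frame(dose = rep(doses, each = 4),
                     value = rep(c(150, 100, 100, 100, 100), each = 4))
  series3 <- setNames(c(list(grad), list(grad), rep(list(mk_series(100)), 4)),
                      eps)
  expect_true(call_activity(series3, lods, hnc = 3)$active)
  expect_false(call_activity(series3, lods, hnc = 1.5)$active)
  expect_false(call_activity(series3, lods, hnc = NA)$active)
})

test_that("reported ECs never exceed the tested dose range", {
  withr::with_seed(77, {
    doses <- dose_series(3, 5)
    lod <- compute_lod(c(9.5, 10, 10.5, 10, 10))
    # steep late-rising curve: EC interpolation stays inside the range
    val <- 10 + 40 * hill_fraction(rep(doses, each = 4), 2.8, 6) +
      rnorm(20, 0, 0.5)
    series <- list(a = data.frame(dose = rep(doses, each = 4), value = val),
                   b = data.frame(dose = rep(doses, each = 4), value = val))
    call <- call_activity(series, list(a = lod, b = lod), hnc = 3)
    for (e in c("ec10", "ec20")) {
      v <- call$per_endpoint[[e]]
      expect_true(all(is.na(v) | v <= 3))
    }
  })
})

test_that("majority aggregation across experiments", {
  mk <- function(active) structure(list(sample_id = "S", active = active),
                                   class = "activity_call")
  expect_true(aggregate_calls(list(mk(TRUE), mk(TRUE), mk(FALSE)))$active)
  expect_false(aggregate_calls(list(mk(TRUE), mk(FALSE), mk(FALSE)))$active)
})
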