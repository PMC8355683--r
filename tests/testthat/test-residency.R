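test_that("residency index uses the tag life unless captured or outperformed", {
  d0 <- as.Date("2009-04-30")
  # plain case: 29 days on the nominal 1877-day life
  expect_equal(round(compute_residency_index(29, d0, d0 + 100, d0 + 3000), 3), 0.015)
  expect_equal(compute_residency_index(0, d0, d0, d0 + 3000), 0)
  # tag outperformed: denominator becomes the tagging-to-last-detection span
  ri <- compute_residency_index(1900, d0, d0 + 1999, d0 + 2100)
  expect_equal(ri, 1900 / 2000)
  # detection span beyond study end: capped at study end
  ri2 <- compute_residency_index(1900, d0, d0 + 2199, d0 + 2099)
  expect_equal(ri2, 1900 / 2100)
  # reported capture overrides the tag life
  ri3 <- compute_residency_index(50, d0, d0 + 300, d0 + 3000,
                                 capture_date = d0 + 561)
  expect_equal(ri3, 50 / 562)
  expect_error(compute_residency_index(5, d0, d0 + 10, d0 + 100, tag_life = -1),
               "positive")
  # capture reported before tagging: negative expected-days denominator
  expect_error(compute_residency_index(5, d0, d0 + 10, d0 + 100,
                                       capture_date = d0 - 5),
               "denominator")
})

test_that("maximum residency index is days over the inclusive detection span", {
  d0 <- as.Date("2007-05-01")
  expect_equal(compute_max_residency_index(50, d0, d0 + 99), 0.5)
  expect_equal(compute_max_residency_index(100, d0, d0 + 99), 1)
  expect_equal(compute_max_residency_index(1, d0, d0), 1)  # single-day animal
  expect_error(compute_max_residency_index(1, d0, d0 - 1), "precedes")
})

test_that("published RI_max values are span-consistent under the inclusive convention (+/- 1 day)", {
  tbl <- lighthouse_table1()
  ok <- vapply(seq_len(nrow(tbl)), function(i) {
    d <- tbl$days_detected[i]; rm <- tbl$ri_max[i]
    if (rm >= 0.9995) return(TRUE)          # detected every day of a short span
    span0 <- round(d / rm)                  # brute-force nearby integer spans
    any(vapply(span0 + (-2:2), function(s) s >= d && round(d / s, 3) == rm,
               logical(1)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("roaming index is receivers visited over array size", {
  expect_equal(round(compute_roaming_index(4), 3), 0.222)
  expect_equal(compute_roaming_index(18), 1)
  expect_equal(round(compute_roaming_index(16), 3), 0.889)
  expect_error(compute_roaming_index(19), "n_stations")
  expect_error(compute_roaming_index(0), "n_stations")
  # the packaged table's roaming column is exactly receivers/18 at 3 dp
  tbl <- lighthouse_table1()
  expect_equal(round(compute_roaming_index(tbl$receivers_visited), 3),
               tbl$roaming_index)
})

test_that("monthly residency series covers tagging through the summary window with zeros for silent months", {
  # 15 detection days in June 2007 (30 days) -> 0.5, nothing in July
  days <- as.Date("2007-06-01") + seq(0, 28, by = 2)
  times <- as.POSIXct(paste(rep(days, each = 2), c("08:00:00", "09:00:00")), tz = "UTC")
  ds <- tiny_ds(format(times, "%Y-%m-%d %H:%M:%S"), rep("R1", length(times)),
                rep("X", length(times)),
                sharks = tiny_sharks("X", tagged = as.Date("2007-05-20")))
  cfg <- study_config(monthly_summary_end = "2007-08-31")
  ser <- compute_monthly_series(ds, "X", cfg)
  expect_equal(ser$month[1], 5)            # starts at the tagging month
  expect_equal(ser$monthly_ri[ser$month == 6], 0.5)
  expect_equal(ser$monthly_ri[ser$month == 5], 0)
  expect_equal(ser$monthly_ri[ser$month == 7], 0)
  expect_true(all(ser$monthly_ri >= 0 & ser$monthly_ri <= 1))
})

test_that("monthly day counts from lossless simulations match ground truth and sum to days detected", {
  sim <- small_sim(seed = 21, n_sharks = c(FC = 2, MB = 1), study_days = 70)
  cfg <- sim_study_config(sim$truth$config)
  clean <- remove_false_detections(sim$detections)
  res <- residency_summary(clean, cfg)
  for (id in res$shark_id) {
    ser <- compute_monthly_series(clean, id, cfg)
    expect_equal(sum(ser$days_detected),
                 res$days_detected[res$shark_id == id])
    tr <- sim$truth$monthly_days[[id]]
    ym <- sprintf("%04d-%02d", ser$year, ser$month)
    want <- rep(0L, length(ym))
    want[match(names(tr), ym)] <- as.integer(tr)
    expect_equal(ser$days_detected, want)
  }
})

test_that("cohort summary reproduces the published headline statistics from the packaged table", {
  tbl <- lighthouse_table1()
  coh <- summarize_cohort(tbl)
  expect_equal(round(coh$mean_ri, 2), 0.22)
  expect_equal(round(coh$sd_ri, 2), 0.21)
  expect_equal(round(coh$mean_ri_max, 2), 0.44)
  expect_equal(coh$n_ri_max_above_half, 30)
  expect_gte(coh$prop_ri_below_half, 0.89)
  expect_equal(coh$n_site_array_faithful, 19)
  expect_equal(round(coh$prop_faithful_mature_female, 2), 0.63)
  expect_equal(round(coh$prop_low_roaming_mature, 2), 0.61)
  # degenerate single-animal cohort
  one <- summarize_cohort(tbl[5, ])
  expect_equal(one$mean_ri, tbl$ri[5])
  expect_equal(one$sd_ri, 0)
  expect_error(summarize_cohort(tbl[0, ]), "empty")
})

test_that("least-squares fits match the closed-form normal-equations solution", {
  # exact line
  d <- data.frame(y = 2 * (1:6), tl_cm = 1:6, sex = rep(c("F", "M"), 3))
  fit <- fit_linear_model("y", d, terms = "tl_cm")
  expect_equal(unname(coef(fit)), c(0, 2), tolerance = 1e-12)
  expect_lt(fit$coefficients["tl_cm", "std_error"], 1e-10)

  # random designs against (X'X)^-1 X'y
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(20:100, 1)
    d <- data.frame(tl_cm = stats::runif(n, 90, 240),
                    sex = sample(c("F", "M"), n, replace = TRUE))
    d$y <- 0.3 - 0.001 * d$tl_cm + 0.1 * (d$sex == "M") + stats::rnorm(n, 0, 0.05)
    fit <- fit_linear_model("y", d, terms = c("tl_cm", "sex"))
    X <- cbind(1, d$tl_cm, d$sex == "M")
    beta <- solve(crossprod(X), crossprod(X, d$y))
    expect_equal(unname(coef(fit)), as.vector(beta), tolerance = 1e-8)
  }
})

test_that("AIC selection on the packaged table picks length + sex for RI and length alone for roaming", {
  tbl <- lighthouse_table1()
  fit_ri <- fit_linear_model("ri", tbl, select = TRUE)
  expect_setequal(fit_ri$terms, c("tl_cm", "sex"))
  expect_equal(round(fit_ri$coefficients["sexM", "estimate"], 2), -0.11)
  expect_lt(fit_ri$coefficients["sexM", "p_value"], 0.05)
  fit_roam <- fit_linear_model("roaming_index", tbl, select = TRUE)
  expect_equal(fit_roam$terms, "tl_cm")
  expect_lt(fit_roam$coefficients["tl_cm", "estimate"], 0)
})

test_that("Mann-Whitney U matches brute-force enumeration of rank assignments", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(10, 11, 12))$U, 0)

  # exact null by enumerating all C(10,5) = 252 group assignments
  set.seed(7)
  a <- stats::rnorm(5); b <- stats::rnorm(5, 0.5)
  got <- mann_whitney_u(a, b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[1:5]) - 5 * 6 / 2
  combos <- utils::combn(10, 5)
  u_null <- apply(combos, 2, function(idx) sum(r[idx]) - 5 * 6 / 2)
  p_exact <- mean(abs(u_null - 12.5) >= abs(u_obs - 12.5))
  expect_equal(got$U, u_obs)
  expect_equal(got$p, p_exact, tolerance = 1e-12)
  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
})

test_that("Kruskal-Wallis statistic matches the hand rank formula and a permutation null", {
  g_same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(kruskal_wallis(g_same)$H, 0, tolerance = 1e-12)

  # disjoint supports, n = 3 each: mean ranks 2, 5, 8 -> H = 7.2 (no ties)
  g <- list(c(1, 2, 3), c(10, 11, 12), c(20, 21, 22))
  expect_equal(kruskal_wallis(g)$H, 7.2, tolerance = 1e-12)

  # p within the Monte-Carlo envelope of a 10,000-permutation null
  # (moderate shifts keep p mid-range, where the chi-squared reference is good)
  set.seed(13)
  g2 <- list(stats::rnorm(6), stats::rnorm(6, 0.4), stats::rnorm(6, 0.8))
  kw <- kruskal_wallis(g2)
  x <- unlist(g2); lab <- rep(1:3, each = 6)
  h_perm <- replicate(10000, {
    stats::kruskal.test(split(x, sample(lab)))$statistic
  })
  p_mc <- mean(h_perm >= kw$H - 1e-12)
  se <- sqrt(p_mc * (1 - p_mc) / 10000)
  expect_lt(abs(kw$p - p_mc), 3 * se + 0.01)
  expect_error(kruskal_wallis(list(1:3)), "two groups")
})

test_that("Dunn-type post hoc comparisons flag the separated pairs", {
  g <- list(A = c(1, 2, 3, 4), B = c(1.5, 2.5, 3.5, 4.5), C = c(30, 31, 32, 33))
  ph <- posthoc_kw(g)
  expect_equal(nrow(ph), 3)
  ac <- ph$significant[(ph$group1 == "A" & ph$group2 == "C") |
                         (ph$group1 == "C" & ph$group2 == "A")]
  ab <- ph$significant[(ph$group1 == "A" & ph$group2 == "B") |
                         (ph$group1 == "B" & ph$group2 == "A")]
  expect_true(ac)
  expect_false(ab)
  expect_true(all(ph$p_adjusted >= 0 & ph$p_adjusted <= 1))
})

test_that("indices stay in [0, 1] across a simulated cohort", {
  sim <- small_sim(seed = 31, n_sharks = c(FA = 2, FB = 1, MC = 2),
                   study_days = 40, p_detect = 0.5, singleton_rate = 0.01)
  clean <- remove_false_detections(sim$detections)
  res <- residency_summary(clean, sim_study_config(sim$truth$config))
  expect_true(all(res$ri >= 0 & res$ri <= 1))
  expect_true(all(res$ri_max >= 0 & res$ri_max <= 1))
  expect_true(all(res$roaming_index > 0 & res$roaming_index <= 1))
})
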