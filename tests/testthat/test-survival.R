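test_that("partial-likelihood fit matches a hand-written grid-search oracle", {
  # three subjects: x = 1 event at t = 1; x = 0 event at t = 2; x = 1
  # censored at t = 3; the partial likelihood is
  # e^b / (2 e^b + 1) * 1 / (e^b + 1)
  d <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0),
                  scr_x = c(1, 0, 1))
  f <- scrmiss:::cox_one(d, survival::Surv(time, event) ~ scr_x)
  grid <- seq(-3, 3, by = 1e-4)
  pl <- exp(grid) / (2 * exp(grid) + 1) * 1 / (exp(grid) + 1)
  expect_equal(f$coef, grid[which.max(pl)], tolerance = 1e-3)
})

test_that("null and true hazard ratios are recovered from large cohorts", {
  null_coh <- generate_cohort(generator_params(
    n = 8000, log_hr_scr = 0, seed = 90))
  h0 <- fit_cox_fixed(null_coh, exam = 1)
  expect_lt(abs(h0$log_hr), 2 * h0$se_log_hr)

  coh <- generate_cohort(generator_params(n = 20000, seed = 91))
  h1 <- fit_cox_fixed(coh, exam = 1)
  expect_lt(abs(h1$log_hr - log(1.15)), 2 * h1$se_log_hr)
  ht <- fit_cox_td(coh)
  expect_lt(abs(ht$log_hr - log(1.15)), 2 * ht$se_log_hr)
  expect_equal(ht$ci_low, exp(ht$log_hr - 1.96 * ht$se_log_hr))
  expect_equal(ht$ci_high, exp(ht$log_hr + 1.96 * ht$se_log_hr))
})

test_that("time-dependent and fixed fits coincide for constant covariates", {
  coh <- generate_cohort(generator_params(n = 3000, sigma_prog = 0, drift = 0,
                                          p_progressor = 0, seed = 92))
  hf <- fit_cox_fixed(coh, exam = 1)
  ht <- fit_cox_td(coh)
  expect_equal(ht$log_hr, hf$log_hr, tolerance = 1e-3)
})

test_that("hazard ratios are invariant to row order and time units", {
  coh <- generate_cohort(generator_params(n = 2000, seed = 93))
  base <- fit_cox_td(coh)
  perm <- coh[sample(nrow(coh)), ]
  expect_equal(fit_cox_td(perm)$log_hr, base$log_hr, tolerance = 1e-8)
  scaled <- coh
  scaled$time <- coh$time * 12            # months instead of years
  hs <- fit_cox_td(scaled, exam_times = c(0, 4, 9) * 12)
  expect_equal(hs$log_hr, base$log_hr, tolerance = 1e-8)
})

test_that("landmarked exam fits restart the clock at the exam", {
  coh <- generate_cohort(generator_params(n = 5000, seed = 110))
  lm2 <- fit_cox_fixed(coh, exam = 2, landmark = TRUE)
  expect_equal(lm2$n_used, sum(coh$time > 4))
  expect_true(is.finite(lm2$log_hr))
  # proportionality check is logged, not fatal
  expect_message(fit_cox_fixed(coh, exam = 1, ph_check = TRUE), "Schoenfeld")
})

test_that("summaries follow the pooling rules for imputed sets", {
  coh <- generate_cohort(generator_params(n = 400, seed = 94))
  s <- summarize_scr(coh)
  expect_equal(s$mean, colMeans(coh[, c("scr1", "scr2", "scr3")]),
               ignore_attr = TRUE)

  mask <- apply_mcar(coh, mechanism_spec("mcar", seed = 95))
  mi <- multiple_impute(coh, mask, m = 2, n_iter = 3, seed = 96)
  # duplicated sets give the single-set summary
  mi$sets[[2]] <- mi$sets[[1]]
  s2 <- summarize_scr(mi)
  expect_equal(s2$mean[1], mean(mi$sets[[1]]$scr1))
  expect_equal(s2$sd[1], sd(mi$sets[[1]]$scr1))

  done <- mean_impute(coh, mask)
  s3 <- summarize_scr(done)
  expect_equal(s3$mean[2], mean(coh$scr2[mask[, 2] == 0]))
})

test_that("fits pooled over imputations widen with between-imputation spread", {
  coh <- generate_cohort(generator_params(n = 1500, seed = 97))
  mask <- apply_mcar(coh, mechanism_spec("mcar", seed = 98))
  mi <- multiple_impute(coh, mask, m = 4, n_iter = 4, seed = 99)
  pooled <- fit_cox_fixed(mi, exam = 2)
  singles <- vapply(mi$sets, function(d) {
    d$scr_x <- d$scr2
    scrmiss:::cox_one(d, survival::Surv(time, event) ~ scr_x + age + gender +
                        diabetes)$se
  }, 0)
  expect_gte(pooled$se_log_hr, min(singles))
  expect_equal(pooled$n_used, 1500)
})

test_that("method ranking orders by discrepancy with complete data first", {
  report <- data.frame(
    model = "nmar",
    method = rep(c("Complete", "A", "B"), each = 2),
    exam = rep(c("3", "td"), 3),
    log_hr = c(0.1, 0.1, 0.4, 0.3, 0.2, 0.15),
    mean = 1,
    discrepancy_loghr = c(0, 0, 0.3, 0.2, 0.1, 0.05),
    discrepancy_mean = c(0, 0, 0.1, 0.1, 0.02, 0.02))
  rk <- rank_methods(report)$nmar
  expect_equal(rk$method, c("Complete", "B", "A"))
  expect_equal(rk$mean_abs_dloghr[1], 0)

  # ties on the hazard ratio break on mean recovery
  report$discrepancy_loghr[3:6] <- 0.2
  report$discrepancy_mean[5:6] <- 0.01
  expect_equal(rank_methods(report)$nmar$method, c("Complete", "B", "A"))

  expect_error(rank_methods(report[, -7]), "discrepancy_mean")
  report$discrepancy_loghr[2] <- NA
  expect_error(rank_methods(report), "incomplete")
})
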