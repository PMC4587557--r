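coh_big <- generate_cohort(generator_params(n = 2264, seed = 77))

test_that("MCAR masks hit target rates and degenerate rates exactly", {
  z <- apply_mcar(coh_big, mechanism_spec("mcar", rates = c(0, 0, 0), seed = 1))
  expect_true(all(z == 0))
  o <- apply_mcar(coh_big, mechanism_spec("mcar", rates = c(1, 1, 1), seed = 1))
  expect_true(all(o == 1))

  m <- apply_mcar(coh_big, mechanism_spec("mcar", seed = 9))
  got <- colMeans(m)
  tgt <- c(0.20, 0.30, 0.40)
  expect_true(all(abs(got - tgt) < 3 * sqrt(tgt * (1 - tgt) / 2264)))
})

test_that("MCAR masks are independent of cohort values", {
  m <- apply_mcar(coh_big, mechanism_spec("mcar", seed = 4))
  for (j in 1:3) {
    p <- t.test(coh_big$scr1 ~ m[, j])$p.value
    expect_gt(p, 1e-4)
  }
})

test_that("autoregressive mechanism arithmetic matches its coefficients", {
  # per-subject Exam-3 probability with the printed intercept and slope
  spec <- mechanism_spec("ar", ar = list(a2 = 0.3, a3 = 0.082, b3 = 0.353),
                         seed = 1)
  p_prev_missing <- scrmiss:::mech_prob(spec, 3, coh_big[1, ], prev = 1)
  expect_equal(unname(p_prev_missing), 0.082 + 0.353, tolerance = 1e-12)
  p_prev_obs <- scrmiss:::mech_prob(spec, 3, coh_big[1, ], prev = 0)
  expect_equal(unname(p_prev_obs), 0.082, tolerance = 1e-12)
})

test_that("autoregressive dependence equals b3 on the probability scale", {
  spec <- mechanism_spec("ar", seed = 21)
  m <- apply_autoregressive(coh_big, spec)
  # difference-of-proportions oracle for the Exam-3 | Exam-2 dependence
  d <- mean(m[m[, 2] == 1, 3]) - mean(m[m[, 2] == 0, 3])
  n1 <- sum(m[, 2] == 1); n0 <- sum(m[, 2] == 0)
  se <- sqrt(0.25 / n1 + 0.25 / n0)
  expect_lt(abs(d - spec$ar$b3), 3 * se)

  # degenerate autoregression: columns 2 and 3 independent
  spec0 <- mechanism_spec("ar", ar = list(a2 = 0.3, a3 = 0.4, b3 = 0),
                          seed = 22)
  m0 <- apply_autoregressive(coh_big, spec0)
  p <- suppressWarnings(chisq.test(table(m0[, 2], m0[, 3]))$p.value)
  expect_gt(p, 1e-4)
})

test_that("covariate-augmented mechanism reduces to MCAR with zero slopes", {
  spec <- mechanism_spec("ar_cov", seed = 5)
  spec$cov$exam2[] <- c(0.25, 0, 0, 0, 0)
  spec$cov$exam3[] <- c(0.25, 0, 0, 0, 0)
  m <- apply_ar_covariates(coh_big, spec)
  for (j in 2:3) {
    expect_lt(abs(mean(m[, j]) - 0.25), 3 * sqrt(0.25 * 0.75 / 2264))
  }
  # requires demographics
  nocov <- coh_big
  nocov$age[1] <- NA
  expect_error(apply_ar_covariates(nocov, mechanism_spec("ar_cov", seed = 1)),
               "gender and age")
})

test_that("selection mechanism has closed-form rates and biases observed means", {
  # beta = 0 collapses to MCAR at expit(alpha)
  spec <- mechanism_spec("nmar", seed = 31)
  spec$nmar$alpha_female[] <- spec$nmar$alpha_male[] <- -2
  spec$nmar$beta_female[] <- spec$nmar$beta_male[] <- 0
  p <- scrmiss:::mech_prob(spec, 1, coh_big)
  expect_equal(unname(p[1]), 0.1192, tolerance = 1e-4)
  expect_equal(max(p) - min(p), 0)

  spec <- mechanism_spec("nmar", seed = 32)    # beta = 1.5 default
  m <- apply_nmar(coh_big, spec)
  for (j in 1:3) {
    col <- coh_big[[paste0("scr", j)]]
    expect_lt(mean(col[m[, j] == 0]), mean(col))
  }
})

test_that("observed-case bias grows monotonically with selection strength", {
  gaps <- sapply(c(0.5, 1.5, 3), function(b) {
    spec <- mechanism_spec("nmar", seed = 40)
    spec$nmar$beta_female[] <- spec$nmar$beta_male[] <- b
    spec$offsets <- calibrate_offsets(coh_big, spec)
    m <- apply_nmar(coh_big, spec)
    mean(coh_big$scr3) - mean(coh_big$scr3[m[, 3] == 0])
  })
  expect_true(all(diff(gaps) > 0))
})

test_that("offset calibration reaches the design rates for every mechanism", {
  for (model in c("ar", "ar_cov", "nmar")) {
    spec <- mechanism_spec(model, seed = 51)
    spec$offsets <- calibrate_offsets(coh_big, spec)
    got <- scrmiss:::expected_rates(coh_big, spec)
    expect_true(all(abs(got - spec$rates) < 0.005), label = model)
  }
  # mcar is the identity case
  expect_identical(calibrate_offsets(coh_big, mechanism_spec("mcar")),
                   c(0, 0, 0))
  # a mechanism already on target keeps offsets near zero
  spec <- mechanism_spec("ar", seed = 52)
  off <- calibrate_offsets(coh_big, spec)
  expect_lt(max(abs(off)), 0.01)
})

test_that("nmar calibration with unit slope hits a 40% Exam-3 rate", {
  spec <- mechanism_spec("nmar", seed = 61)
  spec$nmar$beta_female[] <- spec$nmar$beta_male[] <- 1
  spec$offsets <- calibrate_offsets(coh_big, spec)
  got <- scrmiss:::expected_rates(coh_big, spec)[3]
  expect_lt(abs(got - 0.40), 0.005)
  m <- apply_nmar(coh_big, spec)
  expect_lt(abs(mean(m[, 3]) - 0.40), 3 * sqrt(0.4 * 0.6 / 2264))
})

test_that("masks round-trip through CSV and are seed-reproducible", {
  spec <- mechanism_spec("ar", seed = 71)
  m1 <- apply_autoregressive(coh_big, spec)
  m2 <- apply_autoregressive(coh_big, spec)
  expect_identical(m1, m2)
  path <- tempfile(fileext = ".csv")
  write_mask(m1, coh_big, path)
  expect_equal(unclass(read_mask(path)), unclass(m1), ignore_attr = TRUE)
})
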