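coh_mid <- generate_cohort(generator_params(n = 1000, seed = 55))
mask_mid <- apply_mcar(coh_mid, mechanism_spec("mcar", seed = 56))

test_that("listwise deletion keeps exactly the complete rows", {
  zero <- matrix(0L, 3, 3)
  full <- listwise_delete(tiny_cohort(), zero)
  expect_equal(full$retained, 1:3)

  m <- rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 1))
  ld <- listwise_delete(tiny_cohort(), m)
  expect_equal(ld$retained, 1L)
  expect_equal(nrow(ld$sets[[1]]), 1)

  expect_error(listwise_delete(tiny_cohort(), matrix(1L, 3, 3)), "zero rows")
})

test_that("retained fraction under independent MCAR matches the product rule", {
  coh <- generate_cohort(generator_params(n = 2264, seed = 57))
  m <- apply_mcar(coh, mechanism_spec("mcar", seed = 58))
  frac <- length(listwise_delete(coh, m)$retained) / 2264
  expect_lt(abs(frac - 0.8 * 0.7 * 0.6), 3 * sqrt(0.336 * 0.664 / 2264))
})

test_that("exam-mean substitution has its textbook properties", {
  m <- rbind(c(0, 1, 0), c(0, 0, 0), c(0, 0, 0))
  coh <- tiny_cohort(cbind(c(1.0, 1.0, 0.6),     # scr1
                           c(0.7, 0.9, 1.1),     # scr2 (first cell masked)
                           c(0.6, 0.6, 0.7)))    # scr3
  out <- mean_impute(coh, m)$sets[[1]]
  expect_equal(out$scr2[1], mean(c(0.9, 1.1)))   # observed-case mean

  done <- mean_impute(coh_mid, mask_mid)$sets[[1]]
  for (j in 1:3) {
    col <- paste0("scr", j)
    obs <- mask_mid[, j] == 0
    expect_equal(mean(done[[col]]), mean(coh_mid[[col]][obs]))  # mean preserved
    expect_lte(sd(done[[col]]), sd(coh_mid[[col]][obs]))        # SD shrinks
  }
  none <- mean_impute(coh_mid, matrix(0L, 1000, 3))$sets[[1]]
  expect_identical(none, coh_mid)
})

test_that("adjacent-value imputation follows the carry-forward rule", {
  coh <- tiny_cohort(matrix(c(0.8, NA, 1.0), 1, 3)[rep(1, 3), ])
  m <- rbind(c(0, 1, 0), c(0, 1, 0), c(0, 1, 0))
  coh[, c("scr1", "scr2", "scr3")] <- rbind(c(0.8, 0.5, 1.0),
                                            c(0.7, 0.5, 0.9),
                                            c(0.6, 0.5, 1.1))
  out <- adjacent_value_impute(coh, m)$sets[[1]]
  expect_equal(out$scr2, c(0.8, 0.7, 0.6))       # previous exam wins

  m2 <- rbind(c(1, 0, 1), c(0, 0, 0), c(1, 1, 1))
  av <- adjacent_value_impute(coh, m2)
  expect_equal(av$unresolved, 3L)
  expect_equal(nrow(av$sets[[1]]), 2)
  expect_equal(av$sets[[1]]$scr1[1], coh$scr2[1])
  expect_equal(av$sets[[1]]$scr3[1], coh$scr2[1])
})

test_that("multiple imputation is proper and collapses without missingness", {
  mi <- multiple_impute(coh_mid, mask_mid, m = 3, n_iter = 5, seed = 9)
  i <- which(mask_mid[, 2] == 1)[1]
  vals <- vapply(mi$sets, function(d) d$scr2[i], 0)
  expect_gt(var(vals), 0)                         # between-imputation spread

  none <- multiple_impute(coh_mid, matrix(0L, 1000, 3), m = 2, seed = 9)
  expect_identical(none$sets[[1]], coh_mid)
  expect_identical(none$sets[[2]], coh_mid)

  expect_error(multiple_impute(coh_mid, mask_mid, m = 1), "m >= 2")
})

test_that("no imputation method alters an observed cell", {
  coh <- generate_cohort(generator_params(n = 300, seed = 70))
  mask <- apply_nmar(coh, mechanism_spec("nmar", seed = 71))
  scr <- as.matrix(coh[, c("scr1", "scr2", "scr3")])
  for (method in c("Mean", "AV", "MI", "PM10", "PM50")) {
    sets <- impute_method(method, coh, mask, m = 2, n_iter = 3, seed = 72)
    for (d in sets$sets) {
      keep <- match(d$subject_id, coh$subject_id)
      got <- as.matrix(d[, c("scr1", "scr2", "scr3")])
      same <- got == scr[keep, ]
      expect_true(all(same[mask[keep, ] == 0]), label = method)
    }
  }
  ld <- listwise_delete(coh, mask)
  expect_identical(ld$sets[[1]],
                   coh[rowSums(mask) == 0, , drop = FALSE])
})

test_that("pattern-mixture restriction respects its bound and direction", {
  coh <- generate_cohort(generator_params(n = 800, seed = 80))
  mask <- apply_nmar(coh, mechanism_spec("nmar", seed = 81))

  mi_mean <- mean(vapply(multiple_impute(coh, mask, m = 3, n_iter = 5,
                                         seed = 82)$sets,
                         function(d) mean(d$scr3), 0))
  pm_lo <- mean(vapply(pattern_mixture_impute(coh, mask, 50, "lower_bound",
                                              m = 3, n_iter = 5, seed = 82)$sets,
                       function(d) mean(d$scr3), 0))
  expect_gt(pm_lo, mi_mean)        # lower-bound restriction shifts upward

  # mean increases with the percentile for a fixed direction
  pm_means <- vapply(c(10, 25, 50), function(p) {
    mean(vapply(pattern_mixture_impute(coh, mask, p, "upper_bound",
                                       m = 3, n_iter = 5, seed = 83)$sets,
                function(d) mean(d$scr2), 0))
  }, 0)
  expect_true(all(diff(pm_means) > 0))

  expect_error(pattern_mixture_impute(coh, mask, 0), "p")
})

test_that("Rubin pooling reproduces its closed-form arithmetic", {
  p <- rubin_pool(c(0.5, 0.7), c(0.04, 0.04))
  expect_equal(p$estimate, 0.6)
  expect_equal(p$B, 0.02)
  expect_equal(p$T, 0.07)
  expect_equal(p$se, sqrt(0.07))

  same <- rubin_pool(c(0.4, 0.4, 0.4), c(0.01, 0.02, 0.03))
  expect_equal(same$T, same$W)                   # B = 0
  expect_equal(same$df, Inf)

  set.seed(1)
  est <- rnorm(5); v <- runif(5, 0.01, 0.05)
  expect_gte(rubin_pool(est, v)$se, sqrt(mean(v)))
  expect_error(rubin_pool(0.5, 0.1), "m >= 2")
})

test_that("pooled MI exam means are unbiased under MCAR", {
  hits <- 0; total <- 0
  for (r in 1:100) {
    coh <- generate_cohort(generator_params(n = 300, seed = 9000 + r))
    mask <- apply_mcar(coh, mechanism_spec("mcar", seed = 9500 + r))
    mi <- multiple_impute(coh, mask, m = 5, n_iter = 5, seed = 9900 + r)
    for (j in 2:3) {
      col <- paste0("scr", j)
      ests <- vapply(mi$sets, function(d) mean(d[[col]]), 0)
      vars <- vapply(mi$sets, function(d) var(d[[col]]) / nrow(d), 0)
      pl <- rubin_pool(ests, vars)
      hits <- hits + (abs(pl$estimate - mean(coh[[col]])) < 2 * pl$se)
      total <- total + 1
    }
  }
  expect_gte(hits / total, 0.9)
})
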