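test_that("identity-link GLM with intercept only returns the sample proportion", {
  set.seed(1)
  y <- rbinom(500, 1, 0.23)
  fit <- fit_missingness_glm(y)
  expect_equal(unname(fit$coefficients), mean(y), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_error(fit_missingness_glm(rep(0, 10)), "degenerate")
})

test_that("identity-link GLM recovers linear-probability coefficients", {
  set.seed(2)
  n <- 50000
  x <- rbinom(n, 1, 0.359)
  y <- rbinom(n, 1, 0.089 + 0.036 * x)
  fit <- fit_missingness_glm(y, cbind(gender = x))
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - 0.089), 2 * fit$se[[1]])
  expect_lt(abs(fit$coefficients[["gender"]] - 0.036), 2 * fit$se[[2]])
  expect_equal(unname(fit$t), unname(fit$coefficients / fit$se))
})

test_that("residual deviance drops when a truly predictive covariate is added", {
  set.seed(3)
  n <- 4000
  x <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, 0.10 + 0.15 * x)
  f0 <- fit_missingness_glm(y)
  f1 <- fit_missingness_glm(y, cbind(x = x))
  expect_gt(f0$deviance - f1$deviance, qchisq(0.99, 1))
  # oracle: the deviance is minus twice the Bernoulli log-likelihood
  p1 <- drop(cbind(1, x) %*% f1$coefficients)
  expect_equal(f1$deviance, -2 * sum(y * log(p1) + (1 - y) * log(1 - p1)),
               tolerance = 1e-8)
})

test_that("selection likelihood factorizes exactly when selection is ignorable", {
  d <- sim_selection(800, 12)
  mnp <- markov_normal_params(d$y, d$mask)
  a <- c(-1.2, -0.8, -0.5)
  nll <- troxel_negloglik(a, 0, d$y, d$mask, mnp, quad_order = 24)
  # closed form: Gaussian likelihood of the observed coordinates under the
  # implied trivariate normal + independent Bernoulli mask likelihood
  mu <- numeric(3)
  mu[1] <- mnp$marg_mean[1]
  mu[2] <- mnp$intercept[2] + mnp$slope[2] * mu[1]
  mu[3] <- mnp$intercept[3] + mnp$slope[3] * mu[2]
  v1 <- mnp$marg_sd[1]^2
  v2 <- mnp$slope[2]^2 * v1 + mnp$resid_sd[2]^2
  v3 <- mnp$slope[3]^2 * v2 + mnp$resid_sd[3]^2
  S <- matrix(c(v1, mnp$slope[2] * v1, mnp$slope[2] * mnp$slope[3] * v1,
                mnp$slope[2] * v1, v2, mnp$slope[3] * v2,
                mnp$slope[2] * mnp$slope[3] * v1, mnp$slope[3] * v2, v3), 3, 3)
  gll <- 0
  for (i in seq_len(nrow(d$y))) {
    o <- which(d$mask[i, ] == 0)
    if (!length(o)) next
    x <- d$y[i, o] - mu[o]
    So <- S[o, o, drop = FALSE]
    gll <- gll - 0.5 * (length(o) * log(2 * pi) +
                          as.numeric(determinant(So)$modulus) +
                          drop(x %*% solve(So, x)))
  }
  bern <- sum(dbinom(d$mask, 1,
                     matrix(plogis(a), nrow(d$y), 3, byrow = TRUE), log = TRUE))
  expect_equal(nll, -(gll + bern), tolerance = 1e-10)
})

test_that("quadrature agrees with Monte-Carlo integration on a small fixture", {
  d <- sim_selection(20, 42, alpha = -1.5, beta = 1.2)
  # ensure the fixture exercises every arrangement of missing cells
  d$mask[1:4, ] <- rbind(c(1, 1, 1), c(1, 1, 0), c(0, 1, 1), c(1, 0, 1))
  mnp <- markov_normal_params(sim_selection(5000, 43)$y)
  alpha <- c(-1.5, -1.2, -1.0); beta <- c(1.2, 0.8, 1.0)
  nll_q <- troxel_negloglik(alpha, beta, d$y, d$mask, mnp, quad_order = 64)
  lik_mc <- vapply(seq_len(20), function(i) {
    mc_subject_lik(d$y[i, ], d$mask[i, ], mnp, alpha, beta,
                   draws = 2e6, seed = 100 + i)
  }, 0)
  lik_q <- vapply(seq_len(20), function(i) {
    exp(-troxel_negloglik(alpha, beta, d$y[i, , drop = FALSE],
                          d$mask[i, , drop = FALSE], mnp, quad_order = 64))
  }, 0)
  expect_equal(sum(-log(lik_q)), nll_q, tolerance = 1e-8)  # additivity
  expect_lt(max(abs(lik_q - lik_mc)), 5e-4)
})

test_that("quadrature is converged by order 40 and both engines agree", {
  d <- sim_selection(500, 17)
  mnp <- markov_normal_params(d$y, d$mask)
  n40 <- troxel_negloglik(-2.5, 2, d$y, d$mask, mnp, quad_order = 40)
  n80 <- troxel_negloglik(-2.5, 2, d$y, d$mask, mnp, quad_order = 80)
  expect_lt(abs(n40 - n80), 1e-6)
  nr <- troxel_negloglik(-2.5, 2, d$y, d$mask, mnp, quad_order = 40,
                         engine = "r")
  expect_equal(n40, nr, tolerance = 1e-10)
})

test_that("analytic likelihood gradient matches finite differences", {
  d <- sim_selection(200, 23, alpha = -1.5, beta = 1.2)
  mnp <- markov_normal_params(d$y, d$mask)
  gh <- pracma::gaussHermite(20)
  gx <- sqrt(2) * gh$x; gw <- gh$w / sqrt(pi)
  ym <- d$y; mm <- matrix(as.integer(d$mask), nrow(ym), 3)
  th <- c(-1.4, -1.6, -1.3, 1.1, 1.0, 1.3, scrmiss:::pack_mnp(mnp))
  f <- function(t) scrmiss:::.troxel_nll_cpp(ym, mm, t[1:3], t[4:6], t[7:14],
                                             gx, gw)
  out <- scrmiss:::.troxel_nll_grad_cpp(ym, mm, th[1:3], th[4:6], th[7:14],
                                        gx, gw)
  expect_equal(out$nll, f(th), tolerance = 1e-12)
  num <- vapply(1:14, function(i) {
    e <- numeric(14); e[i] <- 1e-6
    (f(th + e) - f(th - e)) / 2e-6
  }, 0)
  expect_equal(out$grad, num, tolerance = 1e-5)
})

test_that("selection fit recovers a null slope and rejects degenerate input", {
  hits <- vapply(1:20, function(r) {
    set.seed(300 + r)
    n <- 2000
    y1 <- rnorm(n); y2 <- 0.2 + 0.7 * y1 + rnorm(n, 0, 0.6)
    y3 <- 0.1 + 0.7 * y2 + rnorm(n, 0, 0.6)
    y <- cbind(y1, y2, y3)
    mask <- matrix(rbinom(3 * n, 1, 0.25), n, 3)   # beta = 0 truth
    f <- fit_troxel(y, mask, per_exam = FALSE, transform = "identity",
                    quad_order = 16)$strata$all
    abs(f$beta / f$se_beta) < 1.96
  }, NA)
  expect_gte(mean(hits), 0.8)

  d <- sim_selection(200, 5)
  expect_error(fit_troxel(d$y, matrix(0L, 200, 3), transform = "identity"),
               "degenerate")
})

test_that("per-gender fitting returns one stratum per gender", {
  coh <- generate_cohort(generator_params(n = 1500, seed = 15))
  mask <- apply_nmar(coh, mechanism_spec("nmar", seed = 16))
  fit <- fit_troxel(coh, mask, by_gender = TRUE, per_exam = FALSE,
                    quad_order = 16)
  expect_named(fit$strata, c("female", "male"))
  for (s in fit$strata) {
    expect_true(s$converged)
    expect_true(all(is.finite(c(s$alpha, s$beta))))
    # selection deletes high values, so the fitted slope is positive
    expect_gt(s$beta, 0)
  }
})
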