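# shared simulation helpers for the suite

# tiny hand-built cohort with known Scr values (3 subjects)
tiny_cohort <- function(scr = matrix(c(1.0, 0.8, 0.9,
                                       1.0, 0.9, 1.1,
                                       0.6, 1.0, 0.7), 3, 3, byrow = FALSE)) {
  data.frame(subject_id = 1:3, gender = c(0, 1, 0), age = c(50, 60, 55),
             diabetes = c(0, 1, 0),
             scr1 = scr[, 1], scr2 = scr[, 2], scr3 = scr[, 3],
             event = c(1, 0, 1), time = c(5, 14, 10))
}

# Markov-normal series with logistic selection, used by the
# selection-model tests (working scale, no transform)
sim_selection <- function(n, seed, alpha = -2.5, beta = 2.0) {
  set.seed(seed)
  y1 <- rnorm(n)
  y2 <- 0.2 + 0.7 * y1 + rnorm(n, 0, 0.6)
  y3 <- 0.1 + 0.7 * y2 + rnorm(n, 0, 0.6)
  y <- cbind(y1, y2, y3)
  mask <- matrix(rbinom(3 * n, 1, plogis(alpha + beta * y)), n, 3)
  list(y = y, mask = mask)
}

# Monte-Carlo oracle for the per-subject selection-model likelihood:
# sequential forward draws of the missing coordinates, importance weight
# = product of observed-cell densities and all selection terms
mc_subject_lik <- function(yi, mi, mnp, alpha, beta, draws = 2e6, seed = 1) {
  set.seed(seed)
  alpha <- rep_len(alpha, 3); beta <- rep_len(beta, 3)
  w <- rep(1, draws)
  prev <- NULL
  for (t in 1:3) {
    mu <- if (t == 1) rep(mnp$marg_mean[1], draws) else
      mnp$intercept[t] + mnp$slope[t] * prev
    sd_t <- if (t == 1) mnp$marg_sd[1] else mnp$resid_sd[t]
    if (mi[t] == 0) {
      w <- w * dnorm(yi[t], mu, sd_t) * (1 - plogis(alpha[t] + beta[t] * yi[t]))
      prev <- rep(yi[t], draws)
    } else {
      yt <- rnorm(draws, mu, sd_t)
      w <- w * plogis(alpha[t] + beta[t] * yt)
      prev <- yt
    }
  }
  mean(w)
}

# large-sample standard error of a sample SD (delta method)
se_of_sd <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m4 <- mean((x - mean(x))^4)
  sqrt(max(m4 - m2^2, 0) / (4 * m2 * n))
}
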