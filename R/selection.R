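#' Identity-link binary GLM by direct likelihood maximization
#'
#' Fits the linear-probability model `P(y = 1) = X b` by maximizing the
#' Bernoulli log-likelihood with BFGS, clamping fitted probabilities to
#' `(eps, 1 - eps)` during optimization. This is the fitter used to
#' estimate (and to recover, in simulation) the coefficients of the MAR
#' missingness mechanisms. Standard errors come from the inverted numeric
#' Hessian at the optimum; `deviance` is the residual deviance
#' (`-2 * loglik` for a binary response), which supports likelihood-ratio
#' comparison of nested mechanism models.
#'
#' @param y binary response vector (a mask column).
#' @param x covariate matrix or data frame (without intercept column).
#' @param intercept add an intercept term (default TRUE).
#' @param eps probability clamp used inside the likelihood.
#' @return A list of class `"glm_fit"`: `coefficients`, `se`, `t`,
#'   `loglik`, `deviance`, `converged`, `link = "identity"`, `n`.
#' @examples
#' x <- rbinom(5000, 1, 0.36)
#' y <- rbinom(5000, 1, 0.089 + 0.036 * x)
#' fit_missingness_glm(y, x)$coefficients
#' @export
fit_missingness_glm <- function(y, x = NULL, intercept = TRUE, eps = 1e-9) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary", call. = FALSE)
  if (all(y == 0) || all(y == 1)) {
    stop("degenerate response: all 0 or all 1", call. = FALSE)
  }
  X <- if (is.null(x)) matrix(numeric(0), length(y), 0) else as.matrix(x)
  if (is.null(colnames(X)) && ncol(X)) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  if (qr(X)$rank < ncol(X)) stop("covariates are collinear", call. = FALSE)

  nll <- function(b) {
    p <- clamp_prob(drop(X %*% b), eps)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  # least-squares start; for the intercept-only model this is already the
  # MLE (the sample proportion), so BFGS terminates there
  b0 <- drop(qr.solve(X, y))
  opt <- stats::optim(b0, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  H <- num_hessian(nll, opt$par)
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e) rep(NA_real_, ncol(X)))
  cf <- stats::setNames(opt$par, colnames(X))
  structure(list(coefficients = cf, se = stats::setNames(se, colnames(X)),
                 t = cf / se, loglik = -opt$value, deviance = 2 * opt$value,
                 converged = opt$convergence == 0, link = "identity",
                 n = length(y)),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("identity-link binary GLM (n =", x$n, ")\n")
  print(round(cbind(estimate = x$coefficients, se = x$se, t = x$t), 4))
  cat("residual deviance:", format(x$deviance), "\n")
  invisible(x)
}

# central-difference Hessian, step h_i = step * (1 + |theta_i|)
num_hessian <- function(f, theta, step = 1e-4) {
  k <- length(theta)
  h <- step * (1 + abs(theta))
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k); ei[i] <- h[i]; ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(theta + ei + ej) - f(theta + ei - ej) -
           f(theta - ei + ej) + f(theta - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' Estimate the Markov-normal working model for serial measurements
#'
#' The selection-model likelihood treats the serial measurements as
#' first-order Markov normal: `y1 ~ N(mean1, sd1)` and
#' `y_t | y_{t-1} ~ N(intercept_t + slope_t * y_{t-1}, resid_sd_t)`.
#' Parameters are estimated from observed cells (available-case marginal
#' moments; least squares on complete adjacent pairs).
#'
#' @param y n-by-3 numeric matrix of measurements (working scale).
#' @param mask n-by-3 binary missingness matrix (1 = missing).
#' @return A list of class `"markov_normal_params"` with length-3 vectors
#'   `marg_mean`, `marg_sd`, `intercept`, `slope`, `resid_sd` (the last
#'   three are `NA` at exam 1, where the marginal applies).
#' @export
markov_normal_params <- function(y, mask = matrix(0L, nrow(y), 3)) {
  y <- as.matrix(y); mask <- as.matrix(mask)
  stopifnot(ncol(y) == 3, all(dim(y) == dim(mask)))
  obs <- mask == 0
  marg_mean <- marg_sd <- intercept <- slope <- resid_sd <- rep(NA_real_, 3)
  for (t in 1:3) {
    v <- y[obs[, t], t]
    if (length(v) < 2) stop("too few observed values at exam ", t, call. = FALSE)
    marg_mean[t] <- mean(v); marg_sd[t] <- stats::sd(v)
  }
  for (t in 2:3) {
    pair <- obs[, t] & obs[, t - 1]
    if (sum(pair) < 3) stop("too few observed pairs for exams ",
                            t - 1, "-", t, call. = FALSE)
    fit <- stats::lm.fit(cbind(1, y[pair, t - 1]), y[pair, t])
    intercept[t] <- fit$coefficients[1]
    slope[t] <- fit$coefficients[2]
    resid_sd[t] <- sqrt(sum(fit$residuals^2) / (sum(pair) - 2))
  }
  structure(list(marg_mean = marg_mean, marg_sd = marg_sd,
                 intercept = intercept, slope = slope, resid_sd = resid_sd),
            class = "markov_normal_params")
}

# Precompute the theta-independent part of the selection-model likelihood.
# Subjects are grouped by missingness pattern; for each group we build the
# Gauss-Hermite particle grid over the missing coordinates:
#   V1, V2, V3 : k x P matrices of exam values (observed or node values)
#   B          : k x P matrix of density x quadrature weights
# so that the per-subject likelihood is rowSums(B * prod_t selterm_t(Vt)).
troxel_plan <- function(y, mask, mnp, quad_order = 40) {
  y <- as.matrix(y); mask <- as.matrix(mask)
  stopifnot(ncol(y) == 3, all(dim(y) == dim(mask)))
  gh <- pracma::gaussHermite(quad_order)
  gx <- sqrt(2) * gh$x
  gw <- gh$w / sqrt(pi)
  q <- quad_order
  pat_id <- mask[, 1] + 2 * mask[, 2] + 4 * mask[, 3]
  groups <- list()
  for (pid in sort(unique(pat_id))) {
    idx <- which(pat_id == pid)
    m <- c(pid %% 2, (pid %/% 2) %% 2, pid %/% 4)
    mult <- 1L
    if (all(m == 1)) {            # no observed data: identical contribution
      mult <- length(idx); idx <- idx[1]
    }
    k <- length(idx)
    expand <- function(V, P) V[, rep(seq_len(P), each = q), drop = FALSE]
    # exam 1: marginal normal
    if (m[1] == 1) {
      P <- q
      V1 <- matrix(mnp$marg_mean[1] + mnp$marg_sd[1] * gx, k, P, byrow = TRUE)
      B <- matrix(gw, k, P, byrow = TRUE)
    } else {
      P <- 1L
      V1 <- matrix(y[idx, 1], k, 1)
      B <- matrix(stats::dnorm(y[idx, 1], mnp$marg_mean[1], mnp$marg_sd[1]), k, 1)
    }
    V <- list(V1)
    for (t in 2:3) {
      mu <- mnp$intercept[t] + mnp$slope[t] * V[[t - 1]]
      if (m[t] == 1) {
        nodes <- matrix(mnp$resid_sd[t] * gx[rep(seq_len(q), P)],
                        k, P * q, byrow = TRUE)
        Vt <- expand(mu, P) + nodes
        B <- expand(B, P) * matrix(gw[rep(seq_len(q), P)], k, P * q, byrow = TRUE)
        V <- lapply(V, expand, P = P)
        P <- P * q
      } else {
        Vt <- matrix(y[idx, t], k, P)
        B <- B * stats::dnorm(Vt, mu, mnp$resid_sd[t])
      }
      V[[t]] <- Vt
    }
    groups[[length(groups) + 1]] <-
      list(m = m, mult = mult, V = V, B = B, k = k)
  }
  structure(list(groups = groups, n = nrow(y), quad_order = quad_order),
            class = "troxel_plan")
}

#' Negative log-likelihood of the logistic selection model
#'
#' Joint likelihood of the serial measurements and their missingness under
#' a Markov-normal outcome model and a logistic selection mechanism
#' `logit(pi_t(y)) = alpha_t + beta_t * y_t` in which selection may depend
#' on the current, possibly unobserved, value. Observed cells contribute
#' `f(y_t | y_{t-1}) * (1 - pi_t(y_t))`; missing cells contribute the
#' integral of `f(y | y_{t-1}) * pi_t(y)`, evaluated by Gauss-Hermite
#' quadrature, nested over consecutive missing exams (the marginal normal
#' is used at Exam 1).
#'
#' @param alpha,beta selection intercepts and slopes; either length 3 (one
#'   per exam) or length 1 (shared across exams).
#' @param y n-by-3 matrix of measurements on the working scale, or a
#'   precomputed plan from `troxel_plan()` (then `mask`/`mnp` are ignored).
#' @param mask n-by-3 binary missingness matrix.
#' @param mnp a [markov_normal_params()] object; estimated from `(y, mask)`
#'   when omitted.
#' @param quad_order Gauss-Hermite order (default 40).
#' @param engine `"cpp"` (compiled particle propagation, the default) or
#'   `"r"` (vectorized R implementation); both evaluate the identical
#'   quadrature rule and agree to machine precision.
#' @return The negative log-likelihood (scalar).
#' @export
troxel_negloglik <- function(alpha, beta, y, mask = NULL, mnp = NULL,
                             quad_order = 40, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  alpha <- rep_len(as.numeric(alpha), 3)
  beta <- rep_len(as.numeric(beta), 3)
  if (!inherits(y, "troxel_plan")) {
    if (is.null(mnp)) mnp <- markov_normal_params(y, mask)
    if (engine == "cpp") {
      gh <- pracma::gaussHermite(quad_order)
      return(.troxel_nll_cpp(as.matrix(y), matrix(as.integer(mask), nrow(y), 3),
                             alpha, beta, pack_mnp(mnp),
                             sqrt(2) * gh$x, gh$w / sqrt(pi)))
    }
    plan <- troxel_plan(y, mask, mnp, quad_order)
  } else {
    plan <- y
  }
  nll <- 0
  for (g in plan$groups) {
    F <- g$B
    for (t in 1:3) {
      p <- expit(alpha[t] + beta[t] * g$V[[t]])
      F <- F * (if (g$m[t] == 1) p else 1 - p)
    }
    L <- pmax(.rowSums(F, g$k, ncol(F)), 1e-300)
    if (!all(is.finite(L))) {
      stop("non-finite likelihood contribution for subject ",
           which(!is.finite(L))[1], call. = FALSE)
    }
    nll <- nll - g$mult * sum(log(L))
  }
  nll
}

#' Fit the logistic selection model of informative missingness
#'
#' Maximizes the [troxel_negloglik()] likelihood over the selection
#' parameters (alpha, beta) by quasi-Newton (BFGS) search, the
#' Markov-normal outcome parameters being profiled out (estimated once by
#' available-case least squares and held fixed, unless `joint = TRUE`).
#' Standard errors are `sqrt(diag(H^-1))` with `H` the central-difference
#' numeric Hessian at the optimum.
#'
#' @param y n-by-3 matrix of measurements, or a cohort data frame (its
#'   `scr1..scr3` columns are used).
#' @param mask n-by-3 binary missingness matrix.
#' @param by_gender fit women and men separately (requires a cohort with a
#'   `gender` column).
#' @param per_exam estimate a separate (alpha, beta) per exam (default);
#'   otherwise one shared pair.
#' @param transform `"log"` (default) models log-measurements as
#'   Markov normal, with selection on the log scale; `"identity"` uses the
#'   raw scale.
#' @param quad_order Gauss-Hermite order.
#' @param joint also maximize over the Markov-normal parameters.
#' @return A list of class `"selection_fit"`; one stratum (or one per
#'   gender) with `alpha`, `beta`, `se_alpha`, `se_beta`, `loglik`,
#'   `converged`, `quad_order`, `n`.
#' @export
fit_troxel <- function(y, mask, by_gender = FALSE, per_exam = TRUE,
                       transform = c("log", "identity"), quad_order = 40,
                       joint = FALSE) {
  transform <- match.arg(transform)
  gender <- NULL
  if (is.data.frame(y)) {
    gender <- y$gender
    y <- scr_matrix(check_cohort(y))
  }
  if (transform == "log") {
    if (any(y[mask == 0] <= 0)) stop("log transform needs positive values",
                                     call. = FALSE)
    y <- log(y)
  }
  mask <- as.matrix(mask)
  strata <- if (by_gender) {
    if (is.null(gender)) stop("by_gender requires a cohort with gender",
                              call. = FALSE)
    list(female = which(gender == 0), male = which(gender == 1))
  } else list(all = seq_len(nrow(y)))

  fits <- lapply(strata, function(idx) {
    fit_troxel_stratum(y[idx, , drop = FALSE], mask[idx, , drop = FALSE],
                       per_exam, quad_order, joint)
  })
  structure(list(strata = fits, per_exam = per_exam, transform = transform,
                 quad_order = quad_order),
            class = "selection_fit")
}

pack_mnp <- function(mnp) {
  c(mnp$marg_mean[1], mnp$marg_sd[1],
    mnp$intercept[2], mnp$slope[2], mnp$resid_sd[2],
    mnp$intercept[3], mnp$slope[3], mnp$resid_sd[3])
}

# central-difference Hessian computed from an analytic gradient function
hessian_from_grad <- function(gr, theta, step = 1e-5) {
  k <- length(theta)
  h <- step * (1 + abs(theta))
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    e <- numeric(k); e[i] <- h[i]
    H[i, ] <- (gr(theta + e) - gr(theta - e)) / (2 * h[i])
  }
  (H + t(H)) / 2
}

fit_troxel_stratum <- function(y, mask, per_exam, quad_order, joint) {
  n_miss <- colSums(mask)
  if (all(n_miss == 0)) {
    stop("degenerate input: no missing cells, selection intercepts diverge",
         call. = FALSE)
  }
  if (sum(mask == 0) < 50) {
    warning("fewer than 50 observed cells in stratum; fit may be unstable")
  }
  mnp <- markov_normal_params(y, mask)
  rate <- pmin(pmax(colMeans(mask), 0.02), 0.98)
  k <- if (per_exam) 3 else 1
  a0 <- if (per_exam) logit(rate) else logit(mean(rate))
  theta0 <- c(a0, rep(0, k))
  gh <- pracma::gaussHermite(quad_order)
  gx <- sqrt(2) * gh$x
  gw <- gh$w / sqrt(pi)
  ym <- as.matrix(y)
  mm <- matrix(as.integer(mask), nrow(ym), 3)
  sel <- function(th) list(alpha = rep_len(th[1:k], 3),
                           beta = rep_len(th[k + 1:k], 3))
  # selection-parameter gradient mapped onto the optimization layout
  # (shared parameters sum their per-exam components)
  sel_grad <- function(G) if (k == 3) G[1:6] else c(sum(G[1:3]), sum(G[4:6]))
  # memoize the (nll, gradient) pass so optim's fn/gr pair costs one
  # likelihood evaluation per point
  cache <- new.env(parent = emptyenv())
  make_obj <- function(mv_of, extra_grad) {
    eval_at <- function(th) {
      key <- paste(th, collapse = ",")
      if (!identical(cache$key, key)) {
        s <- sel(th)
        out <- .troxel_nll_grad_cpp(ym, mm, s$alpha, s$beta, mv_of(th), gx, gw)
        cache$key <- key
        cache$nll <- out$nll
        cache$grad <- c(sel_grad(out$grad), extra_grad(out$grad, th))
      }
      invisible(NULL)
    }
    list(fn = function(th) { eval_at(th); cache$nll },
         gr = function(th) { eval_at(th); cache$grad })
  }
  # profile stage: selection parameters only, Markov-normal model fixed at
  # its available-case estimate (this is also the starting point for the
  # joint maximization, which corrects the selection bias of the
  # available-case outcome estimates)
  mv0 <- pack_mnp(mnp)
  obj <- make_obj(function(th) mv0, function(G, th) numeric(0))
  opt <- stats::optim(theta0, obj$fn, obj$gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  if (joint) {
    mk_mv <- function(th) {
      c(th[2 * k + 1], exp(th[2 * k + 2]),
        th[2 * k + 3], th[2 * k + 5], exp(th[2 * k + 7]),
        th[2 * k + 4], th[2 * k + 6], exp(th[2 * k + 8]))
    }
    obj <- make_obj(mk_mv, function(G, th) {
      mv <- mk_mv(th)
      # layout: m1, log s1, i2, i3, b2, b3, log r2, log r3
      c(G[7], G[8] * mv[2], G[9], G[12], G[10], G[13],
        G[11] * mv[5], G[14] * mv[8])
    })
    theta0 <- c(opt$par, mnp$marg_mean[1], log(mnp$marg_sd[1]),
                mnp$intercept[2:3], mnp$slope[2:3], log(mnp$resid_sd[2:3]))
    opt <- stats::optim(theta0, obj$fn, obj$gr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-10))
    mv <- mk_mv(opt$par)
    mnp$marg_mean[1] <- mv[1]; mnp$marg_sd[1] <- mv[2]
    mnp$intercept[2:3] <- mv[c(3, 6)]
    mnp$slope[2:3] <- mv[c(4, 7)]
    mnp$resid_sd[2:3] <- mv[c(5, 8)]
  }
  if (opt$convergence != 0) {
    stop("selection-model fit did not converge; last gradient norm ",
         format(sqrt(sum(obj$gr(opt$par)^2))), call. = FALSE)
  }
  H <- hessian_from_grad(obj$gr, opt$par)
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e) {
    warning("singular Hessian: standard errors undefined")
    rep(NA_real_, length(opt$par))
  })
  list(alpha = opt$par[1:k], beta = opt$par[k + 1:k],
       se_alpha = se[1:k], se_beta = se[k + 1:k],
       loglik = -opt$value, converged = TRUE, quad_order = quad_order,
       n = nrow(y), mnp = mnp)
}

#' @export
print.selection_fit <- function(x, ...) {
  cat("logistic selection-model fit (", x$transform, " scale, quadrature order ",
      x$quad_order, ")\n", sep = "")
  for (nm in names(x$strata)) {
    s <- x$strata[[nm]]
    cat(" stratum ", nm, " (n = ", s$n, "), logLik = ",
        format(s$loglik), "\n", sep = "")
    print(round(cbind(alpha = s$alpha, se_a = s$se_alpha,
                      beta = s$beta, se_b = s$se_beta), 4))
  }
  invisible(x)
}

#' Serialize a selection or GLM fit to JSON
#'
#' @param fit a `"selection_fit"` or `"glm_fit"`.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
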