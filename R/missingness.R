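#' Specify a missingness-generating mechanism
#'
#' Describes one of the four mechanisms used to delete serial Scr values
#' from a complete cohort:
#'
#' * `"mcar"` — each cell missing independently with the per-exam target
#'   rate (missing completely at random).
#' * `"ar"` — autoregressive missingness: Exam 1 at random; Exam 2 with a
#'   constant probability (independent of Exam 1); Exam 3 probability
#'   raised by `b3` when Exam 2 is missing. Still MAR: the mask depends
#'   only on the observed missingness history, never on Scr itself.
#' * `"ar_cov"` — the autoregressive mechanism augmented with gender and
#'   age: a linear-probability predictor per exam with intercept, gender,
#'   age, transformed-age and prior-missingness terms.
#' * `"nmar"` — informative selection: each cell missing with probability
#'   `expit(alpha + beta * scr)` where `scr` is the subject's *true*
#'   (pre-deletion) value at that exam, fitted separately by gender. With
#'   `beta > 0`, high-creatinine values are preferentially deleted, so
#'   observed-case summaries are biased low.
#'
#' Linear-probability predictors are clamped to `[epsilon, 1 - epsilon]`.
#' `offsets` shift each exam's predictor (probability scale for the MAR
#' mechanisms, logit scale for `"nmar"`) and are what
#' [calibrate_offsets()] adjusts so that marginal rates match `rates`.
#' The default coefficient sets are pre-calibrated so that the default
#' cohort generator yields marginal missingness close to 20/30/40%.
#'
#' @param model one of `"mcar"`, `"ar"`, `"ar_cov"`, `"nmar"`.
#' @param rates length-3 target marginal missingness rates per exam.
#' @param ar list with `a2`, `a3` (Exam-2/3 intercepts) and `b3`
#'   (autoregressive slope, default 0.353).
#' @param cov list with `exam2` and `exam3` coefficient vectors
#'   (`intercept`, `gender`, `age`, `g_age`, `prior`) and `age_transform`
#'   (one of `"ln"`, `"sqrt"`, `"identity"`) applied to age in the `g_age`
#'   term.
#' @param nmar list with `alpha_female`, `beta_female`, `alpha_male`,
#'   `beta_male`, each a length-3 vector (one entry per exam).
#' @param offsets length-3 additive offsets per exam.
#' @param epsilon clamping bound for probabilities, in (0, 0.5).
#' @param seed integer seed used when a mask is drawn.
#' @return A list of class `"mechanism_spec"`.
#' @export
mechanism_spec <- function(model = c("mcar", "ar", "ar_cov", "nmar"),
                           rates = c(0.20, 0.30, 0.40),
                           ar = list(a2 = 0.30, a3 = 0.2941, b3 = 0.353),
                           cov = list(
                             exam2 = c(intercept = 1.80, gender = 0.035,
                                       age = 0.028, g_age = -0.44, prior = 0),
                             exam3 = c(intercept = 3.22, gender = 0.030,
                                       age = 0.059, g_age = -0.863,
                                       prior = 0.353),
                             age_transform = "ln"),
                           nmar = list(alpha_female = c(-2.747, -2.246, -1.778),
                                       beta_female = c(1.5, 1.5, 1.5),
                                       alpha_male = c(-2.747, -2.246, -1.778),
                                       beta_male = c(1.5, 1.5, 1.5)),
                           offsets = c(0, 0, 0),
                           epsilon = 0.001,
                           seed = 1L) {
  model <- match.arg(model)
  spec <- list(model = model, rates = rates, ar = ar, cov = cov, nmar = nmar,
               offsets = offsets, epsilon = epsilon, seed = as.integer(seed))
  validate_mechanism_spec(spec)
  structure(spec, class = "mechanism_spec")
}

validate_mechanism_spec <- function(spec) {
  if (length(spec$rates) != 3 || any(spec$rates < 0) || any(spec$rates > 1)) {
    stop_param("rates", "must be 3 probabilities in [0, 1]")
  }
  if (spec$epsilon <= 0 || spec$epsilon >= 0.5) {
    stop_param("epsilon", "must lie in (0, 0.5)")
  }
  if (length(spec$offsets) != 3 || !is.numeric(spec$offsets)) {
    stop_param("offsets", "must be 3 numbers")
  }
  if (spec$model == "ar" &&
      !all(c("a2", "a3", "b3") %in% names(spec$ar))) {
    stop_param("ar", "needs components a2, a3, b3")
  }
  if (spec$model == "ar_cov") {
    for (ex in c("exam2", "exam3")) {
      cf <- spec$cov[[ex]]
      if (is.null(cf) || !all(c("intercept", "gender", "age", "g_age",
                                "prior") %in% names(cf))) {
        stop_param("cov", sprintf("%s needs intercept/gender/age/g_age/prior", ex))
      }
    }
    if (!spec$cov$age_transform %in% c("ln", "sqrt", "identity")) {
      stop_param("cov$age_transform", "must be ln, sqrt or identity")
    }
  }
  if (spec$model == "nmar") {
    for (f in c("alpha_female", "beta_female", "alpha_male", "beta_male")) {
      if (length(spec$nmar[[f]]) != 3) stop_param(f, "must have 3 entries (one per exam)")
    }
  }
  invisible(spec)
}

age_transform_fun <- function(tag) {
  switch(tag, ln = log, sqrt = sqrt, identity = identity,
         stop_param("age_transform", "must be ln, sqrt or identity"))
}

as_mask <- function(m, cohort) {
  m <- matrix(as.integer(m), nrow = nrow(cohort), ncol = 3,
              dimnames = list(NULL, c("m1", "m2", "m3")))
  structure(m, class = c("missingness_mask", class(m)))
}

# Per-exam missingness probabilities for one subject set, given the mask
# columns already generated (needed by the autoregressive terms).
# `prev` is the exam-(j-1) mask column (ignored where no AR term exists).
mech_prob <- function(spec, exam, cohort, prev = NULL) {
  eps <- spec$epsilon
  off <- spec$offsets[exam]
  n <- nrow(cohort)
  switch(spec$model,
    # design rates are exact probabilities, clamped only into [0, 1]
    mcar = pmin(pmax(rep(spec$rates[exam] + off, n), 0), 1),
    ar = {
      p <- switch(exam,
                  rep(spec$rates[1], n),
                  rep(spec$ar$a2, n),
                  spec$ar$a3 + spec$ar$b3 * prev)
      clamp_prob(p + off, eps)
    },
    ar_cov = {
      if (exam == 1) return(clamp_prob(rep(spec$rates[1] + off, n), eps))
      cf <- spec$cov[[paste0("exam", exam)]]
      g <- age_transform_fun(spec$cov$age_transform)
      p <- cf[["intercept"]] + cf[["gender"]] * cohort$gender +
        cf[["age"]] * cohort$age + cf[["g_age"]] * g(cohort$age) +
        cf[["prior"]] * (if (is.null(prev)) 0 else prev)
      clamp_prob(p + off, eps)
    },
    nmar = {
      a <- ifelse(cohort$gender == 1, spec$nmar$alpha_male[exam],
                  spec$nmar$alpha_female[exam])
      b <- ifelse(cohort$gender == 1, spec$nmar$beta_male[exam],
                  spec$nmar$beta_female[exam])
      y <- scr_matrix(cohort)[, exam]
      expit(a + off + b * y)
    })
}

draw_mask <- function(cohort, spec) {
  n <- nrow(cohort)
  set.seed(spec$seed)
  m <- matrix(0L, n, 3)
  for (exam in 1:3) {
    prev <- if (exam > 1) m[, exam - 1] else NULL
    p <- mech_prob(spec, exam, cohort, prev)
    m[, exam] <- stats::rbinom(n, 1, p)
  }
  as_mask(m, cohort)
}

#' Apply a missingness mechanism to a complete cohort
#'
#' Each function draws an n-by-3 binary mask (1 = Scr missing at that exam)
#' from one mechanism; [apply_mechanism()] dispatches on `spec$model`.
#' Columns are generated in exam order so autoregressive terms condition on
#' the already-drawn previous column. The draw is deterministic given
#' `spec$seed`.
#'
#' @param cohort a complete cohort data frame.
#' @param spec a [mechanism_spec()].
#' @return An integer matrix of class `"missingness_mask"` with columns
#'   `m1`, `m2`, `m3`.
#' @export
apply_mechanism <- function(cohort, spec) {
  check_cohort(cohort)
  validate_mechanism_spec(spec)
  if (spec$model == "ar_cov" &&
      (any(is.na(cohort$gender)) || any(is.na(cohort$age)))) {
    stop("covariate-augmented mechanism requires complete gender and age",
         call. = FALSE)
  }
  draw_mask(cohort, spec)
}

#' @rdname apply_mechanism
#' @export
apply_mcar <- function(cohort, spec) {
  stopifnot(spec$model == "mcar")
  apply_mechanism(cohort, spec)
}

#' @rdname apply_mechanism
#' @export
apply_autoregressive <- function(cohort, spec) {
  stopifnot(spec$model == "ar")
  top <- spec$ar$a3 + spec$ar$b3 + spec$offsets[3]
  if (top > 1 + spec$epsilon || top < -spec$epsilon) {
    warning("autoregressive Exam-3 predictor strays outside [0, 1]; clamped")
  }
  apply_mechanism(cohort, spec)
}

#' @rdname apply_mechanism
#' @export
apply_ar_covariates <- function(cohort, spec) {
  stopifnot(spec$model == "ar_cov")
  apply_mechanism(cohort, spec)
}

#' @rdname apply_mechanism
#' @export
apply_nmar <- function(cohort, spec) {
  stopifnot(spec$model == "nmar")
  apply_mechanism(cohort, spec)
}

# expected marginal missingness rate per exam, integrating over the
# distribution of the previous exam's mask column (exact, no simulation)
expected_rates <- function(cohort, spec) {
  p_prev <- NULL
  out <- numeric(3)
  for (exam in 1:3) {
    if (exam == 1 || spec$model %in% c("mcar", "nmar")) {
      p <- mech_prob(spec, exam, cohort, prev = rep(0, nrow(cohort)))
    } else {
      # mix over M_{exam-1} = 0/1 with subject-specific weights
      p0 <- mech_prob(spec, exam, cohort, prev = rep(0, nrow(cohort)))
      p1 <- mech_prob(spec, exam, cohort, prev = rep(1, nrow(cohort)))
      p <- (1 - p_prev) * p0 + p_prev * p1
    }
    out[exam] <- mean(p)
    p_prev <- p
  }
  out
}

#' Calibrate per-exam offsets to hit target marginal missingness rates
#'
#' The printed mechanism coefficients need not produce the design marginal
#' rates on a given cohort (the covariate-augmented linear-probability
#' predictors in particular can saturate the clamp). This solves, exam by
#' exam in order 1 to 3, for an additive offset (probability scale for the
#' MAR mechanisms, logit scale for the selection mechanism) such that the
#' *expected* marginal rate — computed exactly from per-subject
#' probabilities, integrating over the previous exam's mask distribution —
#' equals `spec$rates` within `tol`.
#'
#' @param cohort cohort the mechanism will be applied to.
#' @param spec a [mechanism_spec()]; `spec$offsets` are used as the
#'   starting point.
#' @param tol tolerance on the marginal rate (default 0.005).
#' @param n_reps if positive, additionally verifies the calibrated spec by
#'   drawing `n_reps` masks and checking the realized mean rates.
#' @return The calibrated length-3 offset vector. For `"mcar"` the offsets
#'   are exactly 0 (the mechanism is already parameterized by its rates).
#' @export
calibrate_offsets <- function(cohort, spec, tol = 0.005, n_reps = 0) {
  check_cohort(cohort)
  validate_mechanism_spec(spec)
  if (spec$model == "mcar") return(c(0, 0, 0))
  wide <- 20
  for (exam in 1:3) {
    f <- function(off) {
      spec$offsets[exam] <- off
      expected_rates(cohort, spec)[exam] - spec$rates[exam]
    }
    sol <- tryCatch(
      stats::uniroot(f, lower = -wide, upper = wide, tol = min(tol, 1e-4) / 10),
      error = function(e) stop("calibration failed at exam ", exam,
                               ": target rate not bracketed", call. = FALSE))
    spec$offsets[exam] <- sol$root
  }
  if (n_reps > 0) {
    got <- rowMeans(vapply(seq_len(n_reps), function(r) {
      spec$seed <- derive_seed(spec$seed, r)
      colMeans(draw_mask(cohort, spec))
    }, numeric(3)))
    if (any(abs(got - spec$rates) > max(tol, 4 * sqrt(0.25 / (nrow(cohort) * n_reps))))) {
      warning("realized rates deviate from targets beyond tolerance")
    }
  }
  spec$offsets
}

#' Write / read a missingness mask as CSV
#'
#' @param mask a `missingness_mask`.
#' @param cohort the cohort the mask belongs to (for subject ids).
#' @param path file path.
#' @export
write_mask <- function(mask, cohort, path) {
  utils::write.csv(data.frame(subject_id = cohort$subject_id,
                              m1 = mask[, 1], m2 = mask[, 2], m3 = mask[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  d <- utils::read.csv(path)
  structure(as.matrix(d[, c("m1", "m2", "m3")]),
            class = c("missingness_mask", "matrix", "array"))
}
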