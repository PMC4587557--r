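new_imputed_sets <- function(method, sets, cohort, mask, m = length(sets),
                             retained = NULL, unresolved = integer(0),
                             provenance = list()) {
  structure(list(method = method, sets = sets, m = m, retained = retained,
                 unresolved = unresolved, mask = mask,
                 provenance = provenance),
            class = "imputed_sets")
}

#' @export
print.imputed_sets <- function(x, ...) {
  cat("imputed sets: method =", x$method, ", m =", x$m, "\n")
  cat(" rows:", nrow(x$sets[[1]]),
      if (length(x$unresolved)) paste0("(", length(x$unresolved), " unresolved rows dropped)"),
      "\n")
  invisible(x)
}

#' Listwise deletion
#'
#' Drops every subject with any missing Scr value. The result carries the
#' reduced cohort and the retained-row index set, so downstream fits use
#' the reduced sample size.
#'
#' @param cohort complete cohort data frame.
#' @param mask n-by-3 binary missingness matrix.
#' @return An `"imputed_sets"` object with one set (the retained rows) and
#'   `retained` indices.
#' @export
listwise_delete <- function(cohort, mask) {
  check_cohort(cohort)
  keep <- which(rowSums(mask) == 0)
  if (length(keep) == 0) {
    stop("listwise deletion retained zero rows", call. = FALSE)
  }
  new_imputed_sets("LD", list(cohort[keep, , drop = FALSE]), cohort, mask,
                   retained = keep,
                   provenance = list(n_retained = length(keep)))
}

#' Exam-mean substitution
#'
#' Replaces each missing Scr value with the observed-case mean of its own
#' exam column.
#'
#' @inheritParams listwise_delete
#' @return An `"imputed_sets"` object with one completed set.
#' @export
mean_impute <- function(cohort, mask) {
  check_cohort(cohort)
  scr <- scr_matrix(cohort)
  out <- cohort
  for (j in 1:3) {
    obs <- mask[, j] == 0
    if (!any(obs)) stop("exam ", j, " has no observed values", call. = FALSE)
    out[[paste0("scr", j)]][!obs] <- mean(scr[obs, j])
  }
  new_imputed_sets("Mean", list(out), cohort, mask)
}

#' Adjacent-value imputation
#'
#' Fills a missing serial value with the nearest observed neighbour exam's
#' value. For Exam 2 with both neighbours observed, the *previous* exam is
#' carried forward (the working assumption being that kidney function does
#' not recover after an event). Rows with all three values missing cannot
#' be resolved; they are flagged and excluded from the completed set.
#'
#' @inheritParams listwise_delete
#' @return An `"imputed_sets"` object with one completed set and
#'   `unresolved` row indices.
#' @export
adjacent_value_impute <- function(cohort, mask) {
  check_cohort(cohort)
  scr <- scr_matrix(cohort)
  filled <- scr
  filled[mask == 1] <- NA_real_
  unresolved <- which(rowSums(mask) == 3)
  # resolve exams in passes over the original observed values only
  take <- function(j, from) {
    idx <- is.na(filled[, j]) & mask[, from] == 0
    filled[idx, j] <<- scr[idx, from]
  }
  take(2, 1); take(2, 3)        # previous wins for exam 2
  take(1, 2); take(1, 3)
  take(3, 2); take(3, 1)
  out <- cohort
  out[, c("scr1", "scr2", "scr3")] <- filled
  if (length(unresolved)) out <- out[-unresolved, , drop = FALSE]
  new_imputed_sets("AV", list(out), cohort, mask, unresolved = unresolved)
}

# one chained-equations pass: regress each exam's log-Scr on demographics
# and the other two exams' current completed values, draw the regression
# parameters from their large-sample posterior, and redraw the missing
# cells; `restrict` optionally truncates the draws at a percentile of the
# model-predicted values (the pattern-mixture restriction)
mice_chain <- function(cohort, mask, n_iter, restrict = NULL) {
  lscr <- log(scr_matrix(cohort))
  demo <- cbind(age = cohort$age, gender = cohort$gender,
                diabetes = cohort$diabetes)
  comp <- lscr
  for (j in 1:3) {                               # starting fill: column means
    mis <- mask[, j] == 1
    comp[mis, j] <- mean(lscr[!mis, j])
  }
  for (iter in seq_len(n_iter)) {
    for (j in 1:3) {
      mis <- mask[, j] == 1
      if (!any(mis)) next
      X <- cbind(1, demo, comp[, -j, drop = FALSE])
      qrX <- qr(X)
      if (qrX$rank < ncol(X)) {
        bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
        stop("collinear predictors in imputation model for exam ", j,
             ": ", paste(bad, collapse = ", "), call. = FALSE)
      }
      yobs <- lscr[!mis, j]
      Xobs <- X[!mis, , drop = FALSE]
      bhat <- qr.coef(qr(Xobs), yobs)
      res <- yobs - drop(Xobs %*% bhat)
      df <- length(yobs) - ncol(X)
      sigma2 <- sum(res^2) / stats::rchisq(1, df)      # posterior draw
      XtXi <- chol2inv(chol(crossprod(Xobs)))
      bstar <- bhat + drop(t(chol(sigma2 * XtXi)) %*% stats::rnorm(ncol(X)))
      mu <- drop(X[mis, , drop = FALSE] %*% bstar)
      sd <- sqrt(sigma2)
      if (is.null(restrict)) {
        comp[mis, j] <- mu + stats::rnorm(sum(mis), 0, sd)
      } else {
        # threshold: percentile of the model-predicted Scr for this exam's
        # missing cells; draws by inverse-CDF truncated normal (no rejection)
        bound <- log(stats::quantile(exp(mu), restrict$p / 100, names = FALSE))
        z <- (bound - mu) / sd
        u <- stats::runif(sum(mis))
        if (restrict$direction == "upper_bound") {
          u <- pmax(u * stats::pnorm(z), 1e-12)
        } else {
          lo <- stats::pnorm(z)
          u <- pmin(lo + u * (1 - lo), 1 - 1e-12)
        }
        comp[mis, j] <- mu + sd * stats::qnorm(u)
      }
    }
  }
  out <- cohort
  filled <- scr_matrix(cohort)
  filled[mask == 1] <- exp(comp[mask == 1])   # observed cells stay untouched
  out[, c("scr1", "scr2", "scr3")] <- filled
  out
}

#' Multiple imputation by chained equations
#'
#' Proper multiple imputation: `m` independent chains, each running
#' `n_iter` cycles in which every exam's log-Scr is regressed on age,
#' gender, diabetes and the other two exams' current completed values;
#' regression parameters are drawn from their large-sample posterior and
#' residual noise is added, so imputations propagate parameter uncertainty.
#'
#' @inheritParams listwise_delete
#' @param m number of imputed sets (>= 2).
#' @param n_iter chained-equation cycles per set.
#' @param seed integer seed.
#' @return An `"imputed_sets"` object with `m` completed sets.
#' @export
multiple_impute <- function(cohort, mask, m = 5, n_iter = 10, seed = 1L) {
  check_cohort(cohort)
  if (m < 2) stop("multiple imputation needs m >= 2", call. = FALSE)
  sets <- lapply(seq_len(m), function(i) {
    set.seed(derive_seed(seed, i))
    mice_chain(cohort, mask, n_iter)
  })
  new_imputed_sets("MI", sets, cohort, mask,
                   provenance = list(seed = seed, n_iter = n_iter))
}

#' Pattern-mixture restricted multiple imputation
#'
#' Runs the [multiple_impute()] chains but restricts every imputed draw by
#' a percentile threshold of the model-predicted Scr values for that
#' exam's missing cells: under `"upper_bound"` draws come from the
#' conditional distribution truncated *above* at the threshold, under
#' `"lower_bound"` truncated *below*. The restriction encodes the
#' analyst's assumption about how subjects with missing values differ from
#' those observed; the threshold percentile (10, 25 or 50) indexes the
#' strength of that assumption.
#'
#' @inheritParams multiple_impute
#' @param p threshold percentile in (0, 100); conventionally 10, 25 or 50.
#' @param direction `"upper_bound"` (draws capped above, imputations pushed
#'   down) or `"lower_bound"` (draws floored below, imputations pushed up).
#' @return An `"imputed_sets"` object with `m` completed sets; the method
#'   tag records the percentile.
#' @export
pattern_mixture_impute <- function(cohort, mask, p = 50,
                                   direction = c("upper_bound", "lower_bound"),
                                   m = 5, n_iter = 10, seed = 1L) {
  check_cohort(cohort)
  direction <- match.arg(direction)
  if (p <= 0 || p >= 100) stop_param("p", "must lie in (0, 100)")
  if (m < 2) stop("pattern-mixture imputation needs m >= 2", call. = FALSE)
  for (j in 1:3) {
    if (!any(mask[, j] == 1)) {
      message("exam ", j, " has no missing cells; restriction not applicable there")
    }
  }
  restrict <- list(p = p, direction = direction)
  sets <- lapply(seq_len(m), function(i) {
    set.seed(derive_seed(seed, i))
    mice_chain(cohort, mask, n_iter, restrict)
  })
  new_imputed_sets(sprintf("PM%d", round(p)), sets, cohort, mask,
                   provenance = list(seed = seed, n_iter = n_iter,
                                     p = p, direction = direction))
}

#' Pool estimates across imputed sets (Rubin's rules)
#'
#' Combines per-imputation point estimates and variances: pooled mean
#' `Qbar`, total variance `T = W + (1 + 1/m) B` with `W` the mean
#' within-imputation variance and `B` the between-imputation variance, and
#' the Barnard-Rubin small-sample degrees of freedom (reducing to the
#' classical large-sample df when `df_com` is infinite).
#'
#' @param estimates length-m vector of point estimates.
#' @param variances length-m vector of their squared standard errors.
#' @param df_com complete-data degrees of freedom (default `Inf`).
#' @return A list: `estimate`, `se`, `df`, `W`, `B`, `T`, `m`.
#' @export
rubin_pool <- function(estimates, variances, df_com = Inf) {
  m <- length(estimates)
  if (m < 2) stop("pooling needs m >= 2 estimates", call. = FALSE)
  if (length(variances) != m) stop("estimates and variances differ in length",
                                   call. = FALSE)
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tv <- W + (1 + 1 / m) * B
  lambda <- (1 + 1 / m) * B / Tv
  if (lambda <= 0) {
    df <- if (is.finite(df_com)) df_com else Inf
  } else {
    df_old <- (m - 1) / lambda^2
    df <- if (is.finite(df_com)) {
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
      1 / (1 / df_old + 1 / df_obs)
    } else df_old
  }
  list(estimate = qbar, se = sqrt(Tv), df = df, W = W, B = B, T = Tv, m = m)
}

#' Apply one imputation method by name
#'
#' @param method one of `"LD"`, `"Mean"`, `"AV"`, `"MI"`, `"PM10"`,
#'   `"PM25"`, `"PM50"`.
#' @inheritParams multiple_impute
#' @param direction pattern-mixture restriction direction.
#' @return An `"imputed_sets"` object.
#' @export
impute_method <- function(method, cohort, mask, m = 5, n_iter = 10,
                          direction = "lower_bound", seed = 1L) {
  switch(method,
         LD = listwise_delete(cohort, mask),
         Mean = mean_impute(cohort, mask),
         AV = adjacent_value_impute(cohort, mask),
         MI = multiple_impute(cohort, mask, m, n_iter, seed),
         PM10 = pattern_mixture_impute(cohort, mask, 10, direction, m, n_iter, seed),
         PM25 = pattern_mixture_impute(cohort, mask, 25, direction, m, n_iter, seed),
         PM50 = pattern_mixture_impute(cohort, mask, 50, direction, m, n_iter, seed),
         stop("unknown imputation method: ", method, call. = FALSE))
}

#' Write completed imputation sets to CSV
#'
#' One CSV per completed set plus a JSON provenance record.
#'
#' @param sets an `"imputed_sets"` object.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @export
write_imputed_sets <- function(sets, dir, prefix = sets$method) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(sets$sets)) {
    write_cohort(sets$sets[[i]],
                 file.path(dir, sprintf("%s_set%02d.csv", prefix, i)))
  }
  jsonlite::write_json(
    c(list(method = sets$method, m = sets$m,
           unresolved = sets$unresolved,
           retained = sets$retained %||% NA),
      sets$provenance),
    file.path(dir, paste0(prefix, "_provenance.json")),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
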