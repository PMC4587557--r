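as_sets <- function(x) {
  if (inherits(x, "imputed_sets")) return(x)
  check_cohort(x)
  new_imputed_sets("Complete", list(x), x, matrix(0L, nrow(x), 3))
}

#' Per-exam mean and SD of (completed) Scr
#'
#' For single-set methods the plain mean/SD of the completed column; for
#' multiply-imputed methods the mean of per-set means and the square root
#' of the mean per-set variance. Listwise deletion is summarized over its
#' retained rows only.
#'
#' @param sets an `"imputed_sets"` object or a complete cohort.
#' @return A data frame with columns `exam`, `mean`, `sd`, `n`.
#' @export
summarize_scr <- function(sets) {
  sets <- as_sets(sets)
  out <- data.frame(exam = 1:3, mean = NA_real_, sd = NA_real_, n = NA_integer_)
  for (j in 1:3) {
    col <- paste0("scr", j)
    ms <- vapply(sets$sets, function(d) mean(d[[col]]), 0)
    vs <- vapply(sets$sets, function(d) stats::var(d[[col]]), 0)
    out$mean[j] <- mean(ms)
    out$sd[j] <- sqrt(mean(vs))
    out$n[j] <- nrow(sets$sets[[1]])
  }
  out
}

new_hr_estimate <- function(log_hr, se, n_used, exam, adjust, method = NULL) {
  structure(list(hr = exp(log_hr), ci_low = exp(log_hr - 1.96 * se),
                 ci_high = exp(log_hr + 1.96 * se), log_hr = log_hr,
                 se_log_hr = se, n_used = n_used, exam = exam,
                 adjusted_for = adjust, method = method),
            class = "hr_estimate")
}

#' @export
print.hr_estimate <- function(x, ...) {
  cat(sprintf("HR per 1 mg/dL Scr (%s): %.3f (95%% CI %.3f-%.3f), n = %d\n",
              x$exam, x$hr, x$ci_low, x$ci_high, x$n_used))
  cat(" adjusted for:", paste(x$adjusted_for, collapse = ", "), "\n")
  invisible(x)
}

cox_one <- function(d, formula, ph_check = FALSE) {
  environment(formula) <- environment()   # so cox.zph can resolve `d`
  fit <- survival::coxph(formula, data = d, ties = "efron")
  if (any(!is.finite(sqrt(diag(fit$var))))) {
    stop("proportional-hazards fit failed (monotone likelihood?)",
         call. = FALSE)
  }
  if (ph_check) {
    zph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
    if (!is.null(zph)) {
      p <- zph$table["GLOBAL", "p"]
      message(sprintf("Schoenfeld global proportionality p = %.3g%s", p,
                      if (p < 0.05) " (non-proportionality indicated)" else ""))
    }
  }
  list(coef = fit$coefficients[["scr_x"]],
       se = sqrt(fit$var[1, 1]),
       n = fit$n)
}

pool_cox <- function(fits, exam, adjust) {
  if (length(fits) == 1) {
    f <- fits[[1]]
    return(new_hr_estimate(f$coef, f$se, f$n, exam, adjust))
  }
  pooled <- rubin_pool(vapply(fits, `[[`, 0, "coef"),
                       vapply(fits, `[[`, 0, "se")^2)
  new_hr_estimate(pooled$estimate, pooled$se, fits[[1]]$n, exam, adjust)
}

#' Exam-wise proportional-hazards fit
#'
#' Cox partial-likelihood fit (Efron ties) of time-to-event on one exam's
#' Scr value plus adjusters, each subject contributing full follow-up from
#' Exam 1 (the covariate is fixed at its value from the chosen exam).
#' Multiply-imputed sets are fitted per set and pooled on the log-HR scale
#' by [rubin_pool()].
#'
#' @param sets an `"imputed_sets"` object or a complete cohort.
#' @param exam which exam's Scr to use (1, 2 or 3).
#' @param adjust adjustment covariates.
#' @param landmark if `TRUE`, restart the clock at the exam: only subjects
#'   still at risk at the exam time enter, with follow-up measured from
#'   that exam. Off by default (every exam's fit uses full follow-up from
#'   Exam 1).
#' @param exam_times exam times, used only when `landmark = TRUE`.
#' @param ph_check log a global Schoenfeld-style proportionality test for
#'   each fitted set.
#' @return An `"hr_estimate"`: hazard ratio per 1 mg/dL Scr with 95% CI.
#' @export
fit_cox_fixed <- function(sets, exam, adjust = c("age", "gender", "diabetes"),
                          landmark = FALSE, exam_times = c(0, 4, 9),
                          ph_check = FALSE) {
  sets <- as_sets(sets)
  stopifnot(exam %in% 1:3)
  rhs <- paste(c("scr_x", adjust), collapse = " + ")
  formula <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fits <- lapply(sets$sets, function(d) {
    if (landmark) {
      d <- d[d$time > exam_times[exam], , drop = FALSE]
      d$time <- d$time - exam_times[exam]
    }
    if (sum(d$event) < 10) {
      stop("fewer than 10 events in analysis set", call. = FALSE)
    }
    d$scr_x <- d[[paste0("scr", exam)]]
    cox_one(d, formula, ph_check)
  })
  pool_cox(fits, as.character(exam), adjust)
}

#' Time-dependent proportional-hazards fit
#'
#' Cox fit on the counting-process expansion ([long_format()]) with the
#' Scr covariate updated at each exam. Pooling across imputed sets as in
#' [fit_cox_fixed()].
#'
#' @inheritParams fit_cox_fixed
#' @param exam_times exam times passed to [long_format()].
#' @return An `"hr_estimate"` tagged `"time-dependent"`.
#' @export
fit_cox_td <- function(sets, exam_times = c(0, 4, 9),
                       adjust = c("age", "gender", "diabetes"),
                       ph_check = FALSE) {
  sets <- as_sets(sets)
  rhs <- paste(c("scr_x", adjust), collapse = " + ")
  formula <- stats::as.formula(paste("survival::Surv(start, stop, event) ~", rhs))
  fits <- lapply(sets$sets, function(d) {
    if (sum(d$event) < 10) {
      stop("fewer than 10 events in analysis set", call. = FALSE)
    }
    ld <- long_format(d, exam_times)
    ld$scr_x <- ld$scr
    f <- cox_one(ld, formula, ph_check)
    f$n <- nrow(d)
    f
  })
  pool_cox(fits, "time-dependent", adjust)
}

#' Rank imputation methods by discrepancy from the complete-data fit
#'
#' Within each missingness model, methods are ordered by the mean absolute
#' difference between their log hazard ratios and the complete-data log
#' hazard ratios across all fitted cells (exam-wise and time-dependent);
#' ties are broken by the mean absolute Scr-mean discrepancy. The
#' complete-data row always ranks first with discrepancy 0.
#'
#' @param report a comparison report data frame as produced by
#'   [run_study()] (columns `model`, `method`, `exam`, `log_hr`, `mean`,
#'   `discrepancy_loghr`, `discrepancy_mean`).
#' @return A named list (one element per model) of data frames with
#'   columns `method`, `mean_abs_dloghr`, `mean_abs_dmean`, ordered best
#'   first.
#' @export
rank_methods <- function(report) {
  need <- c("model", "method", "exam", "discrepancy_loghr", "discrepancy_mean")
  if (!all(need %in% names(report))) {
    stop("report lacks column(s): ",
         paste(setdiff(need, names(report)), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(report$discrepancy_loghr))) {
    stop("incomplete report: missing discrepancy cells", call. = FALSE)
  }
  out <- list()
  for (mod in unique(report$model)) {
    r <- report[report$model == mod, ]
    agg <- stats::aggregate(
      cbind(mean_abs_dloghr = discrepancy_loghr,
            mean_abs_dmean = discrepancy_mean) ~ method,
      data = r, FUN = mean)
    agg <- agg[order(agg$mean_abs_dloghr, agg$mean_abs_dmean), ]
    rownames(agg) <- NULL
    out[[mod]] <- agg
  }
  out
}

#' Evaluate one analysis set against the complete-data reference
#'
#' Computes the Table-style summary for one method under one mechanism:
#' per-exam means/SDs, exam-wise HRs and the time-dependent HR, plus
#' discrepancies from a reference (complete-data) evaluation when given.
#'
#' @param sets an `"imputed_sets"` object or complete cohort.
#' @param exam_times exam times for the time-dependent fit.
#' @param adjust adjustment covariates.
#' @param reference optional result of a previous `evaluate_sets()` call on
#'   the complete data, used to fill the discrepancy columns.
#' @return A data frame with one row per cell (`exam` in `"1","2","3","td"`).
#' @export
evaluate_sets <- function(sets, exam_times = c(0, 4, 9),
                          adjust = c("age", "gender", "diabetes"),
                          reference = NULL) {
  sets <- as_sets(sets)
  summ <- summarize_scr(sets)
  cells <- lapply(1:3, function(j) fit_cox_fixed(sets, j, adjust))
  cells[[4]] <- fit_cox_td(sets, exam_times, adjust)
  out <- data.frame(
    method = sets$method,
    exam = c("1", "2", "3", "td"),
    mean = c(summ$mean, NA),
    sd = c(summ$sd, NA),
    hr = vapply(cells, `[[`, 0, "hr"),
    ci_low = vapply(cells, `[[`, 0, "ci_low"),
    ci_high = vapply(cells, `[[`, 0, "ci_high"),
    log_hr = vapply(cells, `[[`, 0, "log_hr"),
    se_log_hr = vapply(cells, `[[`, 0, "se_log_hr"),
    n_used = vapply(cells, `[[`, 0L, "n_used"),
    significant = vapply(cells, function(h) h$ci_low > 1 | h$ci_high < 1, NA))
  if (!is.null(reference)) {
    out$discrepancy_loghr <- abs(out$log_hr - reference$log_hr)
    out$discrepancy_mean <- abs(out$mean - reference$mean)
    out$discrepancy_mean[is.na(out$discrepancy_mean)] <- 0
  }
  out
}
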