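#' @keywords internal
#' @useDynLib scrmiss, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# inverse logit, kept explicit so selection-model code reads like the formulas
expit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

# clamp a probability vector into [eps, 1 - eps]
clamp_prob <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

#' Derive a child seed from a master seed
#'
#' Counter-based derivation so that stream `k` is unchanged when more streams
#' are added later. The result is always a valid 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param counter non-negative integer stream index.
#' @return An integer seed.
#' @export
derive_seed <- function(master, counter) {
  stopifnot(is.numeric(master), length(master) == 1, is.numeric(counter))
  # 32-bit LCG-style mix, kept in double arithmetic below 2^31
  x <- (abs(master) %% 2147483647) + 1
  x <- (x * 48271 + 12345 * (counter + 1)) %% 2147483647
  as.integer(x)
}

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

# shared column checker for cohort-shaped data frames
check_cohort <- function(cohort, need = c("subject_id", "gender", "age",
                                          "diabetes", "scr1", "scr2", "scr3",
                                          "event", "time")) {
  if (!is.data.frame(cohort)) {
    stop("`cohort` must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop(sprintf("cohort lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  invisible(cohort)
}

scr_matrix <- function(cohort) {
  as.matrix(cohort[, c("scr1", "scr2", "scr3")])
}
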