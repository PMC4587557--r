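#' Assemble a full study configuration
#'
#' Builds (and validates) the configuration consumed by [run_study()]:
#' one section per pipeline stage, mirroring the module parameter lists.
#' A YAML document with the same section names may be supplied; values in
#' `...` override file values, which override defaults.
#'
#' @param path optional YAML file with sections `cohort`, `missingness`,
#'   `imputation`, `evaluation`, `n_replicates`, `seed`, `output`.
#' @param ... named overrides, e.g. `n_replicates = 10`,
#'   `cohort = list(n = 500)`.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    cohort = list(),                     # overrides for generator_params()
    missingness = list(
      models = c("mcar", "ar", "ar_cov", "nmar"),
      rates = c(0.20, 0.30, 0.40),
      calibrate = TRUE),
    imputation = list(
      methods = c("LD", "Mean", "AV", "MI", "PM10", "PM25", "PM50"),
      m = 5, n_iter = 10, pm_direction = "lower_bound"),
    evaluation = list(
      exam_times = c(0, 4, 9),
      adjust = c("age", "gender", "diabetes")),
    n_replicates = 1L,
    seed = 1L,
    output = NULL,
    keep_imputations = FALSE)
  merge_into <- function(base, extra) {
    for (nm in names(extra)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(extra[[nm]])) {
        merge_into(base[[nm]], extra[[nm]])
      } else extra[[nm]]
    }
    base
  }
  if (!is.null(path)) {
    # keep short keys like `n` intact (YAML 1.1 would read them as booleans)
    handlers <- list(
      "bool#no" = function(x) if (tolower(x) %in% c("false", "off", "no")) FALSE else x,
      "bool#yes" = function(x) if (tolower(x) %in% c("true", "on", "yes")) TRUE else x)
    cfg <- merge_into(cfg, yaml::read_yaml(path, handlers = handlers))
  }
  cfg <- merge_into(cfg, list(...))
  if (cfg$n_replicates < 1) stop_param("n_replicates", "must be >= 1")
  bad <- setdiff(cfg$missingness$models, c("mcar", "ar", "ar_cov", "nmar"))
  if (length(bad)) stop_param("missingness$models",
                              paste("unknown model:", paste(bad, collapse = ", ")))
  bad <- setdiff(cfg$imputation$methods,
                 c("LD", "Mean", "AV", "MI", "PM10", "PM25", "PM50"))
  if (length(bad)) stop_param("imputation$methods",
                              paste("unknown method:", paste(bad, collapse = ", ")))
  structure(cfg, class = "run_config")
}

with_stage <- function(stage, model, method, replicate, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s | model %s | method %s | replicate %d] %s",
                 stage, model, method, replicate, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full missingness-and-imputation study
#'
#' Executes, for each replicate: generate a complete cohort; for each
#' missingness mechanism, draw a mask (with marginal rates calibrated to
#' the design rates); apply each remedial method; evaluate means/SDs,
#' exam-wise and time-dependent hazard ratios; and score every method by
#' its discrepancy from the complete-data fit. Deterministic given
#' `config$seed` (per-replicate and per-stage seeds are derived by a
#' counter scheme, so earlier replicates are unchanged when
#' `n_replicates` grows).
#'
#' @param config a [run_config()] object.
#' @return A list of class `"study_result"`: `report` (cell means across
#'   replicates, with Monte-Carlo SEs when `n_replicates > 1`),
#'   `ranking` (per-model method ordering from [rank_methods()]),
#'   `replicates` (the raw per-replicate report), and `config`.
#' @export
run_study <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  gen_args <- config$cohort
  reps <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    rep_seed <- derive_seed(config$seed, r)
    params <- do.call(generator_params,
                      utils::modifyList(gen_args, list(seed = derive_seed(rep_seed, 0))))
    cohort <- with_stage("simulate", "-", "-", r, generate_cohort(params))
    ev <- config$evaluation
    reference <- with_stage("evaluate", "complete", "Complete", r,
                            evaluate_sets(cohort, ev$exam_times, ev$adjust))
    rows <- list()
    for (mi in seq_along(config$missingness$models)) {
      model <- config$missingness$models[mi]
      spec <- mechanism_spec(model = model, rates = config$missingness$rates,
                             seed = derive_seed(rep_seed, mi))
      if (isTRUE(config$missingness$calibrate)) {
        spec$offsets <- with_stage("calibrate", model, "-", r,
                                   calibrate_offsets(cohort, spec))
      }
      mask <- with_stage("mask", model, "-", r, apply_mechanism(cohort, spec))
      complete_row <- cbind(model = model,
                            evaluate_sets(cohort, ev$exam_times, ev$adjust,
                                          reference = reference))
      rows[[length(rows) + 1]] <- complete_row
      for (me in seq_along(config$imputation$methods)) {
        method <- config$imputation$methods[me]
        sets <- with_stage("impute", model, method, r,
                           impute_method(method, cohort, mask,
                                         m = config$imputation$m,
                                         n_iter = config$imputation$n_iter,
                                         direction = config$imputation$pm_direction,
                                         seed = derive_seed(rep_seed, 100 + 10 * mi + me)))
        res <- with_stage("evaluate", model, method, r,
                          evaluate_sets(sets, ev$exam_times, ev$adjust,
                                        reference = reference))
        rows[[length(rows) + 1]] <- cbind(model = model, res)
        if (isTRUE(config$keep_imputations) && !is.null(config$output)) {
          write_imputed_sets(sets, file.path(config$output,
                                             sprintf("rep%03d_%s", r, model)))
        }
      }
    }
    rep_df <- do.call(rbind, rows)
    rep_df$replicate <- r
    reps[[r]] <- rep_df
    if (!is.null(config$output)) {
      dir.create(config$output, recursive = TRUE, showWarnings = FALSE)
      write_cohort(cohort, file.path(config$output,
                                     sprintf("rep%03d_cohort.csv", r)))
    }
  }
  raw <- do.call(rbind, reps)
  report <- aggregate_report(raw)
  result <- structure(list(report = report,
                           ranking = rank_methods(report),
                           replicates = raw, config = config),
                      class = "study_result")
  if (!is.null(config$output)) {
    dir.create(config$output, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(config$output, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(report = report, ranking = result$ranking),
                         file.path(config$output, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

# mean (and Monte-Carlo SE when replicated) of every numeric cell
aggregate_report <- function(raw) {
  key <- c("model", "method", "exam")
  nums <- setdiff(names(raw)[vapply(raw, is.numeric, NA)], "replicate")
  agg <- stats::aggregate(raw[nums], raw[key], mean)
  n_rep <- max(raw$replicate)
  if (n_rep > 1) {
    mcse <- stats::aggregate(raw[nums], raw[key],
                             function(v) stats::sd(v) / sqrt(length(v)))
    names(mcse)[-seq_along(key)] <- paste0("mcse_", nums)
    agg <- merge(agg, mcse, by = key, sort = FALSE)
  }
  ord <- order(match(agg$model, unique(raw$model)),
               match(agg$method, unique(raw$method)), agg$exam)
  agg <- agg[ord, , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' @export
print.study_result <- function(x, ...) {
  cat("missingness-and-imputation study:",
      length(unique(x$report$model)), "mechanism(s) x",
      length(unique(x$report$method)), "method(s),",
      x$config$n_replicates, "replicate(s)\n\n")
  cat("method ranking by |log HR - complete| (best first):\n")
  for (mod in names(x$ranking)) {
    cat(sprintf(" %-7s: %s\n", mod,
                paste(x$ranking[[mod]]$method, collapse = " > ")))
  }
  invisible(x)
}

#' Render a report section as a plain-text table
#'
#' @param report a report data frame from [run_study()].
#' @param what `"means"` (mean/SD per cell) or `"hr"` (HR with 95% CI).
#' @param exam which exam row(s) to show.
#' @return A character matrix (methods by models), invisibly printed.
#' @export
format_report_table <- function(report, what = c("hr", "means"), exam = "td") {
  what <- match.arg(what)
  r <- report[report$exam == exam, ]
  models <- unique(r$model); methods <- unique(r$method)
  out <- matrix("", length(methods), length(models),
                dimnames = list(methods, models))
  for (i in seq_len(nrow(r))) {
    out[r$method[i], r$model[i]] <- if (what == "hr") {
      sprintf("%.2f (%.2f-%.2f)%s", r$hr[i], r$ci_low[i], r$ci_high[i],
              if (isTRUE(r$significant[i])) "*" else "")
    } else {
      sprintf("%.2f (%.2f)", r$mean[i], r$sd[i])
    }
  }
  print(out, quote = FALSE)
  invisible(out)
}

#' Write small deterministic fixture data sets
#'
#' Fixtures used by the test suite and examples: `"tiny_cohort"` (a
#' 200-subject cohort), `"nmar_20"` (20 subjects with an informative
#' missingness mask attached) and `"glm_50k"` (50,000 rows of gender and
#' mask indicators drawn from the printed linear-probability mechanism
#' equations).
#'
#' @param kind fixture name.
#' @param seed integer seed.
#' @param dir output directory.
#' @return The written file path, invisibly.
#' @export
make_fixture <- function(kind = c("tiny_cohort", "nmar_20", "glm_50k"),
                         seed = 1L, dir = ".") {
  kind <- match.arg(kind)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, paste0(kind, ".csv"))
  if (kind == "tiny_cohort") {
    write_cohort(generate_cohort(generator_params(n = 200, seed = seed)), path)
  } else if (kind == "nmar_20") {
    coh <- generate_cohort(generator_params(n = 20, seed = seed))
    mask <- apply_nmar(coh, mechanism_spec("nmar", seed = seed))
    d <- as.data.frame(coh)
    d[, c("m1", "m2", "m3")] <- unclass(mask)
    utils::write.csv(d, path, row.names = FALSE)
  } else {
    set.seed(seed)
    n <- 50000
    gender <- stats::rbinom(n, 1, 0.359)
    m2 <- stats::rbinom(n, 1, 0.089 + 0.036 * gender)
    m3 <- stats::rbinom(n, 1, 0.082 + 0.029 * gender + 0.353 * m2)
    utils::write.csv(data.frame(gender = gender, m2 = m2, m3 = m3),
                     path, row.names = FALSE)
  }
  invisible(path)
}
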