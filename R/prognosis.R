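#' Filter a survival table to longer-term survivors
#'
#' Keeps samples whose survival time is strictly greater than `min_days`
#' (default 90): very early deaths are typically dominated by causes
#' unrelated to the tumour biology the risk model targets.
#'
#' @param survival A tibble with columns `sample_id`, `time`, `event`.
#' @param min_days Strict lower bound on survival time in days.
#'
#' @return The filtered tibble (possibly empty; a message flags that).
#' @export
filter_survival <- function(survival, min_days = 90) {
  validate_survival(survival)
  check_scalar(min_days, "min_days", min = 0)
  out <- dplyr::filter(survival, .data$time > min_days)
  if (nrow(out) == 0) {
    inform(sprintf("No samples with survival time > %g days remain.", min_days))
  }
  out
}

#' Univariate proportional-hazards screen
#'
#' Fits one Cox proportional-hazards model per feature
#' (`Surv(time, event) ~ x`, via [survival::coxph()]) over the samples
#' shared by the expression view and the survival table, and flags features
#' with `p < p_cutoff` as retained. Constant features and non-convergent
#' fits are skipped with a message. Raw p-values are used by default (the
#' conventional univariate pre-screen before a multivariate model);
#' `adjust = "BH"` switches to Benjamini-Hochberg adjusted p-values.
#'
#' @param expression An [omics_view()] (samples x features) or a tibble
#'   with a `sample_id` first column.
#' @param survival A survival tibble (`sample_id`, `time`, `event`).
#' @param p_cutoff Retention threshold on the (possibly adjusted) p-value.
#' @param min_samples Minimum sample overlap required (default 10).
#' @param adjust `"none"` (default) or `"BH"`.
#'
#' @return A tibble with one row per screened feature: `feature_id`, `hr`,
#'   `hr_low`, `hr_high` (hazard ratio and 95% CI), `p_value`, `retained`.
#' @export
univariate_screen <- function(expression, survival, p_cutoff = 0.05,
                              min_samples = 10, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.data.frame(expression)) {
    expression <- as_omics_view(expression)
  }
  validate_survival(survival)
  check_scalar(p_cutoff, "p_cutoff", min = 0)
  common <- intersect(rownames(expression), survival$sample_id)
  if (length(common) < min_samples) {
    abort(sprintf("Only %d samples shared between expression and survival (need >= %d).",
                  length(common), min_samples),
          class = "spidnmf_error_survival")
  }
  x <- unclass(expression)[common, , drop = FALSE]
  surv <- survival[match(common, survival$sample_id), ]
  y <- survival::Surv(surv$time, surv$event)
  skipped <- character(0)
  rows <- purrr::map_dfr(colnames(x), function(f) {
    v <- x[, f]
    if (sd(v) == 0) {
      skipped <<- c(skipped, f)
      return(tibble())
    }
    res <- tryCatch({
      fit <- survival::coxph(y ~ v)
      s <- summary(fit)
      tibble(feature_id = f,
             hr = unname(s$conf.int[1, "exp(coef)"]),
             hr_low = unname(s$conf.int[1, "lower .95"]),
             hr_high = unname(s$conf.int[1, "upper .95"]),
             p_value = unname(s$coefficients[1, "Pr(>|z|)"]))
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(res) || !is.finite(res$p_value)) {
      skipped <<- c(skipped, f)
      return(tibble())
    }
    res
  })
  if (length(skipped) > 0) {
    inform(sprintf("Skipped %d feature(s) (constant or non-convergent): %s%s",
                   length(skipped), paste(head(skipped, 5), collapse = ", "),
                   if (length(skipped) > 5) ", ..." else ""))
  }
  if (nrow(rows) == 0) {
    return(tibble(feature_id = character(0), hr = numeric(0),
                  hr_low = numeric(0), hr_high = numeric(0),
                  p_value = numeric(0), retained = logical(0)))
  }
  p <- if (adjust == "BH") stats::p.adjust(rows$p_value, "BH") else rows$p_value
  dplyr::mutate(rows, retained = p < p_cutoff)
}

#' Fit a multivariate proportional-hazards risk model
#'
#' Fits a multivariate Cox model over the given features (typically the
#' survivors of [univariate_screen()]), yielding one linear coefficient per
#' feature. The training-cohort median risk score is stored as the default
#' high/low cutoff.
#'
#' @inheritParams univariate_screen
#' @param features Character vector of feature ids to include.
#'
#' @return An object of class `risk_model`: list with `feature_ids`,
#'   `coefficients`, `cutoff`, and the underlying `coxph` fit.
#' @export
fit_risk_model <- function(expression, survival, features) {
  if (is.data.frame(expression)) {
    expression <- as_omics_view(expression)
  }
  validate_survival(survival)
  missing <- setdiff(features, colnames(expression))
  if (length(missing) > 0) {
    abort(sprintf("Feature(s) not in the expression view: %s.",
                  paste(missing, collapse = ", ")),
          class = "spidnmf_error_risk")
  }
  common <- intersect(rownames(expression), survival$sample_id)
  x <- unclass(expression)[common, features, drop = FALSE]
  surv <- survival[match(common, survival$sample_id), ]
  df <- as.data.frame(x)
  df$.time <- surv$time
  df$.event <- surv$event
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", features), collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = df)
  coefs <- setNames(unname(stats::coef(fit)), features)
  model <- new_risk_model(features, coefs, cutoff = NA_real_, fit = fit)
  model$cutoff <- median(risk_score(model, x))
  model
}

new_risk_model <- function(feature_ids, coefficients, cutoff, fit = NULL) {
  stopifnot(length(feature_ids) == length(coefficients),
            length(feature_ids) >= 1)
  structure(
    list(feature_ids = feature_ids,
         coefficients = setNames(as.numeric(coefficients), feature_ids),
         cutoff = cutoff, fit = fit),
    class = "risk_model"
  )
}

#' Construct a risk model from known coefficients
#'
#' Builds a `risk_model` directly from published per-feature Cox
#' coefficients, e.g. to apply a training-cohort model to a validation
#' cohort.
#'
#' @param coefficients Named numeric vector (names = feature ids).
#' @param cutoff Risk-score cutoff for the high/low split (e.g. the
#'   training-cohort median).
#'
#' @return A `risk_model`.
#' @export
#'
#' @examples
#' m <- risk_model(c(IL12RB2 = -0.60498, CNIH2 = -0.43137), cutoff = 0)
#' risk_score(m, c(IL12RB2 = 1, CNIH2 = 1))
risk_model <- function(coefficients, cutoff = NA_real_) {
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
    abort("`coefficients` must be a fully named numeric vector.",
          class = "spidnmf_error_risk")
  }
  new_risk_model(names(coefficients), coefficients, cutoff)
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model: %d feature(s), cutoff %s>\n",
              length(x$feature_ids), format(x$cutoff)))
  print(x$coefficients)
  invisible(x)
}

#' Linear risk score
#'
#' `risk = sum_n coef_n * x_n` over the model's features. Accepts a single
#' named expression vector, a samples-x-features matrix, or an
#' [omics_view()]; every model feature must be present (a missing one is an
#' error naming it).
#'
#' @param model A `risk_model`.
#' @param expression Named numeric vector, matrix with feature columns, or
#'   [omics_view()].
#'
#' @return A numeric vector of scores (named by sample for matrix input).
#' @export
risk_score <- function(model, expression) {
  stopifnot(inherits(model, "risk_model"))
  if (inherits(expression, "omics_view")) {
    expression <- unclass(expression)
  }
  if (is.matrix(expression)) {
    missing <- setdiff(model$feature_ids, colnames(expression))
    if (length(missing) > 0) {
      abort(sprintf("Expression is missing model feature(s): %s.",
                    paste(missing, collapse = ", ")),
            class = "spidnmf_error_risk")
    }
    return(drop(expression[, model$feature_ids, drop = FALSE] %*%
                  model$coefficients))
  }
  missing <- setdiff(model$feature_ids, names(expression))
  if (length(missing) > 0) {
    abort(sprintf("Expression is missing model feature(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "spidnmf_error_risk")
  }
  sum(model$coefficients * expression[model$feature_ids])
}

#' Split samples into high- and low-risk groups
#'
#' Scores strictly above the cutoff are `"high"`, scores at or below it
#' are `"low"` (so with distinct scores and the median as cutoff the two
#' groups differ in size by at most one, and all-tied scores fall to
#' `"low"`).
#'
#' @param scores Numeric risk scores.
#' @param cutoff Finite cutoff; defaults to `median(scores)`.
#'
#' @return A factor with levels `low`, `high`, named like `scores`.
#' @export
assign_risk_groups <- function(scores, cutoff = median(scores)) {
  check_scalar(cutoff, "cutoff")
  factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
}
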