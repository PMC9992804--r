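#' Tidy a fitted joint factorization
#'
#' Returns the factors in long form: either the per-view coefficient
#' loadings (`matrix = "H"`, default) or the per-sample basis scores
#' (`matrix = "W"`).
#'
#' @param x A `jnmf_fit`.
#' @param matrix `"H"` for feature loadings, `"W"` for sample scores.
#' @param ... Unused.
#'
#' @return For `"H"`: a tibble `view`, `factor`, `feature_id`, `loading`.
#'   For `"W"`: a tibble `sample_id`, `factor`, `score`.
#' @method tidy jnmf_fit
#' @export
tidy.jnmf_fit <- function(x, matrix = c("H", "W"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "W") {
    return(
      as_tibble(x$W, rownames = "sample_id") |>
        tidyr::pivot_longer(-"sample_id", names_to = "factor",
                            values_to = "score") |>
        dplyr::mutate(factor = as.integer(sub("^factor", "", .data$factor)))
    )
  }
  purrr::map_dfr(names(x$H), function(vn) {
    as_tibble(x$H[[vn]], rownames = "factor") |>
      tidyr::pivot_longer(-"factor", names_to = "feature_id",
                          values_to = "loading") |>
      dplyr::mutate(view = vn,
                    factor = as.integer(sub("^factor", "", .data$factor))) |>
      dplyr::select("view", "factor", "feature_id", "loading")
  })
}

#' One-row summary of a fitted joint factorization
#'
#' @param x A `jnmf_fit`.
#' @param ... Unused.
#'
#' @return A tibble with `method`, `k`, `iterations`, `converged`,
#'   `stop_reason`, `relative_error`, `objective`.
#' @method glance jnmf_fit
#' @export
glance.jnmf_fit <- function(x, ...) {
  r <- x$report
  last <- r$iterations
  tibble(
    method = x$method,
    k = x$hp$k,
    iterations = last,
    converged = r$converged,
    stop_reason = r$stop_reason,
    relative_error = if (last > 0) r$relative_error_trajectory[last] else NA_real_,
    objective = if (last > 0) r$objective_trajectory[last] else NA_real_
  )
}

#' Plot the optimisation trajectory of a fit
#'
#' Relative reconstruction error and penalized objective per iteration.
#'
#' @param object A `jnmf_fit`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot jnmf_fit
#' @export
autoplot.jnmf_fit <- function(object, ...) {
  r <- object$report
  df <- tibble(
    iteration = rep(seq_len(r$iterations), 2),
    value = c(r$relative_error_trajectory, r$objective_trajectory),
    quantity = rep(c("relative error", "objective"), each = r$iterations)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y") +
    ggplot2::labs(
      title = sprintf("%s fit (k = %d, %s)", object$method, object$hp$k,
                      r$stop_reason),
      x = "iteration", y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a hyperparameter sweep
#'
#' Relative error against combination index, with the selected best
#' combination highlighted.
#'
#' @param object A `grid_search` result.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot grid_search
#' @export
autoplot.grid_search <- function(object, ...) {
  df <- dplyr::filter(object$results, !is.na(.data$relative_error))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$combination_index,
                                   y = .data$relative_error)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::geom_point(data = object$best, colour = "red", size = 2) +
    ggplot2::labs(x = "parameter combination", y = "relative error",
                  title = "Grid search over penalty weights") +
    ggplot2::theme_minimal()
}

#' Plot module coherence scores
#'
#' Per-view and mean absolute Pearson correlation between original and
#' reconstructed member submatrices, per module.
#'
#' @param scores A `module_scores` object from [score_modules()].
#'
#' @return A ggplot object.
#' @export
plot_module_scores <- function(scores) {
  stopifnot(inherits(scores, "module_scores"))
  df <- dplyr::bind_rows(
    dplyr::transmute(scores$per_view, factor = .data$factor,
                     panel = .data$view, value = .data$correlation),
    dplyr::transmute(scores$summary, factor = .data$factor,
                     panel = "mean", value = .data$mean_correlation)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = base::factor(.data$factor),
                                   y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel)) +
    ggplot2::labs(x = "module (factor)",
                  y = "|Pearson r| original vs reconstructed") +
    ggplot2::theme_minimal()
}

#' @method tidy risk_model
#' @export
tidy.risk_model <- function(x, ...) {
  tibble(feature_id = x$feature_ids,
         coefficient = unname(x$coefficients))
}

#' @method glance risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble(n_features = length(x$feature_ids), cutoff = x$cutoff)
}
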