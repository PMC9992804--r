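#' Enumerate a hyperparameter grid
#'
#' Builds the full Cartesian product over candidate values for the five
#' swept weights, in deterministic odometer order: parameters cycle in the
#' fixed order `lambda1, lambda2, beta, gamma1, gamma2` with the last
#' parameter fastest. With the canonical candidate set
#' `c(0.001, 0.01, 0.1, 1)` per parameter this yields `4^5 = 1024`
#' combinations. The rank `k` is not swept: with roughly 70 samples it is
#' fixed by the n/10 heuristic (k = 7 at n = 69) and exposed as an ordinary
#' argument instead.
#'
#' @param values Named list of candidate vectors; missing names fall back
#'   to `default_values`. Only `lambda1`, `lambda2`, `beta`, `gamma1`,
#'   `gamma2` are recognised.
#' @param default_values Candidates used for any parameter not in `values`.
#'
#' @return A tibble with columns `combination_index`, `lambda1`, `lambda2`,
#'   `beta`, `gamma1`, `gamma2`.
#' @export
#'
#' @examples
#' nrow(enumerate_grid()) # 1024
enumerate_grid <- function(values = list(),
                           default_values = c(0.001, 0.01, 0.1, 1)) {
  par_names <- c("lambda1", "lambda2", "beta", "gamma1", "gamma2")
  extra <- setdiff(names(values), par_names)
  if (length(extra) > 0) {
    abort(sprintf("Unknown grid parameter(s): %s.", paste(extra, collapse = ", ")),
          class = "spidnmf_error_grid")
  }
  vals <- lapply(par_names, function(p) {
    v <- values[[p]] %||% default_values
    if (length(v) == 0) {
      abort(sprintf("Empty candidate list for '%s'.", p),
            class = "spidnmf_error_grid")
    }
    if (any(v < 0)) {
      abort(sprintf("Negative candidate value for '%s'.", p),
            class = "spidnmf_error_grid")
    }
    v
  })
  names(vals) <- par_names
  # expand.grid varies the first column fastest; reverse so the LAST
  # parameter (gamma2) is the fast axis of the odometer
  g <- expand.grid(rev(vals), KEEP.OUT.ATTRS = FALSE)
  g <- g[, par_names]
  dplyr::bind_cols(
    tibble(combination_index = seq_len(nrow(g))),
    as_tibble(g)
  )
}

#' Grid search over penalty weights by reconstruction error
#'
#' Fits one model per grid row with per-fit early stopping (iteration stops
#' once the relative error has failed to improve by `tol` for `patience`
#' consecutive iterations) and selects the combination with the smallest
#' relative reconstruction error; ties break to the lowest
#' `combination_index`. Individual fit failures are recorded per
#' combination and do not abort the sweep.
#'
#' @inheritParams fit_jnmf
#' @param grid A tibble from [enumerate_grid()] (or any tibble with the
#'   five weight columns; an index column is added if absent).
#' @param patience Early-stopping patience in iterations (default 5).
#'
#' @return An object of class `grid_search`: list with `best` (one-row
#'   tibble) and `results` (tibble over all combinations with
#'   `relative_error`, `iterations`, `error` message if the fit failed).
#' @export
grid_search <- function(dataset, hp,
                        grid = enumerate_grid(),
                        method = "spid",
                        graph = NULL, priors = NULL,
                        patience = 5L) {
  if (!"combination_index" %in% names(grid)) {
    grid <- dplyr::bind_cols(tibble(combination_index = seq_len(nrow(grid))), grid)
  }
  if (is.null(graph) && method == "spid") graph <- sample_graph(dataset$stage)
  results <- purrr::pmap_dfr(grid, function(combination_index, lambda1,
                                            lambda2, beta, gamma1, gamma2, ...) {
    hpi <- hp
    hpi$lambda1 <- lambda1
    hpi$lambda2 <- lambda2
    hpi$beta <- beta
    hpi$gamma1 <- gamma1
    hpi$gamma2 <- gamma2
    res <- tryCatch({
      fit <- fit_jnmf(dataset, hpi, method = method, graph = graph,
                      priors = priors, patience = patience)
      tibble(relative_error = relative_error(fit, dataset),
             iterations = fit$report$iterations, error = NA_character_)
    }, error = function(e) {
      tibble(relative_error = NA_real_, iterations = NA_integer_,
             error = conditionMessage(e))
    })
    dplyr::bind_cols(
      tibble(combination_index = combination_index, lambda1 = lambda1,
             lambda2 = lambda2, beta = beta, gamma1 = gamma1,
             gamma2 = gamma2),
      res
    )
  })
  ok <- dplyr::filter(results, !is.na(.data$relative_error))
  if (nrow(ok) == 0) {
    abort("Every grid combination failed to fit.", class = "spidnmf_error_grid")
  }
  best <- ok[order(ok$relative_error, ok$combination_index), ][1, ]
  structure(list(best = best, results = results, method = method),
            class = "grid_search")
}

#' @export
print.grid_search <- function(x, ...) {
  cat(sprintf("<grid_search over %d combinations (method '%s')>\n",
              nrow(x$results), x$method))
  cat("best combination:\n")
  print(as.data.frame(x$best))
  invisible(x)
}
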