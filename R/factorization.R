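#' Hyperparameters for joint factorization
#'
#' Bundles the factorization rank and penalty weights. All weights are
#' non-negative; which ones are active depends on the `method` passed to
#' [fit_jnmf()]:
#'
#' * `jnmf` uses only the reconstruction term `sum_l ||X_l - W H_l||_F^2`.
#' * `mdjnmf` adds coefficient orthogonality (`alpha`), entry-sum sparsity
#'   (`gamma2`), basis shrinkage (`gamma1`) and the cross-modal coupling
#'   rewards (`lambda1`, `lambda2`).
#' * `spid` further adds the stage-graph Laplacian penalty
#'   `beta * Tr(W' L W)`.
#'
#' @param k Factorization rank (number of co-expression modules); must not
#'   exceed the sample count or any view's feature count.
#' @param alpha Orthogonality weight on each `H_l H_l' - I`. Default 0.01:
#'   the coefficient-orthogonality weight is routinely fixed at a small
#'   value rather than swept.
#' @param lambda1,lambda2 Coupling weights for the image-miRNA and
#'   image-mRNA priors.
#' @param beta Stage-graph Laplacian weight.
#' @param gamma1 Frobenius shrinkage weight on `W`.
#' @param gamma2 Entry-sum (L1 on non-negatives) sparsity weight on each
#'   `H_l`.
#' @param max_iter Maximum number of multiplicative-update iterations.
#' @param tol Convergence tolerance on the change in relative error.
#' @param eps Floor applied to update denominators (keeps the multiplicative
#'   rules well-defined).
#' @param init_floor Small positive value replacing exact zeros in the
#'   NNDSVD initialization so multiplicative updates can move every entry.
#' @param seed Integer seed recorded with the model (initialization is
#'   deterministic; the seed covers any randomized companions such as the
#'   random-init baseline).
#'
#' @return A list of class `nmf_hyperparameters`.
#' @export
nmf_hyperparameters <- function(k,
                                alpha = 0.01,
                                lambda1 = 0,
                                lambda2 = 0,
                                beta = 0,
                                gamma1 = 0,
                                gamma2 = 0,
                                max_iter = 200L,
                                tol = 1e-6,
                                eps = 1e-10,
                                init_floor = 1e-6,
                                seed = 1L) {
  check_scalar(k, "k", min = 1, integer = TRUE)
  for (nm in c("alpha", "lambda1", "lambda2", "beta", "gamma1", "gamma2")) {
    check_scalar(get(nm), nm, min = 0)
  }
  check_scalar(max_iter, "max_iter", min = 0, integer = TRUE)
  check_scalar(tol, "tol", min = 0)
  check_scalar(eps, "eps", min = 0)
  check_scalar(init_floor, "init_floor", min = 0)
  structure(
    list(k = as.integer(k), alpha = alpha, lambda1 = lambda1,
         lambda2 = lambda2, beta = beta, gamma1 = gamma1, gamma2 = gamma2,
         max_iter = as.integer(max_iter), tol = tol, eps = eps,
         init_floor = init_floor, seed = as.integer(seed)),
    class = "nmf_hyperparameters"
  )
}

# which penalty weights each method keeps; zeroing the rest makes the
# reduction chain (spid -> mdjnmf -> jnmf) exact by construction
effective_weights <- function(hp, method) {
  w <- hp
  if (method == "jnmf") {
    w$alpha <- w$lambda1 <- w$lambda2 <- w$beta <- w$gamma1 <- w$gamma2 <- 0
  } else if (method == "mdjnmf") {
    w$beta <- 0
  }
  w
}

#' Deterministic NNDSVD initialization of the shared factors
#'
#' Initializes the shared basis `W` (samples x k) and the per-view
#' coefficient matrices `H_l` (k x p_l) from the top-k singular triplets of
#' the column-concatenated data matrix, using non-negative double SVD:
#' the leading triplet enters through absolute values, later triplets
#' through whichever of their positive/negative part pairs carries more
#' mass. Exact zeros are replaced by `floor` so multiplicative updates can
#' move every entry. The result is fully deterministic: the same dataset
#' and rank always produce the same factors.
#'
#' @param dataset A [assemble_dataset()] result (or the output of
#'   [simulate_multiview()]).
#' @param k Factorization rank.
#' @param floor Positive replacement for exact zeros.
#'
#' @return A list with `W` (n x k) and `H` (named list of k x p_l matrices).
#' @export
initialize_factors <- function(dataset, k, floor = 1e-6) {
  xs <- dataset_matrices(dataset)
  xcat <- do.call(cbind, xs)
  n <- nrow(xcat)
  if (k > min(n, ncol(xcat))) {
    abort(sprintf("k = %d exceeds min(samples, total features) = %d.",
                  k, min(n, ncol(xcat))),
          class = "spidnmf_error_rank")
  }
  s <- svd(xcat, nu = k, nv = k)
  W <- matrix(0, n, k)
  H <- matrix(0, k, ncol(xcat))
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k >= 2) {
    for (j in 2:k) {
      u <- s$u[, j]
      v <- s$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      nup <- fnorm(up); nun <- fnorm(un)
      nvp <- fnorm(vp); nvn <- fnorm(vn)
      mp <- nup * nvp
      mn <- nun * nvn
      if (mp >= mn && mp > 0) {
        W[, j] <- sqrt(s$d[j] * mp) * up / nup
        H[j, ] <- sqrt(s$d[j] * mp) * vp / nvp
      } else if (mn > 0) {
        W[, j] <- sqrt(s$d[j] * mn) * un / nun
        H[j, ] <- sqrt(s$d[j] * mn) * vn / nvn
      }
      # mp == mn == 0 (degenerate triplet, e.g. constant data): leave at the
      # floor below
    }
  }
  W[W < floor] <- floor
  H[H < floor] <- floor
  rownames(W) <- dataset$sample_ids
  colnames(W) <- paste0("factor", seq_len(k))
  list(W = W, H = split_h(H, xs, k))
}

split_h <- function(H, xs, k) {
  p <- vapply(xs, ncol, integer(1))
  ends <- cumsum(p)
  starts <- c(1, head(ends, -1) + 1)
  hs <- lapply(seq_along(xs), function(l) {
    h <- H[, starts[l]:ends[l], drop = FALSE]
    colnames(h) <- colnames(xs[[l]])
    rownames(h) <- paste0("factor", seq_len(k))
    h
  })
  names(hs) <- names(xs)
  hs
}

# one full multiplicative update sweep: W first, then each H_l, each step
# using the freshest co-factors (Gauss-Seidel order, fixed for
# reproducibility). `w` are the effective weights; graph/priors may be NULL
# when their weights are zero.
update_factors <- function(W, H, xs, w, graph = NULL, priors = NULL,
                           eps = 1e-10) {
  nv <- length(xs)

  num <- Reduce(`+`, lapply(seq_len(nv), function(l) xs[[l]] %*% t(H[[l]])))
  S <- Reduce(`+`, lapply(H, tcrossprod))
  den <- W %*% S
  if (w$gamma1 > 0) den <- den + w$gamma1 * W
  if (w$beta > 0) {
    num <- num + w$beta * (graph$adjacency %*% W)
    den <- den + w$beta * (diag(graph$degree) * W)
  }
  W <- W * num / pmax(den, eps)

  G <- crossprod(W)
  wtx <- lapply(xs, function(x) crossprod(W, x))
  for (l in seq_len(nv)) {
    h <- H[[l]]
    num <- wtx[[l]]
    den <- G %*% h
    if (w$alpha > 0) {
      num <- num + 2 * w$alpha * h
      den <- den + 2 * w$alpha * (tcrossprod(h) %*% h)
    }
    if (w$gamma2 > 0) den <- den + w$gamma2 / 2
    if (nv == 3) {
      if (l == 1) {
        if (w$lambda1 > 0) num <- num + (w$lambda1 / 2) * (H[[2]] %*% t(priors$A1))
        if (w$lambda2 > 0) num <- num + (w$lambda2 / 2) * (H[[3]] %*% t(priors$A2))
      } else if (l == 2) {
        if (w$lambda1 > 0) num <- num + (w$lambda1 / 2) * (H[[1]] %*% priors$A1)
      } else {
        if (w$lambda2 > 0) num <- num + (w$lambda2 / 2) * (H[[1]] %*% priors$A2)
      }
    }
    H[[l]] <- h * num / pmax(den, eps)
  }
  list(W = W, H = H)
}

# full penalized objective; sparsity enters as the linear entry-sum
# gamma2 * sum_ij H_l[i,j], matching the (gamma2/2) E denominator of the
# update rules
objective_value <- function(W, H, xs, w, graph = NULL, priors = NULL) {
  k <- ncol(W)
  obj <- sum(vapply(seq_along(xs), function(l) {
    sum((xs[[l]] - W %*% H[[l]])^2)
  }, numeric(1)))
  if (w$alpha > 0) {
    obj <- obj + w$alpha * sum(vapply(H, function(h) {
      sum((tcrossprod(h) - diag(k))^2)
    }, numeric(1)))
  }
  if (w$gamma2 > 0) {
    obj <- obj + w$gamma2 * sum(vapply(H, sum, numeric(1)))
  }
  if (length(xs) == 3) {
    if (w$lambda1 > 0) {
      obj <- obj - w$lambda1 * sum((H[[1]] %*% priors$A1) * H[[2]])
    }
    if (w$lambda2 > 0) {
      obj <- obj - w$lambda2 * sum((H[[1]] %*% priors$A2) * H[[3]])
    }
  }
  if (w$beta > 0) {
    obj <- obj + w$beta * stage_penalty(W, graph)
  }
  if (w$gamma1 > 0) {
    obj <- obj + w$gamma1 * sum(W^2)
  }
  obj
}

#' One multiplicative update sweep
#'
#' Applies a single simultaneous update of `W` then each `H_l` (W first,
#' then `H_1 .. H_L`, each step using the freshest co-factors). The `W`
#' update splits the Laplacian gradient `2 beta L W` into its attractive
#' part `beta A W` (numerator) and degree part `beta D W` (denominator),
#' the only split that keeps the rule multiplicative and non-negative.
#' Factors must be strictly positive (as produced by
#' [initialize_factors()]); denominators are floored at `hp$eps`.
#'
#' @inheritParams fit_jnmf
#' @param W Current basis, samples x k, strictly positive.
#' @param H Current coefficients: named list of k x p_l matrices.
#'
#' @return A list with the updated `W` and `H`.
#' @export
nmf_update_step <- function(W, H, dataset, hp,
                            method = c("spid", "mdjnmf", "jnmf"),
                            graph = NULL, priors = NULL) {
  method <- match.arg(method)
  xs <- dataset_matrices(dataset)
  w <- effective_weights(hp, method)
  if (method == "spid" && is.null(graph)) graph <- sample_graph(dataset$stage)
  check_method_inputs(w, method, graph, priors, length(xs))
  update_factors(W, H, xs, w, graph, priors, eps = hp$eps)
}

#' Reconstruction error of a fitted model
#'
#' By default the scale-free norm ratio
#' `||X_cat - W H_cat||_F / ||X_cat||_F` over the column-concatenated views
#' (0 for an exact factorization, 1 when `W = 0`). `squared = TRUE` returns
#' the raw squared Frobenius norm `||X_cat - W H_cat||_F^2` instead.
#'
#' @param model A `jnmf_fit` (or a bare `list(W =, H =)` pair).
#' @param dataset The dataset the model was fitted to.
#' @param squared Return the unnormalized squared norm instead of the ratio.
#'
#' @return A non-negative scalar.
#' @export
relative_error <- function(model, dataset, squared = FALSE) {
  xs <- dataset_matrices(dataset)
  relative_error_wh(model$W, model$H, xs, squared)
}

relative_error_wh <- function(W, H, xs, squared = FALSE) {
  res2 <- sum(vapply(seq_along(xs), function(l) {
    sum((xs[[l]] - W %*% H[[l]])^2)
  }, numeric(1)))
  if (squared) {
    return(res2)
  }
  denom2 <- sum(vapply(xs, function(x) sum(x^2), numeric(1)))
  if (denom2 == 0) {
    abort("Relative error is undefined for an all-zero dataset.",
          class = "spidnmf_error_degenerate")
  }
  sqrt(res2) / sqrt(denom2)
}

#' Evaluate the penalized factorization objective
#'
#' The monitored objective is
#' `sum_l ||X_l - W H_l||_F^2 + alpha * sum_l ||H_l H_l' - I||_F^2 +
#'  gamma2 * sum_l sum_ij H_l[i,j] - lambda1 * Tr(H1 A1 H2') -
#'  lambda2 * Tr(H1 A2 H3') + beta * Tr(W' L W) + gamma1 * ||W||_F^2`,
#' with terms dropped according to `method` (see [nmf_hyperparameters()]).
#'
#' @inheritParams fit_jnmf
#' @param model A `jnmf_fit` or a `list(W =, H =)` pair.
#'
#' @return A scalar.
#' @export
jnmf_objective <- function(model, dataset, hp,
                           method = c("spid", "mdjnmf", "jnmf"),
                           graph = NULL, priors = NULL) {
  method <- match.arg(method)
  w <- effective_weights(hp, method)
  check_method_inputs(w, method, graph, priors, length(dataset$views))
  objective_value(model$W, model$H, dataset_matrices(dataset), w, graph, priors)
}

check_method_inputs <- function(w, method, graph, priors, nv) {
  if (method == "spid" && is.null(graph)) {
    abort("method = \"spid\" requires a sample graph.",
          class = "spidnmf_error_missing_graph")
  }
  if ((w$lambda1 > 0 || w$lambda2 > 0)) {
    if (is.null(priors)) {
      abort("Non-zero coupling weights require cross-modal priors.",
            class = "spidnmf_error_missing_prior")
    }
    if (nv != 3) {
      abort("Cross-modal coupling needs all three views.",
            class = "spidnmf_error_missing_prior")
    }
  }
  invisible(NULL)
}

#' Fit a joint non-negative matrix factorization
#'
#' Factorizes 1-3 sample-aligned non-negative views `X_l ~ W H_l` with a
#' shared sample basis `W`, by multiplicative updates from a deterministic
#' NNDSVD start. `method` selects the model family: plain joint NMF
#' (`"jnmf"`), the multi-penalty variant with orthogonality, sparsity and
#' cross-modal coupling (`"mdjnmf"`), or the stage-prior-informed variant
#' that additionally pulls same-stage samples together via the graph
#' Laplacian penalty `beta * Tr(W' L W)` (`"spid"`).
#'
#' Each iteration updates `W` first, then `H_1 .. H_L`, each step using the
#' freshest co-factors; denominators are floored at `hp$eps`. Iteration
#' stops when the change in relative error drops below `hp$tol`
#' (`stop_reason = "tol"`), when the relative error has failed to improve
#' by `hp$tol` for `patience` consecutive iterations
#' (`stop_reason = "early_stop"`), or at `hp$max_iter`.
#'
#' @param dataset A `multiview_dataset` from [assemble_dataset()] or
#'   [simulate_multiview()].
#' @param hp Hyperparameters from [nmf_hyperparameters()].
#' @param method `"spid"`, `"mdjnmf"` or `"jnmf"`.
#' @param graph A [sample_graph()]; required for `method = "spid"`. If
#'   omitted there, it is built from the dataset's stage labels.
#' @param priors Cross-modal priors (list with `A1`, `A2`), required when a
#'   coupling weight is positive; built with [cross_modal_priors()].
#' @param patience Early-stopping patience in iterations (`Inf` disables;
#'   the grid search uses a finite value).
#'
#' @return An object of class `jnmf_fit`: list with `W`, `H`, `method`,
#'   `hp`, and `report` (objective and relative-error trajectories,
#'   `iterations`, `converged`, `stop_reason`).
#' @export
#'
#' @examples
#' sim <- simulate_multiview(n = 24, p = c(12, 15, 18), k = 2, seed = 1)
#' fit <- fit_jnmf(sim$dataset, nmf_hyperparameters(k = 2, max_iter = 50),
#'                 method = "jnmf")
#' glance(fit)
fit_jnmf <- function(dataset,
                     hp,
                     method = c("spid", "mdjnmf", "jnmf"),
                     graph = NULL,
                     priors = NULL,
                     patience = Inf) {
  method <- match.arg(method)
  stopifnot(inherits(hp, "nmf_hyperparameters"))
  xs <- dataset_matrices(dataset)
  pmin_l <- min(vapply(xs, ncol, integer(1)))
  if (hp$k > min(n_samples(dataset), pmin_l)) {
    abort(sprintf("k = %d exceeds min(samples, features) = %d for this dataset.",
                  hp$k, min(n_samples(dataset), pmin_l)),
          class = "spidnmf_error_rank")
  }
  if (method == "spid" && is.null(graph)) {
    graph <- sample_graph(dataset$stage)
  }
  w <- effective_weights(hp, method)
  check_method_inputs(w, method, graph, priors, length(xs))

  init <- initialize_factors(dataset, hp$k, floor = hp$init_floor)
  W <- init$W
  H <- init$H

  obj_traj <- numeric(0)
  err_traj <- numeric(0)
  converged <- FALSE
  stop_reason <- "max_iter"
  prev_err <- relative_error_wh(W, H, xs)
  best_err <- prev_err
  stall <- 0L
  iter <- 0L

  while (iter < hp$max_iter) {
    iter <- iter + 1L
    upd <- update_factors(W, H, xs, w, graph, priors, eps = hp$eps)
    W <- upd$W
    H <- upd$H
    if (!all(is.finite(W)) || !all(vapply(H, function(h) all(is.finite(h)), logical(1)))) {
      abort(sprintf("Non-finite factor entries at iteration %d.", iter),
            class = "spidnmf_error_numeric")
    }
    err <- relative_error_wh(W, H, xs)
    if (!is.finite(err)) {
      abort(sprintf("Non-finite relative error at iteration %d.", iter),
            class = "spidnmf_error_numeric")
    }
    obj_traj[iter] <- objective_value(W, H, xs, w, graph, priors)
    err_traj[iter] <- err
    if (abs(prev_err - err) < hp$tol) {
      converged <- TRUE
      stop_reason <- "tol"
      break
    }
    if (err < best_err - hp$tol) {
      best_err <- err
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) {
        stop_reason <- "early_stop"
        break
      }
    }
    prev_err <- err
  }

  structure(
    list(
      W = W,
      H = H,
      method = method,
      hp = hp,
      graph = graph,
      report = list(
        objective_trajectory = obj_traj,
        relative_error_trajectory = err_traj,
        iterations = iter,
        converged = converged,
        stop_reason = if (iter == 0L) "max_iter" else stop_reason
      )
    ),
    class = "jnmf_fit"
  )
}

#' @export
print.jnmf_fit <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<jnmf_fit method='%s' k=%d: %d iterations (%s), relative error %.4g>\n",
    x$method, x$hp$k, r$iterations, r$stop_reason,
    if (r$iterations > 0) r$relative_error_trajectory[r$iterations] else NA
  ))
  invisible(x)
}

#' Compare the three factorization methods on one dataset
#'
#' Fits `jnmf`, `mdjnmf` and `spid` under identical rank and weights and
#' tabulates the relative reconstruction error together with the per-view
#' flattened absolute Pearson correlation between each `X_l` and its
#' reconstruction `W H_l` — the standard head-to-head comparison of the
#' three model families.
#'
#' @inheritParams fit_jnmf
#' @return A tibble with one row per method: `method`, `relative_error`,
#'   one `corr_<view>` column per view, and `iterations`.
#' @export
compare_methods <- function(dataset, hp, graph = NULL, priors = NULL,
                            patience = Inf) {
  if (is.null(graph)) graph <- sample_graph(dataset$stage)
  xs <- dataset_matrices(dataset)
  purrr::map_dfr(c("jnmf", "mdjnmf", "spid"), function(m) {
    fit <- fit_jnmf(dataset, hp, method = m, graph = graph, priors = priors,
                    patience = patience)
    corrs <- vapply(seq_along(xs), function(l) {
      abs_pearson(as.vector(xs[[l]]), as.vector(fit$W %*% fit$H[[l]]))
    }, numeric(1))
    names(corrs) <- paste0("corr_", names(xs))
    dplyr::bind_cols(
      tibble(method = m, relative_error = relative_error(fit, dataset)),
      as_tibble(as.list(corrs)),
      tibble(iterations = fit$report$iterations)
    )
  })
}
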