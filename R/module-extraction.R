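#' Extract co-expression modules from a fitted model
#'
#' Each factor of the joint decomposition defines one co-expression module:
#' across every view, the features with outlying coefficients in that
#' factor's row of `H_l`. Membership uses the per-row z-score rule standard
#' in the joint-NMF module literature: feature `j` of view `l` belongs to
#' module `i` iff `H_l[i, j] > mean(H_l[i, ]) + z_threshold * sd(H_l[i, ])`.
#' The threshold is the single most consequential tunable of the module
#' step; the default 2.0 selects roughly the upper 2% tail under
#' approximately normal coefficient rows and, more importantly for
#' block-sparse loadings, sits between the background and the active block
#' whenever the active fraction of a row is below ~20%.
#'
#' A zero-variance coefficient row contributes no members for that view
#' (reported via a message). Exactly `k` modules are returned, including
#' any that end up empty.
#'
#' @param model A `jnmf_fit`.
#' @param z_threshold Number of standard deviations above the row mean
#'   (default 2).
#'
#' @return A tibble with one row per member: `factor`, `view`,
#'   `feature_id`, `loading`; attribute `k` records the module count.
#' @export
extract_modules <- function(model, z_threshold = 2) {
  check_scalar(z_threshold, "z_threshold", min = 0)
  k <- model$hp$k
  out <- purrr::map_dfr(names(model$H), function(vn) {
    h <- model$H[[vn]]
    purrr::map_dfr(seq_len(k), function(i) {
      row <- h[i, ]
      s <- sd(row)
      if (s == 0) {
        inform(sprintf(
          "Factor %d has a constant coefficient row in view '%s'; no members there.",
          i, vn))
        return(tibble(factor = integer(0), view = character(0),
                      feature_id = character(0), loading = numeric(0)))
      }
      thr <- mean(row) + z_threshold * s
      sel <- which(row > thr)
      tibble(factor = i, view = vn, feature_id = colnames(h)[sel],
             loading = unname(row[sel]))
    })
  })
  out <- dplyr::arrange(out, .data$factor, .data$view)
  attr(out, "k") <- k
  attr(out, "z_threshold") <- z_threshold
  out
}

#' Score modules by original-vs-reconstructed correlation
#'
#' For every module and view with members, restricts both the original
#' matrix `X_l` and the reconstruction `W H_l` to the member columns,
#' flattens the two submatrices, and takes the absolute Pearson correlation
#' — one scalar per module per view. A module's summary score is the
#' arithmetic mean over the views in which it has members; modules empty in
#' every view get `NA` scores and are flagged with a warning.
#'
#' @param membership Output of [extract_modules()].
#' @param model The fitted `jnmf_fit`.
#' @param dataset The dataset the model was fitted to.
#'
#' @return A list of class `module_scores` with `per_view` (tibble:
#'   `factor`, `view`, `n_members`, `correlation`) and `summary` (tibble:
#'   `factor`, `n_views`, `mean_correlation`).
#' @export
score_modules <- function(membership, model, dataset) {
  k <- attr(membership, "k") %||% max(membership$factor, 0L)
  xs <- dataset_matrices(dataset)
  per_view <- purrr::map_dfr(seq_len(k), function(i) {
    purrr::map_dfr(names(model$H), function(vn) {
      feats <- membership$feature_id[membership$factor == i &
                                       membership$view == vn]
      if (length(feats) == 0) {
        return(tibble(factor = i, view = vn, n_members = 0L,
                      correlation = NA_real_))
      }
      x <- xs[[vn]][, feats, drop = FALSE]
      rec <- (model$W %*% model$H[[vn]])[, feats, drop = FALSE]
      tibble(factor = i, view = vn, n_members = length(feats),
             correlation = abs_pearson(as.vector(x), as.vector(rec)))
    })
  })
  summary <- per_view |>
    dplyr::group_by(.data$factor) |>
    dplyr::summarise(
      n_views = sum(.data$n_members > 0),
      mean_correlation = if (any(.data$n_members > 0)) {
        mean(.data$correlation[.data$n_members > 0])
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  if (any(summary$n_views == 0)) {
    warn(sprintf("%d module(s) have no members in any view; their scores are NA.",
                 sum(summary$n_views == 0)))
  }
  structure(list(per_view = per_view, summary = summary),
            class = "module_scores")
}

#' @export
print.module_scores <- function(x, ...) {
  cat("<module_scores>\n")
  print(as.data.frame(x$summary))
  invisible(x)
}

#' Select the most coherent module
#'
#' Returns the factor index with the maximal mean original-vs-reconstructed
#' correlation; ties break to the lowest factor index. Modules without a
#' score are skipped.
#'
#' @param scores A `module_scores` object from [score_modules()], or a
#'   tibble with columns `factor` and `mean_correlation`.
#'
#' @return The selected factor index (integer).
#' @export
select_top_module <- function(scores) {
  s <- if (inherits(scores, "module_scores")) scores$summary else scores
  s <- s[!is.na(s$mean_correlation), ]
  if (nrow(s) == 0) {
    abort("No scored module to select from.", class = "spidnmf_error_modules")
  }
  s <- s[order(-s$mean_correlation, s$factor), ]
  as.integer(s$factor[1])
}

#' Per-module reconstruction residuals
#'
#' Complementary reading of module quality: the relative Frobenius residual
#' of the member submatrices instead of their correlation. Provided so the
#' "smallest residual" selection rule can be inspected alongside the
#' correlation rule.
#'
#' @inheritParams score_modules
#' @return A tibble: `factor`, `view`, `relative_residual`.
#' @export
module_residuals <- function(membership, model, dataset) {
  k <- attr(membership, "k") %||% max(membership$factor, 0L)
  xs <- dataset_matrices(dataset)
  purrr::map_dfr(seq_len(k), function(i) {
    purrr::map_dfr(names(model$H), function(vn) {
      feats <- membership$feature_id[membership$factor == i &
                                       membership$view == vn]
      if (length(feats) == 0) {
        return(tibble(factor = i, view = vn, relative_residual = NA_real_))
      }
      x <- xs[[vn]][, feats, drop = FALSE]
      rec <- (model$W %*% model$H[[vn]])[, feats, drop = FALSE]
      tibble(factor = i, view = vn,
             relative_residual = if (sum(x^2) == 0) NA_real_ else fnorm(x - rec) / fnorm(x))
    })
  })
}

#' Match recovered modules to planted supports
#'
#' Utility for simulation studies: finds the factor permutation maximising
#' the mean Jaccard index between recovered memberships and planted
#' supports (exact search over permutations; intended for small `k`), and
#' reports the per-planted-factor Jaccard averaged over views.
#'
#' @param membership Output of [extract_modules()].
#' @param truth A `synthetic_truth` from [simulate_multiview()].
#'
#' @return A tibble: `planted_factor`, `recovered_factor`, `jaccard`
#'   (mean over views).
#' @export
match_planted_modules <- function(membership, truth) {
  k <- length(truth$supports[[1]])
  views <- names(truth$supports)
  rec <- lapply(seq_len(k), function(i) {
    lapply(views, function(vn) {
      membership$feature_id[membership$factor == i & membership$view == vn]
    })
  })
  pla <- lapply(seq_len(k), function(i) {
    lapply(views, function(vn) truth$supports[[vn]][[i]])
  })
  jac <- matrix(0, k, k) # planted x recovered
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      jac[i, j] <- mean(vapply(seq_along(views), function(v) {
        jaccard(pla[[i]][[v]], rec[[j]][[v]])
      }, numeric(1)))
    }
  }
  perms <- permutations_of(k)
  scores <- vapply(perms, function(p) mean(jac[cbind(seq_len(k), p)]), numeric(1))
  best <- perms[[which.max(scores)]]
  tibble(planted_factor = seq_len(k), recovered_factor = best,
         jaccard = jac[cbind(seq_len(k), best)])
}

permutations_of <- function(k) {
  if (k == 1) {
    return(list(1L))
  }
  sub <- permutations_of(k - 1)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1]] <- append(p, k, after = pos - 1)
    }
  }
  out
}
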