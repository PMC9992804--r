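#' Simulate a sample-aligned multi-view dataset with planted factors
#'
#' Generates 1-3 non-negative views sharing a common sample basis, the
#' statistical structure the joint factorization assumes: a planted basis
#' `W_true` (samples x k) whose rows carry a stage-specific dominant
#' factor, per-view block-sparse coefficient matrices `H_true_l` with
#' disjoint active feature blocks per factor, and observations
#' `X_l = max(0, W_true H_true_l + N(0, noise_sigma))` (Gaussian noise
#' truncated at zero, so non-negativity holds while `noise_sigma` keeps its
#' additive interpretation).
#'
#' Defaults describe the reference simulation used throughout the package's
#' validation: 60 samples, three views of 50/80/100 features, 4 factors,
#' 3 stages, noise 0.05. Each factor's active block spans about 12.5% of a
#' view's features (`active_frac`) with active values drawn from
#' `U(0.9, 1.1)`: a sub-20% active fraction with near-constant positives is
#' what keeps the mean + 2 sd membership rule well-posed on the truth
#' itself. Stages are assigned round-robin so group sizes are balanced;
#' samples of stage `s` get `stage_strength` (times `U(0.75, 1.25)`) added
#' to factor `((s - 1) mod k) + 1`, which makes same-stage rows of `W_true`
#' similar. Everything is reproducible from `seed`.
#'
#' @param n Number of samples (>= 2).
#' @param p Integer vector of feature counts, one per view (1-3 views).
#' @param k Number of planted factors; requires `k <= min(n, p)`.
#' @param n_stages Number of clinical-stage groups (>= 1).
#' @param noise_sigma Standard deviation of the truncated Gaussian noise.
#' @param stage_strength Size of the stage-specific dominant-factor boost;
#'   0 removes any stage structure from `W_true`.
#' @param active_frac Fraction of a view's features in each factor's active
#'   block (the k blocks must fit disjointly: `k * active_frac <= 1`).
#' @param seed Integer seed.
#'
#' @return A list with `dataset` (a `multiview_dataset`) and `truth`
#'   (class `synthetic_truth`: `W`, `H`, `supports` — per-view per-factor
#'   member feature ids — `stage`, `noise_sigma`, `seed`).
#' @export
#'
#' @examples
#' sim <- simulate_multiview(n = 20, p = c(15, 20), k = 2, seed = 7)
#' sim$dataset
simulate_multiview <- function(n = 60,
                               p = c(50, 80, 100),
                               k = 4,
                               n_stages = 3,
                               noise_sigma = 0.05,
                               stage_strength = 1,
                               active_frac = 0.125,
                               seed = 1L) {
  check_scalar(n, "n", min = 2, integer = TRUE)
  check_scalar(k, "k", min = 1, integer = TRUE)
  check_scalar(n_stages, "n_stages", min = 1, integer = TRUE)
  check_scalar(noise_sigma, "noise_sigma", min = 0)
  check_scalar(stage_strength, "stage_strength", min = 0)
  if (length(p) < 1 || length(p) > 3) {
    abort("`p` must give feature counts for 1 to 3 views.",
          class = "spidnmf_error_synthetic")
  }
  check_scalar(active_frac, "active_frac", min = 0)
  if (any(p < k) || n < k) {
    abort(sprintf("k = %d needs at least k samples and k features per view.", k),
          class = "spidnmf_error_synthetic")
  }
  if (k * active_frac > 1) {
    abort("Active blocks cannot be disjoint: k * active_frac exceeds 1.",
          class = "spidnmf_error_synthetic")
  }
  set.seed(seed)

  sample_ids <- sprintf("S%04d", seq_len(n))
  stage_idx <- ((seq_len(n) - 1) %% n_stages) + 1
  stage <- setNames(as.character(utils::as.roman(stage_idx)), sample_ids)

  W <- matrix(runif(n * k, 0, 0.5), n, k,
              dimnames = list(sample_ids, paste0("factor", seq_len(k))))
  dom <- ((stage_idx - 1) %% k) + 1
  W[cbind(seq_len(n), dom)] <- W[cbind(seq_len(n), dom)] +
    stage_strength * runif(n, 0.75, 1.25)

  view_ids <- c("wsi", "mirna", "mrna")[seq_along(p)]
  H <- list()
  supports <- list()
  views <- list()
  for (l in seq_along(p)) {
    pl <- p[l]
    feat <- sprintf("%s_f%04d", view_ids[l], seq_len(pl))
    block <- max(1L, floor(pl * active_frac))
    h <- matrix(0, k, pl, dimnames = list(paste0("factor", seq_len(k)), feat))
    sup <- vector("list", k)
    for (i in seq_len(k)) {
      cols <- ((i - 1) * block + 1):(i * block)
      h[i, cols] <- runif(block, 0.9, 1.1)
      sup[[i]] <- feat[cols]
    }
    x <- W %*% h
    if (noise_sigma > 0) {
      x <- pmax(x + matrix(rnorm(n * pl, 0, noise_sigma), n, pl), 0)
    }
    H[[view_ids[l]]] <- h
    supports[[view_ids[l]]] <- sup
    views[[view_ids[l]]] <- omics_view(x, view_ids[l])
  }

  dataset <- assemble_dataset(views, setNames(unname(stage), sample_ids))
  truth <- structure(
    list(W = W, H = H, supports = supports, stage = stage,
         noise_sigma = noise_sigma, stage_strength = stage_strength,
         seed = as.integer(seed)),
    class = "synthetic_truth"
  )
  list(dataset = dataset, truth = truth)
}

#' Simulate survival outcomes driven by a planted factor
#'
#' Draws exponential event times with log-hazard
#' `effect_size * W[, effect_factor]` (baseline rate `baseline_rate`), and
#' censors each sample via an independent competing exponential whose rate
#' is chosen so the probability of being censored equals `censor_rate`
#' exactly. With `effect_size = 0`, survival is independent of the
#' factors; with `censor_rate = 0`, every event is observed.
#'
#' @param truth A `synthetic_truth` from [simulate_multiview()], or a bare
#'   basis matrix with sample-id row names.
#' @param effect_factor Column of the basis driving the hazard.
#' @param effect_size Log-hazard slope per unit of the factor (2 is a
#'   strong, easily detectable effect at a few hundred samples).
#' @param censor_rate Probability a sample is censored, in \[0, 1).
#' @param baseline_rate Baseline hazard per day (default 1/1000, i.e. mean
#'   survival about 1000 days for a zero factor score).
#' @param seed Optional integer seed.
#'
#' @return A survival tibble: `sample_id`, `time` (days), `event`.
#' @export
simulate_survival <- function(truth,
                              effect_factor = 1L,
                              effect_size = 0,
                              censor_rate = 0.2,
                              baseline_rate = 1 / 1000,
                              seed = NULL) {
  W <- if (inherits(truth, "synthetic_truth")) truth$W else truth
  stopifnot(is.matrix(W), !is.null(rownames(W)))
  if (effect_factor < 1 || effect_factor > ncol(W)) {
    abort(sprintf("`effect_factor` must be in 1..%d.", ncol(W)),
          class = "spidnmf_error_synthetic")
  }
  check_scalar(censor_rate, "censor_rate", min = 0)
  if (censor_rate >= 1) {
    abort("`censor_rate` must be < 1.", class = "spidnmf_error_synthetic")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(W)
  rate_t <- baseline_rate * exp(effect_size * W[, effect_factor])
  t_event <- rexp(n, rate_t)
  if (censor_rate > 0) {
    # competing exponential with rate r_c = r_t * c/(1-c) gives
    # P(censor first) = r_c / (r_c + r_t) = c for every sample
    t_cens <- rexp(n, rate_t * censor_rate / (1 - censor_rate))
    tibble(sample_id = rownames(W),
           time = pmin(t_event, t_cens),
           event = as.numeric(t_event <= t_cens))
  } else {
    tibble(sample_id = rownames(W), time = t_event, event = 1)
  }
}
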