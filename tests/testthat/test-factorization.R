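# builds a dataset whose concatenated matrix is exactly rank k with
# non-negative factors, returning the planted pair alongside
planted_exact <- function(n = 12, p = c(6, 8), k = 3, seed = 1) {
  sim <- simulate_multiview(n = n, p = p, k = k, noise_sigma = 0, seed = seed)
  sim
}

test_that("NNDSVD initialization is deterministic and strictly positive", {
  ds <- make_dataset(10, c(6, 8), seed = 2)
  a <- initialize_factors(ds, 3)
  b <- initialize_factors(ds, 3)
  expect_identical(a, b)
  expect_true(all(a$W > 0))
  expect_true(all(vapply(a$H, function(h) all(h > 0), logical(1))))
})

test_that("NNDSVD beats seeded random initialization at iteration zero", {
  sim <- planted_exact(n = 20, p = c(10, 12), k = 3, seed = 3)
  ds <- sim$dataset
  init <- initialize_factors(ds, 3)
  err_svd <- relative_error(init, ds)
  set.seed(3)
  xs <- lapply(ds$views, unclass)
  rand <- list(
    W = matrix(runif(20 * 3), 20, 3),
    H = lapply(xs, function(x) matrix(runif(3 * ncol(x)), 3, ncol(x)))
  )
  expect_lt(err_svd, relative_error(rand, ds))
})

test_that("all-constant data initializes without NaN", {
  m <- matrix(2, 5, 4, dimnames = list(sprintf("s%d", 1:5), sprintf("f%d", 1:4)))
  ds <- assemble_dataset(list(omics_view(m)), setNames(rep("I", 5), rownames(m)))
  init <- initialize_factors(ds, 2)
  expect_true(all(is.finite(init$W)) && all(is.finite(init$H[[1]])))
  expect_true(all(init$W > 0))
})

test_that("rank bound is enforced", {
  ds <- make_dataset(4, c(3, 3), seed = 4)
  expect_error(initialize_factors(ds, 5), class = "spidnmf_error_rank")
  expect_error(fit_jnmf(ds, nmf_hyperparameters(k = 4), "jnmf"),
               class = "spidnmf_error_rank")
})

test_that("objective is zero for an exact factorization with zero weights", {
  sim <- planted_exact(seed = 5)
  model <- list(W = sim$truth$W, H = sim$truth$H)
  hp <- nmf_hyperparameters(k = 3, alpha = 0)
  expect_equal(jnmf_objective(model, sim$dataset, hp, "jnmf"), 0,
               tolerance = 1e-20)
})

test_that("objective with zero weights equals an entry-wise residual loop", {
  ds <- make_dataset(7, c(4, 5), seed = 6)
  init <- initialize_factors(ds, 2)
  hp <- nmf_hyperparameters(k = 2, alpha = 0)
  got <- jnmf_objective(init, ds, hp, "jnmf")
  brute <- 0
  for (v in seq_along(ds$views)) {
    x <- unclass(ds$views[[v]])
    rec <- init$W %*% init$H[[v]]
    for (i in seq_len(nrow(x))) {
      for (j in seq_len(ncol(x))) {
        brute <- brute + (x[i, j] - rec[i, j])^2
      }
    }
  }
  expect_equal(got, brute, tolerance = 1e-12)
})

test_that("the graph term contributes nothing when rows agree within stages", {
  ds <- make_dataset(6, c(4, 5), seed = 7, n_stages = 2)
  g <- sample_graph(ds$stage)
  k <- 2
  # rows constant within each stage group
  W <- matrix(0, 6, k)
  for (s in unique(ds$stage)) {
    W[ds$stage == s, ] <- matrix(rep(runif(k), each = sum(ds$stage == s)),
                                 ncol = k)
  }
  H <- initialize_factors(ds, k)$H
  hp_off <- nmf_hyperparameters(k = k, alpha = 0)
  hp_on <- nmf_hyperparameters(k = k, alpha = 0, beta = 3)
  model <- list(W = W, H = H)
  expect_equal(
    jnmf_objective(model, ds, hp_on, "spid", graph = g),
    jnmf_objective(model, ds, hp_off, "jnmf"),
    tolerance = 1e-10
  )
})

test_that("zero-weight updates coincide with a hand-rolled Lee-Seung step", {
  ds <- make_dataset(9, c(5, 7), seed = 8)
  init <- initialize_factors(ds, 3)
  hp <- nmf_hyperparameters(k = 3, alpha = 0)
  X <- do.call(cbind, lapply(ds$views, unclass))
  W <- init$W
  H <- do.call(cbind, init$H)
  for (it in 1:4) {
    W <- W * (X %*% t(H)) / (W %*% H %*% t(H))
    H <- H * (t(W) %*% X) / (t(W) %*% W %*% H)
  }
  cur <- list(W = init$W, H = init$H)
  for (it in 1:4) {
    cur <- nmf_update_step(cur$W, cur$H, ds, hp, "jnmf")
  }
  expect_lt(max(abs(cur$W - W)), 1e-12)
  expect_lt(max(abs(do.call(cbind, cur$H) - H)), 1e-12)
})

test_that("an exact factorization is a fixed point of the zero-weight update", {
  sim <- planted_exact(seed = 9)
  tr <- sim$truth
  # keep factors strictly positive as the update contract requires
  W <- pmax(tr$W, 1e-6)
  H <- lapply(tr$H, pmax, 1e-6)
  xs <- lapply(sim$dataset$views, unclass)
  hp <- nmf_hyperparameters(k = 3, alpha = 0)
  # rebuild data from the floored factors so the factorization is exact
  views <- purrr::imap(xs, function(x, vn) {
    omics_view(W %*% H[[vn]], attr(sim$dataset$views[[vn]], "view_id"))
  })
  ds <- assemble_dataset(views, sim$dataset$stage)
  upd <- nmf_update_step(W, H, ds, hp, "jnmf")
  expect_lt(max(abs(upd$W - W)), 1e-12)
  expect_lt(max(abs(do.call(cbind, upd$H) - do.call(cbind, H))), 1e-12)
})

test_that("a single-view k=1 update matches manual arithmetic", {
  X <- matrix(c(1, 2, 3, 2, 4, 6), 3, 2,
              dimnames = list(c("s1", "s2", "s3"), c("f1", "f2")))
  ds <- assemble_dataset(list(omics_view(X)), setNames(rep("I", 3), rownames(X)))
  W <- matrix(c(0.5, 1, 1.5), 3, 1)
  H <- list(other = matrix(c(2, 1), 1, 2))
  hp <- nmf_hyperparameters(k = 1, alpha = 0)
  upd <- nmf_update_step(W, H[1], ds, hp, "jnmf")
  # scalar arithmetic: W_i <- W_i * (X H')_i / (W (H H'))_i, then H with new W
  hh <- 2^2 + 1^2
  w_exp <- sapply(1:3, function(i) W[i] * sum(X[i, ] * c(2, 1)) / (W[i] * hh))
  ww <- sum(w_exp^2)
  h_exp <- sapply(1:2, function(j) H[[1]][j] * sum(w_exp * X[, j]) / (ww * H[[1]][j]))
  expect_equal(unname(drop(upd$W)), w_exp, tolerance = 1e-14)
  expect_equal(unname(drop(upd$H[[1]])), h_exp, tolerance = 1e-14)
})

test_that("factors stay non-negative through penalized updates", {
  sim <- simulate_multiview(n = 15, p = c(8, 10, 12), k = 3, seed = 10)
  ds <- sim$dataset
  g <- sample_graph(ds$stage)
  pr <- cross_modal_priors(ds)
  hp <- nmf_hyperparameters(k = 3, alpha = 0.05, lambda1 = 0.1, lambda2 = 0.1,
                            beta = 0.5, gamma1 = 0.01, gamma2 = 0.01)
  cur <- initialize_factors(ds, 3)
  for (it in 1:25) {
    cur <- nmf_update_step(cur$W, cur$H, ds, hp, "spid", graph = g, priors = pr)
    expect_true(all(cur$W >= 0))
    expect_true(all(vapply(cur$H, function(h) all(h >= 0), logical(1))))
  }
})

test_that("relative error has its closed-form limits and matches brute force", {
  sim <- planted_exact(seed = 11)
  exact <- list(W = sim$truth$W, H = sim$truth$H)
  expect_equal(relative_error(exact, sim$dataset), 0, tolerance = 1e-10)
  zero <- list(W = sim$truth$W * 0,
               H = lapply(sim$truth$H, function(h) h * 0))
  expect_equal(relative_error(zero, sim$dataset), 1)
  ds <- make_dataset(6, c(4, 5), seed = 12)
  init <- initialize_factors(ds, 2)
  num2 <- 0
  den2 <- 0
  for (v in seq_along(ds$views)) {
    x <- unclass(ds$views[[v]])
    rec <- init$W %*% init$H[[v]]
    num2 <- num2 + sum((x - rec)^2)
    den2 <- den2 + sum(x^2)
  }
  expect_equal(relative_error(init, ds), sqrt(num2 / den2), tolerance = 1e-12)
  expect_equal(relative_error(init, ds, squared = TRUE), num2, tolerance = 1e-12)
})

test_that("fit with max_iter = 0 returns the initialization unchanged", {
  ds <- make_dataset(8, c(5, 6), seed = 13)
  hp <- nmf_hyperparameters(k = 2, max_iter = 0)
  fit <- fit_jnmf(ds, hp, "jnmf")
  init <- initialize_factors(ds, 2)
  expect_identical(fit$W, init$W)
  expect_identical(fit$H, init$H)
  expect_false(fit$report$converged)
  expect_equal(fit$report$iterations, 0L)
})

test_that("fitting is deterministic and records conforming trajectories", {
  ds <- make_dataset(10, c(6, 7), seed = 14)
  hp <- nmf_hyperparameters(k = 3, max_iter = 40, tol = 0)
  f1 <- fit_jnmf(ds, hp, "mdjnmf")
  f2 <- fit_jnmf(ds, hp, "mdjnmf")
  expect_identical(f1$report$relative_error_trajectory,
                   f2$report$relative_error_trajectory)
  expect_identical(f1$W, f2$W)
  expect_length(f1$report$objective_trajectory, f1$report$iterations)
  expect_length(f1$report$relative_error_trajectory, f1$report$iterations)
})

test_that("noiseless planted data is recovered below 1% relative error", {
  sim <- simulate_multiview(n = 30, p = c(15, 20, 25), k = 3, noise_sigma = 0,
                            seed = 15)
  hp <- nmf_hyperparameters(k = 3, alpha = 0, max_iter = 800, tol = 1e-12)
  fit <- fit_jnmf(sim$dataset, hp, "jnmf")
  expect_lt(relative_error(fit, sim$dataset), 0.01)
})

test_that("the objective is non-increasing in the classical limit", {
  for (seed in 1:5) {
    sim <- simulate_multiview(n = 20, p = c(10, 12), k = 3, noise_sigma = 0.2,
                              seed = seed)
    hp <- nmf_hyperparameters(k = 3, alpha = 0, max_iter = 100, tol = 0)
    fit <- fit_jnmf(sim$dataset, hp, "jnmf")
    obj <- fit$report$objective_trajectory
    expect_true(all(diff(obj) <= 1e-8 * pmax(1, obj[-length(obj)])))
  }
})

test_that("the model chain reduces exactly: spid(beta=0) = mdjnmf, stripped mdjnmf = jnmf", {
  sim <- simulate_multiview(n = 18, p = c(10, 12, 14), k = 3, seed = 16)
  ds <- sim$dataset
  g <- sample_graph(ds$stage)
  pr <- cross_modal_priors(ds)
  hp <- nmf_hyperparameters(k = 3, alpha = 0.02, lambda1 = 0.1, lambda2 = 0.05,
                            beta = 0, gamma1 = 0.01, gamma2 = 0.02,
                            max_iter = 25, tol = 0)
  f_spid <- fit_jnmf(ds, hp, "spid", graph = g, priors = pr)
  f_md <- fit_jnmf(ds, hp, "mdjnmf", priors = pr)
  expect_identical(f_spid$W, f_md$W)
  expect_identical(f_spid$H, f_md$H)
  hp0 <- nmf_hyperparameters(k = 3, alpha = 0, max_iter = 25, tol = 0)
  f_md0 <- fit_jnmf(ds, hp0, "mdjnmf")
  f_j <- fit_jnmf(ds, hp0, "jnmf")
  expect_identical(f_md0$W, f_j$W)
  expect_identical(f_md0$H, f_j$H)
})

test_that("missing graph or priors are rejected per method", {
  sim <- simulate_multiview(n = 10, p = c(6, 7, 8), k = 2, seed = 17)
  hp <- nmf_hyperparameters(k = 2, lambda1 = 0.1)
  expect_error(fit_jnmf(sim$dataset, hp, "mdjnmf"),
               class = "spidnmf_error_missing_prior")
  init <- initialize_factors(sim$dataset, 2)
  expect_error(
    jnmf_objective(init, sim$dataset, nmf_hyperparameters(k = 2), "spid"),
    class = "spidnmf_error_missing_graph"
  )
})

test_that("compare_methods collapses to identical rows with zero weights", {
  sim <- simulate_multiview(n = 14, p = c(8, 9, 10), k = 2, seed = 18)
  hp <- nmf_hyperparameters(k = 2, alpha = 0, max_iter = 30, tol = 0)
  tab <- compare_methods(sim$dataset, hp, priors = cross_modal_priors(sim$dataset))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$relative_error[1], tab$relative_error[2], tolerance = 1e-14)
  expect_equal(tab$relative_error[2], tab$relative_error[3], tolerance = 1e-14)
  # self-consistency with an individually computed fit
  f <- fit_jnmf(sim$dataset, hp, "jnmf")
  expect_equal(tab$relative_error[tab$method == "jnmf"],
               relative_error(f, sim$dataset), tolerance = 1e-14)
})

test_that("correlations approach 1 on near-exact planted data", {
  sim <- simulate_multiview(n = 24, p = c(12, 14, 16), k = 3, noise_sigma = 0,
                            seed = 19)
  hp <- nmf_hyperparameters(k = 3, alpha = 0, max_iter = 300, tol = 1e-10)
  tab <- compare_methods(sim$dataset, hp, priors = cross_modal_priors(sim$dataset))
  corr_cols <- grep("^corr_", names(tab))
  expect_true(all(as.matrix(tab[, corr_cols]) > 0.99))
})
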