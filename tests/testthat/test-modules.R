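# a minimal jnmf_fit-shaped object with hand-chosen coefficient rows
fake_fit <- function(H, W = NULL, k = nrow(H[[1]])) {
  structure(list(W = W, H = H,
                 hp = nmf_hyperparameters(k = k), method = "jnmf"),
            class = "jnmf_fit")
}

test_that("membership follows the mean + z*sd rule on a spiked row", {
  h <- matrix(c(10, rep(0, 9)), 1, 10,
              dimnames = list("factor1", paste0("g", 1:10)))
  mem <- extract_modules(fake_fit(list(mrna = h), k = 1), z_threshold = 2)
  # mean 1, sd ~3.16: only the spike exceeds 1 + 2*3.16
  expect_equal(mem$feature_id, "g1")
  expect_equal(mem$factor, 1)
})

test_that("constant coefficient rows contribute no members", {
  h <- matrix(1, 2, 6, dimnames = list(c("factor1", "factor2"), paste0("g", 1:6)))
  h[2, ] <- c(5, 0, 0, 0, 0, 0)
  expect_message(
    mem <- extract_modules(fake_fit(list(mrna = h)), 2),
    "constant"
  )
  expect_false(1 %in% mem$factor)
  expect_equal(mem$feature_id[mem$factor == 2], "g1")
})

test_that("membership is invariant to feature permutation", {
  set.seed(31)
  h <- matrix(rexp(3 * 20), 3, 20,
              dimnames = list(paste0("factor", 1:3), paste0("g", 1:20)))
  mem1 <- extract_modules(fake_fit(list(mrna = h)), 1.5)
  perm <- sample(20)
  mem2 <- extract_modules(fake_fit(list(mrna = h[, perm])), 1.5)
  for (i in 1:3) {
    expect_setequal(mem1$feature_id[mem1$factor == i],
                    mem2$feature_id[mem2$factor == i])
  }
})

test_that("planted block-sparse coefficients are recovered exactly at z = 2", {
  sim <- simulate_multiview(n = 20, p = c(30, 40), k = 3, noise_sigma = 0,
                            seed = 32)
  fit <- fake_fit(sim$truth$H, W = sim$truth$W)
  mem <- extract_modules(fit, 2)
  matched <- match_planted_modules(mem, sim$truth)
  expect_equal(matched$recovered_factor, matched$planted_factor)
  expect_equal(matched$jaccard, rep(1, 3))
})

test_that("exactly k modules are produced per fit", {
  sim <- simulate_multiview(n = 20, p = c(15, 18), k = 4, seed = 33)
  fit <- fit_jnmf(sim$dataset, nmf_hyperparameters(k = 4, max_iter = 100),
                  "spid")
  mem <- extract_modules(fit)
  expect_equal(attr(mem, "k"), 4L)
  scores <- score_modules(mem, fit, sim$dataset)
  expect_equal(nrow(scores$summary), 4)
  expect_equal(sort(unique(scores$per_view$factor)), 1:4)
})

test_that("perfect reconstruction scores |r| = 1 and shifts leave it unchanged", {
  sim <- simulate_multiview(n = 15, p = c(12, 14), k = 2, noise_sigma = 0,
                            seed = 34)
  fit <- fake_fit(sim$truth$H, W = sim$truth$W)
  mem <- extract_modules(fit, 2)
  sc <- score_modules(mem, fit, sim$dataset)
  ok <- !is.na(sc$per_view$correlation)
  expect_true(all(abs(sc$per_view$correlation[ok] - 1) < 1e-10))
  # additive shift of the reconstruction: scale W and add a constant via an
  # extra check on Pearson shift-invariance of the score itself
  x <- unclass(sim$dataset$views[[1]])[, mem$feature_id[mem$factor == 1 &
                                                          mem$view == "wsi"]]
  expect_equal(abs(cor(as.vector(x), as.vector(x + 5))), 1)
})

test_that("module scores agree with a hand-rolled Pearson on flattened members", {
  sim <- simulate_multiview(n = 12, p = c(10, 12), k = 2, noise_sigma = 0.3,
                            seed = 35)
  fit <- fit_jnmf(sim$dataset, nmf_hyperparameters(k = 2, max_iter = 60),
                  "spid")
  mem <- extract_modules(fit, 1)
  sc <- score_modules(mem, fit, sim$dataset)
  row <- sc$per_view[which(sc$per_view$n_members > 0)[1], ]
  feats <- mem$feature_id[mem$factor == row$factor & mem$view == row$view]
  x <- unclass(sim$dataset$views[[row$view]])[, feats, drop = FALSE]
  rec <- (fit$W %*% fit$H[[row$view]])[, feats, drop = FALSE]
  expect_equal(row$correlation,
               abs(pearson_by_hand(as.vector(x), as.vector(rec))),
               tolerance = 1e-12)
})

test_that("the top module maximises mean correlation with ties to the lowest factor", {
  s <- tibble::tibble(factor = 1:3, mean_correlation = c(0.5, 0.9, 0.7))
  expect_equal(select_top_module(s), 2L)
  s2 <- tibble::tibble(factor = 1:2, mean_correlation = c(0.9, 0.9))
  expect_equal(select_top_module(s2), 1L)
  expect_error(select_top_module(tibble::tibble(factor = 1,
                                                mean_correlation = NA_real_)),
               class = "spidnmf_error_modules")
})

test_that("a strongly planted factor is selected on synthetic data", {
  sim <- simulate_multiview(n = 30, p = c(20, 25), k = 3, noise_sigma = 0.02,
                            seed = 36)
  fit <- fit_jnmf(sim$dataset, nmf_hyperparameters(k = 3, max_iter = 200),
                  "spid")
  mem <- extract_modules(fit, 2)
  sc <- score_modules(mem, fit, sim$dataset)
  top <- select_top_module(sc)
  expect_true(top %in% sc$summary$factor[!is.na(sc$summary$mean_correlation)])
  expect_equal(sc$summary$mean_correlation[sc$summary$factor == top],
               max(sc$summary$mean_correlation, na.rm = TRUE))
})

test_that("per-module residuals are finite where members exist", {
  sim <- simulate_multiview(n = 20, p = c(15, 18), k = 2, seed = 37)
  fit <- fit_jnmf(sim$dataset, nmf_hyperparameters(k = 2, max_iter = 80), "spid")
  mem <- extract_modules(fit)
  res <- module_residuals(mem, fit, sim$dataset)
  has <- !is.na(res$relative_residual)
  expect_true(any(has))
  expect_true(all(res$relative_residual[has] >= 0))
})
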