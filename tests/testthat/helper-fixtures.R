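# small in-code fixtures shared across test files

make_view <- function(n = 6, p = 4, view_id = "other", seed = 1,
                      prefix = "s", fprefix = "f") {
  set.seed(seed)
  m <- matrix(runif(n * p, 0.1, 2), n, p,
              dimnames = list(sprintf("%s%02d", prefix, seq_len(n)),
                              sprintf("%s%02d", fprefix, seq_len(p))))
  omics_view(m, view_id)
}

make_dataset <- function(n = 8, p = c(5, 6), seed = 1, n_stages = 2) {
  ids <- c("wsi", "mirna", "mrna")[seq_along(p)]
  views <- lapply(seq_along(p), function(l) {
    make_view(n, p[l], ids[l], seed = seed + l, fprefix = paste0(ids[l], "_f"))
  })
  labels <- setNames(as.character(rep_len(seq_len(n_stages), n)),
                     rownames(views[[1]]))
  assemble_dataset(views, labels)
}

# independent textbook Pearson correlation, written as explicit sums
pearson_by_hand <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}
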