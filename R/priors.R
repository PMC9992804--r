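#' Binary same-stage sample adjacency
#'
#' Treats each sample as a node of an undirected graph and connects two
#' samples iff they carry the same clinical-stage label: `A[i, j] = 1` when
#' `labels[i] == labels[j]`, else 0. The diagonal is 1 (a sample shares its
#' own group); self-loops cancel in the Laplacian penalty
#' `1/2 * sum_ij A_ij ||w_i - w_j||^2`, so the convention is penalty-neutral.
#'
#' @param labels Ordered per-sample stage labels (character or factor),
#'   length >= 2, no missing values. Names, if present, become dimnames.
#'
#' @return An n x n binary symmetric matrix.
#' @export
#'
#' @examples
#' build_sample_adjacency(c("I", "I", "II"))
build_sample_adjacency <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2) {
    abort("At least 2 labels are required.", class = "spidnmf_error_graph")
  }
  if (any(is.na(labels) | !nzchar(labels))) {
    abort("Missing or empty stage label.", class = "spidnmf_error_graph")
  }
  a <- outer(labels, labels, "==") * 1
  nm <- names(labels)
  if (!is.null(nm)) dimnames(a) <- list(nm, nm)
  a
}

#' Sample graph with degree matrix and Laplacian
#'
#' From a binary symmetric adjacency `A`, builds the diagonal degree matrix
#' `D` (`D_ii = sum_j A_ij`) and the graph Laplacian `L = D - A`. The
#' quadratic form `Tr(W' L W)` equals `1/2 * sum_ij A_ij ||w_i - w_j||^2`
#' over rows `w_i` of `W`, which is the penalty that pulls same-stage
#' samples together in factor space.
#'
#' @param adjacency An n x n binary symmetric matrix, e.g. from
#'   [build_sample_adjacency()]. Alternatively pass stage labels directly to
#'   [sample_graph()].
#'
#' @return An object of class `sample_graph`: list with `adjacency`,
#'   `degree` (diagonal matrix) and `laplacian`.
#' @export
build_laplacian <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isTRUE(all.equal(a, t(a))) || !all(a %in% c(0, 1))) {
    abort("Adjacency must be binary and symmetric.",
          class = "spidnmf_error_graph")
  }
  deg <- rowSums(a)
  d <- diag(deg, nrow = nrow(a))
  dimnames(d) <- dimnames(a)
  structure(
    list(adjacency = a, degree = d, laplacian = d - a),
    class = "sample_graph"
  )
}

#' @rdname build_laplacian
#' @param labels Per-sample stage labels, see [build_sample_adjacency()].
#' @export
sample_graph <- function(labels) {
  build_laplacian(build_sample_adjacency(labels))
}

#' @export
print.sample_graph <- function(x, ...) {
  cat(sprintf("<sample_graph: %d nodes, %d same-stage edges (excl. self)>\n",
              nrow(x$adjacency),
              (sum(x$adjacency) - nrow(x$adjacency)) / 2))
  invisible(x)
}

#' Stage-coherence penalty of a basis matrix
#'
#' Computes `Tr(W' L W)` for a sample basis `W` (samples x factors) and a
#' [sample_graph()]; zero exactly when rows of `W` are constant within every
#' stage group.
#'
#' @param W Numeric matrix, samples x factors.
#' @param graph A [sample_graph()].
#' @return A non-negative scalar.
#' @export
stage_penalty <- function(W, graph) {
  sum(diag(crossprod(W, graph$laplacian %*% W)))
}

#' Cross-modal absolute-Pearson coupling prior
#'
#' For each pair (feature i of `view_a`, feature j of `view_b`), computes the
#' absolute Pearson correlation across samples. These matrices (image vs
#' miRNA, image vs mRNA) enter the factorization objective through
#' `Tr(H1 A H2')` reward terms that encourage correlated cross-modal
#' features to load on the same factor. Feature pairs involving a constant
#' column get coupling 0 (their correlation is undefined); a warning reports
#' how many columns were affected.
#'
#' @param view_a,view_b Sample-aligned [omics_view()] objects with identical
#'   sample ids in identical order; at least 3 samples.
#'
#' @return A `p_a` x `p_b` matrix with entries in \[0, 1\].
#' @export
build_cross_modal_prior <- function(view_a, view_b) {
  if (!identical(rownames(view_a), rownames(view_b))) {
    abort("Views must be sample-aligned (same ids, same order).",
          class = "spidnmf_error_alignment")
  }
  if (nrow(view_a) < 3) {
    abort("At least 3 samples are needed for correlation priors.",
          class = "spidnmf_error_prior")
  }
  a <- unclass(view_a)
  b <- unclass(view_b)
  const_a <- apply(a, 2, sd) == 0
  const_b <- apply(b, 2, sd) == 0
  n_const <- sum(const_a) + sum(const_b)
  if (n_const > 0) {
    warn(sprintf(
      "%d constant feature column(s); their coupling entries are set to 0.",
      n_const
    ))
  }
  out <- suppressWarnings(abs(cor(a, b)))
  out[const_a, ] <- 0
  out[, const_b] <- 0
  out
}

#' Build both coupling priors of a three-view dataset
#'
#' Convenience wrapper producing the image-vs-miRNA (`A1`) and image-vs-mRNA
#' (`A2`) coupling matrices from the first view against the second and third.
#'
#' @param dataset A three-view [assemble_dataset()] result.
#' @return A list with elements `A1` (p1 x p2) and `A2` (p1 x p3).
#' @export
cross_modal_priors <- function(dataset) {
  if (length(dataset$views) < 3) {
    abort("Coupling priors need all three views.",
          class = "spidnmf_error_prior")
  }
  v <- dataset$views
  list(
    A1 = build_cross_modal_prior(v[[1]], v[[2]]),
    A2 = build_cross_modal_prior(v[[1]], v[[3]])
  )
}
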