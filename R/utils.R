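# internal helpers shared across modules

# |Pearson r| between two numeric vectors; 0 (not NA) when either side is
# constant, so degenerate features never propagate NA into module scores.
abs_pearson <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) {
    return(0)
  }
  abs(cor(x, y))
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) {
    return(1)
  }
  length(intersect(a, b)) / u
}

# Frobenius norm
fnorm <- function(x) sqrt(sum(x^2))

is_wholenumber <- function(x, tol = .Machine$double.eps^0.5) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && abs(x - round(x)) < tol
}

check_scalar <- function(x, name, min = -Inf, integer = FALSE) {
  if (integer) {
    if (!is_wholenumber(x)) {
      abort(sprintf("`%s` must be a single whole number.", name),
            class = "spidnmf_error_argument")
    }
  } else if (!(is.numeric(x) && length(x) == 1 && is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "spidnmf_error_argument")
  }
  if (x < min) {
    abort(sprintf("`%s` must be >= %s.", name, format(min)),
          class = "spidnmf_error_argument")
  }
  invisible(x)
}

# coerce a labels input (two-column data frame or named vector) to a named
# character vector sample_id -> label
as_label_map <- function(labels) {
  if (is.data.frame(labels)) {
    if (ncol(labels) < 2) {
      abort("A label data frame needs two columns: sample id and label.",
            class = "spidnmf_error_labels")
    }
    out <- as.character(labels[[2]])
    names(out) <- as.character(labels[[1]])
  } else {
    if (is.null(names(labels))) {
      abort("Labels must be a named vector (names = sample ids) or a two-column data frame.",
            class = "spidnmf_error_labels")
    }
    out <- as.character(labels)
    names(out) <- names(labels)
  }
  if (anyDuplicated(names(out))) {
    abort("Duplicate sample ids in labels.", class = "spidnmf_error_labels")
  }
  if (any(is.na(out) | !nzchar(out))) {
    abort("Missing or empty label for at least one sample.",
          class = "spidnmf_error_labels")
  }
  out
}
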