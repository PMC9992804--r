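#' Construct a single-modality feature matrix
#'
#' An `omics_view` holds one modality of sample-aligned data: a non-negative
#' numeric matrix with samples in rows and features in columns, tagged with a
#' view identifier (`"wsi"`, `"mirna"`, `"mrna"` or `"other"`). All joint
#' factorization functions consume views through [assemble_dataset()].
#'
#' @param x A numeric matrix (samples x features) with row and column names,
#'   or a data frame whose first column holds sample ids (see
#'   [as_omics_view()]).
#' @param view_id One of `"wsi"`, `"mirna"`, `"mrna"`, `"other"`.
#'
#' @return An object of class `omics_view`: the validated matrix with
#'   attributes `view_id`.
#' @export
#'
#' @examples
#' m <- matrix(runif(12), 4, 3,
#'             dimnames = list(paste0("S", 1:4), paste0("g", 1:3)))
#' v <- omics_view(m, "mrna")
#' dim(v)
omics_view <- function(x, view_id = "other") {
  view_id <- match.arg(view_id, c("wsi", "mirna", "mrna", "other"))
  if (is.data.frame(x)) {
    return(as_omics_view(x, view_id))
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`x` must be a numeric matrix or a data frame.",
          class = "spidnmf_error_view")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("`x` needs row names (sample ids) and column names (feature ids).",
          class = "spidnmf_error_view")
  }
  validate_view_matrix(x)
  structure(x, view_id = view_id, class = c("omics_view", "matrix", "array"))
}

validate_view_matrix <- function(x) {
  if (anyDuplicated(rownames(x))) {
    abort("Duplicate sample ids.", class = "spidnmf_error_view")
  }
  if (anyDuplicated(colnames(x))) {
    abort("Duplicate feature ids.", class = "spidnmf_error_view")
  }
  bad <- which(!is.finite(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]
    j <- bad[1, 2]
    abort(
      sprintf(
        "Entries must be non-negative and finite; offending value %s at sample '%s', feature '%s'.",
        format(x[i, j]), rownames(x)[i], colnames(x)[j]
      ),
      class = "spidnmf_error_negative"
    )
  }
  invisible(x)
}

#' Coerce a samples-by-features data frame to an omics view
#'
#' The first column (or the column named by `sample_col`) is taken as the
#' sample id; all remaining columns must be numeric features.
#'
#' @param x A data frame, one row per sample.
#' @param view_id View identifier, see [omics_view()].
#' @param sample_col Name or index of the sample-id column (default first).
#'
#' @return An [omics_view()].
#' @export
as_omics_view <- function(x, view_id = "other", sample_col = 1L) {
  stopifnot(is.data.frame(x))
  ids <- as.character(x[[sample_col]])
  body <- x[setdiff(seq_along(x), if (is.numeric(sample_col)) sample_col else match(sample_col, names(x)))]
  if (!all(vapply(body, is.numeric, logical(1)))) {
    abort("All feature columns must be numeric.", class = "spidnmf_error_view")
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  omics_view(m, view_id)
}

#' @method as_tibble omics_view
#' @export
#' @importFrom tibble as_tibble
as_tibble.omics_view <- function(x, ...) {
  out <- as_tibble(unclass(x), .name_repair = "minimal")
  dplyr::bind_cols(tibble(sample_id = rownames(x)), out)
}

#' @export
print.omics_view <- function(x, ...) {
  cat(sprintf("<omics_view '%s': %d samples x %d features>\n",
              attr(x, "view_id"), nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(5, ncol(x))), drop = FALSE], 4))
  invisible(x)
}

view_id <- function(view) attr(view, "view_id") %||% "other"

#' Read a delimited samples-by-features matrix
#'
#' Reads a tab- or comma-separated table (delimiter auto-detected from the
#' header line) whose first column holds sample ids and first row holds
#' feature ids. Negative or non-finite entries are rejected with a message
#' naming the offending cell.
#'
#' @param path Path to the file.
#' @param view_id View identifier, see [omics_view()].
#'
#' @return An [omics_view()].
#' @export
read_omics_view <- function(path, view_id = "other") {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'.", path), class = "spidnmf_error_io")
  }
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, fill = FALSE,
                          colClasses = NA, comment.char = "")
  as_omics_view(df, view_id)
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1)
  if (grepl("\t", header)) "\t" else ","
}

#' Write an omics view to a delimited file
#'
#' Values are written at full double precision (`%.17g`) so a write/read
#' round trip reproduces the matrix exactly.
#'
#' @param view An [omics_view()].
#' @param path Output path.
#' @param sep Field separator, tab by default.
#'
#' @return `path`, invisibly.
#' @export
write_omics_view <- function(view, path, sep = "\t") {
  m <- unclass(view)
  body <- apply(m, c(1, 2), function(v) sprintf("%.17g", v))
  lines <- c(
    paste(c("sample_id", colnames(m)), collapse = sep),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], body[i, ]), collapse = sep)
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Min-max scale features of a view
#'
#' Maps each feature column to \[0, 1\] by `(x - min) / (max - min)`;
#' constant columns map to 0. Heterogeneous modalities (histology features,
#' CPM expression) must sit on comparable scales before joint factorization,
#' otherwise the view with the largest Frobenius norm dominates the shared
#' basis. `mode = "none"` is the identity for callers that scale upstream.
#'
#' @param view An [omics_view()].
#' @param mode `"minmax"` (default) or `"none"`.
#'
#' @return A rescaled [omics_view()].
#' @export
scale_features <- function(view, mode = c("minmax", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") {
    return(view)
  }
  m <- unclass(view)
  rng <- apply(m, 2, range)
  span <- rng[2, ] - rng[1, ]
  scaled <- sweep(m, 2, rng[1, ], "-")
  keep <- span > 0
  scaled[, keep] <- sweep(scaled[, keep, drop = FALSE], 2, span[keep], "/")
  scaled[, !keep] <- 0
  omics_view(scaled, view_id(view))
}
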