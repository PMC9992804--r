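#' Assemble sample-aligned views and stage labels into one dataset
#'
#' Joint factorization requires every view to carry the same samples in the
#' same row order. `assemble_dataset()` restricts all views and the label map
#' to their common sample ids, reorders rows to a single canonical order
#' (lexicographic by sample id), and returns a `multiview_dataset`.
#'
#' @param views A list of [omics_view()] objects (1 to 3). Names default to
#'   each view's `view_id`.
#' @param labels Per-sample stage labels: a two-column data frame
#'   (`sample_id`, `stage`) or a named character vector.
#'
#' @return A `multiview_dataset`: list with elements `views` (named list of
#'   aligned views), `stage` (named character vector, one label per sample)
#'   and `sample_ids`.
#' @export
#'
#' @examples
#' m1 <- matrix(runif(8), 4, 2,
#'              dimnames = list(c("a", "b", "c", "d"), c("f1", "f2")))
#' labs <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
#'                        stage = c("I", "I", "II", "II"))
#' ds <- assemble_dataset(list(omics_view(m1, "mrna")), labs)
#' ds$sample_ids
assemble_dataset <- function(views, labels) {
  if (inherits(views, "omics_view")) {
    views <- list(views)
  }
  if (length(views) < 1 || length(views) > 3) {
    abort("Between 1 and 3 views are supported.", class = "spidnmf_error_dataset")
  }
  if (!all(vapply(views, inherits, logical(1), "omics_view"))) {
    abort("Every element of `views` must be an omics_view.",
          class = "spidnmf_error_dataset")
  }
  label_map <- as_label_map(labels)
  common <- Reduce(intersect, c(lapply(views, rownames), list(names(label_map))))
  if (length(common) == 0) {
    abort("The views and label map share no sample ids.",
          class = "spidnmf_error_empty_intersection")
  }
  common <- sort(common)
  if (length(common) < 2) {
    abort("At least 2 common samples are required.",
          class = "spidnmf_error_dataset")
  }
  aligned <- lapply(views, function(v) {
    omics_view(unclass(v)[common, , drop = FALSE], view_id(v))
  })
  nm <- names(views)
  auto <- vapply(aligned, view_id, character(1))
  if (is.null(nm)) nm <- auto
  nm[!nzchar(nm)] <- auto[!nzchar(nm)]
  if (anyDuplicated(nm)) {
    nm <- make.unique(nm)
  }
  names(aligned) <- nm
  structure(
    list(views = aligned, stage = label_map[common], sample_ids = common),
    class = "multiview_dataset"
  )
}

#' @export
print.multiview_dataset <- function(x, ...) {
  cat(sprintf("<multiview_dataset: %d samples, %d view(s)>\n",
              length(x$sample_ids), length(x$views)))
  for (nm in names(x$views)) {
    cat(sprintf("  %-6s %d features\n", nm, ncol(x$views[[nm]])))
  }
  cat("  stages:", paste(sprintf("%s (%d)", names(table(x$stage)),
                                 table(x$stage)), collapse = ", "), "\n")
  invisible(x)
}

n_samples <- function(dataset) length(dataset$sample_ids)

# bare matrices of a dataset, in view order
dataset_matrices <- function(dataset) {
  lapply(dataset$views, function(v) {
    m <- unclass(v)
    attr(m, "view_id") <- NULL
    m
  })
}

#' Read per-sample stage labels
#'
#' Two-column delimited file (`sample_id`, `stage`); delimiter auto-detected.
#'
#' @param path Path to the label file.
#' @return A tibble with columns `sample_id` and `stage`.
#' @export
read_stage_labels <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'.", path), class = "spidnmf_error_io")
  }
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  tibble(sample_id = as.character(df[[1]]), stage = as.character(df[[2]]))
}

#' Read a survival table
#'
#' Three-column delimited file (`sample_id`, `time_days`, `event`); times
#' must be positive and finite, events coded 0/1 (1 = death observed).
#'
#' @param path Path to the survival file.
#' @return A tibble with columns `sample_id`, `time`, `event`.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'.", path), class = "spidnmf_error_io")
  }
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_survival(tibble(
    sample_id = as.character(df[[1]]),
    time = as.numeric(df[[2]]),
    event = as.numeric(df[[3]])
  ))
}

validate_survival <- function(surv) {
  if (!all(c("sample_id", "time", "event") %in% names(surv))) {
    abort("Survival tables need columns sample_id, time, event.",
          class = "spidnmf_error_survival")
  }
  if (any(!is.finite(surv$time)) || any(surv$time <= 0)) {
    abort("Survival times must be positive and finite.",
          class = "spidnmf_error_survival")
  }
  if (!all(surv$event %in% c(0, 1))) {
    abort("Events must be coded 0/1.", class = "spidnmf_error_survival")
  }
  surv
}
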