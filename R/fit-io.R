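#' Serialize a fitted model to delimited text files
#'
#' Writes `W.tsv` (samples x factors), one `H_<view>.tsv` per view, and a
#' key-value `manifest.txt` recording the method, hyperparameters, stop
#' reason and the per-iteration trajectories, so a run can be inspected or
#' reproduced without R objects.
#'
#' @param fit A `jnmf_fit`.
#' @param dir Output directory (created if needed).
#'
#' @return `dir`, invisibly.
#' @export
write_jnmf_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "jnmf_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(fit$W, file.path(dir, "W.tsv"), id_col = "sample_id")
  for (vn in names(fit$H)) {
    write_matrix_tsv(fit$H[[vn]], file.path(dir, sprintf("H_%s.tsv", vn)),
                     id_col = "factor")
  }
  r <- fit$report
  hp <- fit$hp
  kv <- c(
    sprintf("method=%s", fit$method),
    sprintf("%s=%s", names(unclass(hp)),
            vapply(unclass(hp), function(v) sprintf("%.17g", as.numeric(v)),
                   character(1))),
    sprintf("iterations=%d", r$iterations),
    sprintf("converged=%s", r$converged),
    sprintf("stop_reason=%s", r$stop_reason),
    sprintf("objective_trajectory=%s",
            paste(sprintf("%.17g", r$objective_trajectory), collapse = ",")),
    sprintf("relative_error_trajectory=%s",
            paste(sprintf("%.17g", r$relative_error_trajectory), collapse = ","))
  )
  writeLines(kv, file.path(dir, "manifest.txt"))
  invisible(dir)
}

write_matrix_tsv <- function(m, path, id_col = "id") {
  body <- apply(m, c(1, 2), function(v) sprintf("%.17g", v))
  lines <- c(
    paste(c(id_col, colnames(m)), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], body[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
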