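# the ten cell-level features extracted from each segmented nucleus:
# morphology (area, axis lengths and their ratio), mean RGB intensity, and
# distances to neighbouring nuclei
WSI_CELL_FEATURES <- c("area", "major", "minor", "ratio",
                       "rMean", "gMean", "bMean",
                       "distMean", "distMax", "distMin")

#' Default per-feature histogram bin edges (cohort deciles)
#'
#' Computes the nine interior decile edges per cell-level feature over the
#' whole nucleus table, defining ten bins with open-ended outer bins. Using
#' cohort-wide deciles makes `<feature>_bin1` the fraction of a patient's
#' nuclei falling in the cohort's smallest decile (e.g. `area_bin1` =
#' fraction of extremely small nuclei). Supply the returned edges to
#' [aggregate_cell_features()] for cross-cohort comparability.
#'
#' @param cells A nucleus table, see [aggregate_cell_features()].
#' @return A named list of numeric length-9 edge vectors.
#' @export
wsi_bin_edges <- function(cells) {
  check_cell_table(cells)
  lapply(setNames(WSI_CELL_FEATURES, WSI_CELL_FEATURES), function(f) {
    unname(quantile(cells[[f]], probs = seq(0.1, 0.9, by = 0.1)))
  })
}

check_cell_table <- function(cells) {
  if (!is.data.frame(cells) || nrow(cells) == 0) {
    abort("The nucleus table must be a non-empty data frame.",
          class = "spidnmf_error_wsi")
  }
  missing <- setdiff(c("patient_id", WSI_CELL_FEATURES), names(cells))
  if (length(missing) > 0) {
    abort(sprintf("Nucleus table is missing column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "spidnmf_error_wsi")
  }
  vals <- as.matrix(cells[WSI_CELL_FEATURES])
  if (!all(is.finite(vals))) {
    abort("Non-finite cell-level feature value.", class = "spidnmf_error_wsi")
  }
  invisible(cells)
}

#' Aggregate per-nucleus features to patient-level image features
#'
#' Whole-slide images are represented by distributions of per-nucleus
#' measurements. For each of the ten cell-level features (`area`, `major`,
#' `minor`, `ratio`, `rMean`, `gMean`, `bMean`, `distMean`, `distMax`,
#' `distMin`), each patient's nuclei are summarised by ten histogram
#' fractions over fixed bin edges (outer bins open-ended; fractions sum to
#' 1) plus five summary statistics (mean, sd, median, min, max), giving
#' 10 x 15 = 150 patient-level features named `<feature>_bin1` ..
#' `<feature>_bin10`, `<feature>_mean`, `<feature>_sd`, `<feature>_median`,
#' `<feature>_min`, `<feature>_max`. A single-nucleus patient gets sd = 0.
#'
#' @param cells A data frame with one row per segmented nucleus: a
#'   `patient_id` column plus the ten cell-level feature columns.
#' @param bin_edges Named list of length-9 interior edge vectors per
#'   feature; defaults to cohort deciles via [wsi_bin_edges()].
#'
#' @return A tibble with one row per patient: `patient_id` plus 150
#'   feature columns. Convert with [as_omics_view()] to use as the image
#'   view of a dataset.
#' @export
#'
#' @examples
#' cells <- simulate_cell_table(n_patients = 3, nuclei_per_patient = 40,
#'                              seed = 1)
#' pf <- aggregate_cell_features(cells)
#' ncol(pf) - 1 # 150
aggregate_cell_features <- function(cells, bin_edges = NULL) {
  check_cell_table(cells)
  if (is.null(bin_edges)) {
    bin_edges <- wsi_bin_edges(cells)
  }
  for (f in WSI_CELL_FEATURES) {
    e <- bin_edges[[f]]
    if (is.null(e) || length(e) != 9 || is.unsorted(e)) {
      abort(sprintf("Bin edges for '%s' must be 9 non-decreasing interior edges.", f),
            class = "spidnmf_error_wsi")
    }
  }
  cells |>
    dplyr::group_by(patient_id = as.character(.data$patient_id)) |>
    dplyr::group_modify(function(df, key) {
      out <- unlist(lapply(WSI_CELL_FEATURES, function(f) {
        x <- df[[f]]
        counts <- tabulate(findInterval(x, bin_edges[[f]],
                                        left.open = TRUE) + 1L, nbins = 10L)
        stats <- c(mean(x), if (length(x) > 1) sd(x) else 0,
                   median(x), min(x), max(x))
        setNames(c(counts / length(x), stats),
                 paste0(f, "_", c(paste0("bin", 1:10),
                                  "mean", "sd", "median", "min", "max")))
      }))
      as_tibble(as.list(out))
    }) |>
    dplyr::ungroup()
}

#' Simulate a per-nucleus cell-feature table
#'
#' Generates plausible nucleus-level measurements (log-normal sizes,
#' bounded intensities, positive distances) for testing the patient-level
#' aggregation; it makes no attempt to emulate real segmentation output.
#'
#' @param n_patients Number of patients.
#' @param nuclei_per_patient Nuclei per patient (recycled).
#' @param seed Optional integer seed.
#'
#' @return A tibble with `patient_id` and the ten cell-level features.
#' @export
simulate_cell_table <- function(n_patients = 5, nuclei_per_patient = 100,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nn <- rep_len(nuclei_per_patient, n_patients)
  purrr::map_dfr(seq_len(n_patients), function(i) {
    n <- nn[i]
    major <- exp(rnorm(n, log(12), 0.3))
    minor <- major * runif(n, 0.4, 1)
    dmean <- exp(rnorm(n, log(25), 0.25))
    tibble(
      patient_id = sprintf("P%02d", i),
      area = pi * major * minor / 4,
      major = major,
      minor = minor,
      ratio = major / minor,
      rMean = runif(n, 80, 200),
      gMean = runif(n, 60, 180),
      bMean = runif(n, 100, 220),
      distMean = dmean,
      distMax = dmean * runif(n, 1, 1.8),
      distMin = dmean * runif(n, 0.3, 1)
    )
  })
}
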