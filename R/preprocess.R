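#' Expression matrix container
#'
#' Bundles one organ's transcripts-by-time-points value matrix (normalised
#' log scale) with its same-shape 0/1 detection mask ("signal above local
#' background") and the sampling design.
#'
#' @param organ organ label.
#' @param values numeric matrix, rows = transcripts (unique rownames),
#'   columns = time points.
#' @param detected 0/1 matrix of identical shape.
#' @param design a [diel_design()] whose time points match the columns.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(organ, values, detected, design) {
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    rhythmod_stop("preprocess", "values must have unique rownames")
  }
  if (!all(dim(values) == dim(detected))) {
    rhythmod_stop("preprocess", "values and detected must have identical shape")
  }
  if (ncol(values) != length(design$sample_times_zt)) {
    rhythmod_stop("preprocess", "column count does not match the design")
  }
  structure(list(organ = organ, values = values,
                 detected = detected, design = design),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: organ %s, %d transcripts x %d time points (%.1f%% detected)\n",
              x$organ, nrow(x$values), ncol(x$values), 100 * mean(x$detected)))
  invisible(x)
}

#' Expression call from the detection mask
#'
#' A transcript is considered expressed when its signal is distinguishable
#' from background in at least `min_detected_timepoints` samples; the default
#' of 8 encodes "more than 7 of the 14 time points".
#'
#' @param matrix an [expression_matrix()].
#' @param min_detected_timepoints minimum detected time points (default 8).
#' @return character vector of expressed transcript ids.
#' @export
call_expressed <- function(matrix, min_detected_timepoints = 8) {
  n_tp <- ncol(matrix$detected)
  if (min_detected_timepoints < 1 || min_detected_timepoints > n_tp) {
    rhythmod_stop("preprocess", "min_detected_timepoints out of range")
  }
  rownames(matrix$detected)[rowSums(matrix$detected) >= min_detected_timepoints]
}

#' Z-score a time series
#'
#' Centres to mean 0 and scales to sample (n-1) standard deviation 1.
#' Constant series have no defined Z-score and raise a condition of class
#' `rhythmod_degenerate` rather than being silently zeroed.
#'
#' @param series numeric vector, length >= 2.
#' @return standardised numeric vector.
#' @export
zscore_series <- function(series) {
  if (length(series) < 2) rhythmod_stop("preprocess", "series too short")
  s <- stats::sd(series)
  if (!is.finite(s) || s == 0) {
    rhythmod_stop("preprocess", "constant series has no Z-score",
                  class = "rhythmod_degenerate")
  }
  (series - mean(series)) / s
}

# Row-wise Z-score of a matrix; degenerate (constant) rows are dropped with a
# message and recorded in attr(, "degenerate").
zscore_matrix <- function(values) {
  sds <- apply(values, 1, stats::sd)
  bad <- !is.finite(sds) | sds == 0
  if (any(bad)) {
    message(sprintf("excluding %d degenerate (constant) series: %s",
                    sum(bad), paste(utils::head(rownames(values)[bad], 5),
                                    collapse = ", ")))
  }
  z <- (values[!bad, , drop = FALSE] -
          rowMeans(values[!bad, , drop = FALSE])) / sds[!bad]
  attr(z, "degenerate") <- rownames(values)[bad]
  z
}

#' Intensity-dependent LOWESS normalisation of two-colour log-ratios
#'
#' Removes the intensity-dependent dye-bias trend from per-array (M, A)
#' pairs (M = log-ratio, A = mean log-intensity) by subtracting a locally
#' weighted regression fit of M on A, the standard within-array normalisation
#' for two-colour microarrays.
#'
#' @param M log-ratios.
#' @param A mean log-intensities (same length, >= 10 pairs).
#' @param span LOWESS smoother span in (0, 1].
#' @return corrected log-ratios `M - fit(A)`.
#' @export
lowess_normalize <- function(M, A, span = 2 / 3) {
  if (length(M) != length(A)) rhythmod_stop("preprocess", "M and A lengths differ")
  if (length(M) < 10) rhythmod_stop("preprocess", "need at least 10 (M, A) pairs")
  if (span <= 0 || span > 1) rhythmod_stop("preprocess", "span must be in (0, 1]")
  fit <- stats::lowess(A, M, f = span)
  M - stats::approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
}

#' Average replicate expression matrices
#'
#' Per-cell mean of the replicate values; a cell counts as detected if it is
#' detected in any replicate.  Replicate order does not matter.
#'
#' @param replicates list of [expression_matrix()] objects with identical
#'   transcripts and time points.
#' @return a single [expression_matrix()].
#' @export
collapse_replicates <- function(replicates) {
  if (length(replicates) == 0) rhythmod_stop("preprocess", "no replicates given")
  ref <- replicates[[1]]
  for (r in replicates[-1]) {
    if (!identical(rownames(r$values), rownames(ref$values)) ||
        !identical(colnames(r$values), colnames(ref$values))) {
      rhythmod_stop("preprocess", "replicate ids/time points do not match")
    }
  }
  values <- Reduce(`+`, lapply(replicates, `[[`, "values")) / length(replicates)
  detected <- 1 * (Reduce(`+`, lapply(replicates, `[[`, "detected")) > 0)
  expression_matrix(ref$organ, values, detected, ref$design)
}
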