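#' Per-gene expression z-scores across all samples
#'
#' Standardizes each gene relative to its average expression level across
#' every sample in the cohort: `z = (x - mean) / sd`. The scale uses the
#' sample standard deviation (denominator n - 1) by default; set
#' `sample_sd = FALSE` for the population denominator n. Missing cells are
#' excluded from the per-gene mean/sd and stay missing in the output.
#' Zero-variance genes yield an all-zero z row with a warning.
#'
#' @param expr genes x samples numeric matrix.
#' @param sample_sd use the n - 1 denominator (default TRUE).
#' @return z-score matrix of the same shape and dimnames.
#' @export
compute_zscores <- function(expr, sample_sd = TRUE) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (ncol(expr) < 2) stopf("z-scores need >= 2 samples (got %d)", ncol(expr))
  mu <- rowMeans(expr, na.rm = TRUE)
  nobs <- rowSums(!is.na(expr))
  ss <- rowSums((expr - mu)^2, na.rm = TRUE)
  denom <- if (sample_sd) pmax(nobs - 1, 1) else pmax(nobs, 1)
  sd <- sqrt(ss / denom)
  flat <- sd == 0 | nobs < 2
  if (any(flat))
    warnf("gene(s) with zero variance get all-zero z-scores: %s",
          paste(rownames(expr)[flat], collapse = ", "))
  sd[flat] <- Inf  # (x - mu)/Inf -> 0 while preserving NA positions
  (expr - mu) / sd
}

#' Call aberrant expression from z-scores
#'
#' A (gene, sample) cell is aberrant when the absolute z-score strictly
#' exceeds the threshold (default 2). Missing z-scores are never aberrant.
#'
#' @param z z-score matrix (genes x samples).
#' @param threshold positive z-unit cutoff; strict inequality `|z| > t`.
#' @return logical matrix of the same shape; `threshold` attribute records
#'   the cutoff used.
#' @export
call_aberrant <- function(z, threshold = 2) {
  stopifnot(is.matrix(z))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stopf("threshold must be a single positive number")
  ab <- abs(z) > threshold
  ab[is.na(ab)] <- FALSE
  attr(ab, "threshold") <- threshold
  ab
}

#' Per-sample any-aberrant label over a gene panel
#'
#' A sample is labeled aberrant when at least one panel gene is aberrant in
#' that sample; this is the binarization used to split cohorts for
#' Kaplan-Meier comparison.
#'
#' @param ab logical aberrance matrix (genes x samples).
#' @param panel character vector of gene symbols; all must be rows of `ab`.
#' @return named logical vector over samples.
#' @export
panel_aberrance <- function(ab, panel) {
  stopifnot(is.matrix(ab), is.logical(ab))
  panel <- as.character(panel)
  missing <- setdiff(panel, rownames(ab))
  if (length(missing))
    stopf("panel gene(s) absent from aberrance matrix: %s",
          paste(missing, collapse = ", "))
  colSums(ab[panel, , drop = FALSE]) > 0
}
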