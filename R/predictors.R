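#' Random-selection baseline survival predictor
#'
#' Leave-one-out random selection: for each evaluable patient P the
#' predictor draws a survival time uniformly from the other evaluable
#' patients' observed times, repeats the draw `n_reps` times, and reports
#' the mean of the draws as the point prediction. Evaluation is restricted
#' to uncensored (deceased) patients, whose observed months are true
#' survival from diagnosis to death; censored times would corrupt both the
#' candidate pool and the residuals.
#'
#' @param clinical clinical table (see [read_clinical()]).
#' @param n_reps number of random draws per patient (default 100).
#' @param seed integer seed.
#' @return object of class `survival_prediction`: data.frame with
#'   sample_id, predicted_months, observed_months, residual (against the
#'   mean-of-draws point prediction); attributes `method`,
#'   `rep_median_residuals` (the median residual of each replicate's
#'   single-draw predictions), `mean_rep_median_residual` (their mean —
#'   the estimator's error level, since averaging the draws before taking
#'   residuals would understate the error of a random selection), and
#'   `draw_residuals` (the first replicate's residuals, a fair single-draw
#'   residual set for distributional comparisons against other
#'   predictors).
#' @export
random_baseline <- function(clinical, n_reps = 100, seed = 1L) {
  ev <- clinical[clinical$event & !is.na(clinical$os_months), , drop = FALSE]
  n <- nrow(ev)
  if (n < 2) stopf("random baseline needs >= 2 uncensored samples (got %d)", n)
  obs <- ev$os_months
  draws <- with_seed(stage_seed(seed, "baseline"), {
    vapply(seq_len(n), function(i) {
      pool <- obs[-i]                    # sample indices: a length-1 pool
      pool[sample.int(n - 1, n_reps, replace = TRUE)]  # must stay a pool
    }, numeric(n_reps))
  })                                     # n_reps x n
  pred <- colMeans(draws)
  resid_mat <- abs(draws - rep(obs, each = n_reps))   # n_reps x n
  rep_med <- apply(resid_mat, 1, stats::median)
  new_prediction(ev$sample_id, pred, obs, method = "random_baseline",
                 rep_median_residuals = rep_med,
                 mean_rep_median_residual = mean(rep_med),
                 draw_residuals = resid_mat[1, ])
}

#' Leave-one-out nearest-neighbor survival predictor
#'
#' For each evaluable sample S, finds the other evaluable sample T whose
#' panel-gene expression profile is closest to S in Euclidean distance and
#' predicts T's observed survival. All panel genes carry equal weight, so
#' distances are taken on the z-score scale. Ties are broken by the
#' lexicographically smallest sample id, making predictions invariant to
#' sample order.
#'
#' @param z z-score matrix (genes x samples).
#' @param panel character vector of panel genes (rows of `z`).
#' @param clinical clinical table; sample ids must appear in `colnames(z)`.
#' @param include_censored_neighbors also allow censored patients as
#'   neighbor candidates (their observed months then serve as the
#'   prediction); default FALSE.
#' @return a `survival_prediction` (see [random_baseline()]), with a
#'   `neighbor` column recording each sample's matched neighbor.
#' @export
one_nn_predict <- function(z, panel, clinical,
                           include_censored_neighbors = FALSE) {
  panel <- as.character(panel)
  missing <- setdiff(panel, rownames(z))
  if (length(missing))
    stopf("panel gene(s) absent from z-score matrix: %s",
          paste(missing, collapse = ", "))
  keep <- clinical$sample_id %in% colnames(z)
  cl <- clinical[keep, , drop = FALSE]
  ev <- cl[cl$event & !is.na(cl$os_months), , drop = FALSE]
  if (nrow(ev) < 2) stopf("1NN needs >= 2 uncensored samples (got %d)", nrow(ev))
  pool <- if (include_censored_neighbors) cl else ev
  x <- z[panel, pool$sample_id, drop = FALSE]
  if (anyNA(x))
    stopf("missing z-scores in panel genes; impute or drop before 1NN")
  # order candidates by id once so which.min's first-hit rule = lexicographic
  ord <- order(pool$sample_id)
  pool <- pool[ord, , drop = FALSE]
  x <- x[, ord, drop = FALSE]
  pred <- numeric(nrow(ev))
  nb <- character(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    s <- ev$sample_id[i]
    d2 <- colSums((x - z[panel, s])^2)
    d2[pool$sample_id == s] <- Inf
    j <- which.min(d2)
    nb[i] <- pool$sample_id[j]
    pred[i] <- pool$os_months[j]
  }
  out <- new_prediction(ev$sample_id, pred, ev$os_months, method = "1nn")
  out$neighbor <- nb
  out
}

new_prediction <- function(id, pred, obs, method, ...) {
  out <- data.frame(sample_id = id, predicted_months = pred,
                    observed_months = obs, residual = abs(pred - obs),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("survival_prediction", "data.frame")
  out
}

#' Median absolute residual of a survival predictor
#'
#' Median of `|predicted - observed|` in months; for even n, the mean of
#' the two central order statistics.
#'
#' @param pred a `survival_prediction` or a numeric vector of residuals.
#' @return median residual in months.
#' @export
median_residual <- function(pred) {
  r <- if (inherits(pred, "survival_prediction")) pred$residual else
    as.numeric(pred)
  if (!length(r)) stopf("no residuals to summarize")
  stats::median(r)
}

#' Mann-Whitney U comparison of two residual sets
#'
#' Two-sided nonparametric test that two predictors' absolute-residual
#' distributions share a location. When both samples have at most 8 values
#' the null distribution of U is enumerated exactly over all
#' `choose(m + n, m)` group assignments (ties handled exactly); otherwise
#' the normal approximation with tie-corrected variance is used.
#'
#' @param a,b `survival_prediction` objects or numeric residual vectors.
#' @return two-sided p-value.
#' @export
compare_residuals <- function(a, b) {
  ra <- if (inherits(a, "survival_prediction")) a$residual else as.numeric(a)
  rb <- if (inherits(b, "survival_prediction")) b$residual else as.numeric(b)
  m <- length(ra); n <- length(rb)
  if (!m || !n) stopf("both residual sets must be nonempty")
  pooled <- c(ra, rb)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  if (m <= 8 && n <= 8) {
    # exact two-sided p by enumerating all group assignments of the pool
    idx <- utils::combn(m + n, m)
    us <- apply(idx, 2, function(ii) sum(rk[ii])) - m * (m + 1) / 2
    return(mean(abs(us - mu) >= abs(u - mu) - 1e-9))
  }
  N <- m + n
  ties <- table(pooled)
  sig2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sig2 <= 0) return(1)
  p <- 2 * stats::pnorm(-abs(u - mu) / sqrt(sig2))
  min(1, p)
}

#' Pearson correlation between predictions (or risks) and survival
#'
#' `r1` correlates observed with predicted survival months; `r2` correlates
#' Cox relative risks with observed survival, where a negative value is the
#' expected direction (higher risk, shorter survival).
#'
#' @param x,y numeric vectors of equal length (>= 3 pairs).
#' @return Pearson r in \[-1, 1\]; NA with a warning when either input has
#'   zero variance.
#' @export
prediction_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stopf("correlation needs >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warnf("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' @export
print.survival_prediction <- function(x, ...) {
  cat(sprintf("survival_prediction (%s): %d samples, median residual %.2f months\n",
              attr(x, "method"), nrow(x), median_residual(x)))
  invisible(x)
}
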