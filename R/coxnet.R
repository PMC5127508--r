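# Elastic-net penalized Cox proportional hazards, fit by cyclic coordinate
# descent on the iteratively reweighted least-squares approximation of the
# Breslow partial likelihood (the glmnet-family algorithm). The objective
# minimized at each lambda is
#
#   f(beta) = -(1/n) * pll(X beta) + lambda * (alpha*||beta||_1
#                                              + (1-alpha)/2*||beta||_2^2)
#
# with pll the Breslow-tie log partial likelihood. Covariates are expected
# on the z-score scale already; no internal re-standardization is applied.

# Precompute sorting structures shared by every likelihood evaluation.
cox_setup <- function(time, event) {
  if (any(!is.finite(time)) || any(time < 0)) stopf("times must be finite and >= 0")
  event <- as.logical(event)
  if (sum(event) < 1) stopf("penalized Cox needs at least one event")
  o <- order(time)
  ts <- time[o]; ds <- event[o]
  ut <- unique(ts[ds])                       # distinct event times, ascending
  dk <- as.numeric(table(factor(ts[ds], levels = ut)))
  first_at_risk <- findInterval(ut, ts, left.open = TRUE) + 1L
  k_of_sample <- findInterval(ts, ut)        # events with ut <= ts_j
  list(o = o, ts = ts, ds = ds, ut = ut, dk = dk,
       first_at_risk = first_at_risk, k_of_sample = k_of_sample,
       n = length(time))
}

# Breslow log partial likelihood, gradient and diagonal Hessian in eta,
# all in original sample order.
cox_quantities <- function(eta, su) {
  es <- eta[su$o]
  c0 <- max(es)
  theta <- exp(es - c0)
  revcum <- rev(cumsum(rev(theta)))
  Sk <- revcum[su$first_at_risk]
  cum_dS <- c(0, cumsum(su$dk / Sk))
  cum_dS2 <- c(0, cumsum(su$dk / Sk^2))
  A <- cum_dS[su$k_of_sample + 1L]
  B <- cum_dS2[su$k_of_sample + 1L]
  g_s <- as.numeric(su$ds) - theta * A
  w_s <- theta * A - theta^2 * B
  ll <- sum(es[su$ds]) - sum(su$dk * (log(Sk) + c0))
  g <- numeric(su$n); g[su$o] <- g_s
  w <- numeric(su$n); w[su$o] <- w_s
  list(loglik = ll, grad = g, weight = w)
}

# Log partial likelihood at given coefficients (used for CV deviance).
cox_pll <- function(X, time, event, beta) {
  su <- cox_setup(time, event)
  eta <- as.numeric(X %*% beta)
  .cox_pll_cpp(eta[su$o], su$ds, su$dk, su$first_at_risk, su$k_of_sample)
}

penalty_value <- function(beta, alpha) {
  alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2)
}

# The per-lambda solver (outer IRLS + inner cyclic coordinate descent with
# step halving) lives in src/coxnet_cd.cpp; cox_quantities above is retained
# for the lambda_max gradient and as a readable reference of the same
# derivatives.

#' Fit an elastic-net penalized Cox path by coordinate descent
#'
#' Minimizes the penalized negative Breslow partial log-likelihood over a
#' decreasing, log-spaced lambda path starting at the smallest lambda that
#' zeroes every coefficient, warm-starting each solution from the previous
#' one. Each lambda is solved by iteratively reweighted least squares with
#' coordinate-wise soft-thresholding; step halving enforces monotone
#' descent of the penalized objective.
#'
#' @param z genes x samples z-score matrix (covariates enter unscaled).
#' @param time observed survival months.
#' @param event logical event indicator (TRUE = death observed).
#' @param panel optional subset of genes (default: all rows of `z`).
#' @param alpha elastic-net mixing in (0, 1\]; 1 is the lasso. Default 0.95.
#' @param nlambda path length (default 100).
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max
#'   (default 0.01).
#' @param lambda optional user lambda sequence (decreasing); overrides the
#'   automatic path.
#' @param tol relative objective-change convergence tolerance (default 1e-7).
#' @param max_sweeps cap on coordinate-descent sweeps per lambda
#'   (default 10000).
#' @param dfmax stop the automatic path once this many coefficients are
#'   nonzero; defaults to the number of events, since a near-saturated Cox
#'   fit with more parameters than events is unstable and statistically
#'   meaningless. Ignored (no limit) when an explicit `lambda` sequence is
#'   supplied, unless set.
#' @param on_nonconverge `"error"` (default for explicit `lambda`) or
#'   `"truncate"` (default for the automatic path): what to do when a
#'   lambda does not converge within `max_sweeps` — truncation drops that
#'   lambda and the rest of the path with a warning.
#' @return object of class `coxnet_path`: list with `lambda`, `beta`
#'   (genes x nlambda), `objective`, `nonzero`, `alpha`, `genes`, plus the
#'   per-lambda objective traces (each non-increasing).
#' @export
coxnet_fit <- function(z, time, event, panel = NULL, alpha = 0.95,
                       nlambda = 100, lambda_min_ratio = 0.01,
                       lambda = NULL, tol = 1e-7, max_sweeps = 10000,
                       dfmax = NULL, on_nonconverge = NULL) {
  stopifnot(is.matrix(z))
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stopf("alpha must lie in (0, 1]")
  if (is.null(panel)) panel <- rownames(z)
  missing <- setdiff(panel, rownames(z))
  if (length(missing))
    stopf("panel gene(s) absent from z matrix: %s", paste(missing, collapse = ", "))
  X <- t(z[panel, , drop = FALSE])
  if (anyNA(X) || any(!is.finite(X))) stopf("covariates contain non-finite values")
  n <- nrow(X)
  if (length(time) != n || length(event) != n)
    stopf("time/event length must match number of samples")
  if (sum(event) < 2) stopf("need >= 2 events to fit a Cox path")
  su <- cox_setup(time, event)
  g0 <- cox_quantities(numeric(n), su)$grad
  lmax <- max(abs(crossprod(X, g0))) / (n * alpha)
  auto_path <- is.null(lambda)
  if (auto_path) {
    # tiny upward nudge keeps beta = 0 exact at the first lambda despite
    # floating-point equality in the KKT condition
    lambda <- exp(seq(log(lmax * (1 + 1e-6)),
                      log(lmax * lambda_min_ratio), length.out = nlambda))
  } else {
    lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  }
  if (is.null(dfmax)) dfmax <- if (auto_path) sum(event) else 0L
  if (is.null(on_nonconverge))
    on_nonconverge <- if (auto_path) "truncate" else "error"
  on_nonconverge <- match.arg(on_nonconverge, c("error", "truncate"))
  sol <- .coxnet_path_cpp(X[su$o, , drop = FALSE], su$ds, su$dk,
                          su$first_at_risk, su$k_of_sample, lambda,
                          alpha, tol, as.integer(max_sweeps),
                          as.integer(dfmax),
                          on_nonconverge == "error")
  used <- seq_len(sol$n_used)
  if (sol$n_used < length(lambda)) {
    df_stop <- dfmax > 0 && sum(sol$beta[, sol$n_used] != 0) >= dfmax
    if (!df_stop)   # df-capped truncation is by design; this one is not
      warnf("path truncated at %d of %d lambdas (no convergence beyond)",
            sol$n_used, length(lambda))
  }
  beta_mat <- sol$beta[, used, drop = FALSE]
  dimnames(beta_mat) <- list(panel, NULL)
  structure(list(lambda = lambda[used], beta = beta_mat,
                 objective = as.numeric(sol$objective)[used],
                 obj_traces = sol$obj_traces[used],
                 nonzero = colSums(beta_mat != 0),
                 alpha = alpha, genes = panel, n = n, n_event = sum(event)),
            class = "coxnet_path")
}

#' Cross-validated lambda selection for the penalized Cox path
#'
#' Ten-fold (by default) cross-validation with folds stratified by event
#' status, scoring each lambda by the Verweij-van Houwelingen
#' cross-validated partial-likelihood deviance: for fold k with coefficients
#' beta_(-k) fit without it, the contribution is
#' `-2 * (pll_all(beta_(-k)) - pll_train(beta_(-k)))`. The selected lambda
#' minimizes the mean deviance curve; selected genes are those with nonzero
#' coefficients at that lambda on the full-data path, ordered by decreasing
#' |coefficient|.
#'
#' @inheritParams coxnet_fit
#' @param nfolds number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return object of class `coxnet_cv`: list with `lambda`, `cvm` (mean
#'   deviance), `cvsd`, `fold_deviance`, `lambda_min`, `selected`
#'   (data.frame gene/coefficient, |coefficient| decreasing), and `fit`
#'   (the full-data `coxnet_path`).
#' @export
coxnet_cv <- function(z, time, event, panel = NULL, alpha = 0.95,
                      nlambda = 100, lambda_min_ratio = 0.01, nfolds = 10,
                      tol = 1e-7, max_sweeps = 10000, seed = 1L) {
  if (is.null(panel)) panel <- rownames(z)
  n <- length(time)
  if (n < nfolds) stopf("nfolds (%d) exceeds sample size (%d)", nfolds, n)
  event <- as.logical(event)
  if (sum(event) < nfolds)
    stopf(paste0("only %d events for %d folds; every fold needs an event - ",
                 "use fewer folds"), sum(event), nfolds)
  full <- coxnet_fit(z, time, event, panel = panel, alpha = alpha,
                     nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
                     tol = tol, max_sweeps = max_sweeps)
  folds <- with_seed(stage_seed(seed, "folds"), {
    f <- integer(n)
    f[event] <- sample(rep_len(seq_len(nfolds), sum(event)))
    f[!event] <- sample(rep_len(seq_len(nfolds), sum(!event)))
    f
  })
  X_all <- t(z[panel, , drop = FALSE])
  dev <- matrix(NA_real_, length(full$lambda), nfolds)
  for (k in seq_len(nfolds)) {
    tr <- folds != k
    fit_k <- coxnet_fit(z[, tr, drop = FALSE], time[tr], event[tr],
                        panel = panel, alpha = alpha, lambda = full$lambda,
                        tol = tol, max_sweeps = max_sweeps,
                        dfmax = sum(event[tr]), on_nonconverge = "truncate")
    for (l in seq_along(fit_k$lambda)) {
      b <- fit_k$beta[, l]
      pll_all <- cox_pll(X_all, time, event, b)
      pll_tr <- cox_pll(X_all[tr, , drop = FALSE], time[tr], event[tr], b)
      dev[l, k] <- -2 * (pll_all - pll_tr)
    }
  }
  # score only lambdas every fold reached (folds may truncate near
  # saturation, where the penalty is too weak for their event count)
  complete <- rowSums(is.na(dev)) == 0
  cvm <- ifelse(complete, rowMeans(dev), NA_real_)
  cvsd <- ifelse(complete, apply(dev, 1, stats::sd) / sqrt(nfolds), NA_real_)
  imin <- which.min(cvm)
  selected <- select_features(full, full$lambda[imin])
  structure(list(lambda = full$lambda, cvm = cvm, cvsd = cvsd,
                 fold_deviance = dev, lambda_min = full$lambda[imin],
                 selected = selected, fit = full, nfolds = nfolds,
                 folds = folds, seed = seed),
            class = "coxnet_cv")
}

#' Genes with nonzero coefficients at a lambda on a fitted path
#'
#' @param path a `coxnet_path`.
#' @param lambda a lambda value on the path (matched with relative
#'   tolerance 1e-8).
#' @return data.frame with columns `gene` and `coefficient`, ordered by
#'   decreasing |coefficient|.
#' @export
select_features <- function(path, lambda) {
  stopifnot(inherits(path, "coxnet_path"))
  i <- match_lambda(lambda, path$lambda)
  if (is.na(i)) stopf("lambda %g is not on the fitted path", lambda)
  b <- path$beta[, i]
  nz <- b[b != 0]
  nz <- nz[order(-abs(nz))]
  data.frame(gene = names(nz), coefficient = unname(nz),
             stringsAsFactors = FALSE)
}

#' Per-sample relative risk exp(x . beta)
#'
#' @param beta named coefficient vector, or the `selected` data.frame of a
#'   [coxnet_cv()] result.
#' @param z genes x samples z-score matrix containing all coefficient genes.
#' @return named numeric vector of risks, one per sample (all 1 when beta
#'   is empty or all zero).
#' @export
relative_risk <- function(beta, z) {
  if (is.data.frame(beta)) beta <- stats::setNames(beta$coefficient, beta$gene)
  if (!length(beta)) return(stats::setNames(rep(1, ncol(z)), colnames(z)))
  missing <- setdiff(names(beta), rownames(z))
  if (length(missing))
    stopf("coefficient gene(s) absent from z matrix: %s",
          paste(missing, collapse = ", "))
  risks <- exp(as.numeric(crossprod(z[names(beta), , drop = FALSE], beta)))
  stats::setNames(risks, colnames(z))
}

#' @export
print.coxnet_path <- function(x, ...) {
  cat(sprintf("coxnet_path: %d genes, %d lambdas (%.3g .. %.3g), alpha = %.2f\n",
              length(x$genes), length(x$lambda), x$lambda[1],
              x$lambda[length(x$lambda)], x$alpha))
  cat(sprintf("nonzero coefficients: %d (densest) .. %d (sparsest)\n",
              max(x$nonzero), min(x$nonzero)))
  invisible(x)
}

#' @export
print.coxnet_cv <- function(x, ...) {
  cat(sprintf("coxnet_cv: %d-fold, lambda_min = %.4g, %d gene(s) selected\n",
              x$nfolds, x$lambda_min, nrow(x$selected)))
  if (nrow(x$selected)) print(x$selected, row.names = FALSE)
  invisible(x)
}
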