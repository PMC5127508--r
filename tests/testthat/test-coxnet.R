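# Independent Breslow partial log-likelihood for oracle checks: per event,
# the linear predictor minus the log-sum over the at-risk set.
pll_oracle <- function(beta, x, time, event) {
  eta <- as.numeric(x %*% beta)
  sum(vapply(which(event), function(i)
    eta[i] - log(sum(exp(eta[time >= time[i]]))), numeric(1)))
}

test_that("the path starts at an all-zero solution and densifies downward", {
  co <- make_cohort(n = 120, seed = 37, n_genes = 10, censor_time = 60)
  z <- compute_zscores(co$expression)
  fit <- coxnet_fit(z, co$clinical$os_months, co$clinical$event)
  expect_identical(fit$nonzero[[1]], 0)
  expect_gte(fit$nonzero[[length(fit$lambda)]], fit$nonzero[[1]])
  expect_true(all(diff(fit$lambda) < 0))
  # densest end has at least as many nonzeros as the sparsest
  expect_gte(max(fit$nonzero), fit$nonzero[[1]])
})

test_that("the penalized objective never increases within a lambda", {
  co <- make_cohort(n = 100, seed = 41, n_genes = 8, censor_time = 45,
                    betas = c(HFE = 0.6))
  z <- compute_zscores(co$expression)
  fit <- coxnet_fit(z, co$clinical$os_months, co$clinical$event)
  for (tr in fit$obj_traces) expect_true(all(diff(tr) <= 1e-10))
})

test_that("the lambda -> 0 limit matches the unpenalized Cox MLE", {
  skip_if_not_installed("survival")
  set.seed(43)
  n <- 40
  z <- matrix(rnorm(2 * n), 2, n,
              dimnames = list(c("g1", "g2"), sprintf("s%02d", 1:n)))
  tm <- rexp(n, 0.05 * exp(0.4 * z[1, ] - 0.6 * z[2, ]))
  ev <- tm < 30; tm <- pmin(tm, 30)
  fit <- coxnet_fit(z, tm, ev, lambda = c(0.5, 1e-9), tol = 1e-10)
  ref <- survival::coxph(survival::Surv(tm, ev) ~ t(z), ties = "breslow")
  expect_lt(max(abs(fit$beta[, 2] - unname(coef(ref)))), 1e-4)
  # ... and maximizes the independently coded partial likelihood
  b <- fit$beta[, 2]
  expect_gte(pll_oracle(b, t(z), tm, ev) + 1e-6,
             pll_oracle(b + c(0.01, 0), t(z), tm, ev))
})

test_that("single binary covariate at lambda = 0 matches a grid-search oracle", {
  set.seed(47)
  n <- 30
  x <- matrix(rep(0:1, each = n / 2), ncol = 1, dimnames = list(NULL, "g"))
  tm <- rexp(n, 0.08 * exp(0.9 * x[, 1]))
  tm <- round(tm, 6)                     # continuous: no ties
  ev <- rep(TRUE, n)
  z <- t(x); colnames(z) <- sprintf("s%02d", 1:n)
  fit <- coxnet_fit(z, tm, ev, lambda = 1e-10, tol = 1e-10)
  opt <- optimize(function(b) -pll_oracle(b, x, tm, ev), c(-5, 5),
                  tol = 1e-9)
  expect_lt(abs(fit$beta[1, 1] - opt$minimum), 1e-4)
})

test_that("lasso with one covariate equals the penalized grid-search solution", {
  set.seed(53)
  n <- 60
  z <- matrix(rnorm(n), 1, n, dimnames = list("g", sprintf("s%02d", 1:n)))
  tm <- rexp(n, 0.06 * exp(0.5 * z[1, ])); ev <- rep(TRUE, n)
  for (lam in c(0.02, 0.08)) {
    fit <- coxnet_fit(z, tm, ev, alpha = 1, lambda = lam, tol = 1e-10)
    opt <- optimize(function(b) -pll_oracle(b, t(z), tm, ev) / n + lam * abs(b),
                    c(-3, 3), tol = 1e-10)
    expect_lt(abs(fit$beta[1, 1] - opt$minimum), 1e-4)
  }
})

test_that("the whole path agrees with the reference elastic-net Cox solver", {
  skip_if_not_installed("glmnet")
  skip_if_not_installed("survival")
  co <- make_cohort(n = 150, seed = 59, n_genes = 12, censor_time = 45,
                    betas = c(HFE = 0.7, UROS = -0.5))
  z <- compute_zscores(co$expression)
  tm <- co$clinical$os_months; ev <- co$clinical$event
  ref <- glmnet::glmnet(t(z), survival::Surv(tm, ev), family = "cox",
                        alpha = 0.95, standardize = FALSE, thresh = 1e-12)
  fit <- coxnet_fit(z, tm, ev, alpha = 0.95, lambda = ref$lambda, tol = 1e-9)
  expect_lt(max(abs(fit$beta - as.matrix(ref$beta))), 5e-4)
})

test_that("fits are invariant to sample and gene order", {
  co <- make_cohort(n = 90, seed = 61, n_genes = 7, censor_time = 50)
  z <- compute_zscores(co$expression)
  tm <- co$clinical$os_months; ev <- co$clinical$event
  fit <- coxnet_fit(z, tm, ev, nlambda = 20)
  ps <- sample(ncol(z)); pg <- sample(nrow(z))
  fit2 <- coxnet_fit(z[pg, ps], tm[ps], ev[ps], nlambda = 20)
  expect_equal(fit2$beta[rownames(z), ], fit$beta, tolerance = 1e-8)
  expect_equal(fit2$lambda, fit$lambda)
})

test_that("cross-validation is seeded, stratified, and reports selections", {
  co <- make_cohort(n = 120, seed = 67, n_genes = 10, censor_time = 45,
                    betas = c(HFE = 0.9))
  z <- compute_zscores(co$expression)
  cv1 <- coxnet_cv(z, co$clinical$os_months, co$clinical$event,
                   nfolds = 5, seed = 9)
  cv2 <- coxnet_cv(z, co$clinical$os_months, co$clinical$event,
                   nfolds = 5, seed = 9)
  expect_identical(cv1$lambda_min, cv2$lambda_min)
  expect_identical(cv1$selected, cv2$selected)
  expect_true(all(cv1$selected$gene %in% rownames(z)))
  # selections are ordered by |coefficient|
  expect_true(all(diff(abs(cv1$selected$coefficient)) <= 1e-12))
  # too many folds for the available events errors with advice
  few <- co$clinical[c(which(co$clinical$event)[1:3],
                       which(!co$clinical$event)[1:20]), ]
  zs <- z[, few$sample_id]
  expect_error(coxnet_cv(zs, few$os_months, few$event, nfolds = 10),
               "fewer folds")
})

test_that("feature selection reads the path and validates lambda", {
  co <- make_cohort(n = 100, seed = 71, n_genes = 6, censor_time = 45)
  z <- compute_zscores(co$expression)
  fit <- coxnet_fit(z, co$clinical$os_months, co$clinical$event, nlambda = 25)
  expect_identical(nrow(select_features(fit, fit$lambda[1])), 0L)
  sel <- select_features(fit, fit$lambda[25])
  expect_identical(sel$gene, names(sort(-abs(fit$beta[fit$beta[, 25] != 0, 25]))))
  expect_error(select_features(fit, 123.456), "not on the fitted path")
})

test_that("relative risk is exp(x.beta) with the expected algebra", {
  co <- make_cohort(n = 40, seed = 73, n_genes = 4)
  z <- compute_zscores(co$expression)
  expect_equal(unname(relative_risk(numeric(0), z)), rep(1, 40))
  b <- c(HFE = 0.5, TFRC = -0.25)
  r1 <- relative_risk(b, z)
  r2 <- relative_risk(2 * b, z)
  expect_equal(log(r2), 2 * log(r1), tolerance = 1e-12)
  expect_error(relative_risk(c(NOPE = 1), z), "NOPE")
})

test_that("risk anti-correlates with survival on a planted cohort", {
  co <- make_cohort(n = 250, seed = 79, n_genes = 8, censor_time = 60,
                    betas = c(HFE = 0.8, SFXN1 = -0.8))
  z <- compute_zscores(co$expression)
  cv <- coxnet_cv(z, co$clinical$os_months, co$clinical$event,
                  nfolds = 5, seed = 3)
  expect_gt(nrow(cv$selected), 0)
  risk <- relative_risk(cv$selected, z)
  unc <- co$clinical$event
  r2 <- prediction_correlation(risk[unc], co$clinical$os_months[unc])
  expect_lt(r2, 0)
})

test_that("degenerate inputs are rejected", {
  co <- make_cohort(n = 30, seed = 83, n_genes = 3, censor_time = 1e-9)
  z <- compute_zscores(co$expression)
  expect_error(coxnet_fit(z, co$clinical$os_months, co$clinical$event),
               "2 events")
  z2 <- z; z2[1, 1] <- NA
  co2 <- make_cohort(n = 30, seed = 83, n_genes = 3, censor_time = 30)
  expect_error(coxnet_fit(z2, co2$clinical$os_months, co2$clinical$event),
               "non-finite")
  expect_error(coxnet_fit(z, co$clinical$os_months, co$clinical$event,
                          alpha = 0), "alpha")
})
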