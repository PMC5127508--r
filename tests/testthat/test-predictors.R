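test_that("random baseline is forced with two samples and degenerate cohorts", {
  cl <- clin_table(c(10, 20), c(TRUE, TRUE))
  pr <- random_baseline(cl, seed = 1)
  expect_equal(pr$predicted_months, c(20, 10))  # only one candidate each

  same <- clin_table(rep(12, 6), rep(TRUE, 6))
  pr2 <- random_baseline(same, seed = 2)
  expect_true(all(pr2$residual == 0))

  expect_error(random_baseline(clin_table(5, TRUE)), "2 uncensored")
  # censored samples are excluded from pool and evaluation
  mix <- clin_table(c(10, 20, 99), c(TRUE, TRUE, FALSE))
  pr3 <- random_baseline(mix, seed = 3)
  expect_identical(pr3$sample_id, mix$sample_id[1:2])
  expect_equal(pr3$predicted_months, c(20, 10))
})

test_that("random baseline converges to the leave-one-out mean", {
  co <- make_cohort(n = 60, seed = 23, censor_time = Inf)
  cl <- co$clinical
  pr <- random_baseline(cl, n_reps = 4000, seed = 5)
  loo <- vapply(seq_len(nrow(cl)), function(i) mean(cl$os_months[-i]),
                numeric(1))
  mc_sd <- sd(cl$os_months) / sqrt(4000)
  expect_lt(max(abs(pr$predicted_months - loo)), 6 * mc_sd)
  # and is reproducible under the same seed
  expect_identical(pr, random_baseline(cl, n_reps = 4000, seed = 5))
})

test_that("1NN predicts the nearest evaluable sample's survival", {
  # three samples on a line: coordinates 0, 1, 10; survivals 5, 8, 30
  z <- matrix(c(0, 1, 10), 1, 3, dimnames = list("g1", c("a", "b", "c")))
  cl <- clin_table(c(5, 8, 30), rep(TRUE, 3), id = c("a", "b", "c"))
  pr <- one_nn_predict(z, "g1", cl)
  expect_equal(pr$predicted_months, c(8, 5, 8))

  # zero-distance twins predict each other
  z2 <- cbind(z, d = 1)
  rownames(z2) <- "g1"
  cl2 <- rbind(cl, clin_table(40, TRUE, id = "d"))
  pr2 <- one_nn_predict(z2, "g1", cl2)
  expect_identical(pr2$neighbor[pr2$sample_id == "b"], "d")
  expect_identical(pr2$neighbor[pr2$sample_id == "d"], "b")
  expect_equal(pr2$predicted_months[pr2$sample_id == "d"], 8)
})

test_that("1NN is order invariant and strict about missing values", {
  co <- make_cohort(n = 80, seed = 29, n_genes = 6, censor_time = 40)
  z <- compute_zscores(co$expression)
  panel <- rownames(z)[1:4]
  pr <- one_nn_predict(z, panel, co$clinical)
  perm <- sample(ncol(z))
  pr2 <- one_nn_predict(z[, perm], panel, co$clinical[sample(nrow(co$clinical)), ])
  o <- match(pr$sample_id, pr2$sample_id)
  expect_equal(pr$predicted_months, pr2$predicted_months[o])
  expect_identical(pr$neighbor, pr2$neighbor[o])

  unc_id <- co$clinical$sample_id[co$clinical$event][1]
  z[panel[1], unc_id] <- NA
  expect_error(one_nn_predict(z, panel, co$clinical), "missing")
})

test_that("1NN ignores constant genes and can admit censored neighbors", {
  co <- make_cohort(n = 50, seed = 31, n_genes = 5, censor_time = 35)
  z <- compute_zscores(co$expression)
  panel <- rownames(z)[1:3]
  pr <- one_nn_predict(z, panel, co$clinical)
  zc <- rbind(z, CONST = 0)
  pr2 <- one_nn_predict(zc, c(panel, "CONST"), co$clinical)
  expect_equal(pr$predicted_months, pr2$predicted_months)

  prc <- one_nn_predict(z, panel, co$clinical,
                        include_censored_neighbors = TRUE)
  pool_ids <- co$clinical$sample_id
  expect_true(all(prc$neighbor %in% pool_ids))
})

test_that("median residual follows the order-statistic conventions", {
  expect_equal(median_residual(c(1, 2, 100)), 2)
  expect_equal(median_residual(c(1, 3)), 2)
  cl <- clin_table(c(10, 20), c(TRUE, TRUE))
  pr <- random_baseline(cl, seed = 1)
  pr$residual <- c(0, 0)
  expect_equal(median_residual(pr), 0)
  expect_error(median_residual(numeric(0)), "no residuals")
})

test_that("Mann-Whitney comparison is exact for small samples", {
  expect_equal(compare_residuals(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(compare_residuals(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_equal(compare_residuals(c(10, 11, 12), c(1, 2, 3)), 0.1) # symmetry
})

test_that("Mann-Whitney normal approximation matches the reference", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- rexp(25, 0.1); b <- rexp(30, 0.15)
    ours <- compare_residuals(a, b)
    ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("prediction correlation handles the canonical cases", {
  x <- 1:10
  expect_equal(prediction_correlation(x, 2 * x + 1), 1)
  expect_equal(prediction_correlation(x, -x), -1)
  expect_warning(r <- prediction_correlation(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(r))
  expect_error(prediction_correlation(1:2, 1:2), "3 complete")
  set.seed(8)
  expect_lt(abs(prediction_correlation(rnorm(10000), rnorm(10000))), 0.05)
})
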