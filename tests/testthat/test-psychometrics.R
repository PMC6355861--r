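test_that("omega matches the closed form for an equal-loading model", {
  # 12 items, loadings 0.7, residual variances 0.51:
  # omega = (12*0.7)^2 / ((12*0.7)^2 + 12*0.51) = 70.56 / 76.68
  R <- matrix(0.49, 12, 12)
  diag(R) <- 1
  rep <- mcdonald_omega(covmat = R)
  expect_equal(rep$omega, 70.56 / 76.68, tolerance = 5e-4)
  expect_equal(rep$loadings, rep(0.7, 12), tolerance = 1e-3)
  # maximum-likelihood route agrees on the exact structure
  expect_equal(mcdonald_omega(covmat = R, n_obs = 500, method = "ml")$omega,
               70.56 / 76.68, tolerance = 1e-3)
})

test_that("omega of pure-noise items is near zero", {
  set.seed(1)
  X <- matrix(sample(0:4, 2000 * 12, replace = TRUE), 2000, 12)
  expect_lte(mcdonald_omega(X)$omega, 0.1)
})

test_that("omega is invariant to item relabeling and per-item shifts", {
  set.seed(2)
  f <- rnorm(300)
  X <- sapply(1:6, function(k) 0.6 * f + rnorm(300, 0, 0.8))
  o1 <- mcdonald_omega(X)$omega
  expect_equal(mcdonald_omega(X[, sample(6)])$omega, o1, tolerance = 1e-6)
  X2 <- sweep(X, 2, c(10, -3, 0, 5, 2, 1), "+")
  expect_equal(mcdonald_omega(X2)$omega, o1, tolerance = 1e-6)
})

test_that("omega validates its inputs", {
  expect_error(mcdonald_omega(matrix(rnorm(20), 10, 2)), "at least 3 items")
  expect_error(mcdonald_omega(matrix(rnorm(30), 5, 6)), "as many observations")
  X <- cbind(rep(1, 50), rnorm(50), rnorm(50))
  expect_error(mcdonald_omega(X), "non-finite")
})

test_that("synthetic chronic-stress items carry the designed reliability", {
  st <- replica_study(1)
  rel <- reliability_table(st$panel)
  tics <- rel$omega[rel$instrument == "TICS" & rel$informant == "self"]
  expect_equal(tics, 0.91, tolerance = 0.05)
  expect_equal(rel$n_observations[rel$instrument == "TICS" &
                                    rel$informant == "self"], 74)
  pss <- rel$omega[rel$instrument == "PSS"]
  expect_true(all(abs(pss - 0.88) < 0.06))
})

test_that("lag correlations cover all occasion pairs grouped by lag", {
  sc <- small_scores()$scores
  lc <- lag_correlations(sc, "WHS_occur", "self")
  expect_setequal(unique(lc$lag), 1:11)
  for (l in 1:11) expect_equal(sum(lc$lag == l), 12 - l)
  expect_true(all(lc$r >= -1 & lc$r <= 1))
  # monthly measure: lags in months
  lp <- lag_correlations(sc, "PSS", "self")
  expect_setequal(unique(lp$lag), 1:2)
})

test_that("perfect stability and white noise give the expected extremes", {
  person <- rep(1:50, each = 12)
  week <- rep(1:12, 50)
  stable <- data.frame(participant_id = person, informant = "self",
                       measure = "M", occasion_week = week,
                       value = rep(rnorm(50), each = 12))
  lc <- lag_correlations(stable, "M", "self")
  expect_true(all(abs(lc$r - 1) < 1e-12))

  set.seed(3)
  noise <- data.frame(participant_id = rep(1:2000, each = 12),
                      informant = "self", measure = "M",
                      occasion_week = rep(1:12, 2000),
                      value = rnorm(24000))
  prof <- retest_profile(noise, "M", "self")
  expect_true(all(abs(prof$pooled_r) < 0.05))
})

test_that("zero-variance occasions are skipped with a warning", {
  d <- data.frame(participant_id = rep(1:10, each = 3), informant = "self",
                  measure = "M", occasion_week = rep(1:3, 10),
                  value = c(rbind(rnorm(10), 1, rnorm(10))))
  expect_warning(lc <- lag_correlations(d, "M", "self"), "zero variance")
  expect_equal(nrow(lc), 1)  # only the (1,3) pair survives
})

test_that("random-effects pooling reduces to the Fisher-z oracle", {
  # single correlation: identity
  p1 <- pool_correlations(0.42, 40)
  expect_equal(p1$pooled_r, 0.42)
  expect_equal(p1$tau2, 0)
  # homogeneous correlations: pooled value preserved, no heterogeneity
  ph <- pool_correlations(rep(0.5, 6), rep(25, 6))
  expect_equal(ph$pooled_r, 0.5, tolerance = 1e-10)
  expect_equal(ph$tau2, 0, tolerance = 1e-8)
  # fixed-effect pooling with equal n equals the mean Fisher z
  pf <- pool_correlations(c(0.3, 0.6), c(30, 30), method = "FE")
  z_bar <- mean(atanh(c(0.3, 0.6)))
  expect_equal(pf$pooled_r, tanh(z_bar), tolerance = 1e-6)
  expect_equal(pf$pooled_r, 0.4631652, tolerance = 1e-6)
})

test_that("pooled estimates stay within the range of the inputs", {
  set.seed(4)
  for (k in 1:10) {
    r <- runif(5, -0.4, 0.8)
    n <- sample(10:60, 5, replace = TRUE)
    p <- pool_correlations(r, n)
    expect_gte(p$pooled_r, min(r) - 1e-10)
    expect_lte(p$pooled_r, max(r) + 1e-10)
    expect_gte(p$tau2, 0)
  }
})

test_that("pooling rejects degenerate inputs", {
  expect_error(pool_correlations(c(0.5, 1), c(10, 10)), "infinite Fisher z")
  expect_error(pool_correlations(0.5, 3), ">= 4")
  expect_error(pool_correlations(numeric(0), numeric(0)), "at least one")
})

test_that("the averaged correlation matrix has the documented structure", {
  sc <- small_scores()
  hcc <- preprocess_hcc(sc$study$hair)
  cm <- averaged_correlation_matrix(sc$scores, hcc)
  expect_equal(diag(cm$r), rep(1, nrow(cm$r)), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))
  expect_true("HCC" %in% rownames(cm$r))
  expect_true(cm$between_informant["WHS_occur_self", "WHS_occur_partner"])
  expect_false(cm$between_informant["WHS_occur_self", "PSS_self"])
  expect_false(any(cm$between_informant[, "HCC"]))
  expect_true(all(abs(cm$r) <= 1))
})

test_that("independent white-noise measures are uncorrelated when averaged", {
  set.seed(6)
  n <- 2000
  sc <- rbind(
    data.frame(participant_id = rep(1:n, each = 3), informant = "self",
               measure = "PSS", occasion_week = rep(c(4, 8, 12), n),
               value = rnorm(3 * n)),
    data.frame(participant_id = 1:n, informant = "self", measure = "TICS",
               occasion_week = 12, value = rnorm(n)))
  hcc <- data.frame(participant_id = 1:n, log_hcc = rnorm(n))
  cm <- averaged_correlation_matrix(sc, hcc, measures = c("PSS", "TICS"))
  off <- cm$r[upper.tri(cm$r)]
  expect_true(all(abs(off) < 0.05))
})
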