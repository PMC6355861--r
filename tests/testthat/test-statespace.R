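test_that("standardization gives exact zero mean and unit SD per series", {
  sc <- small_scores()$scores
  std <- standardize_measures(sc, c("WHS_occur", "PSS", "TICS"))
  for (m in c("WHS_occur", "PSS", "TICS")) {
    for (inf in c("self", "partner")) {
      v <- std$value[std$measure == m & std$informant == inf]
      expect_equal(mean(v), 0, tolerance = 1e-12)
      expect_equal(sd(v), 1, tolerance = 1e-12)
    }
  }
  scaling <- attr(std, "scaling")
  expect_true(all(c("measure", "informant", "mean", "sd") %in% names(scaling)))
})

test_that("standardization errors on degenerate series and preserves correlations", {
  sc <- small_scores()$scores
  const <- sc
  const$value[const$measure == "TICS"] <- 5
  expect_error(standardize_measures(const, "TICS"), "zero variance")
  # affine invariance of correlation
  w <- sc[sc$measure == "WHS_occur" & sc$informant == "self", ]
  p <- sc[sc$measure == "PSS" & sc$informant == "self", ]
  m <- merge(w, p, by = c("participant_id", "occasion_week"))
  std <- standardize_measures(sc, c("WHS_occur", "PSS"))
  ws <- std[std$measure == "WHS_occur" & std$informant == "self", ]
  ps <- std[std$measure == "PSS" & std$informant == "self", ]
  ms <- merge(ws, ps, by = c("participant_id", "occasion_week"))
  expect_equal(cor(m$value.x, m$value.y), cor(ms$value.x, ms$value.y),
               tolerance = 1e-12)
})

test_that("split-chain R-hat behaves at its analytic anchors", {
  set.seed(20)
  # converged: all chains from the same distribution
  expect_lt(gelman_rubin(matrix(rnorm(30000), 10000, 3)), 1.01)
  # separated chains: compute the expected value by the standard formula
  x <- cbind(rnorm(1000, 0), rnorm(1000, 5))
  n <- 500
  halves <- cbind(x[1:n, 1], x[n + 1:n, 1], x[1:n, 2], x[n + 1:n, 2])
  W <- mean(apply(halves, 2, var))
  B <- n * var(colMeans(halves))
  expected <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(gelman_rubin(x), expected, tolerance = 1e-12)
  expect_gt(gelman_rubin(x), 1.5)
})

test_that("degenerate chains are handled as documented", {
  expect_warning(r <- gelman_rubin(matrix(1, 100, 3)), "zero within-chain")
  expect_equal(r, 1)
  expect_true(is.na(gelman_rubin(matrix(rnorm(100), 100, 1))))
  expect_error(gelman_rubin(matrix(rnorm(6), 3, 2)), "at least 4")
})

test_that("the state-space spec validates prior settings", {
  expect_error(state_space_spec(iw_df = 1), "exceed dimension")
  expect_error(state_space_spec(iw_scale = matrix(c(1, 2, 2, 1), 2)),
               "not positive")
  expect_warning(state_space_spec(n_chains = 1), "fewer than 2 chains")
})

test_that("the fit rejects malformed panels", {
  sc <- small_scores()$scores
  std <- standardize_measures(sc, c("WHS_occur", "PSS", "TICS"))
  spec <- state_space_spec(n_iter = 50)
  drop_partner <- std[!(std$informant == "partner" & std$participant_id == 2), ]
  expect_error(fit_state_space(drop_partner, spec), "empty partner")
  expect_error(fit_state_space(std[, -5], spec), "lacks columns")
  expect_error(fit_state_space(std, state_space_spec(n_iter = 50,
                                                     adjust_sex = TRUE)),
               "requires a sex vector")
})

test_that("blocked Gibbs and JAGS backends agree on the same data", {
  fit <- replica_fit(1)
  st <- replica_study(1)
  std <- standardize_measures(score_panel(st$panel),
                              c("WHS_occur", "PSS", "TICS"))
  fitj <- cached("fit_jags", suppressWarnings(
    fit_state_space(std, state_space_spec(backend = "jags", n_iter = 3000L),
                    seed = 1)))
  sl <- standardized_loadings(fit)
  slj <- standardized_loadings(fitj)
  expect_lt(max(abs(sl$loading - slj$loading)), 0.08)
  ic <- informant_coupling(fit)
  icj <- informant_coupling(fitj)
  expect_lt(abs(ic$estimate[1] - icj$estimate[1]), 0.15)  # r_xi
  expect_lt(abs(ic$estimate[2] - icj$estimate[2]), 0.20)  # r_delta
  ds <- drift_summary(fit)
  dsj <- drift_summary(fitj)
  expect_lt(max(abs(ds$mean - dsj$mean)), 0.05)
})

test_that("swapping informant labels permutes the fit symmetrically", {
  st <- cached("study_swap",
               simulate_study(true_parameters(n_couples = 12, seed = 55)))
  std <- standardize_measures(score_panel(st$panel),
                              c("WHS_occur", "PSS", "TICS"))
  swapped <- std
  swapped$informant <- ifelse(std$informant == "self", "partner", "self")
  spec <- state_space_spec(n_iter = 1200L)
  f1 <- suppressWarnings(fit_state_space(std, spec, seed = 9))
  f2 <- suppressWarnings(fit_state_space(swapped, spec, seed = 9))
  l1 <- standardized_loadings(f1)
  l2 <- standardized_loadings(f2)
  key <- function(d) paste(d$instrument, d$informant)
  swap_key <- function(d) paste(d$instrument,
                                ifelse(d$informant == "self", "partner", "self"))
  expect_lt(max(abs(l1$loading[match(key(l1), swap_key(l2))] - l2$loading)),
            0.12)
  # innovation correlation is symmetric under the swap
  expect_lt(abs(informant_coupling(f1)$estimate[1] -
                  informant_coupling(f2)$estimate[1]), 0.12)
})

test_that("posterior drift signs follow the generator", {
  fit <- replica_fit(1)
  ds <- drift_summary(fit)
  expect_true(all(ds$mean < 0))   # generator drifts are negative
  ic <- informant_coupling(fit)
  expect_true(all(ic$estimate >= -1 & ic$estimate <= 1))
  # innovation-covariance draws are symmetric positive definite
  Sx <- fit$draws$Sigma_xi
  set.seed(1)
  for (k in sample(dim(Sx)[1], 20)) {
    m <- Sx[k, 1, , ]
    expect_equal(m[1, 2], m[2, 1], tolerance = 1e-12)
    expect_gt(min(eigen(m, symmetric = TRUE)$values), 0)
  }
})

test_that("diagonal innovation truth yields a coupling interval covering zero", {
  st <- cached("study_diag", simulate_study(
    true_parameters(n_couples = 37, seed = 202, innovation_correlation = 0,
                    drift_correlation = 0)))
  std <- standardize_measures(score_panel(st$panel),
                              c("WHS_occur", "PSS", "TICS"))
  fit <- cached("fit_diag", suppressWarnings(
    fit_state_space(std, state_space_spec(n_iter = 1500L), seed = 4)))
  ic <- informant_coupling(fit)
  r_xi <- ic[ic$quantity == "r_xi", ]
  expect_true(r_xi$lower <= 0 && r_xi$upper >= 0)
})
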