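test_that("regenerating with the same seed yields identical datasets", {
  p <- true_parameters(n_couples = 5, seed = 31)
  s1 <- simulate_study(p)
  s2 <- simulate_study(p)
  expect_identical(s1$panel, s2$panel)
  expect_identical(s1$hair, s2$hair)
  expect_identical(s1$truth$trajectories$S, s2$truth$trajectories$S)
})

test_that("degenerate noise yields constant trajectories at the initial state", {
  p <- true_parameters(n_couples = 4, drift_sd = 0,
                       drift_mean = c(self = 0, partner = 0),
                       innovation_covariance = matrix(0, 2, 2))
  tr <- simulate_latent(p, seed = 1)
  for (t in seq_len(p$n_weeks)) {
    expect_equal(tr$S[, , t], tr$S0, ignore_attr = TRUE)
  }
})

test_that("trajectories satisfy the state equation exactly given stored innovations", {
  tr <- simulate_latent(true_parameters(n_couples = 6), seed = 5)
  S_prev <- tr$S0
  for (t in seq_len(dim(tr$S)[3])) {
    expect_equal(tr$S[, , t], S_prev + tr$delta + tr$xi[, , t],
                 ignore_attr = TRUE, tolerance = 1e-12)
    S_prev <- tr$S[, , t]
  }
})

test_that("drift and innovation correlations converge to truth at large n", {
  p <- true_parameters(n_couples = 2000)
  tr <- simulate_latent(p, seed = 99)
  expect_equal(cor(tr$delta[, 1], tr$delta[, 2]), 0.34, tolerance = 0.03)
  expect_equal(cor(as.vector(tr$xi[, 1, ]), as.vector(tr$xi[, 2, ])),
               0.70, tolerance = 0.03)
})

test_that("item panel respects the instrument schedules and informant design", {
  st <- replica_study(1)
  panel <- st$panel
  expect_setequal(unique(panel$occasion_week[panel$instrument == "WHS"]), 1:12)
  expect_setequal(unique(panel$occasion_week[panel$instrument == "PSS"]),
                  c(4, 8, 12))
  expect_equal(unique(panel$occasion_week[panel$instrument == "TICS"]), 12)
  counts <- table(panel$participant_id, panel$informant)
  expect_true(all(counts == counts[1, 1]))  # every participant, both series
  expect_setequal(unique(panel$informant), c("self", "partner"))
  # intensity only for occurred WHS hassles
  whs <- panel[panel$instrument == "WHS", ]
  expect_true(all(is.na(whs$intensity[whs$frequency == 0])))
  expect_true(all(!is.na(whs$intensity[whs$frequency >= 1])))
  expect_true(all(panel$frequency %in% 0:4))
})

test_that("a very large latent propensity saturates all item responses", {
  p <- true_parameters()
  cf <- dyadstress:::emission_coefficients(p)
  for (inst in c("WHS", "PSS", "TICS")) {
    K <- p$item_counts[[inst]]
    z <- matrix(50, 2, K)   # +infinity surrogate on the propensity scale
    resp <- dyadstress:::emit_ordinal(z, p$thresholds[[inst]],
                                      cf[[inst]]$difficulties,
                                      tau = cf[[inst]]$tau)
    expect_true(all(resp == 4))
    expect_true(all(dyadstress:::emit_ordinal(-z, p$thresholds[[inst]],
                                              cf[[inst]]$difficulties,
                                              tau = cf[[inst]]$tau) == 0))
  }
  # panel-level monotonicity: the most stressed decile scores far above the
  # least stressed decile
  st <- replica_study(1)
  sc <- score_panel(st$panel)
  Sz <- dyadstress:::standardize_latent(st$truth$trajectories)
  w <- sc[sc$measure == "WHS_occur" & sc$informant == "self", ]
  sv <- Sz[cbind(w$participant_id, 1, w$occasion_week)]
  hi <- w$value[sv > quantile(sv, 0.9)]
  lo <- w$value[sv < quantile(sv, 0.1)]
  expect_gt(mean(hi), mean(lo) + 0.5)
})

test_that("zero loadings produce scores uncorrelated with the latent state", {
  p <- true_parameters(
    n_couples = 150,
    loadings = matrix(0, 3, 2, dimnames = list(c("WHS", "PSS", "TICS"),
                                               c("self", "partner"))))
  st <- simulate_study(p)
  sc <- score_panel(st$panel)
  Sz <- dyadstress:::standardize_latent(st$truth$trajectories)
  w <- sc[sc$measure == "WHS_occur" & sc$informant == "self", ]
  sv <- Sz[cbind(w$participant_id, 1, w$occasion_week)]
  expect_lt(abs(cor(w$value, sv)), 0.05)
})

test_that("scored synthetic scales match the observed descriptive anchors", {
  st <- cached("study_moments",
               simulate_study(true_parameters(n_couples = 300, seed = 17)))
  sc <- score_panel(st$panel)
  means <- tapply(sc$value, sc$measure, mean)
  expect_equal(unname(means["WHS_n"]), 11.8, tolerance = 0.1)      # ~11.8/30
  expect_equal(unname(means["WHS_occur"]), 0.69, tolerance = 0.1)
  expect_equal(unname(means["PSS"]), 13.9, tolerance = 0.15)
  expect_equal(unname(means["TICS"]), 13.7, tolerance = 0.15)
  # possible score ranges
  expect_true(all(sc$value[sc$measure == "WHS_n"] >= 0 &
                    sc$value[sc$measure == "WHS_n"] <= 30))
  expect_true(all(sc$value[sc$measure == "WHS_occur"] >= 0 &
                    sc$value[sc$measure == "WHS_occur"] <= 4))
  expect_true(all(sc$value[sc$measure == "PSS"] >= 0 &
                    sc$value[sc$measure == "PSS"] <= 40))
  expect_true(all(sc$value[sc$measure == "TICS"] >= 0 &
                    sc$value[sc$measure == "TICS"] <= 48))
})

test_that("hair samples reproduce the assay's replicate variability", {
  st <- replica_study(1)
  hcc <- preprocess_hcc(st$hair)
  expect_gte(attr(hcc, "median_cv"), 3)
  expect_lte(attr(hcc, "median_cv"), 7)
  expect_equal(nrow(st$hair), 74 * 9)
})

test_that("hair generation validates its inputs", {
  p <- true_parameters(n_couples = 3)
  tr <- simulate_latent(p, seed = 1)
  p_bad <- p
  p_bad$hcc_noise_sd <- -1
  expect_error(simulate_hair(tr, p_bad), "nonnegative")
  p_short <- p
  p_short$hcc_lag_kernel <- rep(0.5, 2)
  expect_error(simulate_hair(tr, p_short), "equal n_weeks")
})

test_that("study round-trips through the CSV/JSON writers", {
  dir <- withr::local_tempdir()
  st <- simulate_study(true_parameters(n_couples = 3, seed = 9))
  paths <- write_study(st, dir)
  expect_true(all(file.exists(paths)))
  panel2 <- read_panel(paths[["panel"]])
  expect_equal(nrow(panel2), nrow(st$panel))
  hair2 <- read_hair(paths[["hair"]])
  expect_equal(hair2$cortisol_pg_per_mg, st$hair$cortisol_pg_per_mg,
               tolerance = 1e-8)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$seed, 9)
  expect_error(read_panel(paths[["hair"]]), "lacks columns")
})
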