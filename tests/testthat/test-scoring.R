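test_that("weekly hassle scoring matches hand-computed definitions", {
  # empty week
  expect_equal(score_whs(rep(0L, 30)),
               c(WHS_n = 0, WHS_occur = 0, WHS_intens = 0))
  # three hassles occurred
  f <- c(2, 1, 3, rep(0, 27))
  i <- c(4, 2, 0, rep(NA, 27))
  expect_equal(score_whs(f, i),
               c(WHS_n = 3, WHS_occur = 6 / 30, WHS_intens = 2))
  # occurred-items denominator option
  expect_equal(unname(score_whs(f, i, occur_denominator = "occurred_items")[2]),
               2)
})

test_that("weekly hassle scoring validates its inputs", {
  expect_error(score_whs(c(0, 0), c(3, NA)), "non-occurred")
  expect_error(score_whs(c(5, 0), c(NA, NA)), "outside 0..4")
  expect_error(score_whs(rep(0, 31)), "more than 30")
  expect_error(score_whs(c(1, 1), c(2, NA, NA)), "equal length")
})

test_that("perceived stress scoring reverse-codes the standard items", {
  expect_equal(score_pss(rep(0L, 10)), 16)      # four reversed items become 4
  expect_equal(score_pss(rep(4L, 10)), 24)      # 6*4 + 4*0
  expect_equal(score_pss(rep(2L, 10)), 20)      # midpoint symmetric
  expect_equal(score_pss(rep(4L, 10), reverse_items = integer(0)), 40)
  expect_error(score_pss(rep(1L, 9)), "exactly 10")
})

test_that("chronic stress scoring is a plain sum over 12 items", {
  expect_equal(score_tics(rep(0L, 12)), 0)
  expect_equal(score_tics(rep(4L, 12)), 48)
  expect_equal(score_tics(c(rep(1L, 11), 2L)), 13)
  expect_error(score_tics(rep(1L, 10)), "exactly 12")
})

test_that("scoring is permutation-invariant over item order", {
  set.seed(42)
  f <- sample(0:4, 30, replace = TRUE)
  i <- ifelse(f >= 1, sample(0:4, 30, replace = TRUE), NA)
  perm <- sample(30)
  expect_equal(score_whs(f, i), score_whs(f[perm], i[perm]))
  x <- sample(0:4, 12, replace = TRUE)
  expect_equal(score_tics(x), score_tics(rev(x)))
})

test_that("the three weekly hassle measures vanish together", {
  set.seed(11)
  for (k in 1:20) {
    f <- sample(0:4, 30, replace = TRUE, prob = c(0.8, 0.1, 0.05, 0.03, 0.02))
    i <- ifelse(f >= 1, sample(0:4, 30, replace = TRUE), NA)
    s <- score_whs(f, i)
    zero <- c(s["WHS_n"] == 0, s["WHS_occur"] == 0)
    expect_true(all(zero) || !any(zero))
    if (s["WHS_n"] == 0) expect_equal(unname(s["WHS_intens"]), 0)
  }
})

test_that("panel scoring agrees with the per-cell scoring rules", {
  sc <- small_scores()
  st <- sc$study
  scores <- sc$scores
  # pick one participant-occasion and recompute by hand
  sub <- st$panel[st$panel$participant_id == 3 & st$panel$informant == "self" &
                    st$panel$instrument == "WHS" & st$panel$occasion_week == 5, ]
  sub <- sub[order(sub$item), ]
  by_hand <- score_whs(sub$frequency, sub$intensity)
  got <- scores[scores$participant_id == 3 & scores$informant == "self" &
                  scores$occasion_week == 5 &
                  scores$measure %in% c("WHS_n", "WHS_occur", "WHS_intens"), ]
  expect_equal(got$value[match(c("WHS_n", "WHS_occur", "WHS_intens"),
                               got$measure)],
               unname(by_hand))
  pss <- st$panel[st$panel$participant_id == 3 & st$panel$informant == "partner" &
                    st$panel$instrument == "PSS" & st$panel$occasion_week == 8, ]
  pss <- pss[order(pss$item), ]
  expect_equal(scores$value[scores$participant_id == 3 &
                              scores$informant == "partner" &
                              scores$measure == "PSS" &
                              scores$occasion_week == 8],
               score_pss(pss$frequency))
})

test_that("hair preprocessing follows segment-then-log averaging", {
  h <- data.frame(participant_id = 1, segment = rep(1:3, each = 3),
                  replicate = rep(1:3, 3), cortisol_pg_per_mg = 4.06)
  out <- preprocess_hcc(h)
  expect_equal(out$hcc_avg, 4.06)
  expect_equal(out$log_hcc, log(4.06), tolerance = 1e-12)
  expect_equal(out$median_cv, 0)

  h2 <- data.frame(participant_id = 1, segment = rep(1:3, each = 3),
                   replicate = rep(1:3, 3),
                   cortisol_pg_per_mg = c(2, 4, 6, rep(4, 6)))
  out2 <- preprocess_hcc(h2)
  expect_equal(max(tapply(h2$cortisol_pg_per_mg,
                          interaction(h2$segment), function(v) 100 * sd(v) / mean(v))),
               50)
  expect_equal(attr(out2, "median_cv"), 0)  # median over the three sets
  cvs <- c(50, 0, 0)
  expect_equal(out2$median_cv, median(cvs))
})

test_that("hair preprocessing validates and flags", {
  h <- data.frame(participant_id = 1, segment = rep(1:3, each = 3),
                  replicate = rep(1:3, 3), cortisol_pg_per_mg = 4)
  h$cortisol_pg_per_mg[5] <- -1
  expect_error(preprocess_hcc(h), "nonpositive")
  h2 <- data.frame(participant_id = 1, segment = rep(1:2, each = 3),
                   replicate = rep(1:3, 2), cortisol_pg_per_mg = 4)
  expect_error(preprocess_hcc(h2), "lacks segment")
  expect_warning(out <- preprocess_hcc(h2, missing_segment = "average"),
                 "averaged available")
  expect_equal(out$hcc_avg, 4)
  h3 <- data.frame(participant_id = 1, segment = rep(1:3, each = 3),
                   replicate = rep(1:3, 3), cortisol_pg_per_mg = 0.05)
  expect_equal(preprocess_hcc(h3)$n_below_floor, 9)
})

test_that("log transform preserves the ranking of participants", {
  st <- small_scores()$study
  hcc <- preprocess_hcc(st$hair)
  expect_equal(order(hcc$hcc_avg), order(hcc$log_hcc))
})
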