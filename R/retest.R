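#' Occasion-pair retest correlations of a scored measure
#'
#' For one measure and informant, computes the across-participant Pearson
#' correlation between every ordered pair of assessment occasions, using
#' pairwise-complete observations, and groups the pairs by time lag.
#' Occasion pairs where either occasion has zero variance are skipped with
#' a warning.
#'
#' @param scores tidy score table (see [score_panel()]).
#' @param measure measure to analyse (e.g. `"WHS_occur"`, `"PSS"`).
#' @param informant `"self"` or `"partner"`.
#' @param lag_unit width of one lag step in weeks; by default the smallest
#'   spacing between the measure's occasions, so weekly measures get weekly
#'   lags (1..11) and monthly measures monthly lags (1, 2).
#' @param min_n minimum complete pairs per occasion pair.
#' @return A data.frame with columns `measure`, `informant`, `from`, `to`
#'   (occasion weeks), `lag` (in `lag_unit` steps), `r`, `n`.
#' @export
lag_correlations <- function(scores, measure, informant = "self",
                             lag_unit = NULL, min_n = 4L) {
  sub <- scores[scores$measure == measure & scores$informant == informant, ]
  occ <- sort(unique(sub$occasion_week))
  if (length(occ) < 2) {
    stop("need at least 2 occasions for retest correlations", call. = FALSE)
  }
  if (is.null(lag_unit)) lag_unit <- min(diff(occ))
  wide <- stats::reshape(sub[, c("participant_id", "occasion_week", "value")],
                         idvar = "participant_id", timevar = "occasion_week",
                         direction = "wide")
  cols <- paste0("value.", occ)
  rows <- list()
  skipped <- 0L
  for (i in seq_along(occ)) {
    for (j in seq_along(occ)) {
      if (j <= i) next
      x <- wide[[cols[i]]]
      y <- wide[[cols[j]]]
      ok <- stats::complete.cases(x, y)
      n <- sum(ok)
      if (n < min_n) next
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        skipped <- skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        measure = measure, informant = informant,
        from = occ[i], to = occ[j],
        lag = (occ[j] - occ[i]) / lag_unit,
        r = stats::cor(x[ok], y[ok]), n = n)
    }
  }
  if (skipped > 0) {
    warning(skipped, " occasion pair(s) skipped due to zero variance")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(measure = character(), informant = character(),
                                      from = integer(), to = integer(),
                                      lag = numeric(), r = numeric(), n = integer())
  out
}

#' Pool correlations by random-effects meta-analysis
#'
#' Pools a set of Pearson correlations (with their sample sizes) on the
#' Fisher-z scale using a random-effects model: sampling variances
#' `1/(n-3)`, between-pair heterogeneity tau^2 estimated by REML (the
#' DerSimonian-Laird estimator and a fixed-effect model are available), and
#' inverse-variance weights `1/(1/(n-3) + tau^2)`. The pooled estimate is
#' back-transformed to the correlation scale.
#'
#' @param r vector of correlations, all strictly inside (-1, 1).
#' @param n vector of sample sizes (>= 4).
#' @param method `"REML"`, `"DL"` or `"FE"` (fixed effect, tau^2 = 0).
#' @return An object of class `pooled_correlation`: list with `pooled_r`,
#'   `se_z` (standard error on the z scale), `se_r` (delta-method SE on the
#'   correlation scale), `tau2`, `ci_lower`, `ci_upper`, `k`, and the
#'   inputs.
#' @examples
#' pool_correlations(c(0.3, 0.6), c(30, 30), method = "FE")$pooled_r
#' @export
pool_correlations <- function(r, n, method = c("REML", "DL", "FE")) {
  method <- match.arg(method)
  if (length(r) < 1) stop("need at least one correlation", call. = FALSE)
  if (length(r) != length(n)) stop("r and n must have equal length", call. = FALSE)
  if (any(n < 4)) stop("all sample sizes must be >= 4", call. = FALSE)
  if (any(abs(r) >= 1)) {
    stop("correlations of |r| = 1 cannot be pooled (infinite Fisher z)",
         call. = FALSE)
  }
  zi <- atanh(r)
  vi <- 1 / (n - 3)
  if (length(r) == 1L) {
    z <- zi; se <- sqrt(vi); tau2 <- 0
  } else {
    fit <- metafor::rma(yi = zi, vi = vi, method = method)
    z <- as.numeric(fit$b); se <- fit$se; tau2 <- fit$tau2
  }
  pooled_r <- tanh(z)
  structure(list(
    pooled_r = pooled_r, pooled_z = z, se_z = se,
    se_r = se * (1 - pooled_r^2),
    tau2 = tau2,
    ci_lower = tanh(z - 1.96 * se), ci_upper = tanh(z + 1.96 * se),
    k = length(r), method = method, r = r, n = n
  ), class = "pooled_correlation")
}

#' @export
print.pooled_correlation <- function(x, ...) {
  cat(sprintf("Pooled r = %.3f (SE %.3f, 95%% CI %.3f..%.3f), tau^2 = %.4f, k = %d [%s]\n",
              x$pooled_r, x$se_r, x$ci_lower, x$ci_upper, x$tau2, x$k, x$method))
  invisible(x)
}

#' Pooled retest-stability profile across lags
#'
#' Combines [lag_correlations()] and [pool_correlations()]: for every time
#' lag of one measure/informant, the occasion-pair correlations are pooled
#' meta-analytically, yielding the retest-stability profile usually shown
#' as an autocorrelation plot.
#'
#' @inheritParams lag_correlations
#' @inheritParams pool_correlations
#' @return A data.frame with one row per lag: `measure`, `informant`,
#'   `lag`, `k` (number of occasion pairs), `pooled_r`, `se_r`, `tau2`,
#'   `ci_lower`, `ci_upper`.
#' @export
retest_profile <- function(scores, measure, informant = "self",
                           method = "REML", lag_unit = NULL, min_n = 4L) {
  lc <- lag_correlations(scores, measure, informant, lag_unit = lag_unit,
                         min_n = min_n)
  rows <- lapply(sort(unique(lc$lag)), function(l) {
    sub <- lc[lc$lag == l, ]
    p <- pool_correlations(sub$r, sub$n, method = method)
    data.frame(measure = measure, informant = informant, lag = l,
               k = p$k, pooled_r = p$pooled_r, se_r = p$se_r, tau2 = p$tau2,
               ci_lower = p$ci_lower, ci_upper = p$ci_upper)
  })
  do.call(rbind, rows)
}

#' Correlation matrix of time-averaged stress measures and hair cortisol
#'
#' Averages every scored measure within participant x informant across its
#' assessment occasions, joins log hair cortisol concentration, and returns
#' the full Pearson correlation matrix (pairwise-complete), flagging the
#' between-informant cells.
#'
#' @param scores tidy score table (see [score_panel()]).
#' @param hcc output of [preprocess_hcc()] (or any data.frame with
#'   `participant_id` and `log_hcc`).
#' @param measures measures to include.
#' @return An object of class `stress_cor_matrix`: list with `r` (the
#'   correlation matrix, variables named `measure_informant` plus `HCC`),
#'   `n` (pairwise sample sizes), `between_informant` (logical matrix
#'   flagging cells that compare informants).
#' @export
averaged_correlation_matrix <- function(scores, hcc,
                                        measures = c("WHS_n", "WHS_occur",
                                                     "WHS_intens", "PSS", "TICS")) {
  sub <- scores[scores$measure %in% measures, ]
  key <- interaction(sub$participant_id, sub$measure, sub$informant, drop = TRUE)
  avg <- tapply(sub$value, key, mean)
  parts <- do.call(rbind, strsplit(names(avg), ".", fixed = TRUE))
  long <- data.frame(participant_id = as.integer(parts[, 1]),
                     variable = paste(parts[, 2], parts[, 3], sep = "_"),
                     value = as.numeric(avg))
  wide <- stats::reshape(long, idvar = "participant_id", timevar = "variable",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  m <- merge(wide, hcc[, c("participant_id", "log_hcc")],
             by = "participant_id", all.x = TRUE)
  names(m)[names(m) == "log_hcc"] <- "HCC"
  vars <- c("HCC", sort(setdiff(names(m), c("participant_id", "HCC"))))
  X <- as.matrix(m[, vars])
  if (sum(stats::complete.cases(X)) < 4) {
    stop("fewer than 4 complete cases for the correlation matrix", call. = FALSE)
  }
  r <- stats::cor(X, use = "pairwise.complete.obs")
  nmat <- crossprod(!is.na(X))
  inf_of <- function(v) {
    ifelse(grepl("_self$", v), "self", ifelse(grepl("_partner$", v), "partner", NA))
  }
  infs <- inf_of(vars)
  flag <- outer(infs, infs, function(a, b) !is.na(a) & !is.na(b) & a != b)
  dimnames(flag) <- dimnames(r)
  structure(list(r = r, n = nmat, between_informant = flag),
            class = "stress_cor_matrix")
}

#' @export
print.stress_cor_matrix <- function(x, digits = 2, ...) {
  cat("Pearson correlations of time-averaged stress measures\n")
  print(round(x$r, digits))
  invisible(x)
}
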