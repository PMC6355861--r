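#' Ground-truth parameters for the synthetic study generator
#'
#' Bundles every quantity the synthetic-data generator needs to emulate a
#' 12-week dyadic stress study: latent random-walk dynamics with individual
#' drift, dyadic coupling of the self- and partner-perspective series,
#' instrument loadings and reliabilities, ordinal item emission thresholds,
#' and the lag kernel linking latent stress to hair cortisol.
#'
#' The defaults reproduce the design of a 37-couple, 12-week ambulatory
#' protocol: a 30-item weekly hassle scale (WHS) at every week, a 10-item
#' perceived stress scale (PSS) at weeks 4, 8 and 12, and a 12-item chronic
#' stress screening scale (TICS) at the final week, each answered once about
#' oneself (self-report) and once about the partner (partner-report).
#' Default standardized loadings are 0.87/0.91 (WHS self/partner),
#' 0.49/0.53 (PSS) and 0.44/0.47 (TICS); the innovation correlation between
#' the two informant perspectives is 0.70 and the drift correlation 0.34.
#'
#' @param n_couples number of couples (two participants each).
#' @param n_weeks number of weekly assessment occasions.
#' @param pss_weeks occasions (weeks) at which the PSS is administered.
#' @param tics_week single occasion at which the TICS is administered.
#' @param drift_mean length-2 vector, mean weekly drift of latent stress for
#'   the self- and partner-perspective series (latent units / week, with
#'   the initial-state SD fixed at 1; the defaults correspond to mildly
#'   decreasing stress over the assessment period).
#' @param drift_sd between-person SD of the individual drifts.
#' @param drift_correlation correlation of the (self, partner) drift pairs.
#' @param innovation_sd length-2 vector of innovation SDs.
#' @param innovation_correlation correlation of the per-week innovation pairs.
#' @param innovation_covariance optional 2x2 symmetric positive-definite
#'   matrix; overrides `innovation_sd`/`innovation_correlation`.
#' @param loadings 3x2 matrix of target standardized loadings, rows
#'   `WHS_occur`, `PSS`, `TICS`, columns `self`, `partner`.
#' @param scale_reliability named vector of target internal consistencies
#'   (omega) per instrument, used to size the item-specific noise.
#' @param item_counts named vector of items per instrument.
#' @param thresholds list of marginal category probabilities (length 5,
#'   categories 0-4) per instrument, plus `WHS_intensity` for the
#'   conditional stressfulness ratings.
#' @param item_difficulty_sd named vector, SD (probit scale) of the spread
#'   of item difficulty offsets per instrument; heterogeneous difficulties
#'   keep the scale-level response curve approximately linear.
#' @param pss_reverse_items indices of the positively worded PSS items that
#'   the generator emits mirrored (and scoring reverse-codes).
#' @param hcc_lag_kernel nonnegative weights over the `n_weeks` occasions,
#'   summing to 1; the default is a discretized Gaussian centred at
#'   `hcc_kernel_peak` with SD `hcc_kernel_sd` occasions.
#' @param hcc_kernel_peak,hcc_kernel_sd location/scale of the default kernel.
#' @param hcc_effect regression weight of kernel-integrated latent stress on
#'   log hair cortisol concentration (log pg/mg per latent SD).
#' @param hcc_noise_sd SD of the log-HCC residual.
#' @param hcc_log_mean intercept of log-HCC (log pg/mg).
#' @param sex_effect_hcc additive effect of sex (coded 0/1) on log-HCC.
#' @param segment_sd log-scale SD of the three 1-cm hair segments around the
#'   participant-level concentration.
#' @param replicate_cv coefficient of variation of the assay triplicates.
#' @param seed integer seed controlling all stochastic stages.
#'
#' @return An object of class `true_parameters` (a validated list).
#' @examples
#' p <- true_parameters(n_couples = 5, seed = 42)
#' p$loadings
#' @export
true_parameters <- function(n_couples = 37,
                            n_weeks = 12,
                            pss_weeks = c(4, 8, 12),
                            tics_week = 12,
                            drift_mean = c(self = -0.42, partner = -0.38),
                            drift_sd = 0.38,
                            drift_correlation = 0.34,
                            innovation_sd = c(0.7, 0.7),
                            innovation_correlation = 0.70,
                            innovation_covariance = NULL,
                            loadings = default_loadings(),
                            scale_reliability = c(WHS = 0.88, PSS = 0.88, TICS = 0.91),
                            item_counts = c(WHS = 30, PSS = 10, TICS = 12),
                            thresholds = default_thresholds(),
                            item_difficulty_sd = c(WHS = 1.0, PSS = 0.6, TICS = 0.6),
                            pss_reverse_items = c(4, 5, 7, 8),
                            hcc_lag_kernel = NULL,
                            hcc_kernel_peak = 8,
                            hcc_kernel_sd = 2,
                            hcc_effect = 0.24,
                            hcc_noise_sd = 0.47,
                            hcc_log_mean = 1.26,
                            sex_effect_hcc = 0.2,
                            segment_sd = 0.10,
                            replicate_cv = 0.049,
                            seed = 1L) {
  if (is.null(innovation_covariance)) {
    innovation_covariance <- diag(innovation_sd) %*%
      matrix(c(1, innovation_correlation, innovation_correlation, 1), 2) %*%
      diag(innovation_sd)
  }
  innovation_covariance <- unname(as.matrix(innovation_covariance))
  if (is.null(hcc_lag_kernel)) {
    w <- stats::dnorm(seq_len(n_weeks), mean = hcc_kernel_peak, sd = hcc_kernel_sd)
    hcc_lag_kernel <- w / sum(w)
  }
  p <- structure(list(
    n_couples = as.integer(n_couples), n_weeks = as.integer(n_weeks),
    pss_weeks = as.integer(pss_weeks), tics_week = as.integer(tics_week),
    drift_mean = drift_mean, drift_sd = drift_sd,
    drift_correlation = drift_correlation,
    innovation_covariance = innovation_covariance,
    loadings = loadings, scale_reliability = scale_reliability,
    item_counts = item_counts, thresholds = thresholds,
    item_difficulty_sd = item_difficulty_sd,
    pss_reverse_items = as.integer(pss_reverse_items),
    hcc_lag_kernel = hcc_lag_kernel, hcc_effect = hcc_effect,
    hcc_noise_sd = hcc_noise_sd, hcc_log_mean = hcc_log_mean,
    sex_effect_hcc = sex_effect_hcc, segment_sd = segment_sd,
    replicate_cv = replicate_cv, seed = as.integer(seed)
  ), class = "true_parameters")
  validate_true_parameters(p)
  p
}

default_loadings <- function() {
  matrix(c(0.87, 0.49, 0.44, 0.91, 0.53, 0.47), nrow = 3,
         dimnames = list(c("WHS", "PSS", "TICS"), c("self", "partner")))
}

# Marginal category probabilities chosen so that scored scales land near the
# observed descriptive means: WHS_n ~ 11.8/30 occurred, WHS_occur ~ 0.69,
# PSS sum ~ 14/40, TICS sum ~ 14/48, WHS_intens ~ 0.70 conditional.
default_thresholds <- function() {
  list(
    WHS           = c(0.607, 0.200, 0.115, 0.050, 0.028),
    WHS_intensity = c(0.580, 0.240, 0.110, 0.045, 0.025),
    PSS           = c(0.240, 0.330, 0.270, 0.110, 0.050),
    TICS          = c(0.340, 0.320, 0.210, 0.090, 0.040)
  )
}

validate_true_parameters <- function(p) {
  stopifnot(p$n_couples >= 1, p$n_weeks >= 2)
  check_covariance(p$innovation_covariance, "innovation_covariance",
                   strict = FALSE)
  k <- p$hcc_lag_kernel
  if (length(k) != p$n_weeks) {
    stop("hcc_lag_kernel must have one weight per weekly occasion", call. = FALSE)
  }
  if (any(k < 0) || abs(sum(k) - 1) > 1e-12) {
    stop("hcc_lag_kernel weights must be nonnegative and sum to 1", call. = FALSE)
  }
  if (any(abs(p$loadings) > 1)) {
    stop("standardized loadings must lie in [-1, 1]", call. = FALSE)
  }
  if (abs(p$drift_correlation) > 1) {
    stop("drift_correlation must lie in [-1, 1]", call. = FALSE)
  }
  if (p$hcc_noise_sd < 0) stop("hcc_noise_sd must be nonnegative", call. = FALSE)
  if (p$replicate_cv < 0) stop("replicate_cv must be nonnegative", call. = FALSE)
  for (nm in names(p$thresholds)) {
    pr <- p$thresholds[[nm]]
    if (length(pr) != 5 || any(pr < 0) || abs(sum(pr) - 1) > 1e-8) {
      stop("thresholds$", nm, " must be 5 category probabilities summing to 1",
           call. = FALSE)
    }
  }
  if (!all(p$pss_weeks %in% seq_len(p$n_weeks)) ||
      !(p$tics_week %in% seq_len(p$n_weeks))) {
    stop("pss_weeks and tics_week must be within 1..n_weeks", call. = FALSE)
  }
  invisible(p)
}

# strict = TRUE demands positive definiteness; strict = FALSE additionally
# admits singular (e.g. all-zero) covariances for degenerate simulations.
check_covariance <- function(m, name, strict = TRUE) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-10) {
    stop(name, " must be a symmetric square matrix", call. = FALSE)
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  bad <- if (strict) min(ev) <= 0 else min(ev) < -1e-10
  if (bad) {
    stop(name, " is not positive ", if (strict) "definite" else "semi-definite",
         " (eigenvalues: ", paste(signif(ev, 4), collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(m)
}

#' @export
print.true_parameters <- function(x, ...) {
  cat("Synthetic study ground truth\n")
  cat(sprintf("  %d couples (N = %d), %d weekly occasions\n",
              x$n_couples, 2L * x$n_couples, x$n_weeks))
  cat("  PSS weeks:", paste(x$pss_weeks, collapse = ", "),
      "| TICS week:", x$tics_week, "\n")
  cat("  standardized loadings (self/partner):\n")
  for (i in rownames(x$loadings)) {
    cat(sprintf("    %-9s %.2f / %.2f\n", i, x$loadings[i, 1], x$loadings[i, 2]))
  }
  sx <- x$innovation_covariance
  cat(sprintf("  innovation SDs %.2f/%.2f, correlation %.2f\n",
              sqrt(sx[1, 1]), sqrt(sx[2, 2]), stats::cov2cor(sx)[1, 2]))
  cat(sprintf("  drift mean %.2f/%.2f, SD %.2f, correlation %.2f\n",
              x$drift_mean[1], x$drift_mean[2], x$drift_sd, x$drift_correlation))
  cat(sprintf("  HCC kernel peak at week %d, effect %.2f, noise SD %.2f\n",
              which.max(x$hcc_lag_kernel), x$hcc_effect, x$hcc_noise_sd))
  invisible(x)
}
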