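#' Lag-association profile of hair cortisol on latent stress
#'
#' Sequentially regresses standardized log hair cortisol concentration on
#' the latent stress state at each assessment occasion, separately per
#' informant perspective, propagating posterior uncertainty by running the
#' regression within every posterior draw. For each occasion the profile
#' reports the regression coefficient `alpha` (on the latent scale as
#' sampled), the implied Pearson correlation `r`, and the regression `R^2`,
#' each summarized over draws by the median and a 95% credible interval.
#' The peak occasion is the one maximizing the `alpha` summary.
#'
#' @param x a `dyad_fit` with monitored states, or a 4-dimensional array of
#'   state draws `[draw, participant, perspective, occasion]`.
#' @param log_hcc one log-HCC value per participant (standardized
#'   internally), in the order of `fit$participants` (or named by id).
#'   Participants with missing HCC are dropped with a warning.
#' @param sex optional 0/1 covariate per participant.
#' @param adjust_sex include sex in the regression.
#' @param standardize_states re-standardize the states within each draw
#'   before regressing, in which case `alpha` equals `r` exactly;
#'   by default states enter on the latent scale as sampled.
#' @param plugin_means use the posterior-mean states in a single regression
#'   instead of per-draw propagation (fast approximation; interval columns
#'   are then reported as NA).
#' @param seed integer seed for the regression-posterior draws.
#' @details Within every posterior draw the ordinary least-squares
#'   coefficient is augmented with a draw from its conditional posterior
#'   (normal-inverse-chi-squared with flat priors), so the reported
#'   intervals propagate both the latent-state uncertainty and the
#'   regression's finite-sample uncertainty across participants. The
#'   implied correlation is `r = alpha * SD(S_t) / SD(log HCC)` per draw,
#'   which under OLS equals the Pearson correlation; with
#'   `standardize_states = TRUE` it equals `alpha` identically. Because the
#'   sampled latent scale can vary strongly across occasions, the peak is
#'   located on the scale-free correlation profile (`r_med`).
#'
#' @return An object of class `lag_association_profile`: a data.frame with
#'   one row per informant x occasion (`alpha_med`, `alpha_lo`, `alpha_hi`,
#'   `r_med`, `r_lo`, `r_hi`, `r2_med`) and attribute `"peak"`, a
#'   data.frame with the peak occasion, peak alpha/r and variance explained
#'   per informant.
#' @export
lag_profile <- function(x, log_hcc, sex = NULL, adjust_sex = FALSE,
                        standardize_states = FALSE, plugin_means = FALSE,
                        seed = 1L) {
  if (inherits(x, "dyad_fit")) {
    if (is.null(x$draws$S)) {
      stop("latent states were not monitored; refit with monitor_states = TRUE",
           call. = FALSE)
    }
    S <- flatten_chains(x$draws$S)
    informants <- x$informants
    if (!is.null(names(log_hcc))) {
      log_hcc <- log_hcc[as.character(x$participants)]
    }
  } else {
    S <- x
    informants <- c("self", "partner")
  }
  if (length(dim(S)) != 4) {
    stop("state draws must be a [draw, participant, perspective, occasion] array",
         call. = FALSE)
  }
  n_part <- dim(S)[2]
  if (length(log_hcc) != n_part) {
    stop("log_hcc must supply one value per participant", call. = FALSE)
  }
  keep <- which(!is.na(log_hcc))
  if (length(keep) < n_part) {
    warning(n_part - length(keep), " participant(s) without HCC dropped")
    S <- S[, keep, , , drop = FALSE]
    log_hcc <- log_hcc[keep]
    if (!is.null(sex)) sex <- sex[keep]
  }
  if (length(log_hcc) < 5) {
    stop("fewer than 5 participants with HCC", call. = FALSE)
  }
  if (adjust_sex && is.null(sex)) {
    stop("adjust_sex = TRUE requires a sex vector", call. = FALSE)
  }
  yz <- as.vector(scale(log_hcc))
  n_occ <- dim(S)[4]
  if (plugin_means) {
    Sm <- apply(S, c(2, 3, 4), mean)
    S <- array(Sm, dim = c(1, dim(Sm)))
  }
  n_draw <- dim(S)[1]
  n <- length(yz)
  set.seed(seed)

  rows <- list()
  peaks <- list()
  for (p in seq_along(informants)) {
    a_mat <- r_mat <- r2_mat <- matrix(NA_real_, n_draw, n_occ)
    for (t in seq_len(n_occ)) {
      X <- S[, , p, t, drop = FALSE]
      dim(X) <- c(n_draw, n)
      if (standardize_states) {
        X <- (X - rowMeans(X)) / apply(X, 1, stats::sd)
      }
      sd_x <- apply(X, 1, stats::sd)
      if (!adjust_sex) {
        xc <- X - rowMeans(X)
        sxx <- rowSums(xc^2)
        bhat <- as.vector(xc %*% yz) / sxx
        rss <- pmax(sum(yz^2) - n * mean(yz)^2 - bhat^2 * sxx, 0)
        a_t <- bhat
        if (!plugin_means) {
          sig2 <- rss / stats::rchisq(n_draw, n - 2)
          a_t <- bhat + stats::rnorm(n_draw, 0, sqrt(sig2 / sxx))
        }
      } else {
        a_t <- numeric(n_draw)
        for (d in seq_len(n_draw)) {
          qrX <- qr(cbind(1, X[d, ], sex))
          bhat <- qr.coef(qrX, yz)
          a_t[d] <- bhat[2]
          if (!plugin_means) {
            rss <- sum(qr.resid(qrX, yz)^2)
            xtxinv <- chol2inv(qr.R(qrX))
            sig2 <- rss / stats::rchisq(1, n - 3)
            a_t[d] <- a_t[d] + stats::rnorm(1, 0, sqrt(sig2 * xtxinv[2, 2]))
          }
        }
      }
      r_t <- pmin(pmax(a_t * sd_x, -1), 1)
      a_mat[, t] <- a_t; r_mat[, t] <- r_t; r2_mat[, t] <- r_t^2
    }
    qs <- function(m, pr) apply(m, 2, stats::quantile, probs = pr, names = FALSE)
    has_ci <- n_draw > 1
    df <- data.frame(
      informant = informants[p], occasion_week = seq_len(n_occ),
      alpha_med = qs(a_mat, 0.5),
      alpha_lo = if (has_ci) qs(a_mat, 0.025) else NA_real_,
      alpha_hi = if (has_ci) qs(a_mat, 0.975) else NA_real_,
      r_med = qs(r_mat, 0.5),
      r_lo = if (has_ci) qs(r_mat, 0.025) else NA_real_,
      r_hi = if (has_ci) qs(r_mat, 0.975) else NA_real_,
      r2_med = qs(r2_mat, 0.5))
    peak_t <- which.max(df$r_med)
    peaks[[p]] <- data.frame(
      informant = informants[p], peak_occasion = peak_t,
      alpha = df$alpha_med[peak_t], r = df$r_med[peak_t],
      variance_explained_pct = 100 * df$r2_med[peak_t])
    rows[[p]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "peak") <- do.call(rbind, peaks)
  class(out) <- c("lag_association_profile", "data.frame")
  out
}

#' Variance in hair cortisol explained per occasion
#'
#' Extracts the posterior-summary regression R^2 of the lag-association
#' profile, expressed as a percentage per occasion and informant.
#'
#' @param profile a [lag_profile()] result.
#' @return A data.frame with `informant`, `occasion_week`, `r2_pct`.
#' @export
variance_explained <- function(profile) {
  stopifnot(inherits(profile, "lag_association_profile"))
  data.frame(informant = profile$informant,
             occasion_week = profile$occasion_week,
             r2_pct = 100 * profile$r2_med)
}

#' @export
print.lag_association_profile <- function(x, ...) {
  cat("Lag-association profile of log-HCC on latent stress\n")
  print.data.frame(round_df(x), row.names = FALSE)
  cat("\nPeak associations:\n")
  print.data.frame(round_df(attr(x, "peak")), row.names = FALSE)
  invisible(x)
}

round_df <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Plot a lag-association profile
#'
#' Draws the per-occasion regression coefficients with their credible bands
#' for each informant perspective.
#'
#' @param x a [lag_profile()] result.
#' @param ... passed to [plot()].
#' @export
plot.lag_association_profile <- function(x, ...) {
  infs <- unique(x$informant)
  old <- graphics::par(mfrow = c(1, length(infs)))
  on.exit(graphics::par(old))
  for (inf in infs) {
    sub <- x[x$informant == inf, ]
    ylim <- range(c(sub$alpha_lo, sub$alpha_hi, 0), na.rm = TRUE)
    plot(sub$occasion_week, sub$alpha_med, type = "b", pch = 16,
         ylim = ylim, xlab = "assessment occasion (week)",
         ylab = expression(alpha[t]), main = paste0(inf, "-report"), ...)
    graphics::arrows(sub$occasion_week, sub$alpha_lo, sub$occasion_week,
                     sub$alpha_hi, angle = 90, code = 3, length = 0.03)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}

#' Attenuation bound of an observable correlation
#'
#' The maximal correlation observable between two measures is limited by
#' their reliabilities: `r_max = sqrt(r_tt1 * r_tt2)`. `retest_floor()`
#' gives the minimal retest stability implied by a fraction of transient
#' (e.g. within-day) variance: `1 - fraction`.
#'
#' @param r_tt1,r_tt2 reliabilities (retest stabilities) of the two measures.
#' @return The upper bound on the observable correlation.
#' @examples
#' attenuation_bound(0.72, retest_floor(0.88))  # ~0.29
#' @export
attenuation_bound <- function(r_tt1, r_tt2) {
  stopifnot(r_tt1 >= 0, r_tt2 >= 0)
  sqrt(r_tt1 * r_tt2)
}

#' @rdname attenuation_bound
#' @param transient_fraction fraction of variance attributable to
#'   transient influences.
#' @export
retest_floor <- function(transient_fraction) {
  stopifnot(transient_fraction >= 0, transient_fraction <= 1)
  1 - transient_fraction
}
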