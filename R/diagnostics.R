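#' Split-chain Gelman-Rubin diagnostic
#'
#' Computes the split-chain potential scale reduction factor: each chain is
#' split in half, and R-hat = sqrt(((n-1)/n * W + B/n) / W) with W the mean
#' within-half variance and B the between-half variance of the half means.
#' Values near 1 indicate convergence.
#'
#' For a `dyad_fit`, R-hat is computed for every monitored scalar parameter
#' (free loadings, residual SDs, drift hyperparameters, drift and
#' innovation covariance entries, sex coefficients if present) and returned
#' as a named vector.
#'
#' @param x an iterations x chains matrix of draws of one parameter, or a
#'   `dyad_fit` object.
#' @param ... unused.
#' @return A single R-hat value (matrix input) or a named vector
#'   (`dyad_fit` input); `NA` with fewer than 2 chains.
#' @examples
#' set.seed(1)
#' gelman_rubin(matrix(rnorm(2000), 1000, 2))  # ~1
#' @export
gelman_rubin <- function(x, ...) UseMethod("gelman_rubin")

#' @export
gelman_rubin.default <- function(x, ...) {
  x <- as.matrix(x)
  if (ncol(x) < 2) return(NA_real_)
  if (nrow(x) < 4) stop("need at least 4 draws per chain", call. = FALSE)
  n <- nrow(x) %/% 2L
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(ch) {
    cbind(x[seq_len(n), ch], x[seq_len(n) + (nrow(x) - n), ch])
  }))
  W <- mean(apply(halves, 2, stats::var))
  B <- n * stats::var(colMeans(halves))
  if (W == 0) {
    if (B == 0) {
      warning("zero within-chain variance everywhere; R-hat defined as 1")
      return(1)
    }
    return(Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
gelman_rubin.dyad_fit <- function(x, ...) {
  d <- x$draws
  if (dim(d$mu_delta)[2] < 2) {
    return(stats::setNames(NA_real_, "mu_delta[self]"))
  }
  out <- list()
  grab <- function(arr, base, idx_list) {
    for (nm in names(idx_list)) {
      ix <- idx_list[[nm]]
      mat <- arr[, , ix[1], ix[2]]
      out[[paste0(base, "[", nm, "]")]] <<- gelman_rubin.default(mat)
    }
  }
  inst <- x$instruments; infs <- x$informants
  lam_idx <- list()
  for (j in seq_along(inst)[-1]) {
    for (p in 1:2) lam_idx[[paste(inst[j], infs[p], sep = ",")]] <- c(j, p)
  }
  if (length(lam_idx)) grab(d$lambda, "lambda", lam_idx)
  eps_idx <- list()
  for (j in seq_along(inst)) {
    for (p in 1:2) eps_idx[[paste(inst[j], infs[p], sep = ",")]] <- c(j, p)
  }
  grab(d$sigma_eps, "sigma_eps", eps_idx)
  out[["mu_delta[self]"]] <- gelman_rubin.default(d$mu_delta[, , 1])
  out[["mu_delta[partner]"]] <- gelman_rubin.default(d$mu_delta[, , 2])
  cov_idx <- list("1,1" = c(1, 1), "2,2" = c(2, 2), "1,2" = c(1, 2))
  grab(d$Sigma_xi, "Sigma_xi", cov_idx)
  grab(d$Sigma_delta, "Sigma_delta", cov_idx)
  if (!is.null(d$beta_sex)) grab(d$beta_sex, "beta_sex", eps_idx)
  unlist(out)
}

# flatten [iter, chain, ...] draws to [draw, ...]
flatten_chains <- function(arr) {
  d <- dim(arr)
  out <- aperm(arr, c(1, 2, seq_along(d)[-(1:2)]))
  dim(out) <- c(d[1] * d[2], d[-(1:2)])
  out
}

#' Fully standardized loadings and residual-variance fractions
#'
#' Converts the raw loadings of a [fit_state_space()] result to the fully
#' standardized scale: per posterior draw, `lambda* = lambda * SD(S) /
#' SD(Q)`, where `SD(S)` is the SD of that draw's latent states (per
#' informant, across participants and occasions) and `SD(Q)` the observed
#' SD of the instrument's scores (1 when the input was standardized). The
#' residual-variance fraction is `1 - lambda*^2`.
#'
#' @param fit a `dyad_fit` (with monitored states).
#' @param prob credible-interval mass.
#' @return A data.frame with one row per instrument x informant:
#'   posterior mean, median and interval of `lambda*`, and the posterior
#'   mean residual-variance fraction.
#' @export
standardized_loadings <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "dyad_fit"))
  if (is.null(fit$draws$S)) {
    stop("latent states were not monitored; refit with monitor_states = TRUE",
         call. = FALSE)
  }
  lam <- flatten_chains(fit$draws$lambda)   # [draw, J, 2]
  S <- flatten_chains(fit$draws$S)          # [draw, N, 2, T]
  ndraw <- dim(lam)[1]
  sd_s <- vapply(1:2, function(p) {
    apply(S[, , p, , drop = FALSE], 1, stats::sd)
  }, numeric(ndraw))                        # [draw, 2]
  alpha <- (1 - prob) / 2
  rows <- list()
  for (j in seq_along(fit$instruments)) {
    for (p in 1:2) {
      lam_star <- lam[, j, p] * sd_s[, p] / fit$sd_q[j, p]
      rows[[length(rows) + 1L]] <- data.frame(
        instrument = fit$instruments[j], informant = fit$informants[p],
        loading = mean(lam_star), loading_median = stats::median(lam_star),
        lower = stats::quantile(lam_star, alpha, names = FALSE),
        upper = stats::quantile(lam_star, 1 - alpha, names = FALSE),
        residual_fraction = mean(1 - lam_star^2))
    }
  }
  do.call(rbind, rows)
}

#' Informant-coupling correlations of latent stress changes
#'
#' Summarizes how strongly self- and partner-perspective latent stress
#' changes co-vary: `r_xi`, the correlation of the stochastic (transient)
#' weekly innovations, taken per draw from the innovation covariance; and
#' `r_delta`, the correlation of the systematic individual drifts, taken
#' per draw from the hierarchical drift covariance. For reference, the
#' Pearson correlation of the participants' posterior-mean drifts
#' (`r_delta_unconditional`) and its per-draw analogue are also reported.
#'
#' @param fit a `dyad_fit`.
#' @param prob credible-interval mass.
#' @return A data.frame with rows `r_xi`, `r_delta`,
#'   `r_delta_unconditional`, `r_delta_perdraw`: posterior mean/estimate
#'   and interval.
#' @export
informant_coupling <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "dyad_fit"))
  alpha <- (1 - prob) / 2
  qs <- function(v) stats::quantile(v, c(alpha, 1 - alpha), names = FALSE)
  Sx <- flatten_chains(fit$draws$Sigma_xi)
  r_xi <- Sx[, 1, 2] / sqrt(Sx[, 1, 1] * Sx[, 2, 2])
  Sd <- flatten_chains(fit$draws$Sigma_delta)
  r_delta <- Sd[, 1, 2] / sqrt(Sd[, 1, 1] * Sd[, 2, 2])
  delta <- flatten_chains(fit$draws$delta)  # [draw, N, 2]
  n_part <- dim(delta)[2]
  if (n_part < 4) {
    warning("fewer than 4 participants: drift correlations are unstable")
  }
  dbar <- apply(delta, c(2, 3), mean)
  r_unc <- stats::cor(dbar[, 1], dbar[, 2])
  r_pd <- vapply(seq_len(dim(delta)[1]),
                 function(d) stats::cor(delta[d, , 1], delta[d, , 2]),
                 numeric(1))
  out <- rbind(
    data.frame(quantity = "r_xi", estimate = mean(r_xi),
               lower = qs(r_xi)[1], upper = qs(r_xi)[2]),
    data.frame(quantity = "r_delta", estimate = mean(r_delta),
               lower = qs(r_delta)[1], upper = qs(r_delta)[2]),
    data.frame(quantity = "r_delta_unconditional", estimate = r_unc,
               lower = NA_real_, upper = NA_real_),
    data.frame(quantity = "r_delta_perdraw", estimate = mean(r_pd),
               lower = qs(r_pd)[1], upper = qs(r_pd)[2]))
  rownames(out) <- NULL
  out
}

#' Posterior mean drift summaries
#'
#' @param fit a `dyad_fit`.
#' @return A data.frame per informant with the posterior mean and SD of the
#'   population drift `mu_delta`.
#' @export
drift_summary <- function(fit) {
  mu <- flatten_chains(fit$draws$mu_delta)
  data.frame(informant = fit$informants,
             mean = colMeans(mu),
             sd = apply(mu, 2, stats::sd))
}

#' Sample latent states of a single series at fixed parameters
#'
#' Draws latent state trajectories of one participant-perspective series by
#' forward filtering / backward sampling with all model parameters
#' (loadings, innovation SD, residual SDs, drift) held fixed -- the
#' linear-Gaussian special case whose exact posterior the
#' [kalman_smoother()] provides in closed form. Used to validate the
#' sampling machinery against that independent oracle.
#'
#' @inheritParams kalman_filter
#' @param n_chains,n_iter number of chains and kept draws per chain.
#' @param seed integer seed.
#' @return A list with `mean`, `sd`, `mcse` (Monte-Carlo standard error of
#'   the posterior mean, from the effective sample size), `ess` and
#'   `draws` (iterations x chains x occasions array).
#' @export
fit_single_series <- function(y, lambda, sigma_xi, sigma_eps, delta = 0,
                              m0 = 0, P0 = 1, n_chains = 3L, n_iter = 2000L,
                              seed = 1L) {
  y <- rbind(y)
  J <- nrow(y); T <- ncol(y)
  stopifnot(length(lambda) == J, length(sigma_eps) == J, sigma_xi > 0,
            all(sigma_eps > 0))
  draws <- array(NA_real_, c(n_iter, n_chains, T))
  for (ch in seq_len(n_chains)) {
    set.seed(seed + 1000L * ch)
    for (it in seq_len(n_iter)) {
      draws[it, ch, ] <- ffbs_single(y, lambda, sigma_xi, sigma_eps,
                                     delta, m0, P0)
    }
  }
  flat <- flatten_chains(draws)
  ess <- vapply(seq_len(T), function(t) {
    sum(vapply(seq_len(n_chains),
               function(ch) coda::effectiveSize(draws[, ch, t]), numeric(1)))
  }, numeric(1))
  post_sd <- apply(flat, 2, stats::sd)
  list(mean = colMeans(flat), sd = post_sd,
       mcse = post_sd / sqrt(pmax(ess, 1)), ess = ess, draws = draws)
}

# one forward-filter backward-sampling pass of the univariate local-level
# model with drift (exact posterior draw at fixed parameters)
ffbs_single <- function(y, lambda, sigma_xi, sigma_eps, delta, m0, P0) {
  T <- ncol(y); J <- nrow(y)
  m <- numeric(T); P <- numeric(T)
  m_cur <- m0; P_cur <- P0
  Pp <- numeric(T)
  for (t in seq_len(T)) {
    m_cur <- m_cur + delta
    P_cur <- P_cur + sigma_xi^2
    Pp[t] <- P_cur
    for (j in seq_len(J)) {
      if (is.na(y[j, t])) next
      f <- lambda[j]^2 * P_cur + sigma_eps[j]^2
      K <- P_cur * lambda[j] / f
      m_cur <- m_cur + K * (y[j, t] - lambda[j] * m_cur)
      P_cur <- P_cur - K * lambda[j] * P_cur
    }
    m[t] <- m_cur; P[t] <- P_cur
  }
  s <- numeric(T)
  s[T] <- stats::rnorm(1, m[T], sqrt(P[T]))
  if (T > 1) {
    for (t in (T - 1):1) {
      Ppred <- P[t] + sigma_xi^2
      Jg <- P[t] / Ppred
      cm <- m[t] + Jg * (s[t + 1] - delta - m[t])
      cv <- P[t] - Jg^2 * Ppred
      s[t] <- stats::rnorm(1, cm, sqrt(max(cv, 0)))
    }
  }
  s
}
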