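#' Kalman filter and smoother for a univariate local-level model with drift
#'
#' Exact filtering/smoothing for the linear-Gaussian single-series case of
#' the latent stress model: state `S[t] = S[t-1] + delta + xi[t]`,
#' `xi ~ N(0, sigma_xi^2)`, initial state `S[0] ~ N(m0, P0)`, and
#' observations `y[j, t] = lambda[j] * S[t] + eps`, `eps ~ N(0,
#' sigma_eps[j]^2)` (missing entries allowed). Serves as the closed-form
#' oracle against which the MCMC sampler is validated.
#'
#' @param y instruments x occasions matrix of observations (`NA` = missing).
#' @param lambda vector of loadings, one per instrument (row of `y`).
#' @param sigma_xi innovation SD (> 0).
#' @param sigma_eps vector of residual SDs, one per instrument.
#' @param delta drift per occasion.
#' @param m0,P0 prior mean and variance of the pre-series state `S[0]`.
#' @return `kalman_filter()`: list with `mean`, `var` (filtered moments per
#'   occasion), `predicted_mean`, `predicted_var` and `loglik`.
#'   `kalman_smoother()`: list with `mean`, `var` (smoothed moments) and
#'   `loglik`.
#' @examples
#' y <- matrix(rnorm(12), 1, 12)
#' ks <- kalman_smoother(y, lambda = 1, sigma_xi = 0.3, sigma_eps = 0.5)
#' ks$mean
#' @export
kalman_filter <- function(y, lambda, sigma_xi, sigma_eps, delta = 0,
                          m0 = 0, P0 = 1) {
  y <- rbind(y)
  J <- nrow(y); T <- ncol(y)
  stopifnot(length(lambda) == J, length(sigma_eps) == J, sigma_xi > 0)
  m <- numeric(T); P <- numeric(T)
  mp <- numeric(T); Pp <- numeric(T)
  loglik <- 0
  m_cur <- m0; P_cur <- P0
  for (t in seq_len(T)) {
    m_cur <- m_cur + delta
    P_cur <- P_cur + sigma_xi^2
    mp[t] <- m_cur; Pp[t] <- P_cur
    for (j in seq_len(J)) {
      if (is.na(y[j, t])) next
      # sequential scalar updates: instruments are conditionally independent
      f <- lambda[j]^2 * P_cur + sigma_eps[j]^2
      v <- y[j, t] - lambda[j] * m_cur
      loglik <- loglik - 0.5 * (log(2 * pi * f) + v^2 / f)
      K <- P_cur * lambda[j] / f
      m_cur <- m_cur + K * v
      P_cur <- P_cur - K * lambda[j] * P_cur
    }
    m[t] <- m_cur; P[t] <- P_cur
  }
  list(mean = m, var = P, predicted_mean = mp, predicted_var = Pp,
       loglik = loglik)
}

#' @rdname kalman_filter
#' @export
kalman_smoother <- function(y, lambda, sigma_xi, sigma_eps, delta = 0,
                            m0 = 0, P0 = 1) {
  kf <- kalman_filter(y, lambda, sigma_xi, sigma_eps, delta, m0, P0)
  T <- length(kf$mean)
  ms <- kf$mean; Ps <- kf$var
  if (T > 1) {
    for (t in (T - 1):1) {
      # Rauch-Tung-Striebel backward pass; transition matrix is 1
      C <- kf$var[t] / kf$predicted_var[t + 1]
      ms[t] <- kf$mean[t] + C * (ms[t + 1] - kf$predicted_mean[t + 1])
      Ps[t] <- kf$var[t] + C^2 * (Ps[t + 1] - kf$predicted_var[t + 1])
    }
  }
  list(mean = ms, var = Ps, loglik = kf$loglik)
}

#' Direct joint-Gaussian log-likelihood of the single-series model
#'
#' Computes the same marginal likelihood as [kalman_filter()] by building
#' the dense joint covariance of all observations from the random-walk
#' prefix sums, `Cov(S[t], S[u]) = P0 + sigma_xi^2 * min(t, u)`, and
#' evaluating the multivariate normal density directly. Used as an
#' independent cross-check of the filter recursion.
#'
#' @inheritParams kalman_filter
#' @return The log-likelihood of the non-missing observations.
#' @export
direct_loglik <- function(y, lambda, sigma_xi, sigma_eps, delta = 0,
                          m0 = 0, P0 = 1) {
  y <- rbind(y)
  J <- nrow(y); T <- ncol(y)
  obs <- which(!is.na(y), arr.ind = TRUE)
  jj <- obs[, 1]; tt <- obs[, 2]
  K <- P0 + sigma_xi^2 * outer(tt, tt, pmin)
  Sigma <- (lambda[jj] %o% lambda[jj]) * K
  diag(Sigma) <- diag(Sigma) + sigma_eps[jj]^2
  mu <- lambda[jj] * (m0 + delta * tt)
  v <- y[!is.na(y)]
  v <- y[cbind(jj, tt)] - mu
  ch <- chol(Sigma)
  q <- backsolve(ch, v, transpose = TRUE)
  -0.5 * (length(v) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(q^2))
}
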