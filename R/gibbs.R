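# Blocked Gibbs sampler for the dyadic state-space model.
#
# Sampling scheme per iteration:
#   1. delta_i | y, theta  -- drift pairs drawn from their marginal posterior
#      with the latent states integrated out analytically (the model is
#      linear-Gaussian in delta; the marginal covariance of the de-drifted
#      observations follows from Cov(S_t, S_u) = 1[p=p'] + min(t,u)*Sigma_xi).
#   2. S | delta, y, theta -- forward filter, backward sampling (FFBS) on the
#      2-dimensional (self, partner) state.
#   3. Sigma_xi | S, delta -- conjugate inverse-Wishart update on the
#      innovation pairs (the pre-series state S_0 is sampled en route).
#   4. mu_delta, Sigma_delta | delta -- conjugate normal / inverse-Wishart.
#   5. loadings, sex effects, residual variances | S, y -- conjugate
#      normal-inverse-gamma regressions per instrument x informant.
#
# Blocking delta with the states removes the slow level-vs-trend alternation
# that plagues single-site samplers for random walks with drift. Because the
# assessment design is balanced, participants sharing an observation pattern
# share all covariance recursions; only the mean recursions differ and are
# vectorized across participants.
#
# The remaining slow direction of a pure conditional sweep -- the trade-off
# between the innovation covariance and the reference instrument's residual
# variances through the sampled states -- is removed by partially collapsed
# Metropolis updates: at the top of each sweep, Sigma_xi and the reference
# residual variances are updated under the exact marginal likelihood of the
# observations (states and drifts integrated out analytically), which is
# valid because (delta, S) are redrawn from their exact conditionals before
# they are next used.

run_gibbs_chain <- function(dat, spec, chain_seed, n_iter, n_warm, thin) {
  set.seed(chain_seed)
  N <- dat$N; T <- dat$T; J <- dat$J
  Y <- dat$Y                       # [N, 2, J, T], NA where unobserved
  sex <- dat$sex                   # NULL or length-N 0/1
  adjust_sex <- !is.null(sex)

  Y1 <- Y[1, , , ]
  dim(Y1) <- dim(Y)[-1]
  obs_grid <- which(!is.na(Y1), arr.ind = TRUE)
  obs <- data.frame(p = obs_grid[, 1], j = obs_grid[, 2], t = obs_grid[, 3])
  obs <- obs[order(obs$t, obs$p, obs$j), ]
  n_obs <- nrow(obs)

  lam_prior_var <- spec$loading_sd^2
  sex_prior_var <- 4
  ig_a0 <- 2; ig_b0 <- 0.5
  R_xi <- spec$iw_scale; R_delta <- spec$drift_iw_scale
  df_iw <- spec$iw_df

  # --- initial values (overdispersed across chains) ---
  lam <- matrix(1, J, 2)
  if (J > 1) lam[2:J, ] <- stats::runif(2 * (J - 1), 0.1, 1.5)
  sig2_eps <- matrix(stats::runif(2 * J, 0.1, 1.5), J, 2)
  Sigma_xi <- diag(stats::runif(1, 0.02, 0.4), 2)
  Sigma_delta <- diag(stats::runif(1, 0.002, 0.05), 2)
  mu_delta <- stats::rnorm(2, 0, 0.15)
  beta_sex <- matrix(0, J, 2)
  if (adjust_sex) beta_sex <- matrix(stats::rnorm(2 * J, 0, 0.3), J, 2)
  delta <- matrix(stats::rnorm(2 * N, mu_delta, 0.05), N, 2, byrow = TRUE)
  S <- array(0, dim = c(N, 2, T))

  n_keep <- (n_iter - n_warm) %/% thin
  keep <- list(
    lambda = array(NA_real_, c(n_keep, J, 2)),
    sigma_eps = array(NA_real_, c(n_keep, J, 2)),
    mu_delta = array(NA_real_, c(n_keep, 2)),
    Sigma_delta = array(NA_real_, c(n_keep, 2, 2)),
    Sigma_xi = array(NA_real_, c(n_keep, 2, 2)),
    delta = array(NA_real_, c(n_keep, N, 2)),
    S = if (spec$monitor_states) array(NA_real_, c(n_keep, N, 2, T)) else NULL,
    beta_sex = if (adjust_sex) array(NA_real_, c(n_keep, J, 2)) else NULL
  )

  # flattened observation matrix [n_obs, N]: row order matches `obs`
  Yo <- matrix(NA_real_, n_obs, N)
  for (r in seq_len(n_obs)) Yo[r, ] <- Y[, obs$p[r], obs$j[r], obs$t[r]]
  if (anyNA(Yo)) {
    stop("the blocked Gibbs backend requires a complete balanced panel ",
         "(every participant observed at every scheduled cell); use ",
         'backend = "jags" for data with participant-specific missingness',
         call. = FALSE)
  }

  # fixed pieces of the marginal covariance construction
  same_p <- outer(obs$p, obs$p, "==") * 1
  mint <- outer(obs$t, obs$t, pmin)
  p_row <- rep(obs$p, times = n_obs)
  p_col <- rep(obs$p, each = n_obs)
  eps_cells <- cbind(obs$j, obs$p)

  build_V <- function(lam, sig2_eps, Sigma_xi) {
    lam_r <- lam[eps_cells]
    sig_pp <- matrix(Sigma_xi[cbind(p_row, p_col)], n_obs, n_obs)
    V <- (lam_r %o% lam_r) * (same_p + mint * sig_pp)
    diag(V) <- diag(V) + sig2_eps[eps_cells]
    V
  }
  design_M <- function(lam) {
    M <- matrix(0, n_obs, 2)
    M[cbind(seq_len(n_obs), obs$p)] <- lam[eps_cells] * obs$t
    M
  }
  # log marginal likelihood of all participants' observations with both the
  # states and the drifts integrated out
  marg_loglik <- function(lam, sig2_eps, Sigma_xi, mu_delta, Sigma_delta, Yc) {
    M <- design_M(lam)
    Vf <- build_V(lam, sig2_eps, Sigma_xi) + M %*% Sigma_delta %*% t(M)
    ch <- tryCatch(chol(Vf), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    R <- Yc - as.vector(M %*% mu_delta)
    Q <- backsolve(ch, R, transpose = TRUE)
    -0.5 * (n_obs * N * log(2 * pi)) - N * sum(log(diag(ch))) -
      0.5 * sum(Q^2)
  }
  log_iw_prior <- function(Sigma, R, df) {
    ch <- chol(Sigma)
    -(df + 3) * sum(log(diag(ch))) - 0.5 * sum(diag(R %*% chol2inv(ch)))
  }
  mh_scale <- 0.25

  kidx <- 0L
  for (it in seq_len(n_iter)) {
    off_r <- if (adjust_sex) outer(beta_sex[eps_cells], sex) else 0
    Yc <- Yo - off_r                      # [n_obs, N]

    ## ---- step 0: partially collapsed Metropolis moves ----
    ## Sigma_xi under the marginal likelihood (S, delta integrated out)
    cur_ll <- marg_loglik(lam, sig2_eps, Sigma_xi, mu_delta, Sigma_delta, Yc)
    cov_to_u <- function(S) {
      c(log(S[1, 1]), log(S[2, 2]),
        atanh(S[1, 2] / sqrt(S[1, 1] * S[2, 2])))
    }
    u_to_cov <- function(u) {
      rho <- tanh(u[3])
      diag(exp(u[1:2] / 2)) %*% matrix(c(1, rho, rho, 1), 2) %*%
        diag(exp(u[1:2] / 2))
    }
    log_jac <- function(u) 1.5 * sum(u[1:2]) + log(1 - tanh(u[3])^2)
    for (sub in 1:3) {
      u <- cov_to_u(Sigma_xi)
      u_new <- u + stats::rnorm(3, 0, mh_scale)
      Sx_new <- u_to_cov(u_new)
      new_ll <- marg_loglik(lam, sig2_eps, Sx_new, mu_delta, Sigma_delta, Yc)
      lr <- new_ll - cur_ll +
        log_iw_prior(Sx_new, R_xi, df_iw) - log_iw_prior(Sigma_xi, R_xi, df_iw) +
        log_jac(u_new) - log_jac(u)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        Sigma_xi <- Sx_new; cur_ll <- new_ll
      }
    }
    ## drift covariance under the marginal likelihood
    for (sub in 1:2) {
      u <- cov_to_u(Sigma_delta)
      u_new <- u + stats::rnorm(3, 0, mh_scale)
      Sd_new <- u_to_cov(u_new)
      new_ll <- marg_loglik(lam, sig2_eps, Sigma_xi, mu_delta, Sd_new, Yc)
      lr <- new_ll - cur_ll +
        log_iw_prior(Sd_new, R_delta, df_iw) -
        log_iw_prior(Sigma_delta, R_delta, df_iw) +
        log_jac(u_new) - log_jac(u)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        Sigma_delta <- Sd_new; cur_ll <- new_ll
      }
    }
    ## reference-instrument residual variances under the marginal likelihood
    for (p in 1:2) {
      s2 <- sig2_eps
      lv <- log(s2[1, p])
      lv_new <- lv + stats::rnorm(1, 0, mh_scale)
      s2[1, p] <- exp(lv_new)
      new_ll <- marg_loglik(lam, s2, Sigma_xi, mu_delta, Sigma_delta, Yc)
      lr <- new_ll - cur_ll +
        (-(ig_a0 + 1) * lv_new - ig_b0 / exp(lv_new)) -
        (-(ig_a0 + 1) * lv - ig_b0 / exp(lv)) +
        lv_new - lv
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        sig2_eps <- s2; cur_ll <- new_ll
      }
    }

    ## ---- step 1: delta | y (states integrated out) ----
    lam_r <- lam[eps_cells]
    V <- build_V(lam, sig2_eps, Sigma_xi)
    M <- design_M(lam)
    Vch <- chol(V)
    ViM <- backsolve(Vch, backsolve(Vch, M, transpose = TRUE))
    ViY <- backsolve(Vch, backsolve(Vch, Yc, transpose = TRUE))
    Om_d <- solve(Sigma_delta)
    prec <- Om_d + crossprod(M, ViM)
    prec_ch <- chol(prec)
    rhs <- as.vector(Om_d %*% mu_delta) + crossprod(M, ViY)  # [2, N]
    mean_d <- backsolve(prec_ch, backsolve(prec_ch, rhs, transpose = TRUE))
    z <- matrix(stats::rnorm(2 * N), 2, N)
    delta <- t(mean_d + backsolve(prec_ch, z))

    ## ---- step 2: S | delta, y (FFBS, shared covariances) ----
    P <- diag(2) + Sigma_xi                # prior of x_1 = S0 + delta + xi_1
    mcur <- delta                          # E[x_1] = delta (S0 mean 0)
    Ms <- array(NA_real_, c(N, 2, T)); Ps <- vector("list", T)
    Pred <- vector("list", T)
    for (t in seq_len(T)) {
      if (t > 1) {
        mcur <- mcur + delta
        P <- P + Sigma_xi
      }
      Pred[[t]] <- P
      rows <- which(obs$t == t)
      for (r in rows) {
        p <- obs$p[r]; j <- obs$j[r]
        h <- c(0, 0); h[p] <- lam[j, p]
        f <- as.numeric(h %*% P %*% h) + sig2_eps[j, p]
        Kg <- as.vector(P %*% h) / f
        off <- if (adjust_sex) beta_sex[j, p] * sex else 0
        v <- Yo[r, ] - mcur %*% h - off
        mcur <- mcur + as.vector(v) %o% Kg
        P <- P - Kg %o% as.vector(h %*% P)
        P <- (P + t(P)) / 2
      }
      Ms[, , t] <- mcur
      Ps[[t]] <- P
    }
    # backward sampling
    x <- Ms[, , T] + matrix(stats::rnorm(2 * N), N, 2) %*% chol(Ps[[T]])
    S[, , T] <- x
    if (T > 1) {
      for (t in (T - 1):1) {
        Ppred <- Ps[[t]] + Sigma_xi
        Jg <- Ps[[t]] %*% solve(Ppred)
        cond_m <- Ms[, , t] + (x - delta - Ms[, , t]) %*% t(Jg)
        cond_P <- Ps[[t]] - Jg %*% Ppred %*% t(Jg)
        cond_P <- (cond_P + t(cond_P)) / 2
        x <- cond_m + matrix(stats::rnorm(2 * N), N, 2) %*% safe_chol(cond_P)
        S[, , t] <- x
      }
    }

    ## ---- step 3: Sigma_xi | S, delta ----
    # sample the pre-series state S_0 | x_1: prior N(0, I), x_1 = S0+delta+xi
    V1 <- diag(2) + Sigma_xi
    G <- diag(2) - solve(V1)               # posterior cov of S0
    A1 <- solve(V1)                        # E[S0 | x1] = A1 (x1 - delta)
    S0 <- (S[, , 1] - delta) %*% t(A1) +
      matrix(stats::rnorm(2 * N), N, 2) %*% safe_chol(G)
    E <- S[, , 1] - S0 - delta
    SS <- crossprod(E)
    for (t in 2:T) {
      E <- S[, , t] - S[, , t - 1] - delta
      SS <- SS + crossprod(E)
    }
    Om_xi <- stats::rWishart(1, df_iw + N * T, solve(R_xi + SS))[, , 1]
    Sigma_xi <- solve(Om_xi)

    ## ---- step 4: mu_delta, Sigma_delta | delta ----
    Dc <- sweep(delta, 2, mu_delta)
    Om_dd <- stats::rWishart(1, df_iw + N, solve(R_delta + crossprod(Dc)))[, , 1]
    Sigma_delta <- solve(Om_dd)
    prec_mu <- diag(2) + N * Om_dd         # prior mu ~ N(0, I)
    mean_mu <- solve(prec_mu, Om_dd %*% colSums(delta))
    mu_delta <- as.vector(mean_mu) +
      backsolve(chol(prec_mu), stats::rnorm(2))

    ## ---- step 5: loadings, sex effects, residual variances ----
    for (j in seq_len(J)) {
      for (p in 1:2) {
        tt <- obs$t[obs$j == j & obs$p == p]
        if (!length(tt)) next
        yv <- as.vector(t(Yo[which(obs$j == j & obs$p == p), , drop = FALSE]))
        xs <- as.vector(S[, p, tt])        # [N x length(tt)] column-major
        # design: loading (free unless reference) and sex effect
        Xd <- NULL; prior_prec <- NULL
        yadj <- yv
        if (j > 1) { Xd <- cbind(Xd, xs); prior_prec <- c(prior_prec, 1 / lam_prior_var) }
        else yadj <- yadj - xs             # reference loading fixed at 1
        if (adjust_sex) {
          Xd <- cbind(Xd, rep(sex, times = length(tt)))
          prior_prec <- c(prior_prec, 1 / sex_prior_var)
        }
        if (is.null(Xd)) {
          resid <- yadj
        } else {
          A <- crossprod(Xd) / sig2_eps[j, p] + diag(prior_prec, ncol(Xd))
          bmean <- solve(A, crossprod(Xd, yadj) / sig2_eps[j, p])
          bdraw <- as.vector(bmean) + backsolve(chol(A), stats::rnorm(ncol(Xd)))
          ix <- 1
          if (j > 1) { lam[j, p] <- bdraw[ix]; ix <- ix + 1 }
          if (adjust_sex) beta_sex[j, p] <- bdraw[ix]
          resid <- yadj - Xd %*% bdraw
        }
        sig2_eps[j, p] <- 1 / stats::rgamma(1, ig_a0 + length(yv) / 2,
                                            ig_b0 + sum(resid^2) / 2)
      }
    }

    ## ---- store ----
    if (it > n_warm && (it - n_warm) %% thin == 0) {
      kidx <- kidx + 1L
      keep$lambda[kidx, , ] <- lam
      keep$sigma_eps[kidx, , ] <- sqrt(sig2_eps)
      keep$mu_delta[kidx, ] <- mu_delta
      keep$Sigma_delta[kidx, , ] <- Sigma_delta
      keep$Sigma_xi[kidx, , ] <- Sigma_xi
      keep$delta[kidx, , ] <- delta
      if (spec$monitor_states) keep$S[kidx, , , ] <- S
      if (adjust_sex) keep$beta_sex[kidx, , ] <- beta_sex
    }
  }
  keep
}

# Cholesky tolerant of positive semi-definite matrices (deterministic
# backward-sampling steps can make conditional covariances singular).
safe_chol <- function(P) {
  ch <- tryCatch(chol(P), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen(P, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  ch <- sqrt(ev) * t(e$vectors)
  ch
}

fit_state_space_gibbs <- function(dat, spec, seed) {
  n_sample <- max(2L, round(spec$n_iter * (1 - spec$warmup)))
  n_warm <- spec$n_iter - n_sample
  thin <- if (identical(spec$thin, "auto")) max(1L, n_sample %/% 1000L)
          else as.integer(spec$thin)
  chains <- lapply(seq_len(spec$n_chains), function(ch) {
    run_gibbs_chain(dat, spec, chain_seed = seed + 1000L * ch,
                    n_iter = spec$n_iter, n_warm = n_warm, thin = thin)
  })
  # assemble [iter, chain, ...] arrays
  bind_chains <- function(name) {
    a1 <- chains[[1]][[name]]
    if (is.null(a1)) return(NULL)
    d <- dim(a1)
    out <- array(NA_real_, c(d[1], length(chains), prod(d[-1])))
    for (ch in seq_along(chains)) {
      a <- chains[[ch]][[name]]
      dim(a) <- c(d[1], prod(d[-1]))
      out[, ch, ] <- a
    }
    dim(out) <- c(d[1], length(chains), d[-1])
    out
  }
  draws <- list(lambda = bind_chains("lambda"),
                sigma_eps = bind_chains("sigma_eps"),
                mu_delta = bind_chains("mu_delta"),
                Sigma_delta = bind_chains("Sigma_delta"),
                Sigma_xi = bind_chains("Sigma_xi"),
                delta = bind_chains("delta"),
                S = bind_chains("S"),
                beta_sex = bind_chains("beta_sex"))
  draws <- draws[!vapply(draws, is.null, logical(1))]
  attr(draws, "thin") <- thin
  draws
}
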