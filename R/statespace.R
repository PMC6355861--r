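#' Standardize scored stress measures
#'
#' Standardizes each measure x informant series to mean 0 and SD 1 across
#' all persons and occasions jointly, the scale on which the state-space
#' model operates.
#'
#' @param scores tidy score table (see [score_panel()]).
#' @param measures measures to keep; defaults to all present.
#' @return The filtered score table with standardized `value`; the
#'   attribute `"scaling"` records the mean/SD removed per series.
#' @export
standardize_measures <- function(scores, measures = NULL) {
  if (is.null(measures)) measures <- unique(scores$measure)
  out <- scores[scores$measure %in% measures, ]
  scaling <- list()
  for (m in measures) {
    for (inf in unique(out$informant)) {
      idx <- out$measure == m & out$informant == inf
      if (!any(idx)) next
      v <- out$value[idx]
      if (sum(!is.na(v)) < 2) {
        stop("measure ", m, " (", inf, ") has fewer than 2 observations",
             call. = FALSE)
      }
      s <- stats::sd(v, na.rm = TRUE)
      if (s == 0) {
        stop("measure ", m, " (", inf, ") has zero variance", call. = FALSE)
      }
      mu <- mean(v, na.rm = TRUE)
      out$value[idx] <- (v - mu) / s
      scaling[[paste(m, inf, sep = "_")]] <-
        data.frame(measure = m, informant = inf, mean = mu, sd = s)
    }
  }
  attr(out, "scaling") <- do.call(rbind, scaling)
  out
}

#' Specification of the dyadic state-space model
#'
#' Collects the structural choices, priors and MCMC settings of the dyadic
#' dynamic factor model. The latent subjective-stress level of each
#' participant follows, per informant perspective, a random walk with
#' individual drift (`S[t] = S[t-1] + delta + xi[t]`); the self- and
#' partner-perspective innovations are coupled through a 2x2 covariance
#' with a weakly informative inverse-Wishart prior, and the drift pairs
#' through a hierarchical bivariate normal whose covariance also carries an
#' inverse-Wishart prior. Standardized questionnaire scores load on the
#' latent level via instrument-specific loadings; the latent scale is
#' identified by fixing the reference instrument's loading to 1, with
#' fully standardized loadings computed per posterior draw afterwards.
#'
#' @param instruments measures entering the model; the first is the
#'   reference instrument (loading fixed to 1) and must be scheduled at
#'   every weekly occasion.
#' @param backend `"gibbs"` (default) for the package's blocked Gibbs
#'   sampler, which draws each participant's drift pair from its marginal
#'   posterior with the states integrated out and the states by forward
#'   filtering / backward sampling; or `"jags"` for single-site Gibbs via
#'   JAGS. The blocked sampler requires a complete balanced panel; JAGS
#'   also handles participant-specific missingness. With `"jags"` the
#'   residual-SD prior is half-normal with scale `resid_sd_scale`; the
#'   blocked sampler uses a weakly informative inverse-gamma(2, 0.5) on the
#'   residual variances for conjugacy.
#' @param n_chains number of Markov chains.
#' @param n_iter total iterations per chain (first `warmup` fraction
#'   discarded).
#' @param warmup fraction of iterations discarded as burn-in.
#' @param thin `"auto"` keeps about 1000 draws per chain; or an integer.
#' @param adjust_sex include sex as a covariate on the observation means.
#' @param iw_df,iw_scale inverse-Wishart prior on the innovation
#'   covariance: degrees of freedom (must exceed 1 for dimension 2) and
#'   scale matrix. The default scale `0.1 * I` is weakly informative for
#'   weekly innovations of series standardized to unit total variance,
#'   whose per-week innovation variances are well below 1.
#' @param drift_iw_scale inverse-Wishart scale matrix of the drift
#'   covariance prior (degrees of freedom `iw_df`); the default expects
#'   weekly drifts of order 0.1 standardized units.
#' @param loading_sd prior SD of the free loadings (normal, mean 0).
#' @param resid_sd_scale half-normal prior scale of the residual SDs.
#' @param rhat_threshold convergence is flagged when any monitored
#'   parameter's split-chain R-hat exceeds this value.
#' @param monitor_states keep posterior draws of the latent states
#'   (required for lag-scan analyses).
#' @return An object of class `state_space_spec`.
#' @export
state_space_spec <- function(instruments = c("WHS_occur", "PSS", "TICS"),
                             backend = c("gibbs", "jags"),
                             n_chains = 3L, n_iter = 20000L, warmup = 0.5,
                             thin = "auto", adjust_sex = FALSE,
                             iw_df = 3, iw_scale = diag(0.1, 2),
                             drift_iw_scale = diag(0.01, 2),
                             loading_sd = 5, resid_sd_scale = 2.5,
                             rhat_threshold = 1.05,
                             monitor_states = TRUE) {
  backend <- match.arg(backend)
  if (iw_df <= 1) {
    stop("inverse-Wishart degrees of freedom must exceed dimension - 1 = 1",
         call. = FALSE)
  }
  check_covariance(iw_scale, "iw_scale")
  check_covariance(drift_iw_scale, "drift_iw_scale")
  if (n_chains < 2) {
    warning("fewer than 2 chains: Gelman-Rubin diagnostics will be unavailable")
  }
  structure(list(
    instruments = instruments, backend = backend,
    n_chains = as.integer(n_chains),
    n_iter = as.integer(n_iter), warmup = warmup, thin = thin,
    adjust_sex = adjust_sex, iw_df = iw_df, iw_scale = iw_scale,
    drift_iw_scale = drift_iw_scale, loading_sd = loading_sd,
    resid_sd_scale = resid_sd_scale, rhat_threshold = rhat_threshold,
    monitor_states = monitor_states
  ), class = "state_space_spec")
}

dyad_model_template <- "
model {
  for (i in 1:N) {
    S0[i, 1] ~ dnorm(0, 1)
    S0[i, 2] ~ dnorm(0, 1)
    delta[i, 1:2] ~ dmnorm(mu_delta[1:2], Omega_delta[1:2, 1:2])
    S[i, 1:2, 1] ~ dmnorm(S0[i, 1:2] + delta[i, 1:2], Omega_xi[1:2, 1:2])
    for (t in 2:T) {
      S[i, 1:2, t] ~ dmnorm(S[i, 1:2, t - 1] + delta[i, 1:2], Omega_xi[1:2, 1:2])
    }
  }
  for (k in 1:K) {
    y[k] ~ dnorm(lam[jj[k], pp[k]] * S[ii[k], pp[k], tt[k]]%SEXTERM%,
                 tau_eps[jj[k], pp[k]])
  }
  for (p in 1:2) {
    lam[1, p] <- 1
    for (j in 2:J) {
      lam[j, p] ~ dnorm(0, lam_prec)
    }
    for (j in 1:J) {
      sigma_eps[j, p] ~ dnorm(0, eps_prec) T(0,)
      tau_eps[j, p] <- pow(sigma_eps[j, p], -2)
%SEXPRIOR%    }
    mu_delta[p] ~ dnorm(0, 1)
  }
  Omega_xi[1:2, 1:2] ~ dwish(R_xi[1:2, 1:2], df_iw)
  Omega_delta[1:2, 1:2] ~ dwish(R_delta[1:2, 1:2], df_iw)
  Sigma_xi[1:2, 1:2] <- inverse(Omega_xi[1:2, 1:2])
  Sigma_delta[1:2, 1:2] <- inverse(Omega_delta[1:2, 1:2])
}
"

build_dyad_model <- function(adjust_sex) {
  code <- dyad_model_template
  if (adjust_sex) {
    code <- sub("%SEXTERM%", " + beta_sex[jj[k], pp[k]] * sex[ii[k]]",
                code, fixed = TRUE)
    code <- sub("%SEXPRIOR%", "      beta_sex[j, p] ~ dnorm(0, 0.25)\n",
                code, fixed = TRUE)
  } else {
    code <- sub("%SEXTERM%", "", code, fixed = TRUE)
    code <- sub("%SEXPRIOR%", "", code, fixed = TRUE)
  }
  code
}

#' Fit the dyadic state-space model by MCMC
#'
#' Jointly fits the self- and partner-perspective latent stress series of
#' every participant to their standardized questionnaire scores using Gibbs
#' sampling (JAGS). Observation likelihood contributions arise only at
#' scheduled, non-missing occasions; latent states evolve at every weekly
#' occasion regardless.
#'
#' @param panel standardized score table (see [standardize_measures()])
#'   with columns `participant_id`, `informant` (`self`/`partner`),
#'   `measure`, `occasion_week`, `value`.
#' @param spec a [state_space_spec()].
#' @param sex optional named or ordered 0/1 vector per participant
#'   (required when `spec$adjust_sex` is `TRUE`).
#' @param n_weeks number of weekly occasions; inferred from the panel when
#'   `NULL`.
#' @param seed integer seed; per-chain RNG streams are derived from it.
#' @param quiet suppress JAGS progress output.
#' @return An object of class `dyad_fit`: list with `draws` (per-chain
#'   arrays, iterations x chains x ..., of `lambda`, `sigma_eps`,
#'   `mu_delta`, `Sigma_delta`, `Sigma_xi`, `delta`, `S` and optionally
#'   `beta_sex`), `rhat` (split-chain diagnostics of all monitored scalar
#'   parameters), `converged`, `participants`, `instruments`, `sd_q`
#'   (observed-score SDs used for post-hoc standardization), `spec`,
#'   `seed`.
#' @export
fit_state_space <- function(panel, spec = state_space_spec(), sex = NULL,
                            n_weeks = NULL, seed = 1L, quiet = TRUE) {
  stopifnot(inherits(spec, "state_space_spec"))
  need <- c("participant_id", "informant", "measure", "occasion_week", "value")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    stop("panel lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  panel <- panel[panel$measure %in% spec$instruments & !is.na(panel$value), ]
  ids <- sort(unique(panel$participant_id))
  N <- length(ids)
  if (N < 1) stop("no participants in panel", call. = FALSE)
  informants <- c("self", "partner")
  for (inf in informants) {
    have <- unique(panel$participant_id[panel$informant == inf])
    lack <- setdiff(ids, have)
    if (length(lack)) {
      stop("participant(s) ", paste(utils::head(lack, 5), collapse = ", "),
           " have an empty ", inf, "-report series", call. = FALSE)
    }
  }
  if (is.null(n_weeks)) n_weeks <- max(panel$occasion_week)
  J <- length(spec$instruments)

  ii <- match(panel$participant_id, ids)
  pp <- match(panel$informant, informants)
  jj <- match(panel$measure, spec$instruments)
  tt <- as.integer(panel$occasion_week)
  if (any(tt < 1 | tt > n_weeks)) {
    stop("occasion weeks outside 1..", n_weeks, call. = FALSE)
  }
  ref_weeks <- sort(unique(tt[jj == 1]))
  if (!all(seq_len(n_weeks) %in% ref_weeks)) {
    warning("reference instrument not observed at every weekly occasion")
  }

  sd_q <- matrix(NA_real_, J, 2,
                 dimnames = list(spec$instruments, informants))
  for (j in seq_len(J)) {
    for (p in 1:2) {
      v <- panel$value[jj == j & pp == p]
      sd_q[j, p] <- if (length(v) > 1) stats::sd(v) else NA_real_
    }
  }

  if (spec$adjust_sex) {
    if (is.null(sex)) stop("adjust_sex = TRUE requires a sex vector", call. = FALSE)
    if (!is.null(names(sex))) sex <- sex[as.character(ids)]
    if (length(sex) != N || any(is.na(sex))) {
      stop("sex must provide one 0/1 value per participant", call. = FALSE)
    }
  }

  if (spec$backend == "gibbs") {
    Y <- array(NA_real_, dim = c(N, 2, J, n_weeks))
    Y[cbind(ii, pp, jj, tt)] <- panel$value
    dat <- list(N = N, T = n_weeks, J = J, Y = Y,
                sex = if (spec$adjust_sex) as.numeric(sex) else NULL)
    draws <- fit_state_space_gibbs(dat, spec, seed)
    thin <- attr(draws, "thin")
    dimnames(draws$lambda) <- dimnames(draws$sigma_eps) <-
      list(NULL, NULL, spec$instruments, informants)
    dimnames(draws$mu_delta) <- list(NULL, NULL, informants)
    dimnames(draws$delta) <- list(NULL, NULL, NULL, informants)
    if (!is.null(draws$S)) {
      dimnames(draws$S) <- list(NULL, NULL, NULL, informants, NULL)
    }
    if (!is.null(draws$beta_sex)) {
      dimnames(draws$beta_sex) <- list(NULL, NULL, spec$instruments, informants)
    }
  } else {
    dat <- list(N = N, T = n_weeks, K = nrow(panel), J = J,
                y = panel$value, ii = ii, pp = pp, jj = jj, tt = tt,
                R_xi = spec$iw_scale, R_delta = spec$drift_iw_scale,
                df_iw = spec$iw_df,
                lam_prec = 1 / spec$loading_sd^2,
                eps_prec = 1 / spec$resid_sd_scale^2)
    if (spec$adjust_sex) dat$sex <- as.numeric(sex)

    set.seed(seed)
    inits <- lapply(seq_len(spec$n_chains), function(ch) {
      lam0 <- matrix(NA_real_, J, 2)
      if (J > 1) lam0[2:J, ] <- stats::runif(2 * (J - 1), 0.1, 1.5)
      ini <- list(
        lam = lam0,
        sigma_eps = matrix(stats::runif(2 * J, 0.3, 1.2), J, 2),
        mu_delta = stats::rnorm(2, 0, 0.2),
        Omega_xi = diag(stats::runif(1, 2, 40), 2),
        Omega_delta = diag(stats::runif(1, 30, 300), 2),
        .RNG.name = "base::Mersenne-Twister",
        .RNG.seed = seed + 1000L * ch
      )
      if (J == 1) ini$lam <- NULL
      if (spec$adjust_sex) ini$beta_sex <- matrix(stats::rnorm(2 * J, 0, 0.3), J, 2)
      ini
    })

    n_sample <- max(2L, round(spec$n_iter * (1 - spec$warmup)))
    n_warm <- spec$n_iter - n_sample
    thin <- if (identical(spec$thin, "auto")) max(1L, n_sample %/% 1000L)
            else as.integer(spec$thin)

    monitors <- c("lam", "sigma_eps", "mu_delta", "Sigma_delta", "Sigma_xi",
                  "delta")
    if (spec$monitor_states) monitors <- c(monitors, "S")
    if (spec$adjust_sex) monitors <- c(monitors, "beta_sex")

    jm <- rjags::jags.model(textConnection(build_dyad_model(spec$adjust_sex)),
                            data = dat, inits = inits,
                            n.chains = spec$n_chains,
                            n.adapt = min(1000L, max(100L, n_warm %/% 2L)),
                            quiet = quiet)
    if (n_warm > 0) stats::update(jm, n_warm, progress.bar = "none")
    samp <- rjags::coda.samples(jm, monitors, n.iter = n_sample, thin = thin,
                                progress.bar = "none")

    draws <- list(
      lambda = extract_draws(samp, "lam", c(J, 2),
                             list(spec$instruments, informants)),
      sigma_eps = extract_draws(samp, "sigma_eps", c(J, 2),
                                list(spec$instruments, informants)),
      mu_delta = extract_draws(samp, "mu_delta", 2, list(informants)),
      Sigma_delta = extract_draws(samp, "Sigma_delta", c(2, 2)),
      Sigma_xi = extract_draws(samp, "Sigma_xi", c(2, 2)),
      delta = extract_draws(samp, "delta", c(N, 2), list(NULL, informants))
    )
    if (spec$monitor_states) {
      draws$S <- extract_draws(samp, "S", c(N, 2, n_weeks),
                               list(NULL, informants, NULL))
    }
    if (spec$adjust_sex) {
      draws$beta_sex <- extract_draws(samp, "beta_sex", c(J, 2),
                                      list(spec$instruments, informants))
    }
  }

  fit <- structure(list(
    draws = draws, participants = ids, instruments = spec$instruments,
    informants = informants, n_weeks = n_weeks, sd_q = sd_q,
    sex = if (spec$adjust_sex) as.numeric(sex) else NULL,
    spec = spec, seed = seed, thin = thin
  ), class = "dyad_fit")
  fit$rhat <- gelman_rubin(fit)
  fit$converged <- if (all(is.na(fit$rhat))) NA else
    max(fit$rhat, na.rm = TRUE) < spec$rhat_threshold
  if (isFALSE(fit$converged)) {
    warning("chains not converged: max split-chain R-hat = ",
            signif(max(fit$rhat, na.rm = TRUE), 4))
  }
  fit
}

# reshape a coda mcmc.list into an [iteration, chain, ...] array for one
# monitored variable
extract_draws <- function(samp, base, dims, dimnm = NULL) {
  vn <- coda::varnames(samp)
  if (length(dims) == 1 && dims == 1) {
    sel <- vn == base
  } else {
    sel <- startsWith(vn, paste0(base, "["))
  }
  if (!any(sel)) return(NULL)
  names_sel <- vn[sel]
  n_iter <- nrow(samp[[1]])
  n_chain <- length(samp)
  out <- array(NA_real_, dim = c(n_iter, n_chain, prod(dims)))
  if (length(dims) == 1 && dims == 1) {
    pos <- 1L
  } else {
    idx <- sub("^.*\\[", "", sub("\\]$", "", names_sel))
    idx_mat <- do.call(rbind, lapply(strsplit(idx, ","), as.integer))
    pos <- as.vector((idx_mat - 1) %*% cumprod(c(1, dims[-length(dims)]))) + 1L
  }
  for (ch in seq_len(n_chain)) {
    m <- samp[[ch]][, names_sel, drop = FALSE]
    out[, ch, pos] <- m
  }
  dim(out) <- c(n_iter, n_chain, dims)
  if (!is.null(dimnm)) dimnames(out) <- c(list(NULL, NULL), dimnm)
  out
}

#' @export
print.dyad_fit <- function(x, ...) {
  cat("Dyadic latent state-space model fit\n")
  cat(sprintf("  %d participants, %d weeks, instruments: %s\n",
              length(x$participants), x$n_weeks,
              paste(x$instruments, collapse = ", ")))
  cat(sprintf("  %d chains x %d kept draws (thin %d)\n",
              dim(x$draws$mu_delta)[2], dim(x$draws$mu_delta)[1], x$thin))
  if (all(is.na(x$rhat))) {
    cat("  convergence diagnostics unavailable (single chain)\n")
  } else {
    cat(sprintf("  max split-chain R-hat = %.4f (%s)\n",
                max(x$rhat, na.rm = TRUE),
                if (isTRUE(x$converged)) "converged" else "NOT converged"))
  }
  invisible(x)
}
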