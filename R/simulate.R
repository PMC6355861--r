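#' Simulate coupled latent stress trajectories
#'
#' Draws, for every participant, two coupled latent subjective-stress series
#' (the self-perspective and the partner-perspective view of the same
#' person) following a random walk with individual drift:
#' `S[t] = S[t-1] + delta + xi[t]`, where the per-week innovation pairs
#' `(xi_self, xi_partner)` share a 2x2 covariance and the drift pairs
#' `(delta_self, delta_partner)` share a correlation. Initial states are
#' standard normal.
#'
#' @param params a [true_parameters()] object.
#' @param seed optional integer seed; if `NULL` the current RNG state is used.
#' @return An object of class `latent_trajectories`: a list with
#'   `S` (`n_participants x 2 x n_weeks` array, perspectives `self`,
#'   `partner`), `S0` (initial states), `delta`, `xi`, `sex` (0/1, balanced
#'   within couples), `couple_id` and `params`.
#' @examples
#' tr <- simulate_latent(true_parameters(n_couples = 4), seed = 7)
#' dim(tr$S)
#' @export
simulate_latent <- function(params, seed = NULL) {
  validate_true_parameters(params)
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * params$n_couples
  T <- params$n_weeks
  persp <- c("self", "partner")

  sd_d <- params$drift_sd
  rho_d <- params$drift_correlation
  sigma_delta <- sd_d^2 * matrix(c(1, rho_d, rho_d, 1), 2)
  mu_delta <- rep(params$drift_mean, length.out = 2)
  delta <- matrix(mu_delta, n, 2, byrow = TRUE)
  if (sd_d > 0) {
    delta <- delta + matrix(stats::rnorm(2 * n), n, 2) %*% chol(sigma_delta)
  }

  S0 <- matrix(stats::rnorm(2 * n), n, 2)
  xi <- array(0, dim = c(n, 2, T))
  zero_innov <- max(abs(params$innovation_covariance)) == 0
  L <- if (zero_innov) NULL else chol(params$innovation_covariance)
  S <- array(NA_real_, dim = c(n, 2, T),
             dimnames = list(NULL, persp, paste0("week", seq_len(T))))
  prev <- S0
  for (t in seq_len(T)) {
    e <- if (zero_innov) matrix(0, n, 2) else matrix(stats::rnorm(2 * n), n, 2) %*% L
    xi[, , t] <- e
    prev <- prev + delta + e
    S[, , t] <- prev
  }
  dimnames(delta) <- dimnames(S0) <- list(NULL, persp)

  structure(list(
    S = S, S0 = S0, delta = delta, xi = xi,
    sex = rep(c(1L, 0L), params$n_couples),
    couple_id = rep(seq_len(params$n_couples), each = 2L),
    participant_id = seq_len(n),
    params = params
  ), class = "latent_trajectories")
}

#' Standardize latent trajectories per perspective
#'
#' Centers and scales each perspective's latent series over all participants
#' and occasions jointly; this is the scale on which item emission and the
#' hair-cortisol kernel operate.
#' @param traj a `latent_trajectories` object.
#' @return An array of the same shape as `traj$S`.
#' @keywords internal
standardize_latent <- function(traj) {
  S <- traj$S
  for (p in 1:2) {
    v <- S[, p, ]
    s <- stats::sd(v)
    if (s == 0) s <- 1
    S[, p, ] <- (v - mean(v)) / s
  }
  S
}

# Per-instrument emission weights on the standardized latent scale.
# Each ordinal item is a thresholded Gaussian propensity
#   z_k = a*S + b*eta + c*e_k,   a^2 + b^2 + c^2 = 1,
# with eta an occasion-level instrument residual shared by all items, e_k
# item-specific noise, and item-specific difficulty offsets d_k spreading
# the thresholds so that the scale-level response curve stays close to
# linear over the occupied latent range (heterogeneous item difficulties
# linearize the test characteristic curve). h = a^2 + b^2 (the item
# communality) is sized from the target omega and the a:b ratio from the
# target scale-level standardized loading; the common part is then inflated
# by a factor gamma, found by root-finding on a deterministic quadrature of
# the threshold model, so that corr(score, S) hits the target loading
# despite the ordinal coarsening.
emission_coefficients <- function(params) {
  out <- list()
  for (inst in c("WHS", "PSS", "TICS")) {
    K <- params$item_counts[[inst]]
    omega <- params$scale_reliability[[inst]]
    probs <- params$thresholds[[inst]]
    diffs <- item_difficulties(K, params$item_difficulty_sd[[inst]])
    tau <- aggregate_thresholds(probs, diffs)
    # common propensity variance v solved so the coarsened items carry the
    # target omega; the S-share of the common part then sets the loading
    v <- calibrate_common_variance(omega, tau, diffs, K)
    mom <- ordinal_emission_moments(v, tau, diffs, K)
    coef_p <- list()
    for (p in c("self", "partner")) {
      lam <- params$loadings[inst, p]
      w <- lam / mom$cor_score_y
      if (w > 1) {
        stop("target loading for ", inst, " (", p, ") exceeds what the target ",
             "reliability permits after ordinal coarsening", call. = FALSE)
      }
      a <- sqrt(v) * w
      b <- sqrt(v - a^2)
      coef_p[[p]] <- c(a = a, b = b, c = sqrt(1 - v))
    }
    out[[inst]] <- list(self = coef_p$self, partner = coef_p$partner,
                        difficulties = diffs, tau = tau)
  }
  out
}

# deterministic spread of item difficulty offsets (probit scale)
item_difficulties <- function(K, sd) {
  if (K == 1) return(0)
  stats::qnorm((seq_len(K) - 0.5) / K) * sd
}

# base cut-points such that the marginal category probabilities, aggregated
# over the item difficulty offsets, equal the stated targets
aggregate_thresholds <- function(probs, diffs) {
  cum <- cumsum(probs)[1:4]
  vapply(cum, function(cm) {
    stats::uniroot(function(t) mean(stats::pnorm(t + diffs)) - cm,
                   c(-8, 8), tol = 1e-9)$root
  }, numeric(1))
}

# moments of the thresholded scale by quadrature over the common propensity
# part y ~ N(0, v): per-item conditional means/variances, the implied scale
# score moments, corr(score, y), and the omega the ordinal items carry.
ordinal_emission_moments <- function(v, tau, diffs, K) {
  csd <- sqrt(1 - v)
  ygrid <- seq(-6, 6, length.out = 241) * sqrt(max(v, 1e-8))
  wy <- stats::dnorm(ygrid, 0, sqrt(max(v, 1e-8)))
  wy <- wy / sum(wy)
  l_k <- vb_k <- vw_k <- numeric(K)
  Escore_y <- numeric(length(ygrid))
  for (k in seq_len(K)) {
    cuts <- tau + diffs[k]
    pr <- vapply(cuts, function(tt) 1 - stats::pnorm((tt - ygrid) / csd),
                 numeric(length(ygrid)))
    Ec <- rowSums(pr)                      # E[cat | y]
    Ec2 <- as.vector(pr %*% (2 * seq_len(4) - 1))  # E[cat^2 | y]
    mu_k <- sum(wy * Ec)
    vb_k[k] <- sum(wy * (Ec - mu_k)^2)
    vw_k[k] <- sum(wy * (Ec2 - Ec^2))
    l_k[k] <- sum(wy * ygrid * Ec) / sqrt(max(v, 1e-8))
    Escore_y <- Escore_y + Ec / K
  }
  mu <- sum(wy * Escore_y)
  var_score <- sum(wy * (Escore_y - mu)^2) + sum(vw_k) / K^2
  cov_y <- sum(wy * ygrid * Escore_y)
  list(cor_score_y = cov_y / sqrt(max(v, 1e-8) * var_score),
       omega = sum(l_k)^2 / (sum(l_k)^2 + sum(vw_k)),
       score_mean = mu, score_sd = sqrt(var_score))
}

calibrate_common_variance <- function(omega_target, tau, diffs, K) {
  f <- function(v) ordinal_emission_moments(v, tau, diffs, K)$omega - omega_target
  if (f(0.97) < 0) return(0.97)  # ceiling: best achievable reliability
  stats::uniroot(f, c(0.02, 0.97), tol = 1e-4)$root
}

emit_ordinal <- function(z, probs, diffs = NULL, tau = NULL) {
  if (is.null(tau)) tau <- stats::qnorm(cumsum(probs)[1:4])
  if (is.null(diffs)) return(findInterval(z, tau))
  # z is persons x items; item k uses thresholds tau + diffs[k]
  K <- ncol(z)
  out <- matrix(0L, nrow(z), K)
  for (k in seq_len(K)) {
    out[, k] <- findInterval(z[, k], tau + diffs[k])
  }
  out
}

#' Emit item-level questionnaire responses from latent trajectories
#'
#' Produces the long-format item panel of the study design: a 30-item weekly
#' hassle scale (frequency 0-4 at every week plus a conditional 0-4
#' stressfulness rating for hassles that occurred), a 10-item perceived
#' stress scale at the monthly occasions, and a 12-item chronic stress
#' screening scale at the final occasion -- each once per informant
#' perspective. Responses are graded thresholdings of `loading * S` plus
#' occasion- and item-level noise, calibrated so that the scored scales
#' carry the standardized loadings and reliabilities in `params`.
#' Positively worded PSS items (the reverse-coded set) are emitted mirrored.
#'
#' @param traj a `latent_trajectories` object covering all scheduled occasions.
#' @param params a [true_parameters()] object.
#' @param seed optional integer seed.
#' @return A long data.frame with columns `couple_id`, `participant_id`,
#'   `informant`, `instrument`, `occasion_week`, `item`, `frequency`
#'   (the 0-4 response; for the WHS the occurrence frequency) and
#'   `intensity` (0-4 stressfulness, WHS only, `NA` unless frequency >= 1).
#' @export
simulate_items <- function(traj, params = traj$params, seed = NULL) {
  if (!inherits(traj, "latent_trajectories")) {
    stop("traj must be a latent_trajectories object", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  T <- params$n_weeks
  if (dim(traj$S)[3] < max(c(T, params$pss_weeks, params$tics_week))) {
    stop("trajectories are missing scheduled occasions (have ",
         dim(traj$S)[3], " weeks)", call. = FALSE)
  }
  n <- nrow(traj$delta)
  Sz <- standardize_latent(traj)
  cf <- emission_coefficients(params)
  schedules <- list(WHS = seq_len(T), PSS = params$pss_weeks,
                    TICS = params$tics_week)
  pieces <- vector("list", 0)
  for (inst in c("WHS", "PSS", "TICS")) {
    K <- params$item_counts[[inst]]
    weeks <- schedules[[inst]]
    probs <- params$thresholds[[inst]]
    diffs <- cf[[inst]]$difficulties
    for (p_i in 1:2) {
      p <- c("self", "partner")[p_i]
      co <- cf[[inst]][[p]]
      for (w in weeks) {
        s_vec <- Sz[, p_i, w]
        eta <- stats::rnorm(n)
        common <- co["a"] * s_vec + co["b"] * eta
        z <- matrix(common, n, K) + co["c"] * matrix(stats::rnorm(n * K), n, K)
        resp <- emit_ordinal(z, probs, diffs, tau = cf[[inst]]$tau)
        intens <- matrix(NA_integer_, n, K)
        if (inst == "WHS") {
          z2 <- matrix(common, n, K) + co["c"] * matrix(stats::rnorm(n * K), n, K)
          iv <- emit_ordinal(z2, params$thresholds$WHS_intensity)
          dim(iv) <- c(n, K)
          intens[resp >= 1] <- iv[resp >= 1]
        }
        if (inst == "PSS" && length(params$pss_reverse_items)) {
          rev <- params$pss_reverse_items
          resp[, rev] <- 4L - resp[, rev]
        }
        pieces[[length(pieces) + 1L]] <- data.frame(
          couple_id = rep(traj$couple_id, K),
          participant_id = rep(traj$participant_id, K),
          informant = p,
          instrument = inst,
          occasion_week = w,
          item = rep(seq_len(K), each = n),
          frequency = as.integer(resp),
          intensity = as.integer(intens)
        )
      }
    }
  }
  panel <- do.call(rbind, pieces)
  rownames(panel) <- NULL
  panel
}

#' Generate hair-cortisol samples from latent trajectories
#'
#' Log hair cortisol concentration is a kernel-weighted integral of the
#' standardized self-perspective latent stress series plus a sex effect and
#' Gaussian noise:
#' `log HCC = mu + effect * sum_t w_t S[t] + sex_effect * sex + N(0, sd)`.
#' The participant-level concentration is then split into three 1-cm
#' segment values (log-normal scatter `segment_sd`) and each segment into
#' three assay replicates with coefficient of variation `replicate_cv`,
#' mimicking triplicate LC-MS/MS quantification.
#'
#' @inheritParams simulate_items
#' @return A long data.frame with columns `participant_id`, `segment`
#'   (1-3), `replicate` (1-3) and `cortisol_pg_per_mg`. The attribute
#'   `"truth"` holds the participant-level `log_hcc` and the kernel-weighted
#'   stress exposure `u`.
#' @export
simulate_hair <- function(traj, params = traj$params, seed = NULL) {
  if (!inherits(traj, "latent_trajectories")) {
    stop("traj must be a latent_trajectories object", call. = FALSE)
  }
  if (params$hcc_noise_sd < 0) stop("hcc_noise_sd must be nonnegative", call. = FALSE)
  if (length(params$hcc_lag_kernel) != params$n_weeks) {
    stop("hcc_lag_kernel length must equal n_weeks", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(traj$delta)
  Sz <- standardize_latent(traj)
  u <- as.vector(Sz[, "self", seq_len(params$n_weeks)] %*% params$hcc_lag_kernel)
  log_hcc <- params$hcc_log_mean + params$hcc_effect * u +
    params$sex_effect_hcc * traj$sex +
    stats::rnorm(n, 0, params$hcc_noise_sd)
  hcc <- exp(log_hcc)
  seg <- exp(log(rep(hcc, each = 3L)) +
               stats::rnorm(3L * n, 0, params$segment_sd))
  reps <- rep(seg, each = 3L) *
    pmax(1 + stats::rnorm(9L * n, 0, params$replicate_cv), 1e-6)
  hair <- data.frame(
    participant_id = rep(traj$participant_id, each = 9L),
    segment = rep(rep(1:3, each = 3L), n),
    replicate = rep(1:3, 3L * n),
    cortisol_pg_per_mg = reps
  )
  attr(hair, "truth") <- list(log_hcc = log_hcc, u = u, sex = traj$sex)
  hair
}

#' Simulate a complete synthetic study dataset
#'
#' Runs the three generator stages (latent trajectories, item emission,
#' hair samples) under a single seed, with per-stage sub-seeds derived
#' deterministically so that regenerating with the same seed yields an
#' identical dataset.
#'
#' @param params a [true_parameters()] object; `params$seed` controls all
#'   randomness unless `seed` is given.
#' @param seed optional override of `params$seed`.
#' @return An object of class `dyad_study`: a list with `panel` (item
#'   responses), `hair` (triplicate cortisol values) and `truth` (the
#'   latent trajectories, sex indicators and the parameters used).
#' @examples
#' study <- simulate_study(true_parameters(n_couples = 3, seed = 11))
#' head(study$panel)
#' @export
simulate_study <- function(params = true_parameters(), seed = NULL) {
  if (is.null(seed)) seed <- params$seed
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 3L)
  traj <- simulate_latent(params, seed = stage_seeds[1])
  panel <- simulate_items(traj, params, seed = stage_seeds[2])
  hair <- simulate_hair(traj, params, seed = stage_seeds[3])
  structure(list(
    panel = panel, hair = hair,
    truth = list(trajectories = traj, sex = traj$sex, params = params,
                 hair_truth = attr(hair, "truth"), seed = seed)
  ), class = "dyad_study")
}

#' @export
print.dyad_study <- function(x, ...) {
  p <- x$truth$params
  cat("Synthetic dyadic stress study\n")
  cat(sprintf("  %d couples (N = %d), %d weeks; %d item responses, %d hair replicates\n",
              p$n_couples, 2L * p$n_couples, p$n_weeks,
              nrow(x$panel), nrow(x$hair)))
  invisible(x)
}

#' Write / read study datasets as CSV and JSON
#'
#' `write_study()` persists the item panel and hair samples as long-format
#' CSV files and the ground truth (parameters, sex, drifts, latent states)
#' as JSON. `read_panel()` and `read_hair()` load the CSVs back, checking
#' the expected columns.
#'
#' @param study a `dyad_study` object.
#' @param dir output directory (created if needed).
#' @return `write_study()` returns the file paths invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "dyad_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(panel = file.path(dir, "panel.csv"),
             hair = file.path(dir, "hair.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(study$panel, paths["panel"], row.names = FALSE)
  utils::write.csv(study$hair, paths["hair"], row.names = FALSE)
  tr <- study$truth$trajectories
  truth <- list(
    seed = study$truth$seed,
    params = unclass(study$truth$params),
    sex = tr$sex, couple_id = tr$couple_id,
    delta = tr$delta, S = tr$S, S0 = tr$S0,
    log_hcc = study$truth$hair_truth$log_hcc
  )
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(paths)
}

#' @rdname write_study
#' @param path a CSV file written by `write_study()`.
#' @export
read_panel <- function(path) {
  panel <- utils::read.csv(path)
  need <- c("couple_id", "participant_id", "informant", "instrument",
            "occasion_week", "item", "frequency", "intensity")
  missing <- setdiff(need, names(panel))
  if (length(missing)) {
    stop("panel file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  panel
}

#' @rdname write_study
#' @export
read_hair <- function(path) {
  hair <- utils::read.csv(path)
  need <- c("participant_id", "segment", "replicate", "cortisol_pg_per_mg")
  missing <- setdiff(need, names(hair))
  if (length(missing)) {
    stop("hair file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  hair
}
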