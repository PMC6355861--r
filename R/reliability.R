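#' McDonald's omega (total) from a one-factor model
#'
#' Fits a single-factor model to the item correlation matrix and returns
#' omega_total = (sum lambda)^2 / ((sum lambda)^2 + sum theta), where theta
#' are the residual item variances. The default extraction is a
#' minimum-residual (minres) fit: loadings minimize the sum of squared
#' off-diagonal discrepancies between the observed correlations and
#' `lambda %*% t(lambda)`. Maximum likelihood via [stats::factanal()] is
#' available as an alternative.
#'
#' @param x persons x items matrix (or data.frame) of item scores; ignored
#'   if `covmat` is supplied.
#' @param covmat optional item covariance or correlation matrix to fit
#'   directly (scaled internally to a correlation matrix).
#' @param n_obs number of observations behind `covmat` (bookkeeping only).
#' @param method `"minres"` (default) or `"ml"`.
#' @return An object of class `reliability_report`: a list with `omega`,
#'   `loadings`, `residual_variances`, `n_items`, `n_obs`, `method`.
#' @examples
#' R <- matrix(0.49, 12, 12); diag(R) <- 1
#' mcdonald_omega(covmat = R)$omega  # equal loadings 0.7 -> 0.920
#' @export
mcdonald_omega <- function(x = NULL, covmat = NULL, n_obs = NA_integer_,
                           method = c("minres", "ml")) {
  method <- match.arg(method)
  if (is.null(covmat)) {
    x <- as.matrix(x)
    if (ncol(x) < 3) stop("omega requires at least 3 items", call. = FALSE)
    if (nrow(x) < 2 * ncol(x)) {
      stop("omega requires at least 2x as many observations as items",
           call. = FALSE)
    }
    n_obs <- nrow(x)
    covmat <- stats::cor(x, use = "pairwise.complete.obs")
  }
  R <- stats::cov2cor(as.matrix(covmat))
  k <- ncol(R)
  if (k < 3) stop("omega requires at least 3 items", call. = FALSE)
  if (any(!is.finite(R))) {
    stop("item correlation matrix contains non-finite entries ",
         "(zero-variance or empty items?)", call. = FALSE)
  }
  l <- switch(method,
    minres = minres_loadings(R),
    ml = {
      fa <- stats::factanal(covmat = R, factors = 1, n.obs = max(n_obs, k + 2, na.rm = TRUE))
      as.vector(fa$loadings)
    })
  if (sum(l) < 0) l <- -l
  theta <- pmax(1 - l^2, 0)
  omega <- sum(l)^2 / (sum(l)^2 + sum(theta))
  structure(list(omega = omega, loadings = l, residual_variances = theta,
                 n_items = k, n_obs = n_obs, method = method),
            class = "reliability_report")
}

# One-factor minimum-residual loadings: minimize
# sum_{i<j} (r_ij - l_i l_j)^2 over l, starting from the leading
# eigenvector solution.
minres_loadings <- function(R) {
  k <- ncol(R)
  e <- eigen(R, symmetric = TRUE)
  start <- e$vectors[, 1] * sqrt(max(e$values[1], 0.1))
  start <- pmin(pmax(start, -0.95), 0.95)
  off <- upper.tri(R)
  obj <- function(l) {
    M <- tcrossprod(l)
    sum((R[off] - M[off])^2)
  }
  gr <- function(l) {
    D <- R - tcrossprod(l)
    diag(D) <- 0
    -2 * as.vector(D %*% l)
  }
  fit <- stats::optim(start, obj, gr, method = "L-BFGS-B",
                      lower = rep(-0.999, k), upper = rep(0.999, k),
                      control = list(maxit = 500, factr = 1e4))
  if (fit$convergence != 0) {
    stop("minres factor extraction did not converge (code ", fit$convergence,
         ", objective ", signif(fit$value, 4), ")", call. = FALSE)
  }
  fit$par
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("McDonald's omega = %.3f (%d items, %s obs, %s extraction)\n",
              x$omega, x$n_items,
              ifelse(is.na(x$n_obs), "?", x$n_obs), x$method))
  invisible(x)
}

#' Reliability of each scored measure
#'
#' Convenience wrapper computing McDonald's omega for every
#' instrument x informant combination of an item panel. WHS items enter
#' with their occurrence frequency, pooling person-occasions as
#' observations.
#'
#' @param panel long-format item panel (see [score_panel()]).
#' @param method passed to [mcdonald_omega()].
#' @param pss_reverse_items positively worded PSS items, recoded (`4 - x`)
#'   before the factor fit so all items point in the same direction.
#' @return A data.frame with columns `instrument`, `informant`, `omega`,
#'   `n_items`, `n_observations`.
#' @export
reliability_table <- function(panel, method = "minres",
                              pss_reverse_items = c(4, 5, 7, 8)) {
  combos <- unique(panel[, c("instrument", "informant")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- panel[panel$instrument == combos$instrument[i] &
                   panel$informant == combos$informant[i], ]
    if (combos$instrument[i] == "PSS" && length(pss_reverse_items)) {
      rev <- sub$item %in% pss_reverse_items
      sub$frequency[rev] <- 4L - sub$frequency[rev]
    }
    wide <- stats::reshape(
      sub[, c("participant_id", "occasion_week", "item", "frequency")],
      idvar = c("participant_id", "occasion_week"),
      timevar = "item", direction = "wide")
    X <- as.matrix(wide[, -(1:2)])
    rep <- mcdonald_omega(X, method = method)
    data.frame(instrument = combos$instrument[i],
               informant = combos$informant[i],
               omega = rep$omega, n_items = rep$n_items,
               n_observations = rep$n_obs)
  })
  do.call(rbind, rows)
}
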