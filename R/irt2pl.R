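#' Quadrature grid for the latent ability
#'
#' The default scaling grid uses 21 equally spaced points on `[-5, 5]` with
#' standard normal prior weights, renormalized to sum to one. Joint models
#' reuse the same grid per dimension.
#'
#' @param n_points Number of integration points.
#' @param lower,upper Grid range.
#' @return A list with `points` and `prior_weights`.
#' @export
quadrature_grid <- function(n_points = 21, lower = -5, upper = 5) {
  pts <- seq(lower, upper, length.out = n_points)
  w <- stats::dnorm(pts)
  list(points = pts, prior_weights = w / sum(w))
}

# Vectorized Newton update of per-item logistic parameters (c0, c1) with
# linear predictor c0_i + c1_i * theta_t given expected success counts r
# (T x I) and trials n (T x I). Step-halving keeps the expected
# complete-data log-likelihood non-decreasing (GEM step).
update_items_2pl <- function(c0, c1, r, n, theta, n_newton = 3,
                             a_bounds = c(0.05, 8), b_bounds = c(-8, 8)) {
  I <- length(c0)
  q_fun <- function(c0, c1) {
    eta <- outer(theta, c1) + rep(c0, each = length(theta))
    # log probabilities stay finite for any finite eta
    colSums(r * stats::plogis(eta, log.p = TRUE) +
              (n - r) * stats::plogis(-eta, log.p = TRUE))
  }
  q_old <- q_fun(c0, c1)
  for (it in seq_len(n_newton)) {
    eta <- outer(theta, c1) + rep(c0, each = length(theta))
    mu <- psi(eta)
    v <- n * mu * (1 - mu)
    g0 <- colSums(r - n * mu)
    g1 <- colSums(theta * (r - n * mu))
    h00 <- colSums(v); h01 <- colSums(theta * v); h11 <- colSums(theta^2 * v)
    det <- pmax(h00 * h11 - h01^2, 1e-12)
    d0 <- (h11 * g0 - h01 * g1) / det
    d1 <- (h00 * g1 - h01 * g0) / det
    step <- rep(1, I)
    for (half in 1:12) {
      c0_new <- c0 + step * d0
      c1_new <- c1 + step * d1
      # enforce bounds in (a, b) space
      a_new <- pmin(pmax(c1_new, a_bounds[1]), a_bounds[2])
      b_new <- pmin(pmax(-c0_new / a_new, b_bounds[1]), b_bounds[2])
      c1_new <- a_new
      c0_new <- -a_new * b_new
      q_new <- q_fun(c0_new, c1_new)
      worse <- q_new < q_old - 1e-10
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    still_worse <- q_new < q_old
    c0_new[still_worse] <- c0[still_worse]
    c1_new[still_worse] <- c1[still_worse]
    q_new[still_worse] <- q_old[still_worse]
    c0 <- c0_new; c1 <- c1_new; q_old <- q_new
  }
  list(c0 = c0, c1 = c1)
}

#' Fit the 2PL model by marginal maximum likelihood EM
#'
#' Maximizes the marginal likelihood of a scored response matrix over a
#' discrete ability grid with a fixed standard normal prior (the ability
#' metric is identified by `theta ~ N(0, 1)`). Entries may be fractional in
#' `[0, 1]` (partially correct pseudo-responses weight the success and
#' failure terms), and missing entries contribute nothing to the likelihood,
#' so the same routine covers wrong-scoring, partial-credit scoring and
#' ignoring missing responses.
#'
#' @param scored Persons x items matrix with entries in `[0, 1]` or `NA`.
#' @param weights Optional nonnegative person weights.
#' @param grid A [quadrature_grid()].
#' @param max_iter Maximum EM iterations.
#' @param conv_ll Relative log-likelihood convergence tolerance.
#' @param conv_par Maximum absolute parameter-change tolerance.
#' @return A list of class `fit_2pl` with item parameters `a`, `b`,
#'   `loglik`, `n_params`, the per-person posterior over the grid
#'   (rows sum to 1), the grid, convergence diagnostics and the
#'   log-likelihood trace.
#' @export
fit_2pl <- function(scored, weights = NULL, grid = quadrature_grid(),
                    max_iter = 1000, conv_ll = 1e-9, conv_par = 1e-4) {
  x <- as.matrix(scored)
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop("scored entries must lie in [0, 1] or be NA", call. = FALSE)
  n <- nrow(x); I <- ncol(x)
  if (is.null(weights)) weights <- rep(1, n)
  obs <- !is.na(x)
  xv <- x; xv[!obs] <- 0
  m <- matrix(as.numeric(obs), n, I)
  theta <- grid$points; prior <- grid$prior_weights

  # boundary screen: items whose observed values are all equal
  col_n <- colSums(m)
  col_mean <- ifelse(col_n > 0, colSums(xv) / pmax(col_n, 1), 0.5)
  degenerate <- col_n > 0 & (col_mean <= 0 | col_mean >= 1)
  if (any(degenerate))
    warning("item(s) with all-equal observed responses; estimates bounded: ",
            paste(which(degenerate), collapse = ", "), call. = FALSE)

  a <- rep(1, I)
  b <- -stats::qlogis(pmin(pmax(col_mean, 0.02), 0.98))
  c1 <- a; c0 <- -a * b
  ll_old <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  wH <- NULL
  for (iter in seq_len(max_iter)) {
    eta <- outer(theta, c1) + rep(c0, each = length(theta))   # T x I
    log_p <- stats::plogis(eta, log.p = TRUE)
    log_q <- stats::plogis(-eta, log.p = TRUE)
    ll_mat <- tcrossprod(xv, log_p) + tcrossprod(m - xv, log_q)  # N x T
    lik <- exp(ll_mat)
    marg <- as.vector(lik %*% prior)
    ll <- sum(weights * log(marg))
    ll_trace <- c(ll_trace, ll)
    h <- sweep(lik, 2, prior, "*") / marg
    wH <- h * weights
    r_cnt <- crossprod(wH, xv)   # T x I expected successes
    n_cnt <- crossprod(wH, m)    # T x I expected trials
    upd <- update_items_2pl(c0, c1, r_cnt, n_cnt, theta)
    par_change <- max(abs(upd$c0 - c0), abs(upd$c1 - c1))
    c0 <- upd$c0; c1 <- upd$c1
    if (is.finite(ll_old) &&
        (abs(ll - ll_old) < conv_ll * abs(ll_old) || par_change < conv_par)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  # final E-step so the reported likelihood and posteriors match the
  # returned parameters exactly
  eta <- outer(theta, c1) + rep(c0, each = length(theta))
  log_p <- stats::plogis(eta, log.p = TRUE)
  log_q <- stats::plogis(-eta, log.p = TRUE)
  lik <- exp(tcrossprod(xv, log_p) + tcrossprod(m - xv, log_q))
  marg <- as.vector(lik %*% prior)
  ll_trace <- c(ll_trace, sum(weights * log(marg)))
  h <- sweep(lik, 2, prior, "*") / marg
  a <- c1; b <- -c0 / c1
  structure(list(a = a, b = b, item_id = colnames(x),
                 loglik = ll_trace[length(ll_trace)],
                 n_params = 2L * I, n_persons = n,
                 posterior = h, grid = grid, weights = weights,
                 converged = converged, n_iter = length(ll_trace),
                 ll_trace = ll_trace),
            class = "fit_2pl")
}

#' Fit the 2PL with a latent background (latent-regression) model
#'
#' Replaces the common standard normal ability prior by a person-specific
#' conditional normal `theta_p | Z_p ~ N(gamma0 + gamma1 * Z_p, sigma_e^2)`,
#' where `Z_p` is a manifest covariate such as the proportion of missing or
#' not-reached responses. Regression coefficients and the residual SD are
#' updated in each M-step. After convergence the ability metric is
#' standardized so the model-implied marginal mean and SD of `theta` are 0
#' and 1 (item parameters and regression coefficients are rescaled
#' accordingly), keeping all treatments on one identification convention.
#'
#' @inheritParams fit_2pl
#' @param covariate Per-person finite covariate `Z_p`.
#' @return A `fit_2pl` object with additional elements `gamma0`, `gamma1`,
#'   `sigma_e` (on the standardized metric).
#' @export
fit_2pl_latent_regression <- function(scored, covariate, weights = NULL,
                                      grid = quadrature_grid(),
                                      max_iter = 1000, conv_ll = 1e-9,
                                      conv_par = 1e-4) {
  x <- as.matrix(scored)
  n <- nrow(x); I <- ncol(x)
  if (length(covariate) != n || any(!is.finite(covariate)))
    stop("covariate must be finite with one value per person", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (stats::var(covariate) == 0) {
    message("constant covariate: falling back to fit_2pl")
    return(fit_2pl(x, weights, grid, max_iter, conv_ll, conv_par))
  }
  obs <- !is.na(x)
  xv <- x; xv[!obs] <- 0
  m <- matrix(as.numeric(obs), n, I)
  theta <- grid$points
  col_n <- colSums(m)
  col_mean <- ifelse(col_n > 0, colSums(xv) / pmax(col_n, 1), 0.5)
  a <- rep(1, I); b <- -stats::qlogis(pmin(pmax(col_mean, 0.02), 0.98))
  c1 <- a; c0 <- -a * b
  gamma0 <- 0; gamma1 <- 0; sigma_e <- 1
  wsum <- sum(weights)
  zbar <- sum(weights * covariate) / wsum
  ll_old <- -Inf; ll_trace <- numeric(0); converged <- FALSE
  for (iter in seq_len(max_iter)) {
    mu_p <- gamma0 + gamma1 * covariate
    prior_p <- stats::dnorm(outer(rep(1, n), theta), mean = mu_p, sd = sigma_e)
    prior_p <- prior_p / rowSums(prior_p)
    eta <- outer(theta, c1) + rep(c0, each = length(theta))
    log_p <- stats::plogis(eta, log.p = TRUE)
    log_q <- stats::plogis(-eta, log.p = TRUE)
    lik <- exp(tcrossprod(xv, log_p) + tcrossprod(m - xv, log_q))
    joint <- lik * prior_p
    marg <- rowSums(joint)
    ll <- sum(weights * log(marg))
    ll_trace <- c(ll_trace, ll)
    h <- joint / marg
    wH <- h * weights
    r_cnt <- crossprod(wH, xv); n_cnt <- crossprod(wH, m)
    upd <- update_items_2pl(c0, c1, r_cnt, n_cnt, theta)
    # latent-regression M-step from posterior moments
    e1 <- as.vector(h %*% theta)
    e2 <- as.vector(h %*% theta^2)
    szz <- sum(weights * (covariate - zbar)^2)
    g1_new <- sum(weights * (covariate - zbar) * e1) / szz
    g0_new <- sum(weights * e1) / wsum - g1_new * zbar
    fitted <- g0_new + g1_new * covariate
    s2 <- sum(weights * (e2 - 2 * fitted * e1 + fitted^2)) / wsum
    par_change <- max(abs(upd$c0 - c0), abs(upd$c1 - c1),
                      abs(g0_new - gamma0), abs(g1_new - gamma1),
                      abs(sqrt(s2) - sigma_e))
    c0 <- upd$c0; c1 <- upd$c1
    gamma0 <- g0_new; gamma1 <- g1_new; sigma_e <- sqrt(max(s2, 1e-6))
    if (is.finite(ll_old) &&
        (abs(ll - ll_old) < conv_ll * abs(ll_old) || par_change < conv_par)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  # final E-step at the returned parameters
  mu_p <- gamma0 + gamma1 * covariate
  prior_p <- stats::dnorm(outer(rep(1, n), theta), mean = mu_p, sd = sigma_e)
  prior_p <- prior_p / rowSums(prior_p)
  eta <- outer(theta, c1) + rep(c0, each = length(theta))
  log_p <- stats::plogis(eta, log.p = TRUE)
  log_q <- stats::plogis(-eta, log.p = TRUE)
  joint <- exp(tcrossprod(xv, log_p) + tcrossprod(m - xv, log_q)) * prior_p
  marg <- rowSums(joint)
  ll_trace <- c(ll_trace, sum(weights * log(marg)))
  h <- joint / marg
  # standardize the ability metric: marginal mean 0, SD 1
  zvar <- sum(weights * (covariate - zbar)^2) / wsum
  mu_marg <- gamma0 + gamma1 * zbar
  sd_marg <- sqrt(gamma1^2 * zvar + sigma_e^2)
  a <- c1 * sd_marg
  b <- (-c0 / c1 - mu_marg) / sd_marg
  structure(list(a = a, b = b, item_id = colnames(x),
                 loglik = ll_trace[length(ll_trace)],
                 n_params = 2L * I + 3L, n_persons = n,
                 posterior = h, grid = grid, weights = weights,
                 gamma0 = (gamma0 - mu_marg) / sd_marg,
                 gamma1 = gamma1 / sd_marg,
                 sigma_e = sigma_e / sd_marg,
                 metric_shift = c(mean = mu_marg, sd = sd_marg),
                 converged = converged, n_iter = length(ll_trace),
                 ll_trace = ll_trace),
            class = "fit_2pl")
}

#' Person posterior over the ability grid
#'
#' Normalized posterior of one person's scored response row under a fitted
#' 2PL. An all-missing row returns the prior weights exactly.
#'
#' @param fit A `fit_2pl` object.
#' @param responses One scored row (entries in `[0, 1]` or `NA`).
#' @return Probability vector over the grid points (sums to 1).
#' @export
person_posterior <- function(fit, responses) {
  theta <- fit$grid$points
  prior <- fit$grid$prior_weights
  obs <- which(!is.na(responses))
  if (!length(obs)) return(prior)
  ll <- rep(0, length(theta))
  for (i in obs) {
    eta <- fit$a[i] * (theta - fit$b[i])
    ll <- ll + responses[i] * stats::plogis(eta, log.p = TRUE) +
      (1 - responses[i]) * stats::plogis(-eta, log.p = TRUE)
  }
  post <- exp(ll) * prior
  post / sum(post)
}
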