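#' Specification of a joint model for responses and response indicators
#'
#' The Mislevy-Wu family models the response indicator of item i as
#' `P(R = 1 | X, theta, xi) = psi(xi - beta_i - delta_i * X)` jointly with a
#' 2PL for the responses, over a bivariate normal `(theta, xi)`. The family
#' members differ only in how `delta` is handled and whether the latent
#' correlation is estimated:
#' * `MO1` — `delta = 0`, `Cor(theta, xi)` fixed to 0 (manifest ignorability),
#' * `MO2` — `delta = 0`, correlation free (latent ignorability),
#' * `MW`  — `delta` fixed at -10 (missing only from incorrect responses;
#'   the model-based version of scoring as wrong),
#' * `MM1` — one common free `delta`,
#' * `MM2` — one free `delta` per item format (CR / MC).
#'
#' @param delta_mode One of `"zero"`, `"fixed"`, `"common"`, `"by_format"`.
#' @param delta_value Fixed value when `delta_mode = "fixed"`.
#' @param correlation_free Estimate `Cor(theta, xi)`?
#' @param sd_xi_free Estimate `SD(xi)`?
#' @return A list of class `joint_spec`.
#' @export
joint_spec <- function(delta_mode = c("zero", "fixed", "common", "by_format"),
                       delta_value = -10, correlation_free = TRUE,
                       sd_xi_free = TRUE) {
  delta_mode <- match.arg(delta_mode)
  structure(list(delta_mode = delta_mode, delta_value = delta_value,
                 correlation_free = correlation_free,
                 sd_xi_free = sd_xi_free),
            class = "joint_spec")
}

#' @rdname joint_spec
#' @param label One of `"MO1"`, `"MO2"`, `"MW"`, `"MM1"`, `"MM2"`.
#' @export
joint_spec_from_label <- function(label) {
  switch(label,
         MO1 = joint_spec("zero", correlation_free = FALSE),
         MO2 = joint_spec("zero"),
         MW  = joint_spec("fixed", delta_value = -10),
         MM1 = joint_spec("common"),
         MM2 = joint_spec("by_format"),
         stop("unknown joint model label: ", label, call. = FALSE))
}

#' Recode responses and indicators into one three-category variable
#'
#' Within the administered mask, `(X = 0, R = 1)` becomes category 0,
#' `(X = 1, R = 1)` category 1, and a missing response category 2; cells
#' outside the mask are `NA`. The recoded variable carries the full
#' information of the pair, so the joint model is an ordinary IRT model for
#' a polytomous variable without missing data (up to the booklet design).
#'
#' @param data A [response_data()].
#' @return Persons x items integer matrix with entries 0, 1, 2 or `NA`.
#' @export
to_three_category <- function(data) {
  v <- matrix(NA_integer_, nrow(data$observed), ncol(data$observed),
              dimnames = dimnames(data$observed))
  adm <- data$administered == 1L
  v[adm & !is.na(data$observed) & data$observed == 0] <- 0L
  v[adm & !is.na(data$observed) & data$observed == 1] <- 1L
  v[adm & is.na(data$observed)] <- 2L
  v
}

#' Category probabilities of the joint model at one node
#'
#' Probabilities of the three categories (observed wrong, observed correct,
#' missing) for one item at latent values `(theta, xi)`; they sum to one.
#'
#' @param a,b 2PL item parameters.
#' @param beta,delta Missingness parameters.
#' @param theta,xi Latent values (vectors of equal length are allowed).
#' @return A matrix with columns `p0`, `p1`, `p2`.
#' @export
joint_category_probs <- function(a, b, beta, delta, theta, xi) {
  p <- psi(a * (theta - b))
  q0 <- psi(xi - beta)          # respond given X = 0
  q1 <- psi(xi - beta - delta)  # respond given X = 1
  cbind(p0 = (1 - p) * q0, p1 = p * q1,
        p2 = p * (1 - q1) + (1 - p) * (1 - q0))
}

# normalized bivariate normal prior over the product grid
prior_2d <- function(th, xi_v, sd_xi, correlation) {
  det_s <- sd_xi^2 * (1 - correlation^2)
  z <- (th^2 - 2 * correlation * th * xi_v / sd_xi + (xi_v / sd_xi)^2) /
    (1 - correlation^2)
  w <- exp(-z / 2) / sqrt(det_s)
  w / sum(w)
}

# vectorized 1-D Newton with step halving for the indicator model
# intercepts: eta_iu = xi_u - beta_i - delta_i * x, aggregated over x = 0, 1.
update_beta <- function(beta, delta_i, xi, n0, y0, n1, y1,
                        bounds = c(-12, 12), n_newton = 3) {
  q_fun <- function(beta) {
    e0 <- outer(xi, beta, "-")
    e1 <- e0 - rep(delta_i, each = length(xi))
    colSums(y0 * stats::plogis(e0, log.p = TRUE) +
              (n0 - y0) * stats::plogis(-e0, log.p = TRUE)) +
      colSums(y1 * stats::plogis(e1, log.p = TRUE) +
                (n1 - y1) * stats::plogis(-e1, log.p = TRUE))
  }
  q_old <- q_fun(beta)
  for (it in seq_len(n_newton)) {
    e0 <- outer(xi, beta, "-")
    e1 <- e0 - rep(delta_i, each = length(xi))
    mu0 <- psi(e0); mu1 <- psi(e1)
    # eta = xi - beta, so dQ/dbeta = -(sum(y - n * mu)) and the Newton step
    # is +gradient/hess with the concave Q
    g <- -(colSums(y0 - n0 * mu0) + colSums(y1 - n1 * mu1))
    hess <- colSums(n0 * mu0 * (1 - mu0)) + colSums(n1 * mu1 * (1 - mu1))
    d <- g / pmax(hess, 1e-10)
    step <- rep(1, length(beta))
    for (half in 1:12) {
      beta_new <- pmin(pmax(beta + step * d, bounds[1]), bounds[2])
      q_new <- q_fun(beta_new)
      worse <- q_new < q_old - 1e-10
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    keep <- q_new >= q_old
    beta[keep] <- beta_new[keep]
    q_old[keep] <- q_new[keep]
  }
  beta
}

# Newton update for a delta shared across the items in `items`
# (only x = 1 cells involve delta).
update_delta <- function(delta, items, beta, xi, n1, y1,
                         bounds = c(-10, 3), n_newton = 3) {
  q_fun <- function(delta) {
    e1 <- outer(xi, beta[items], "-") - delta
    sum(y1[, items] * stats::plogis(e1, log.p = TRUE) +
          (n1[, items] - y1[, items]) * stats::plogis(-e1, log.p = TRUE))
  }
  q_old <- q_fun(delta)
  for (it in seq_len(n_newton)) {
    e1 <- outer(xi, beta[items], "-") - delta
    mu1 <- psi(e1)
    g <- -sum(y1[, items] - n1[, items] * mu1)
    hess <- sum(n1[, items] * mu1 * (1 - mu1))
    d <- g / max(hess, 1e-10)
    step <- 1
    for (half in 1:12) {
      delta_new <- min(max(delta + step * d, bounds[1]), bounds[2])
      q_new <- q_fun(delta_new)
      if (q_new >= q_old - 1e-10) break
      step <- step / 2
    }
    if (q_new >= q_old) { delta <- delta_new; q_old <- q_new }
  }
  delta
}

#' Fit a joint model for item responses and response indicators
#'
#' Marginal maximum likelihood EM over a product quadrature for `(theta,
#' xi)`: 21 points per dimension on `[-5, 5]` by default. The ability prior
#' is standard normal; `SD(xi)` and `Cor(theta, xi)` are re-estimated each
#' M-step from the posterior-weighted node moments and the prior weights are
#' rebuilt from the implied bivariate normal density. Missing cells enter
#' through the category-2 mixture probability, and the E-step imputes the
#' unobserved response with its conditional probability so all M-steps are
#' weighted logistic regressions.
#'
#' @param data A [response_data()].
#' @param spec A [joint_spec()] or a model label (`"MO1"`, `"MO2"`, `"MW"`,
#'   `"MM1"`, `"MM2"`).
#' @param formats Item formats (needed for `delta_mode = "by_format"`);
#'   defaults to a single CR format.
#' @param weights Optional person weights.
#' @param grid A [quadrature_grid()] used for each dimension.
#' @param max_iter Maximum EM iterations.
#' @param conv_ll Relative log-likelihood tolerance.
#' @param conv_par Maximum parameter-change tolerance.
#' @param accelerate Use extrapolation-accelerated EM (kept monotone by a
#'   likelihood safeguard)? Plain EM when `FALSE`.
#' @param start Optional named list of starting values (`a`, `b`, `beta`,
#'   `delta`, `sd_xi`, `correlation`); starting values affect the path, not
#'   the maximum.
#' @return A list of class `fit_joint` with item parameters `a`, `b`,
#'   `beta`, per-item `delta`, `sd_xi`, `correlation`, `loglik`,
#'   `n_params`, the per-person posterior over the 2-D grid (rows sum
#'   to 1), node coordinates, and convergence diagnostics.
#' @export
fit_joint <- function(data, spec = joint_spec("common"), formats = NULL,
                      weights = NULL, grid = quadrature_grid(),
                      max_iter = 1000, conv_ll = 1e-9, conv_par = 1e-4,
                      accelerate = TRUE, start = NULL) {
  if (is.character(spec)) spec <- joint_spec_from_label(spec)
  v <- to_three_category(data)
  n <- nrow(v); I <- ncol(v)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(formats)) formats <- rep("CR", I)
  if (spec$delta_mode == "by_format" && length(unique(formats)) == 1L)
    message("single item format present: format-specific delta degenerates ",
            "to a common delta")
  theta <- grid$points; xi <- grid$points
  tt <- length(theta); tu <- length(xi)
  tidx <- rep(seq_len(tt), times = tu)
  uidx <- rep(seq_len(tu), each = tt)
  th_node <- theta[tidx]; xi_node <- xi[uidx]
  # sparse aggregation: node -> theta margin / xi margin
  s_theta <- Matrix::sparseMatrix(i = seq_len(tt * tu), j = tidx, x = 1,
                                  dims = c(tt * tu, tt))
  s_xi <- Matrix::sparseMatrix(i = seq_len(tt * tu), j = uidx, x = 1,
                               dims = c(tt * tu, tu))

  a0 <- matrix(as.numeric(!is.na(v) & v == 0L), n, I)
  a1 <- matrix(as.numeric(!is.na(v) & v == 1L), n, I)
  a2m <- matrix(as.numeric(!is.na(v) & v == 2L), n, I)
  adm <- a0 + a1 + a2m
  a2s <- Matrix::Matrix(a2m, sparse = TRUE)
  any_missing <- any(a2m > 0)
  # with delta = 0 the category-2 probability depends on xi alone, so the
  # likelihood stays separable and the wide sparse products are skipped
  coupled <- any_missing && spec$delta_mode != "zero"

  # starting values
  p_obs <- colSums(a1) / pmax(colSums(a0 + a1), 1)
  wrong_p <- colSums(a1) / pmax(colSums(adm), 1)  # wrong-scored difficulty
  c1 <- rep(1, I)
  c0 <- stats::qlogis(pmin(pmax(wrong_p, 0.02), 0.98))
  miss_rate <- colSums(a2m) / pmax(colSums(adm), 1)
  beta <- stats::qlogis(pmin(pmax(miss_rate, 1e-3), 0.999))
  no_missing_item <- miss_rate == 0
  delta_i <- switch(spec$delta_mode,
                    zero = rep(0, I),
                    fixed = rep(spec$delta_value, I),
                    common = rep(0, I),
                    by_format = rep(0, I))
  sd_xi <- 1
  correlation <- 0
  if (!is.null(start)) {
    if (!is.null(start$a)) c1 <- rep_len(start$a, I)
    if (!is.null(start$b)) c0 <- -c1 * rep_len(start$b, I)
    if (!is.null(start$beta)) beta <- rep_len(start$beta, I)
    if (!is.null(start$delta) && spec$delta_mode %in% c("common", "by_format"))
      delta_i <- rep_len(start$delta, I)
    if (!is.null(start$sd_xi)) sd_xi <- start$sd_xi
    if (!is.null(start$correlation)) correlation <- start$correlation
  }
  delta_free <- spec$delta_mode %in% c("common", "by_format")
  fmt_groups <- if (spec$delta_mode == "by_format")
    split(seq_len(I), formats) else list(all = seq_len(I))

  # one EM step: E-step (expected counts + log-likelihood at the current
  # parameters) followed by the conditional M-steps; parameters travel as a
  # packed vector so the accelerated loop below can extrapolate them
  n_free_delta <- if (delta_free) length(fmt_groups) else 0L
  pack <- function(c0, c1, beta, delta_i, sd_xi, correlation) {
    d_free <- if (delta_free)
      vapply(fmt_groups, function(g) delta_i[g[1]], numeric(1)) else numeric(0)
    c(c0, c1, beta, d_free,
      if (spec$sd_xi_free) log(sd_xi) else numeric(0),
      if (spec$correlation_free) atanh(correlation) else numeric(0))
  }
  unpack <- function(p) {
    c0 <- p[seq_len(I)]; c1 <- p[I + seq_len(I)]; beta <- p[2L * I + seq_len(I)]
    pos <- 3L * I
    delta_v <- delta_i
    if (delta_free) {
      for (k in seq_along(fmt_groups))
        delta_v[fmt_groups[[k]]] <- p[pos + k]
      pos <- pos + n_free_delta
    }
    sd_v <- sd_xi; cor_v <- correlation
    if (spec$sd_xi_free) { pos <- pos + 1L; sd_v <- exp(p[pos]) }
    if (spec$correlation_free) { pos <- pos + 1L; cor_v <- tanh(p[pos]) }
    list(c0 = c0, c1 = c1, beta = beta, delta = delta_v,
         sd_xi = sd_v, correlation = cor_v)
  }
  clamp <- function(p) {
    q <- unpack(p)
    q$c1 <- pmin(pmax(q$c1, 0.05), 8)
    b <- pmin(pmax(-q$c0 / q$c1, -8), 8)
    q$c0 <- -q$c1 * b
    q$beta <- pmin(pmax(q$beta, -12), 12)
    q$delta <- pmin(pmax(q$delta, -10), 3)
    q$sd_xi <- min(max(q$sd_xi, 0.05), 10)
    q$correlation <- min(max(q$correlation, -0.99), 0.99)
    pack(q$c0, q$c1, q$beta, q$delta, q$sd_xi, q$correlation)
  }

  estep <- function(q, want_h = FALSE) {
    prior <- prior_2d(th_node, xi_node, q$sd_xi, q$correlation)
    eta <- outer(theta, q$c1) + rep(q$c0, each = tt)    # tt x I
    log_p <- stats::plogis(eta, log.p = TRUE)
    log_1p <- stats::plogis(-eta, log.p = TRUE)
    p_mat <- exp(log_p)
    e0 <- outer(xi, q$beta, "-")                        # tu x I
    e1 <- e0 - rep(q$delta, each = tu)
    q1 <- psi(e1)

    l_theta <- tcrossprod(a0, log_1p) + tcrossprod(a1, log_p)  # N x tt
    l_xi <- tcrossprod(a0, stats::plogis(e0, log.p = TRUE)) +
      tcrossprod(a1, stats::plogis(e1, log.p = TRUE))          # N x tu
    if (any_missing && !coupled)
      l_xi <- l_xi + tcrossprod(a2m, stats::plogis(-e0, log.p = TRUE))
    ll_mat <- l_theta[, tidx, drop = FALSE] + l_xi[, uidx, drop = FALSE]
    w2 <- NULL
    if (coupled) {
      # category-2 mixture per item over all nodes (theta index fast)
      p2 <- p_mat[tidx, , drop = FALSE] * (1 - q1[uidx, , drop = FALSE]) +
        (1 - p_mat[tidx, , drop = FALSE]) *
          (1 - psi(e0)[uidx, , drop = FALSE])
      ll_mat <- ll_mat + as.matrix(a2s %*% t(log(pmax(p2, 1e-300))))
      w2 <- t(p_mat[tidx, , drop = FALSE] * (1 - q1[uidx, , drop = FALSE])) /
        pmax(t(p2), 1e-300)                             # I x nodes
    }
    joint_post <- exp(ll_mat) * rep(prior, each = n)
    marg <- rowSums(joint_post)
    ll <- sum(weights * log(marg))
    h <- joint_post / marg
    w_h <- h * weights
    w_h_theta <- as.matrix(w_h %*% s_theta)             # N x tt
    w_h_xi <- as.matrix(w_h %*% s_xi)                   # N x tu

    r_theta <- crossprod(w_h_theta, a1)                 # tt x I successes
    n_theta <- crossprod(w_h_theta, adm)
    y0 <- crossprod(w_h_xi, a0)                         # tu x I, R=1 | X=0
    y1 <- crossprod(w_h_xi, a1)                         # tu x I, R=1 | X=1
    n0 <- y0; n1 <- y1
    if (coupled) {
      b2 <- as.matrix(Matrix::crossprod(a2s, w_h))      # I x nodes
      r2 <- b2 * w2
      r_theta <- r_theta + t(as.matrix(r2 %*% s_theta))
      n1 <- n1 + t(as.matrix(r2 %*% s_xi))
      n0 <- n0 + t(as.matrix((b2 - r2) %*% s_xi))
    } else if (any_missing) {
      # delta = 0: P(X=1 | missing, theta) is the 2PL probability and the
      # indicator model ignores X, so margins suffice
      r_theta <- r_theta + p_mat * crossprod(w_h_theta, a2m)
      n0 <- n0 + crossprod(w_h_xi, a2m)
    }
    g_nodes <- colSums(w_h) / sum(weights)
    out <- list(ll = ll, r_theta = r_theta, n_theta = n_theta,
                y0 = y0, y1 = y1, n0 = n0, n1 = n1,
                s11 = sum(g_nodes * th_node^2),
                s22 = sum(g_nodes * xi_node^2),
                s12 = sum(g_nodes * th_node * xi_node))
    if (want_h) out$h <- h
    out
  }

  mstep <- function(q, e) {
    upd <- update_items_2pl(q$c0, q$c1, e$r_theta, e$n_theta, theta)
    beta_new <- q$beta; delta_new <- q$delta
    for (cycle in 1:2) {  # alternate the indicator-model updates
      beta_new <- update_beta(beta_new, delta_new, xi, e$n0, e$y0, e$n1, e$y1)
      if (delta_free) {
        for (g in fmt_groups)
          delta_new[g] <- update_delta(delta_new[g[1]], g, beta_new, xi,
                                       e$n1, e$y1)
      }
    }
    beta_new[no_missing_item] <- pmin(beta_new[no_missing_item], -12)
    sd_new <- q$sd_xi; cor_new <- q$correlation
    if (spec$sd_xi_free) sd_new <- min(max(sqrt(e$s22), 0.05), 10)
    if (spec$correlation_free)
      cor_new <- min(max(e$s12 / sqrt(e$s11 * e$s22), -0.99), 0.99)
    list(c0 = upd$c0, c1 = upd$c1, beta = beta_new, delta = delta_new,
         sd_xi = sd_new, correlation = cor_new)
  }

  em_step <- function(p) {
    q <- unpack(p)
    e <- estep(q)
    list(p = pack_q(mstep(q, e)), ll = e$ll)
  }
  pack_q <- function(q) pack(q$c0, q$c1, q$beta, q$delta, q$sd_xi,
                             q$correlation)

  natural <- function(p) {
    q <- unpack(p)
    c(q$c0, q$c1, q$beta, q$delta, q$sd_xi, q$correlation)
  }

  # accelerated EM (SQUAREM-type extrapolation with a likelihood safeguard)
  run_em <- function(p_init, budget) {
    p0 <- p_init
    ll_trace <- numeric(0); converged <- FALSE
    n_em <- 0L
    while (n_em < budget) {
      s1 <- em_step(p0); n_em <- n_em + 1L
      s2 <- em_step(s1$p); n_em <- n_em + 1L
      ll_trace <- c(ll_trace, s1$ll, s2$ll)
      r_vec <- s1$p - p0
      v_vec <- s2$p - 2 * s1$p + p0
      p_next <- s2$p
      v_norm <- sqrt(sum(v_vec^2))
      if (accelerate && v_norm > 1e-12) {
        alpha <- min(max(sqrt(sum(r_vec^2)) / v_norm, 1), 64)
        p_try <- clamp(p0 + 2 * alpha * r_vec + alpha^2 * v_vec)
        s3 <- em_step(p_try); n_em <- n_em + 1L
        if (s3$ll >= s2$ll) {
          ll_trace <- c(ll_trace, s3$ll)
          p_next <- s3$p
        }
      }
      par_change <- max(abs(natural(p_next) - natural(p0)))
      nll <- length(ll_trace)
      ll_change <- if (nll >= 2)
        abs(ll_trace[nll] - ll_trace[nll - 1]) else Inf
      p0 <- p_next
      # the cycle spans about three EM steps, so the parameter criterion is
      # applied to the per-cycle movement
      if (par_change < 3 * conv_par ||
          ll_change < conv_ll * abs(ll_trace[nll])) {
        converged <- TRUE
        break
      }
    }
    list(p = p0, ll_trace = ll_trace, converged = converged, n_em = n_em)
  }

  p_init <- pack(c0, c1, beta, delta_i, sd_xi, correlation)
  if (delta_free && any_missing && is.null(start$delta)) {
    # the free-delta likelihood can be bimodal when missingness is extreme;
    # probe the strongly negative delta basin as well and keep the mode with
    # the higher likelihood
    probes <- list(run_em(p_init, 36L),
                   run_em(pack(c0, c1, beta, rep(-4, I), sd_xi, correlation),
                          36L))
    lls <- vapply(probes, function(r) max(r$ll_trace), numeric(1))
    winner <- probes[[which.max(lls)]]
    res <- run_em(winner$p, max_iter)
    res$ll_trace <- c(winner$ll_trace, res$ll_trace)
  } else {
    res <- run_em(p_init, max_iter)
  }
  p0 <- res$p
  ll_trace <- res$ll_trace
  converged <- res$converged
  q_fin <- unpack(p0)
  c0 <- q_fin$c0; c1 <- q_fin$c1; beta <- q_fin$beta; delta_i <- q_fin$delta
  sd_xi <- q_fin$sd_xi; correlation <- q_fin$correlation
  # final E-step at the returned parameters
  prior <- prior_2d(th_node, xi_node, sd_xi, correlation)
  eta <- outer(theta, c1) + rep(c0, each = tt)
  log_p <- stats::plogis(eta, log.p = TRUE)
  log_1p <- stats::plogis(-eta, log.p = TRUE)
  p_mat <- exp(log_p)
  e0 <- outer(xi, beta, "-")
  e1 <- e0 - rep(delta_i, each = tu)
  q0 <- psi(e0); q1 <- psi(e1)
  l_theta <- tcrossprod(a0, log_1p) + tcrossprod(a1, log_p)
  l_xi <- tcrossprod(a0, stats::plogis(e0, log.p = TRUE)) +
    tcrossprod(a1, stats::plogis(e1, log.p = TRUE))
  if (any_missing && !coupled)
    l_xi <- l_xi + tcrossprod(a2m, stats::plogis(-e0, log.p = TRUE))
  ll_mat <- l_theta[, tidx, drop = FALSE] + l_xi[, uidx, drop = FALSE]
  if (coupled) {
    p2 <- p_mat[tidx, , drop = FALSE] * (1 - q1[uidx, , drop = FALSE]) +
      (1 - p_mat[tidx, , drop = FALSE]) * (1 - q0[uidx, , drop = FALSE])
    ll_mat <- ll_mat + as.matrix(a2s %*% t(log(pmax(p2, 1e-300))))
  }
  joint_post <- sweep(exp(ll_mat), 2, prior, "*")
  marg <- rowSums(joint_post)
  ll_trace <- c(ll_trace, sum(weights * log(marg)))
  h <- joint_post / marg
  a <- c1; b <- -c0 / c1
  structure(list(a = a, b = b, beta = beta, delta = delta_i,
                 delta_mode = spec$delta_mode,
                 sd_xi = sd_xi, correlation = correlation,
                 item_id = colnames(v), formats = formats,
                 loglik = ll_trace[length(ll_trace)],
                 n_params = n_parameters(spec, I, formats),
                 n_persons = n,
                 posterior = h, theta_nodes = th_node, xi_nodes = xi_node,
                 grid = grid, weights = weights,
                 converged = converged, n_iter = length(ll_trace),
                 ll_trace = ll_trace),
            class = "fit_joint")
}

#' Number of free parameters of a joint model
#'
#' `2I` measurement parameters, `I` missingness intercepts, the free
#' `delta`s (0, 1, or one per format), plus `SD(xi)` and the latent
#' correlation when estimated.
#'
#' @param spec A [joint_spec()] or model label.
#' @param n_items Number of items.
#' @param formats Item formats (used for `by_format`).
#' @return Integer parameter count.
#' @export
n_parameters <- function(spec, n_items, formats = NULL) {
  if (is.character(spec)) spec <- joint_spec_from_label(spec)
  n_delta <- switch(spec$delta_mode,
                    zero = 0L, fixed = 0L, common = 1L,
                    by_format = length(unique(formats %||% "CR")))
  as.integer(2L * n_items + n_items + n_delta +
               spec$sd_xi_free + spec$correlation_free)
}

#' Registry of missing-data treatment recipes
#'
#' Maps each of the 19 treatment labels to its pipeline: a pre-scaling
#' scoring rule ("U" models), a joint model for responses and indicators
#' ("M" models), or an imputation source plus stacked 2PL scaling
#' ("I" models).
#'
#' @param label One of `"UW"`, `"MW"`, `"IW"`, `"UP"`, `"IP"`, `"UN1"`,
#'   `"UN2"`, `"UO1"`, `"MO1"`, `"IO1"`, `"UO2"`, `"MO2"`, `"IO2"`,
#'   `"MM1"`, `"IM1"`, `"MM2"`, `"IM2"`, `"IF1"`, `"IF2"` (alias `"UO"`
#'   for `"UO1"`, `"CD"` for the complete-data reference).
#' @return A list describing the recipe: `strategy` (`"scoring"`,
#'   `"model"`, `"imputation"`, `"complete"`), and strategy-specific fields
#'   (`scoring`, `covariate`, `joint`, `imputation`).
#' @export
model_registry <- function(label) {
  recipes <- list(
    CD  = list(strategy = "complete"),
    UW  = list(strategy = "scoring", scoring = "wrong_all"),
    UP  = list(strategy = "scoring", scoring = "partial"),
    UN1 = list(strategy = "scoring", scoring = "wrong_omitted"),
    UN2 = list(strategy = "scoring", scoring = "wrong_omitted",
               covariate = "not_reached"),
    UO1 = list(strategy = "scoring", scoring = "ignore"),
    UO  = list(strategy = "scoring", scoring = "ignore"),
    UO2 = list(strategy = "scoring", scoring = "ignore",
               covariate = "all_missing"),
    MW  = list(strategy = "model", joint = "MW"),
    MO1 = list(strategy = "model", joint = "MO1"),
    MO2 = list(strategy = "model", joint = "MO2"),
    MM1 = list(strategy = "model", joint = "MM1"),
    MM2 = list(strategy = "model", joint = "MM2"),
    IW  = list(strategy = "imputation", imputation = "model", joint = "MW"),
    IO1 = list(strategy = "imputation", imputation = "model", joint = "MO1"),
    IO2 = list(strategy = "imputation", imputation = "model", joint = "MO2"),
    IM1 = list(strategy = "imputation", imputation = "model", joint = "MM1"),
    IM2 = list(strategy = "imputation", imputation = "model", joint = "MM2"),
    IP  = list(strategy = "imputation", imputation = "partial"),
    IF1 = list(strategy = "imputation", imputation = "fcs",
               include_indicators = FALSE),
    IF2 = list(strategy = "imputation", imputation = "fcs",
               include_indicators = TRUE)
  )
  if (!label %in% names(recipes))
    stop("unknown treatment label: ", label, call. = FALSE)
  c(recipes[[label]], list(label = label))
}
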