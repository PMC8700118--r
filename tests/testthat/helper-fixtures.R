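# Small deterministic fixtures shared across test files.

# tiny response dataset with known missing pattern:
# rows: fully observed / omission inside / trailing run / all observed
tiny_data <- function() {
  obs <- rbind(c(1L, 0L, 1L, 1L),
               c(1L, NA, 0L, NA),
               c(1L, 1L, NA, NA),
               c(0L, 1L, 0L, 1L))
  colnames(obs) <- paste0("I", 1:4)
  response_data(obs)
}

tiny_bank <- function() {
  bank <- make_item_bank(4, c(-1, 1))
  bank$format <- c("MC", "CR", "MC", "CR")
  bank$n_options <- c(4L, NA, 5L, NA)
  bank
}

# independent marginal log-likelihood of a 2PL via direct summation over a
# quadrature grid (oracle; kept free of package internals on purpose)
oracle_ll_2pl <- function(x, a, b, grid_points, prior_weights) {
  n <- nrow(x)
  ll <- 0
  for (p in seq_len(n)) {
    lik_t <- vapply(seq_along(grid_points), function(t) {
      pr <- 1 / (1 + exp(-a * (grid_points[t] - b)))
      obs <- which(!is.na(x[p, ]))
      prod(pr[obs]^x[p, obs] * (1 - pr[obs])^(1 - x[p, obs]))
    }, numeric(1))
    ll <- ll + log(sum(lik_t * prior_weights))
  }
  ll
}

# independent joint-model log-likelihood: brute-force double sum over the
# 2-D grid using explicit category probabilities
oracle_ll_joint <- function(v, a, b, beta, delta, grid_points, sd_xi,
                            correlation) {
  tt <- length(grid_points)
  th <- rep(grid_points, times = tt)
  xv <- rep(grid_points, each = tt)
  dens <- exp(-(th^2 - 2 * correlation * th * xv / sd_xi +
                  (xv / sd_xi)^2) / (2 * (1 - correlation^2)))
  w <- dens / sum(dens)
  ll <- 0
  for (p in seq_len(nrow(v))) {
    lik_nodes <- rep(1, length(th))
    for (i in seq_len(ncol(v))) {
      if (is.na(v[p, i])) next
      pr <- 1 / (1 + exp(-a[i] * (th - b[i])))
      q0 <- 1 / (1 + exp(-(xv - beta[i])))
      q1 <- 1 / (1 + exp(-(xv - beta[i] - delta[i])))
      cat_p <- switch(as.character(v[p, i]),
                      "0" = (1 - pr) * q0,
                      "1" = pr * q1,
                      "2" = pr * (1 - q1) + (1 - pr) * (1 - q0))
      lik_nodes <- lik_nodes * cat_p
    }
    ll <- ll + log(sum(lik_nodes * w))
  }
  ll
}

# closed-form two-group log-mean-mean linking oracle
oracle_log_mean_mean <- function(ref, est) {
  nu1 <- exp(mean(log(est$a)) - mean(log(ref$a)))
  nu0 <- mean(ref$b) - nu1 * mean(est$b)
  c(nu0 = nu0, nu1 = nu1)
}
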