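#' Posterior probability of a correct response for a missing cell
#'
#' Bayes-rule probability that an unobserved response is correct given that
#' it is missing, at latent values `(theta*, xi*)`:
#' the numerator is `P(R = 0 | X = 1, xi*) * P(X = 1 | theta*)` and the
#' denominator sums the same product over both response values. With
#' `delta = 0` this reduces to the plain 2PL probability; with a strongly
#' negative `delta` it collapses to zero because correct responses are then
#' (almost) always delivered.
#'
#' @param a,b 2PL item parameters.
#' @param beta,delta Missingness parameters of the item.
#' @param theta_star,xi_star Latent values (vectors allowed).
#' @return Probability in `[0, 1]`.
#' @export
imputation_probability <- function(a, b, beta, delta, theta_star, xi_star) {
  p1 <- psi(a * (theta_star - b))
  miss_given_1 <- 1 - psi(xi_star - beta - delta)
  miss_given_0 <- 1 - psi(xi_star - beta)
  num <- miss_given_1 * p1
  den <- num + miss_given_0 * (1 - p1)
  ifelse(den > 0, num / den, 0)
}

#' Draw latent values from fitted per-person posteriors
#'
#' One categorical draw per person from the normalized posterior over the
#' 2-D quadrature nodes of a joint fit (or the 1-D grid of a 2PL fit, in
#' which case `xi` is `NA`).
#'
#' @param fit A `fit_joint` or `fit_2pl` object.
#' @param seed Optional integer seed.
#' @return A list with vectors `theta` and `xi` (node values per person).
#' @export
draw_posterior_latents <- function(fit, seed = NULL) {
  draw <- function() {
    h <- fit$posterior
    cum <- h %*% upper.tri(diag(ncol(h)), diag = TRUE)
    u <- stats::runif(nrow(h))
    idx <- rowSums(cum < u) + 1L
    if (inherits(fit, "fit_joint")) {
      list(theta = fit$theta_nodes[idx], xi = fit$xi_nodes[idx])
    } else {
      list(theta = fit$grid$points[idx], xi = rep(NA_real_, nrow(h)))
    }
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Model-based multiple imputation from a joint fit
#'
#' For each of `m` completed datasets, draws `(theta*, xi*)` per person from
#' the fitted posterior, then fills each missing cell with a Bernoulli draw
#' at its [imputation_probability()]. Observed cells are never altered.
#' Sourced from the wrong-scoring joint fit this yields treatment IW, from
#' the latent-ignorable fits IO1/IO2, and from the Mislevy-Wu fits IM1/IM2.
#'
#' @param fit A `fit_joint` object.
#' @param data The [response_data()] the fit was computed on.
#' @param m Number of imputations.
#' @param seed Optional integer master seed.
#' @return A list of class `imputation_set`: `imputations` (list of m
#'   completed matrices), `source`, `m`, `seed`.
#' @export
impute_model_based <- function(fit, data, m = 5, seed = NULL) {
  miss <- which(is.na(data$observed) & data$administered == 1L,
                arr.ind = TRUE)
  seeds <- if (is.null(seed)) sample.int(.Machine$integer.max - 1L, m)
           else derive_seeds(seed, m, tag = 11L)
  imps <- vector("list", m)
  for (k in seq_len(m)) {
    imps[[k]] <- with_seed(seeds[k], {
      lat <- draw_posterior_latents(fit)
      x <- data$observed
      if (nrow(miss)) {
        pr <- imputation_probability(
          fit$a[miss[, 2]], fit$b[miss[, 2]],
          fit$beta[miss[, 2]], fit$delta[miss[, 2]],
          lat$theta[miss[, 1]], lat$xi[miss[, 1]])
        x[miss] <- as.integer(stats::runif(nrow(miss)) < pr)
      }
      x
    })
  }
  structure(list(imputations = imps, source = "model", m = m, seed = seed),
            class = "imputation_set")
}

#' Guessing-based imputation of missing multiple-choice responses
#'
#' Missing MC responses are imputed as correct with the random-guessing
#' probability `1 / K_i`; missing CR responses become 0. This is the
#' imputation implementation of partially correct scoring (treatment IP);
#' no fitted model is involved.
#'
#' @param data A [response_data()].
#' @param bank Item bank carrying `format` and `n_options`.
#' @param m Number of imputations.
#' @param seed Optional integer master seed.
#' @return An `imputation_set`.
#' @export
impute_partial_guess <- function(data, bank, m = 5, seed = NULL) {
  if (any(bank$format == "MC" & (is.na(bank$n_options) | bank$n_options < 2)))
    stop("MC items require n_options metadata", call. = FALSE)
  miss <- which(is.na(data$observed) & data$administered == 1L,
                arr.ind = TRUE)
  guess <- ifelse(bank$format == "MC", 1 / bank$n_options, 0)
  seeds <- if (is.null(seed)) sample.int(.Machine$integer.max - 1L, m)
           else derive_seeds(seed, m, tag = 13L)
  imps <- vector("list", m)
  for (k in seq_len(m)) {
    imps[[k]] <- with_seed(seeds[k], {
      x <- data$observed
      if (nrow(miss))
        x[miss] <- as.integer(stats::runif(nrow(miss)) < guess[miss[, 2]])
      x
    })
  }
  structure(list(imputations = imps, source = "partial", m = m, seed = seed),
            class = "imputation_set")
}

# NIPALS partial least squares: components of X that successively maximize
# covariance with y. Returns scores, loadings and the training column means.
pls_nipals <- function(x, y, n_factors) {
  x <- as.matrix(x)
  mx <- colMeans(x)
  e <- sweep(x, 2, mx)
  f <- y - mean(y)
  n_factors <- min(n_factors, ncol(x), nrow(x) - 1L)
  weights <- matrix(0, ncol(x), n_factors)
  loadings <- matrix(0, ncol(x), n_factors)
  scores <- matrix(0, nrow(x), n_factors)
  kept <- 0L
  for (f_idx in seq_len(n_factors)) {
    w <- crossprod(e, f)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-10) break  # degenerate component: no covariance left
    w <- w / wn
    t_sc <- e %*% w
    tt <- sum(t_sc^2)
    if (tt < 1e-10) break
    p <- crossprod(e, t_sc) / tt
    e <- e - tcrossprod(t_sc, p)
    f <- f - t_sc * as.numeric(crossprod(t_sc, f) / tt)
    kept <- kept + 1L
    weights[, kept] <- w
    loadings[, kept] <- p
    scores[, kept] <- t_sc
  }
  if (kept == 0L)
    return(list(scores = NULL, rotation = NULL, center = mx, n_factors = 0L))
  w_mat <- weights[, seq_len(kept), drop = FALSE]
  p_mat <- loadings[, seq_len(kept), drop = FALSE]
  # rotation mapping centered X to scores: W (P'W)^{-1}
  rotation <- w_mat %*% solve(crossprod(p_mat, w_mat))
  list(scores = scores[, seq_len(kept), drop = FALSE], rotation = rotation,
       center = mx, n_factors = kept)
}

# predictive mean matching: for each target prediction pick one of the
# n_donors observed cases with closest predicted value, return its observed y
pmm_match <- function(pred_obs, y_obs, pred_miss, n_donors = 5) {
  vapply(pred_miss, function(pm) {
    d <- abs(pred_obs - pm)
    donors <- order(d)[seq_len(min(n_donors, length(d)))]
    y_obs[donors[sample.int(length(donors), 1L)]]
  }, numeric(1))
}

#' Fully conditional specification imputation with PLS and PMM
#'
#' Cycles over item columns with missing values. The imputation model for a
#' column regresses it on all other item columns (and, when
#' `include_indicators = TRUE`, on all response-indicator columns except the
#' target's own), after compressing the predictors to `n_pls_factors`
#' partial least squares components. Predictions are turned into imputed
#' values by predictive mean matching against observed donors, so imputed
#' values only take values present in the observed data. Without indicators
#' this is treatment IF1, with indicators IF2.
#'
#' @param data A [response_data()].
#' @param include_indicators Include response indicators as predictors?
#' @param n_pls_factors Number of PLS components (capped at the predictor
#'   rank).
#' @param m Number of stored imputations.
#' @param n_cycles FCS cycles before each stored imputation.
#' @param pmm_donors Number of nearest donors for predictive mean matching.
#' @param seed Optional integer master seed.
#' @param booklet Optional per-person grouping; the algorithm is then run
#'   separately within each booklet group.
#' @return An `imputation_set`.
#' @export
fcs_impute <- function(data, include_indicators = FALSE, n_pls_factors = 10,
                       m = 5, n_cycles = 10, pmm_donors = 5, seed = NULL,
                       booklet = NULL) {
  obs_mat <- data$observed
  if (!is.null(booklet)) {
    groups <- split(seq_len(nrow(obs_mat)), booklet)
    imps <- replicate(m, obs_mat, simplify = FALSE)
    seeds <- if (is.null(seed)) sample.int(.Machine$integer.max - 1L,
                                           length(groups))
             else derive_seeds(seed, length(groups), tag = 17L)
    for (g_idx in seq_along(groups)) {
      rows <- groups[[g_idx]]
      sub <- response_data(obs_mat[rows, , drop = FALSE],
                           data$indicators[rows, , drop = FALSE],
                           data$administered[rows, , drop = FALSE])
      sub_imp <- fcs_impute(sub, include_indicators, n_pls_factors, m,
                            n_cycles, pmm_donors, seed = seeds[g_idx])
      for (k in seq_len(m)) imps[[k]][rows, ] <- sub_imp$imputations[[k]]
    }
    return(structure(list(imputations = imps,
                          source = if (include_indicators) "fcs2" else "fcs1",
                          m = m, seed = seed),
                     class = "imputation_set"))
  }
  miss_cols <- which(colSums(is.na(obs_mat)) > 0)
  if (any(colSums(!is.na(obs_mat)) == 0))
    stop("imputation error: a column has no observed values", call. = FALSE)
  seeds <- if (is.null(seed)) sample.int(.Machine$integer.max - 1L, m)
           else derive_seeds(seed, m, tag = 19L)
  r_mat <- data$indicators
  imps <- vector("list", m)
  for (k in seq_len(m)) {
    imps[[k]] <- with_seed(seeds[k], {
      x <- obs_mat
      # initial fill by marginal draws from each column's observed values
      for (v in miss_cols) {
        nas <- is.na(x[, v])
        pool <- x[!nas, v]
        x[nas, v] <- pool[sample.int(length(pool), sum(nas), replace = TRUE)]
      }
      for (cycle in seq_len(n_cycles)) {
        for (v in miss_cols) {
          target_miss <- is.na(obs_mat[, v])
          preds <- x[, -v, drop = FALSE]
          if (include_indicators)
            preds <- cbind(preds, r_mat[, -v, drop = FALSE])
          pls <- pls_nipals(preds[!target_miss, , drop = FALSE],
                            x[!target_miss, v], n_pls_factors)
          if (pls$n_factors == 0L) {
            # no usable predictor signal: marginal donor draw
            pool <- obs_mat[!target_miss, v]
            x[target_miss, v] <-
              pool[sample.int(length(pool), sum(target_miss), replace = TRUE)]
            next
          }
          sc_obs <- pls$scores
          fit <- stats::lm.fit(cbind(1, sc_obs), x[!target_miss, v])
          sc_miss <- sweep(preds[target_miss, , drop = FALSE], 2,
                           pls$center) %*% pls$rotation
          pred_obs <- cbind(1, sc_obs) %*% fit$coefficients
          pred_miss <- cbind(1, sc_miss) %*% fit$coefficients
          x[target_miss, v] <- pmm_match(as.vector(pred_obs),
                                         x[!target_miss, v],
                                         as.vector(pred_miss), pmm_donors)
        }
      }
      x
    })
  }
  structure(list(imputations = imps,
                 source = if (include_indicators) "fcs2" else "fcs1",
                 m = m, seed = seed),
            class = "imputation_set")
}

#' Stack multiply imputed datasets and fit the 2PL
#'
#' Row-concatenates the `m` completed matrices (each row keeping its person
#' weight) and applies the 2PL scaling model to the stack. Stacking instead
#' of combining per-imputation fits leaves item parameter estimates
#' unbiased; standard errors would require resampling, which is out of scope
#' here.
#'
#' @param imps An `imputation_set`.
#' @param weights Optional per-person weights (recycled over imputations).
#' @param grid A [quadrature_grid()].
#' @param ... Passed to [fit_2pl()].
#' @return A `fit_2pl` object for the stacked data.
#' @export
stack_and_scale <- function(imps, weights = NULL, grid = quadrature_grid(),
                            ...) {
  stacked <- do.call(rbind, imps$imputations)
  if (!is.null(weights)) weights <- rep(weights, imps$m)
  fit_2pl(stacked, weights = weights, grid = grid, ...)
}

#' Write an imputation set as one long CSV
#'
#' Rows of all completed datasets with a leading `.imp` index column.
#'
#' @param imps An `imputation_set`.
#' @param path File path.
#' @export
write_imputations <- function(imps, path) {
  long <- do.call(rbind, lapply(seq_len(imps$m), function(k)
    cbind(.imp = k, as.data.frame(imps$imputations[[k]]))))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
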