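test_that("the imputation probability follows Bayes' rule", {
  # delta = 0: reduces to the plain 2PL probability
  th <- seq(-2, 2, by = 0.5)
  expect_equal(imputation_probability(1.2, 0.3, -1, 0, th, 0),
               psi(1.2 * (th - 0.3)), tolerance = 1e-12)
  # missing only from incorrect responses
  expect_lt(imputation_probability(1, 0, 0, -10, 0, 0), 1e-3)
  # direct scalar arithmetic oracle
  num <- (1 - psi(2)) * psi(0)
  den <- num + (1 - psi(0)) * (1 - psi(0))
  expect_equal(imputation_probability(1, 0, 0, -2, 0, 0), num / den,
               tolerance = 1e-12)
  expect_equal(round(num / den, 4), 0.1925)
})

test_that("posterior latent draws match the posterior distribution", {
  gen <- generate_dataset(n = 30, n_items = 6, delta = -1, target_rate = 0.2,
                          seed = 61)
  fit <- fit_joint(gen$data, "MO2", max_iter = 60)
  d1 <- draw_posterior_latents(fit, seed = 62)
  d2 <- draw_posterior_latents(fit, seed = 62)
  expect_identical(d1, d2)
  # empirical node frequencies for one person over many draws
  reps <- 4000
  one <- fit$posterior[1, , drop = FALSE]
  small <- list(posterior = one[rep(1, reps), ],
                theta_nodes = fit$theta_nodes, xi_nodes = fit$xi_nodes,
                grid = fit$grid)
  class(small) <- "fit_joint"
  dr <- draw_posterior_latents(small, seed = 63)
  em <- mean(dr$theta)
  expect_lt(abs(em - sum(one * fit$theta_nodes)), 4 * sd(dr$theta) / sqrt(reps))
})

test_that("model-based imputation respects observed data and the source fit", {
  gen <- generate_dataset(n = 60, n_items = 6, delta = -10, target_rate = 0.25,
                          seed = 64)
  # no missing: identical copies
  full <- response_data(gen$complete)
  fitc <- fit_joint(full, "MO2", max_iter = 40)
  imps <- impute_model_based(fitc, full, m = 3, seed = 65)
  expect_identical(imps$imputations[[1]], gen$complete)
  expect_identical(imps$imputations[[3]], gen$complete)

  # delta = -10 source: every imputed cell is 0
  fit_mw <- fit_joint(gen$data, "MW", max_iter = 60)
  imps2 <- impute_model_based(fit_mw, gen$data, m = 3, seed = 66)
  miss <- is.na(gen$data$observed)
  for (k in 1:3) {
    expect_true(all(imps2$imputations[[k]][miss] == 0))
    expect_identical(imps2$imputations[[k]][!miss], gen$data$observed[!miss])
  }
})

test_that("imputed-one frequencies match the imputation probability", {
  # single missing cell with a hand-built joint fit pinned to one node
  obs <- matrix(c(1L, NA, 0L, 1L), 1, 4)
  d <- response_data(obs)
  grid <- quadrature_grid()
  fit <- structure(list(a = rep(1, 4), b = rep(0, 4), beta = rep(0, 4),
                        delta = rep(-2, 4), item_id = NULL,
                        posterior = matrix(c(rep(0, 220), 1, rep(0, 220)), 1),
                        theta_nodes = rep(grid$points, times = 21),
                        xi_nodes = rep(grid$points, each = 21),
                        grid = grid), class = "fit_joint")
  # node 221 is (theta = 0, xi = 0); expected P(X=1 | miss) = 0.1925
  m <- 4000
  imps <- impute_model_based(fit, d, m = m, seed = 67)
  freq <- mean(vapply(imps$imputations, function(x) x[1, 2], numeric(1)))
  expect_lt(abs(freq - 0.1925), 3 * sqrt(0.1925 * 0.8075 / m))
})

test_that("guessing imputation uses 1/K for MC and 0 for CR", {
  obs <- matrix(NA_integer_, 500, 2)
  obs[, 1] <- rep(c(1L, NA), 250)
  d <- response_data(obs)
  bank <- make_item_bank(2)
  bank$format <- c("MC", "CR"); bank$n_options <- c(4L, NA)
  imps <- impute_partial_guess(d, bank, m = 40, seed = 68)
  vals1 <- unlist(lapply(imps$imputations, function(x) x[is.na(obs[, 1]), 1]))
  expect_lt(abs(mean(vals1) - 0.25), 3 * sqrt(0.25 * 0.75 / length(vals1)))
  vals2 <- unlist(lapply(imps$imputations, function(x) x[, 2]))
  expect_true(all(vals2 == 0))
})

test_that("FCS imputation copies observed donor values only", {
  gen <- generate_dataset(n = 150, n_items = 8, delta = -1, target_rate = 0.2,
                          seed = 69)
  imps <- fcs_impute(gen$data, include_indicators = FALSE, m = 2,
                     n_cycles = 3, seed = 70)
  for (k in 1:2) {
    x <- imps$imputations[[k]]
    expect_true(all(x %in% c(0, 1)))
    obs <- !is.na(gen$data$observed)
    expect_equal(x[obs], as.numeric(gen$data$observed[obs]))
  }
  imps2 <- fcs_impute(gen$data, include_indicators = TRUE, m = 1,
                      n_cycles = 3, seed = 71)
  expect_true(all(imps2$imputations[[1]] %in% c(0, 1)))

  # no missing anywhere: output equals input
  full <- response_data(gen$complete)
  expect_identical(fcs_impute(full, m = 2, seed = 72)$imputations[[1]],
                   gen$complete)
})

test_that("a duplicated predictor column drives PMM imputations", {
  set.seed(73)
  n <- 300
  base <- rbinom(n, 1, 0.5)
  x <- cbind(v1 = base, v2 = base, v3 = rbinom(n, 1, 0.5),
             v4 = rbinom(n, 1, 0.5))
  x[sample(n, 60), 1] <- NA  # v1 missing but exactly duplicated by v2
  d <- response_data(x)
  imps <- fcs_impute(d, m = 1, n_cycles = 5, n_pls_factors = 3, seed = 74)
  filled <- imps$imputations[[1]]
  agree <- mean(filled[is.na(x[, 1]), 1] == filled[is.na(x[, 1]), 2])
  expect_gte(agree, 0.95)
})

test_that("stacking reproduces the direct fit when nothing is imputed", {
  gen <- generate_dataset(n = 200, n_items = 6, seed = 75, target_rate = 0.1)
  full <- response_data(gen$complete)
  imps <- structure(list(imputations = list(gen$complete), source = "none",
                         m = 1, seed = 1), class = "imputation_set")
  f_stack <- stack_and_scale(imps)
  f_direct <- fit_2pl(gen$complete)
  expect_equal(f_stack$a, f_direct$a, tolerance = 1e-12)
  expect_equal(f_stack$b, f_direct$b, tolerance = 1e-12)
  # stacked person count
  imps5 <- impute_partial_guess(gen$data, gen$bank, m = 5, seed = 76)
  expect_equal(nrow(do.call(rbind, imps5$imputations)), 5 * 200)
})
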