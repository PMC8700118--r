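test_that("the default quadrature grid has 21 points on [-5, 5]", {
  g <- quadrature_grid()
  expect_length(g$points, 21)
  expect_equal(range(g$points), c(-5, 5))
  expect_equal(sum(g$prior_weights), 1)
  expect_true(all(diff(g$points) > 0))
})

test_that("EM log-likelihood is monotone and beats a brute-force grid", {
  set.seed(31)
  gen <- generate_dataset(n = 50, n_items = 2, delta = 0, target_rate = 0.1,
                          seed = 32, difficulty_range = c(-0.5, 0.5))
  x <- score_as_wrong(gen$data)
  fit <- fit_2pl(x)
  expect_true(all(diff(fit$ll_trace) >= -1e-8))

  g <- quadrature_grid()
  # oracle marginal likelihood at the EM solution matches the reported value
  expect_equal(fit$loglik,
               oracle_ll_2pl(x, fit$a, fit$b, g$points, g$prior_weights),
               tolerance = 1e-10)
  # EM solution beats a grid search over each item's (a, b)
  a_grid <- seq(0.3, 3, length.out = 25)
  b_grid <- seq(-2, 2, length.out = 25)
  for (item in 1:2) {
    for (a_try in a_grid) {
      lls <- vapply(b_grid, function(b_try) {
        a_vec <- fit$a; b_vec <- fit$b
        a_vec[item] <- a_try; b_vec[item] <- b_try
        oracle_ll_2pl(x, a_vec, b_vec, g$points, g$prior_weights)
      }, numeric(1))
      expect_lte(max(lls), fit$loglik + 1e-6)
    }
  }
})

test_that("item parameters are recovered from their own model", {
  bank <- make_item_bank(10, c(-1.5, 1.5))
  lat <- draw_latents(5000, 0, seed = 33)
  x <- simulate_complete(lat, bank, seed = 34)
  fit <- fit_2pl(x)
  expect_lt(max(abs(fit$b - bank$b)), 0.15)
  expect_lt(max(abs(fit$a - bank$a)), 0.2)
  expect_true(fit$converged)
})

test_that("missing entries contribute nothing to the likelihood", {
  x <- rbind(c(1, 0, NA), c(NA, 1, 0), c(1, NA, 1), c(0, 0, 0),
             c(1, 1, NA), c(0, NA, 1))
  fit <- fit_2pl(x)
  g <- fit$grid
  expect_equal(fit$loglik,
               oracle_ll_2pl(x, fit$a, fit$b, g$points, g$prior_weights),
               tolerance = 1e-10)
})

test_that("fractional scoring approximates stacked Bernoulli imputations", {
  # the pseudo-likelihood with fractional cells and the stacked-imputation
  # fit are alternative implementations of partially correct scoring; for
  # the 2PL they agree approximately, and increasingly so as the missing
  # share shrinks (a fractional cell's likelihood term is not exactly the
  # mixture over imputed values)
  gap <- function(rate) {
    gen <- generate_dataset(n = 2000, n_items = 8, delta = 0,
                            target_rate = rate, seed = 35)
    bank <- gen$bank
    bank$format <- "MC"; bank$n_options <- 4L
    frac_fit <- fit_2pl(score_partially_correct(gen$data, bank))
    imps <- impute_partial_guess(gen$data, bank, m = 80, seed = 36)
    stack_fit <- stack_and_scale(imps)
    list(par = max(abs(frac_fit$b - stack_fit$b),
                   abs(frac_fit$a - stack_fit$a)),
         linked = max(abs(link_to_truth(frac_fit, gen$bank) -
                            link_to_truth(stack_fit, gen$bank))))
  }
  lo <- gap(0.05); hi <- gap(0.20)
  expect_lt(lo$linked, 0.05)   # population summaries agree closely at 5%
  expect_lt(lo$par, hi$par)    # agreement improves as missingness shrinks
  expect_lt(lo$par, 0.2)
})

test_that("person posteriors normalize and respond to evidence", {
  gen <- generate_dataset(n = 200, n_items = 5, seed = 37, target_rate = 0.1)
  fit <- fit_2pl(score_as_wrong(gen$data))
  prior <- fit$grid$prior_weights
  expect_equal(person_posterior(fit, rep(NA, 5)), prior)
  post <- person_posterior(fit, c(1, NA, NA, NA, NA))
  expect_equal(sum(post), 1, tolerance = 1e-12)
  expect_gt(sum(post * fit$grid$points), sum(prior * fit$grid$points))
  # posterior matrix rows sum to 1
  expect_equal(rowSums(fit$posterior), rep(1, 200), tolerance = 1e-9)
})

test_that("weights only matter up to scale", {
  gen <- generate_dataset(n = 300, n_items = 6, seed = 38, target_rate = 0.1)
  x <- score_as_wrong(gen$data)
  w <- runif(300, 0.5, 2)
  f1 <- fit_2pl(x, weights = w)
  f2 <- fit_2pl(x, weights = 10 * w)
  expect_equal(f1$a, f2$a, tolerance = 1e-8)
  expect_equal(f1$b, f2$b, tolerance = 1e-8)
})

test_that("the latent background model recovers a generating regression", {
  set.seed(39)
  n <- 4000
  z <- rnorm(n)
  theta <- 0.5 * z + rnorm(n, 0, sqrt(0.75))  # marginal SD(theta) = 1
  bank <- make_item_bank(12, c(-1.5, 1.5))
  x <- simulate_complete(list(theta = theta, xi = theta), bank, seed = 40)
  fit <- fit_2pl_latent_regression(x, z)
  expect_lt(abs(fit$gamma1 - 0.5), 0.06)
  expect_lt(abs(fit$sigma_e - sqrt(0.75)), 0.06)

  # independent covariate: gamma1 near zero
  fit0 <- fit_2pl_latent_regression(x, rnorm(n))
  expect_lt(abs(fit0$gamma1), 0.06)

  # constant covariate: falls back to the plain fit
  expect_message(fitc <- fit_2pl_latent_regression(x, rep(1, n)), "constant")
  plain <- fit_2pl(x)
  expect_equal(fitc$a, plain$a, tolerance = 1e-10)
})

test_that("degenerate items are bounded with a warning", {
  x <- cbind(rep(1, 40), rbinom(40, 1, 0.5), rbinom(40, 1, 0.6))
  expect_warning(fit <- fit_2pl(x), "all-equal")
  expect_true(all(fit$a >= 0.05 & fit$a <= 8))
  expect_true(all(fit$b >= -8 & fit$b <= 8))
})
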