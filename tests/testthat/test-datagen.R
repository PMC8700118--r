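test_that("item banks have equidistant difficulties with endpoints included", {
  bank <- make_item_bank(20)
  expect_equal(round(bank$b[1:3], 3), c(-2.000, -1.789, -1.579))
  expect_equal(make_item_bank(2)$b, c(-2, 2))
  expect_equal(make_item_bank(5)$b, c(-2, -1, 0, 1, 2))
  expect_true(all(bank$a == 1))
  expect_error(make_item_bank(1), "at least 2")
  expect_error(make_item_bank(4, format = "MC"), "n_options")
})

test_that("latent draws match the requested moments", {
  ind <- draw_latents(1e5, correlation = 0, seed = 1)
  expect_lt(abs(cor(ind$theta, ind$xi)), 3 / sqrt(1e5))
  dep <- draw_latents(4e5, correlation = 0.5, seed = 2)
  expect_lt(abs(cor(dep$theta, dep$xi) - 0.5), 0.008)
  expect_lt(abs(sd(dep$xi) - 1), 3 / sqrt(2 * 4e5))
  expect_lt(abs(sd(dep$theta) - 1), 3 / sqrt(2 * 4e5))
  expect_error(draw_latents(10, correlation = 1), "correlation")
})

test_that("complete responses follow the logistic response function", {
  bank <- make_item_bank(2, c(0, 0))  # both items at b = 0
  lat <- list(theta = rep(0, 4e4), xi = rep(0, 4e4))
  x <- simulate_complete(lat, bank, seed = 3)
  expect_lt(abs(mean(x) - 0.5), 3 * sqrt(0.25 / length(x)))
  lat2 <- list(theta = rep(2, 4e4), xi = rep(0, 4e4))
  x2 <- simulate_complete(lat2, bank, seed = 4)
  expect_lt(abs(mean(x2) - psi(2)), 3 * sqrt(psi(2) * (1 - psi(2)) / length(x2)))
})

test_that("response indicators follow the Mislevy-Wu mechanism", {
  bank <- make_item_bank(4, c(0, 0))
  n <- 3e4
  lat <- list(theta = rnorm(n), xi = rep(0, n))  # fix xi to isolate delta
  x <- simulate_complete(lat, bank, seed = 5)

  bank$beta <- 0; bank$delta <- 0
  r <- simulate_indicators(x, lat, bank, seed = 6)
  rate1 <- mean(r[x == 1] == 0); rate0 <- mean(r[x == 0] == 0)
  expect_lt(abs(rate1 - rate0), 0.02)  # delta = 0 removes X-dependence

  bank$delta <- -10
  r <- simulate_indicators(x, lat, bank, seed = 7)
  expect_lt(mean(r[x == 1] == 0), 1e-3)  # correct responses always delivered
  expect_gt(mean(r[x == 0] == 0), 0.45)  # psi(0) = 0.5 for wrong responses
})

test_that("beta calibration hits the target missing rate", {
  bank <- make_item_bank(20)
  # monotonicity of the quadrature expectation in beta
  rates <- vapply(c(-4, -2, 0, 2), expected_missing_rate, numeric(1),
                  delta = -2, correlation = 0.5, bank = bank)
  expect_true(all(diff(rates) > 0))

  expect_lt(calibrate_beta(0, 0.001, 0.5, bank), -5)

  beta <- calibrate_beta(0, 0.10, 0.5, bank)
  lat <- draw_latents(5e4, 0.5, seed = 8)
  miss <- 1 - psi(lat$xi - beta)  # delta = 0: rate independent of the items
  expect_lt(abs(mean(miss) - 0.10), 0.002)

  expect_error(calibrate_beta(0, 1.5, 0.5, bank), "target_rate")
})

test_that("generated datasets are reproducible with the design shape", {
  gen <- generate_dataset(n = 400, n_items = 20, delta = -1,
                          target_rate = 0.10, seed = 9)
  gen2 <- generate_dataset(n = 400, n_items = 20, delta = -1,
                           target_rate = 0.10, seed = 9)
  expect_identical(gen$data$observed, gen2$data$observed)
  expect_equal(dim(gen$data$observed), c(400, 20))
  # realized rate within 3 binomial SE plus slack for person clustering
  expect_lt(abs(mean(is.na(gen$data$observed)) - 0.10), 0.03)
  # indicators consistent with mask
  expect_true(all((gen$data$indicators == 0) == is.na(gen$data$observed)))
})

test_that("delta = -10 missingness comes from incorrect responses only", {
  gen <- generate_dataset(n = 2000, delta = -10, target_rate = 0.3, seed = 10)
  miss <- is.na(gen$data$observed)
  expect_gte(mean(gen$complete[miss] == 0), 0.999)
})

test_that("response matrices round-trip through CSV", {
  gen <- generate_dataset(n = 20, n_items = 5, seed = 11)
  path <- tempfile(fileext = ".csv")
  write_response_matrix(gen$data$observed, path)
  back <- read_response_matrix(path)
  expect_equal(unname(back), unname(gen$data$observed))
  expect_equal(colnames(back), colnames(gen$data$observed))
})
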