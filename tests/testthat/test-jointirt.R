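test_that("three-category recoding is a bijection on administered cells", {
  d <- tiny_data()
  v <- to_three_category(d)
  expect_equal(unname(v[1, ]), c(1L, 0L, 1L, 1L))
  expect_equal(unname(v[2, ]), c(1L, 2L, 0L, 2L))
  adm <- matrix(1L, 4, 4); adm[1, 4] <- 0L
  d2 <- response_data(d$observed, administered = adm)
  expect_true(is.na(to_three_category(d2)[1, 4]))
})

test_that("category probabilities sum to one everywhere", {
  set.seed(51)
  for (k in 1:20) {
    p <- joint_category_probs(a = runif(1, 0.3, 3), b = rnorm(1),
                              beta = rnorm(1, 0, 2), delta = runif(1, -10, 3),
                              theta = seq(-5, 5, length.out = 21),
                              xi = seq(-5, 5, length.out = 21))
    expect_equal(unname(rowSums(p)), rep(1, 21), tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
})

test_that("parameter counts follow the registry", {
  expect_equal(n_parameters("MO1", 20), 61L)
  expect_equal(n_parameters("MO2", 20), 62L)
  expect_equal(n_parameters("MM1", 20), 63L)
  expect_equal(n_parameters("MW", 20), 62L)
  expect_equal(n_parameters("MM2", 20, formats = rep(c("CR", "MC"), 10)), 64L)
})

test_that("the model registry maps labels to recipes", {
  expect_equal(model_registry("UW")$scoring, "wrong_all")
  expect_equal(model_registry("UW")$strategy, "scoring")
  expect_equal(model_registry("MM2")$joint, "MM2")
  expect_equal(model_registry("IW")$joint, "MW")
  expect_equal(model_registry("IF2")$include_indicators, TRUE)
  expect_equal(model_registry("UO")$scoring, "ignore")
  expect_error(model_registry("XX"), "unknown")
})

test_that("joint-model likelihood matches a brute-force double sum", {
  obs <- rbind(c(1L, 0L, NA), c(0L, NA, 1L), c(1L, 1L, 1L), c(NA, 0L, 0L))
  d <- response_data(obs)
  for (label in c("MO2", "MM1", "MW")) {
    fit <- fit_joint(d, label, max_iter = 50)
    v <- to_three_category(d)
    expect_equal(fit$loglik,
                 oracle_ll_joint(v, fit$a, fit$b, fit$beta, fit$delta,
                                 fit$grid$points, fit$sd_xi, fit$correlation),
                 tolerance = 1e-8)
  }
})

test_that("nested joint models order their likelihoods", {
  gen <- generate_dataset(n = 400, n_items = 8, delta = -2,
                          target_rate = 0.2, seed = 52)
  f_mo1 <- fit_joint(gen$data, "MO1")
  f_mo2 <- fit_joint(gen$data, "MO2")
  f_mm1 <- fit_joint(gen$data, "MM1")
  expect_gte(f_mo2$loglik, f_mo1$loglik - 1e-4)
  expect_gte(f_mm1$loglik, f_mo2$loglik - 1e-4)
})

test_that("MO1 factorizes into the ignore-missing 2PL", {
  gen <- generate_dataset(n = 600, n_items = 8, delta = 0, target_rate = 0.15,
                          seed = 53)
  f_mo1 <- fit_joint(gen$data, "MO1", conv_par = 1e-5)
  f_uo <- fit_2pl(gen$data$observed, conv_par = 1e-5)
  expect_lt(max(abs(f_mo1$a - f_uo$a)), 0.02)
  expect_lt(max(abs(f_mo1$b - f_uo$b)), 0.02)
})

test_that("MW matches the wrong-scored 2PL on delta = -10 data", {
  gen <- generate_dataset(n = 800, n_items = 8, delta = -10,
                          target_rate = 0.2, seed = 54)
  f_mw <- fit_joint(gen$data, "MW")
  f_uw <- fit_2pl(score_as_wrong(gen$data))
  expect_lt(max(abs(f_mw$b - f_uw$b)), 0.1)
  expect_lt(max(abs(f_mw$a - f_uw$a)), 0.15)
  expect_true(all(f_mw$delta == -10))
})

test_that("MM1 recovers its generating parameters on one large dataset", {
  gen <- generate_dataset(n = 6000, delta = -2, target_rate = 0.15, seed = 55)
  fit <- fit_joint(gen$data, "MM1")
  expect_lt(abs(fit$delta[1] - (-2)), 0.5)
  expect_lt(abs(fit$correlation - 0.5), 0.1)
  expect_lt(abs(fit$sd_xi - 1), 0.12)
  lk <- link_to_truth(fit, gen$bank)
  expect_lt(abs(lk["mean"]), 0.08)
  expect_lt(abs(lk["sd"] - 1), 0.08)
})

test_that("MM2 degenerates to MM1 with a single format", {
  gen <- generate_dataset(n = 300, n_items = 6, delta = -1,
                          target_rate = 0.15, seed = 56)
  expect_message(fit <- fit_joint(gen$data, "MM2", formats = rep("CR", 6)),
                 "single item format")
  expect_equal(length(unique(fit$delta)), 1L)
})
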