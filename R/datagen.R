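#' Draw latent ability and response propensity
#'
#' Samples `(theta, xi)` from a bivariate normal distribution with
#' `Var(theta) = 1`, `SD(xi) = sd_xi`, mean zero and the given correlation.
#' `theta` drives correctness of item responses, `xi` the tendency to respond
#' at all.
#'
#' @param n Number of persons.
#' @param correlation Correlation between ability and response propensity,
#'   strictly inside (-1, 1).
#' @param sd_xi Standard deviation of the response propensity.
#' @param seed Optional integer seed for this draw.
#' @return A list with numeric vectors `theta` and `xi`.
#' @export
draw_latents <- function(n, correlation, sd_xi = 1, seed = NULL) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (abs(correlation) >= 1) stop("|correlation| must be < 1", call. = FALSE)
  if (sd_xi <= 0) stop("sd_xi must be positive", call. = FALSE)
  draw <- function() {
    theta <- stats::rnorm(n)
    xi <- sd_xi * (correlation * theta +
                     sqrt(1 - correlation^2) * stats::rnorm(n))
    list(theta = theta, xi = xi)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate complete item responses from the 2PL model
#'
#' Each cell is Bernoulli with success probability
#' `psi(a_i * (theta_p - b_i))`; items are conditionally independent given
#' ability.
#'
#' @param latents Latent draws from [draw_latents()].
#' @param bank An [make_item_bank()] item bank.
#' @param seed Optional integer seed.
#' @return A persons x items 0/1 matrix with item ids as column names.
#' @export
simulate_complete <- function(latents, bank, seed = NULL) {
  stopifnot(all(is.finite(bank$a)), all(is.finite(bank$b)))
  draw <- function() {
    p <- psi(outer(latents$theta, seq_len(nrow(bank)),
                   function(th, i) bank$a[i] * (th - bank$b[i])))
    x <- matrix(as.integer(stats::runif(length(p)) < p), nrow(p), ncol(p))
    colnames(x) <- bank$item_id
    x
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate response indicators from the Mislevy-Wu mechanism
#'
#' The probability of responding to item i is
#' `psi(xi_p - beta_i - delta_i * X_pi)`, so a negative `delta` makes correct
#' responses more likely to be delivered; `delta = 0` gives latent
#' ignorability, and `delta = -10` effectively restricts omissions to
#' incorrectly solved items.
#'
#' @param complete_x Complete 0/1 response matrix (no missing cells).
#' @param latents Latent draws matching the rows of `complete_x`.
#' @param bank Item bank supplying `beta` and `delta`.
#' @param seed Optional integer seed.
#' @return A persons x items 0/1 indicator matrix (1 = observed).
#' @export
simulate_indicators <- function(complete_x, latents, bank, seed = NULL) {
  if (anyNA(complete_x)) stop("complete_x must have no missing cells", call. = FALSE)
  draw <- function() {
    eta <- outer(latents$xi, bank$beta, "-") -
      sweep(complete_x, 2, bank$delta, "*")
    r <- matrix(as.integer(stats::runif(length(eta)) < psi(eta)),
                nrow(eta), ncol(eta))
    colnames(r) <- bank$item_id
    r
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Expected missing proportion under the Mislevy-Wu mechanism
#'
#' Computes, by two-dimensional Gauss-Hermite quadrature over the bivariate
#' normal `(theta, xi)`, the expected proportion of missing responses
#' averaged over the item bank:
#' `(1/I) * sum_i E[1 - psi(xi - beta)*(1 - P_i(theta))
#'                    - psi(xi - beta - delta)*P_i(theta)]`.
#'
#' @param beta Common missingness intercept.
#' @param delta Common missingness shift.
#' @param correlation Correlation between ability and response propensity.
#' @param bank Item bank (supplies `a`, `b`).
#' @param sd_xi SD of the response propensity.
#' @param n_points Gauss-Hermite points per dimension.
#' @return Expected missing proportion in (0, 1).
#' @export
expected_missing_rate <- function(beta, delta, correlation, bank,
                                  sd_xi = 1, n_points = 41) {
  q <- gh_bivariate(n_points, correlation, sd_xi)
  p_resp_wrong <- psi(q$xi - beta)          # response prob when X = 0
  p_resp_right <- psi(q$xi - beta - delta)  # response prob when X = 1
  rate <- 0
  for (i in seq_len(nrow(bank))) {
    p_i <- psi(bank$a[i] * (q$theta - bank$b[i]))
    rate <- rate +
      sum(q$weight * (1 - p_resp_wrong * (1 - p_i) - p_resp_right * p_i))
  }
  rate / nrow(bank)
}

#' Calibrate the common missingness intercept to a target missing rate
#'
#' The expected missing proportion is strictly increasing in `beta`, so the
#' root is found by bisection on `beta` in `[-12, 12]` to a tolerance of
#' 1e-4 on the rate.
#'
#' @inheritParams expected_missing_rate
#' @param target_rate Desired expected missing proportion, in (0, 1).
#' @param tol Tolerance on the achieved rate.
#' @return The calibrated common `beta`.
#' @export
calibrate_beta <- function(delta, target_rate, correlation, bank,
                           sd_xi = 1, tol = 1e-4) {
  if (target_rate <= 0 || target_rate >= 1)
    stop("target_rate must be strictly between 0 and 1", call. = FALSE)
  lo <- -12; hi <- 12
  f <- function(beta)
    expected_missing_rate(beta, delta, correlation, bank, sd_xi) - target_rate
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0 || fhi < 0)
    stop("calibration failure: no root for beta in [-12, 12]", call. = FALSE)
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
  stop("calibration failure: bisection did not converge", call. = FALSE)
}

#' Assemble a response dataset
#'
#' Bundles the observed response matrix (with `NA` marking missing cells),
#' the response-indicator matrix and the administered mask. Cells outside
#' the administered mask are missing by design (multi-matrix booklet
#' designs) and are excluded from all likelihoods.
#'
#' @param observed Persons x items matrix with values 0, 1 or `NA`.
#' @param indicators 0/1 matrix; 0 exactly where an administered response is
#'   missing. Inferred from `observed` when `NULL`.
#' @param administered 0/1 mask; defaults to all ones.
#' @return A list of class `response_data`.
#' @export
response_data <- function(observed, indicators = NULL, administered = NULL) {
  observed <- as.matrix(observed)
  if (is.null(administered))
    administered <- matrix(1L, nrow(observed), ncol(observed))
  if (is.null(indicators))
    indicators <- matrix(as.integer(!is.na(observed)), nrow(observed),
                         ncol(observed))
  bad <- administered == 1L & ((indicators == 0L) != is.na(observed))
  if (any(bad))
    stop("indicators must be 0 exactly where observed is missing", call. = FALSE)
  structure(list(observed = observed, indicators = indicators,
                 administered = administered),
            class = "response_data")
}

#' Generate a dataset from the Mislevy-Wu data-generating process
#'
#' Full pipeline for one simulated dataset under a linear fixed test design:
#' build the item bank, calibrate the common missingness intercept to the
#' target missing rate, draw latents, simulate complete responses and
#' response indicators, and mask unobserved responses. Sub-stream seeds for
#' the latent, response and indicator draws are derived deterministically
#' from the master seed so each component is individually reproducible.
#'
#' @param n Number of persons.
#' @param n_items Number of items.
#' @param delta Common missingness shift.
#' @param target_rate Target expected missing proportion in (0, 1).
#' @param correlation Correlation between ability and response propensity.
#' @param sd_xi SD of the response propensity.
#' @param seed Master integer seed.
#' @param beta Optional pre-calibrated common missingness intercept; when
#'   `NULL` it is calibrated to `target_rate`.
#' @param difficulty_range Interval for equidistant item difficulties.
#' @param discrimination Common generating discrimination.
#' @return A list with elements `data` (a [response_data()]), `complete`
#'   (the unmasked response matrix), `latents`, `bank`, and `truth`
#'   (a provenance record with the generating conditions and seed).
#' @export
generate_dataset <- function(n = 1500, n_items = 20, delta = 0,
                             target_rate = 0.1, correlation = 0.5,
                             sd_xi = 1, seed = 1, beta = NULL,
                             difficulty_range = c(-2, 2),
                             discrimination = 1) {
  bank <- make_item_bank(n_items, difficulty_range, discrimination)
  if (is.null(beta))
    beta <- calibrate_beta(delta, target_rate, correlation, bank, sd_xi)
  bank$beta <- beta
  bank$delta <- delta
  seeds <- derive_seeds(seed, 3L)
  latents <- draw_latents(n, correlation, sd_xi, seed = seeds[1])
  x <- simulate_complete(latents, bank, seed = seeds[2])
  r <- simulate_indicators(x, latents, bank, seed = seeds[3])
  observed <- x
  observed[r == 0L] <- NA_integer_
  truth <- list(mean = 0, sd = 1, correlation = correlation, sd_xi = sd_xi,
                delta = delta, beta = beta, target_missing_rate = target_rate,
                seed = as.integer(seed))
  list(data = response_data(observed, r), complete = x, latents = latents,
       bank = bank, truth = truth)
}

#' Write and read a response matrix as CSV
#'
#' Persons x items CSV with item ids as header and cells 0/1/NA.
#'
#' @param x Response matrix (may contain `NA`).
#' @param path File path.
#' @return `read_response_matrix` returns an integer matrix.
#' @export
write_response_matrix <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
                   na = "NA")
  invisible(path)
}

#' @rdname write_response_matrix
#' @export
read_response_matrix <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}
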