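#' Standard logistic distribution function
#'
#' The item response function of the 2PL model and the response-indicator
#' model are both logistic; `psi()` is used throughout the package.
#'
#' @param x Numeric vector of logits.
#' @return `1 / (1 + exp(-x))`.
#' @export
psi <- function(x) stats::plogis(x)

# Derive reproducible sub-stream seeds from one master seed without
# disturbing the caller's RNG state. Seeds stay below 2^31 - 1.
derive_seeds <- function(master_seed, n, tag = 0L) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(master_seed) + 97L * as.integer(tag)) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# Run an expression under a given seed, restoring the previous RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Bivariate normal Gauss-Hermite quadrature over (theta, xi):
# theta ~ N(0, 1), xi ~ N(0, sd_xi^2), Cor(theta, xi) = correlation.
# Returns nodes (n^2 x 2) and normalized weights.
gh_bivariate <- function(n_points, correlation, sd_xi = 1) {
  gh <- pracma::gaussHermite(n_points)
  z <- sqrt(2) * gh$x
  w <- gh$w / sqrt(pi)
  theta <- rep(z, times = n_points)
  u <- rep(z, each = n_points)
  xi <- sd_xi * (correlation * theta + sqrt(1 - correlation^2) * u)
  weight <- rep(w, times = n_points) * rep(w, each = n_points)
  list(theta = theta, xi = xi, weight = weight / sum(weight))
}
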