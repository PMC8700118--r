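#' Information criteria
#'
#' `AIC = -2 loglik + 2k`, `BIC = -2 loglik + k log(n)` with `n` the number
#' of persons.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of persons.
#' @return Named vector `c(AIC, BIC)`.
#' @export
information_criteria <- function(loglik, k, n) {
  stopifnot(n >= 1, k >= 0)
  c(AIC = -2 * loglik + 2 * k, BIC = -2 * loglik + k * log(n))
}

#' Gilula-Haberman penalty
#'
#' A sample-size-normalized variant of the AIC: `GHP = AIC / (2 * sum I_p)`,
#' where `I_p` counts the person-attributed parameters, i.e.
#' `params_per_item` times the number of items administered to person p
#' (40 for 20 administered 2PL items; 140 for 70). Differences larger than
#' 0.001 between models are conventionally notable.
#'
#' @param aic AIC of the model.
#' @param administered_items_per_person Vector of administered item counts.
#' @param params_per_item Parameters attributed per administered item
#'   (2 for the 2PL; 3 for joint models counting `a`, `b`, `beta`).
#' @return The penalty value.
#' @export
ghp <- function(aic, administered_items_per_person, params_per_item = 2) {
  denom <- 2 * params_per_item * sum(administered_items_per_person)
  if (denom <= 0) stop("GHP undefined: no administered items", call. = FALSE)
  aic / denom
}

#' Compare fitted models by information criteria and GHP
#'
#' @param fits Named list of fitted models (`fit_2pl` / `fit_joint`).
#' @param administered_items_per_person Administered item counts (shared).
#' @param params_per_item Per-model `I_p` convention, recycled.
#' @return Data frame with loglik, k, AIC, BIC, GHP, the GHP difference to
#'   the best model and a `best` flag (minimum BIC).
#' @export
fit_comparison <- function(fits, administered_items_per_person,
                           params_per_item = 2) {
  params_per_item <- rep_len(params_per_item, length(fits))
  rows <- lapply(seq_along(fits), function(k) {
    f <- fits[[k]]
    ic <- information_criteria(f$loglik, f$n_params, f$n_persons)
    data.frame(model = names(fits)[k], loglik = f$loglik, k = f$n_params,
               AIC = ic[["AIC"]], BIC = ic[["BIC"]],
               GHP = ghp(ic[["AIC"]], administered_items_per_person,
                         params_per_item[k]))
  })
  out <- do.call(rbind, rows)
  out$dGHP <- out$GHP - min(out$GHP)
  out$best <- out$BIC == min(out$BIC)
  out
}

#' Balanced repeated replication standard error
#'
#' `SE = sqrt(A * sum_r (est_r - est)^2)` over replicate-weight estimates;
#' the scaling factor `A` is 0.05 in the PISA design with 80 replicates.
#' Applies identically to single means and to between-model mean differences
#' computed per replicate.
#'
#' @param full_estimate Estimate under the base weights.
#' @param replicate_estimates Estimates under the replicate weights.
#' @param A Scaling factor.
#' @return The standard error.
#' @export
brr_se <- function(full_estimate, replicate_estimates, A = 0.05) {
  if (!length(replicate_estimates)) stop("need replicate estimates", call. = FALSE)
  sqrt(A * sum((replicate_estimates - full_estimate)^2))
}

#' Weighted posterior mean of transformed ability
#'
#' The weight-normalized average over persons of the posterior-expected
#' ability on the reporting metric `nu0 + nu1 * theta`; with replicate
#' weights this is the estimate entering [brr_se()]. Numerically equivalent
#' to averaging a large number of plausible values.
#'
#' @param posteriors Persons x grid-points matrix of normalized posteriors.
#' @param grid_points Grid node values.
#' @param weights Person weights.
#' @param transform `c(nu0, nu1)` linear map to the reporting metric.
#' @return The weighted mean.
#' @export
weighted_posterior_mean <- function(posteriors, grid_points,
                                    weights = rep(1, nrow(posteriors)),
                                    transform = c(0, 1)) {
  if (sum(weights) <= 0) stop("zero total weight", call. = FALSE)
  person_means <- as.vector(posteriors %*% (transform[1] + transform[2] *
                                              grid_points))
  sum(weights * person_means) / sum(weights)
}
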