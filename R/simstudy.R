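#' Apply a missing-data treatment to one dataset
#'
#' Executes a [model_registry()] recipe on one generated (or observed)
#' dataset and returns the scaled fit whose item parameters feed the
#' linking step. `CD` requires the complete, unmasked matrix.
#'
#' @param label Treatment label understood by [model_registry()].
#' @param data A [response_data()].
#' @param bank Item bank (formats and option counts for UP/IP/MM2).
#' @param complete Complete response matrix (needed for `"CD"`).
#' @param weights Optional person weights.
#' @param m Number of imputations for imputation-based treatments.
#' @param seed Optional seed for imputation draws.
#' @param start Optional starting values forwarded to [fit_joint()].
#' @param ... Passed to the underlying fitters.
#' @return A `fit_2pl` or `fit_joint` object.
#' @export
fit_treatment <- function(label, data, bank, complete = NULL, weights = NULL,
                          m = 5, seed = NULL, start = NULL, ...) {
  recipe <- model_registry(label)
  if (recipe$strategy == "complete") {
    if (is.null(complete)) stop("CD needs the complete matrix", call. = FALSE)
    return(fit_2pl(complete, weights = weights, ...))
  }
  if (recipe$strategy == "scoring") {
    scored <- switch(recipe$scoring,
                     wrong_all = score_as_wrong(data, "all"),
                     wrong_omitted = score_as_wrong(data, "omitted_only"),
                     partial = score_partially_correct(data, bank),
                     ignore = data$observed)
    if (!is.null(recipe$covariate)) {
      z <- missing_covariates(data, recipe$covariate)
      return(fit_2pl_latent_regression(scored, z, weights = weights, ...))
    }
    return(fit_2pl(scored, weights = weights, ...))
  }
  if (recipe$strategy == "model") {
    return(fit_joint(data, recipe$joint, formats = bank$format,
                     weights = weights, start = start, ...))
  }
  # imputation-based treatments
  imps <- switch(recipe$imputation,
                 model = {
                   src <- fit_joint(data, recipe$joint, formats = bank$format,
                                    weights = weights, start = start, ...)
                   impute_model_based(src, data, m = m, seed = seed)
                 },
                 partial = impute_partial_guess(data, bank, m = m, seed = seed),
                 fcs = fcs_impute(data,
                                  include_indicators = recipe$include_indicators,
                                  m = m, seed = seed))
  stack_and_scale(imps, weights = weights, ...)
}

#' Bias and RMSE of a vector of estimates
#'
#' @param estimates Per-replication estimates.
#' @param truth Generating value.
#' @return Named vector `c(bias, rmse)` with `bias = mean - truth` and
#'   `rmse = sqrt(mean((estimates - truth)^2))`.
#' @export
summarize_estimates <- function(estimates, truth) {
  if (!length(estimates)) stop("no estimates to summarize", call. = FALSE)
  c(bias = mean(estimates) - truth,
    rmse = sqrt(mean((estimates - truth)^2)))
}

#' Jackknife Monte Carlo standard error of a simulation summary
#'
#' Replications are split into `n_zones` zones (round-robin); the summary
#' statistic is recomputed with each zone deleted and the standard error is
#' `sqrt(((G - 1) / G) * sum((s_g - mean(s_g))^2))`.
#'
#' @param values Per-replication inputs of the statistic.
#' @param statistic Function of a value vector, e.g. bias or RMSE.
#' @param n_zones Number of jackknife zones.
#' @return The Monte Carlo standard error.
#' @export
jackknife_mc_se <- function(values, statistic = mean, n_zones = 20) {
  if (n_zones < 2) stop("need at least 2 jackknife zones", call. = FALSE)
  n <- length(values)
  zones <- rep_len(seq_len(n_zones), n)
  used <- sort(unique(zones))
  s_g <- vapply(used, function(g) statistic(values[zones != g]), numeric(1))
  g_n <- length(used)
  sqrt((g_n - 1) / g_n * sum((s_g - mean(s_g))^2))
}

#' Run one cell of the simulation design
#'
#' For each replication: generate a dataset from the Mislevy-Wu process,
#' apply each requested treatment, link the estimated item parameters to the
#' generating truth, and record the linked mean and SD. The common
#' missingness intercept is calibrated once per cell; replication seeds are
#' derived from the master seed so the cell is independently reproducible.
#' A failed fit is recorded and excluded with a count, never silently
#' dropped.
#'
#' @param missing_rate Target missing proportion of the cell.
#' @param delta Common missingness shift of the cell.
#' @param models Character vector of treatment labels (see
#'   [model_registry()]; `"CD"` and `"UO"` are allowed).
#' @param replications Number of replications.
#' @param seed Master integer seed of the cell.
#' @param n,n_items,correlation,sd_xi Design constants.
#' @param m Imputations for imputation-based treatments.
#' @param warm_start Start each replication's joint-model EM from the
#'   previous replication's estimates (the first replication uses the
#'   default multi-start); starting values affect the optimization path,
#'   not the maximum.
#' @param ... Passed to the fitters (e.g. `max_iter`).
#' @return A list with `estimates` (replications x models x c(mean, sd)
#'   array), `params` (per-replication delta, correlation and SD(xi) for
#'   joint models), `n_failed` per model, and the cell settings.
#' @export
run_cell <- function(missing_rate, delta, models, replications = 500,
                     seed = 1, n = 1500, n_items = 20, correlation = 0.5,
                     sd_xi = 1, m = 5, warm_start = TRUE, ...) {
  bank <- make_item_bank(n_items)
  beta <- calibrate_beta(delta, missing_rate, correlation, bank, sd_xi)
  rep_seeds <- derive_seeds(seed, 2L * replications, tag = 23L)
  est <- array(NA_real_, dim = c(replications, length(models), 2),
               dimnames = list(NULL, models, c("mean", "sd")))
  params <- array(NA_real_, dim = c(replications, length(models), 3),
                  dimnames = list(NULL, models,
                                  c("delta", "correlation", "sd_xi")))
  n_failed <- stats::setNames(integer(length(models)), models)
  starts <- stats::setNames(vector("list", length(models)), models)
  for (r in seq_len(replications)) {
    gen <- generate_dataset(n = n, n_items = n_items, delta = delta,
                            target_rate = missing_rate,
                            correlation = correlation, sd_xi = sd_xi,
                            seed = rep_seeds[r], beta = beta)
    for (mdl in models) {
      res <- tryCatch({
        fit <- fit_treatment(mdl, gen$data, gen$bank,
                             complete = gen$complete,
                             seed = rep_seeds[replications + r],
                             start = starts[[mdl]], ...)
        if (inherits(fit, "fit_joint")) {
          if (warm_start)
            starts[[mdl]] <- list(a = fit$a, b = fit$b, beta = fit$beta,
                                  delta = fit$delta, sd_xi = fit$sd_xi,
                                  correlation = fit$correlation)
          params[r, mdl, ] <- c(fit$delta[1], fit$correlation, fit$sd_xi)
        }
        link_to_truth(fit, gen$bank)
      }, error = function(e) {
        warning("replication ", r, ", model ", mdl, " failed: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(res)) {
        n_failed[mdl] <- n_failed[mdl] + 1L
      } else {
        est[r, mdl, ] <- res
      }
    }
  }
  list(estimates = est, params = params, n_failed = n_failed,
       settings = list(missing_rate = missing_rate, delta = delta,
                       models = models, replications = replications,
                       seed = seed, n = n, n_items = n_items,
                       correlation = correlation, sd_xi = sd_xi, beta = beta))
}

#' Summarize one cell into a results table
#'
#' @param cell Output of [run_cell()].
#' @param truth_mean,truth_sd Generating mean and SD.
#' @param n_zones Jackknife zones for Monte Carlo standard errors.
#' @return Data frame with one row per model x target (mean, sd): bias,
#'   RMSE, their jackknife MC standard errors and the effective number of
#'   replications.
#' @export
summarize_cell <- function(cell, truth_mean = 0, truth_sd = 1, n_zones = 20) {
  out <- list()
  for (mdl in dimnames(cell$estimates)[[2]]) {
    for (target in c("mean", "sd")) {
      vals <- cell$estimates[, mdl, target]
      vals <- vals[!is.na(vals)]
      truth <- if (target == "mean") truth_mean else truth_sd
      s <- summarize_estimates(vals, truth)
      out[[length(out) + 1]] <- data.frame(
        missing = cell$settings$missing_rate, delta = cell$settings$delta,
        model = mdl, target = target,
        bias = s[["bias"]], rmse = s[["rmse"]],
        mcse_bias = jackknife_mc_se(vals, function(v) mean(v) - truth,
                                    n_zones),
        mcse_rmse = jackknife_mc_se(vals,
                                    function(v) sqrt(mean((v - truth)^2)),
                                    n_zones),
        n_effective = length(vals))
    }
  }
  do.call(rbind, out)
}

#' Run a full simulation design
#'
#' Crosses missing rates with missingness shifts, runs every cell with
#' [run_cell()] and stacks the summaries into one results table shaped like
#' a bias/RMSE report (cells x models x targets).
#'
#' @param missing_rates Vector of target missing proportions.
#' @param deltas Vector of common missingness shifts.
#' @param models Treatment labels.
#' @param replications Replications per cell.
#' @param seed Master seed; cell seeds are derived from it.
#' @param out_csv Optional path; the table is also written as CSV.
#' @param ... Passed to [run_cell()].
#' @return Results data frame (one row per cell x model x target).
#' @export
run_design <- function(missing_rates = c(0.05, 0.1, 0.2, 0.3),
                       deltas = c(-10, -3, -2, -1, 0),
                       models = c("CD", "MM1", "UW", "UO", "MO2",
                                  "IF1", "IF2"),
                       replications = 500, seed = 1, out_csv = NULL, ...) {
  grid_cells <- expand.grid(missing = missing_rates, delta = deltas)
  cell_seeds <- derive_seeds(seed, nrow(grid_cells), tag = 29L)
  res <- lapply(seq_len(nrow(grid_cells)), function(k) {
    cell <- run_cell(grid_cells$missing[k], grid_cells$delta[k], models,
                     replications, seed = cell_seeds[k], ...)
    summarize_cell(cell)
  })
  res <- do.call(rbind, res)
  if (!is.null(out_csv))
    utils::write.csv(res, out_csv, row.names = FALSE, quote = FALSE)
  res
}
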