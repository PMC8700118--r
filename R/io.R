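#' Serialize a fitted model as JSON
#'
#' Writes the item parameter table and scalar summaries (log-likelihood,
#' parameter count, and for joint fits `SD(xi)` and the latent correlation).
#' Posteriors are not serialized; export them separately if needed.
#'
#' @param fit A `fit_2pl` or `fit_joint`.
#' @param path File path.
#' @export
write_fit_json <- function(fit, path) {
  items <- data.frame(item_id = fit$item_id %||% seq_along(fit$a),
                      a = fit$a, b = fit$b)
  if (inherits(fit, "fit_joint")) {
    items$beta <- fit$beta
    items$delta <- fit$delta
  }
  out <- list(items = items, loglik = fit$loglik, n_params = fit$n_params,
              n_persons = fit$n_persons, converged = fit$converged,
              n_iter = fit$n_iter)
  if (inherits(fit, "fit_joint")) {
    out$sd_xi <- fit$sd_xi
    out$correlation <- fit$correlation
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize the generating-truth record of a dataset as JSON
#'
#' @param truth The `truth` element returned by [generate_dataset()].
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
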