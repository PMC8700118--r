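#' Classify missing cells as omitted or not reached
#'
#' Not-reached responses are the maximal trailing run of consecutive missing
#' cells in a person's administered item sequence (the end of the test);
#' every other missing cell is an omission. Item order is taken to be column
#' order unless `item_order` is supplied.
#'
#' @param data A [response_data()].
#' @param item_order Optional permutation giving booklet item order.
#' @return A persons x items character matrix with entries `"observed"`,
#'   `"omitted"`, `"not_reached"` or `"not_administered"`.
#' @export
classify_not_reached <- function(data, item_order = NULL) {
  obs <- data$observed
  adm <- data$administered
  n <- nrow(obs); I <- ncol(obs)
  if (is.null(item_order)) item_order <- seq_len(I)
  lab <- matrix("observed", n, I, dimnames = dimnames(obs))
  lab[is.na(obs) & adm == 1L] <- "omitted"
  lab[adm == 0L] <- "not_administered"
  for (p in seq_len(n)) {
    seq_i <- item_order[adm[p, item_order] == 1L]
    if (!length(seq_i)) next
    miss <- is.na(obs[p, seq_i])
    if (miss[length(miss)]) {
      run_start <- length(miss)
      while (run_start > 1 && miss[run_start - 1]) run_start <- run_start - 1
      lab[p, seq_i[run_start:length(miss)]] <- "not_reached"
    }
  }
  lab
}

#' Score missing responses as wrong
#'
#' The operational reference treatment: missing responses become 0. With
#' `which = "omitted_only"`, not-reached cells (trailing missing runs) stay
#' missing and are ignored by the scaling model.
#'
#' @param data A [response_data()].
#' @param which `"all"` (score every missing cell) or `"omitted_only"`.
#' @param item_order Optional booklet item order for not-reached detection.
#' @return A persons x items scored matrix with attribute `treatment`.
#' @export
score_as_wrong <- function(data, which = c("all", "omitted_only"),
                           item_order = NULL) {
  which <- match.arg(which)
  x <- data$observed
  if (which == "all") {
    x[is.na(x) & data$administered == 1L] <- 0
  } else {
    lab <- classify_not_reached(data, item_order)
    x[lab == "omitted"] <- 0
  }
  attr(x, "treatment") <- if (which == "all") "UW" else "UN1"
  x
}

#' Score missing responses as partially correct
#'
#' Missing multiple-choice responses are scored as the guessing value
#' `1 / K_i` (a fractional pseudo-response); missing constructed-response
#' cells are scored 0 because they cannot be guessed. Observed cells are
#' unchanged.
#'
#' @param data A [response_data()].
#' @param bank Item bank carrying `format` and `n_options`.
#' @return A persons x items scored matrix with entries in `[0, 1]`.
#' @export
score_partially_correct <- function(data, bank) {
  if (any(bank$format == "MC" & (is.na(bank$n_options) | bank$n_options < 2)))
    stop("MC items require n_options metadata", call. = FALSE)
  x <- data$observed
  fill <- ifelse(bank$format == "MC", 1 / bank$n_options, 0)
  for (i in seq_len(ncol(x))) {
    miss <- is.na(x[, i]) & data$administered[, i] == 1L
    x[miss, i] <- fill[i]
  }
  attr(x, "treatment") <- "UP"
  x
}

#' Per-person missing-proportion covariates
#'
#' Computes `Z_p = 1 - (observed count) / (administered count)` restricted
#' to a missing class: all missing responses (feeding the latent background
#' model of treatment UO2) or only not-reached responses (treatment UN2).
#'
#' @param data A [response_data()].
#' @param which `"all_missing"` or `"not_reached"`.
#' @param item_order Optional booklet item order.
#' @return Numeric vector of proportions in `[0, 1]`.
#' @export
missing_covariates <- function(data, which = c("all_missing", "not_reached"),
                               item_order = NULL) {
  which <- match.arg(which)
  n_adm <- rowSums(data$administered == 1L)
  if (any(n_adm == 0))
    stop("undefined covariate: person with no administered items", call. = FALSE)
  if (which == "all_missing") {
    n_miss <- rowSums(is.na(data$observed) & data$administered == 1L)
  } else {
    lab <- classify_not_reached(data, item_order)
    n_miss <- rowSums(lab == "not_reached")
  }
  n_miss / n_adm
}

#' Write a missing-data classification in long format
#'
#' @param labels Output of [classify_not_reached()].
#' @param path File path for a (person, item, label) CSV.
#' @export
write_classification <- function(labels, path) {
  long <- data.frame(
    person = rep(seq_len(nrow(labels)), times = ncol(labels)),
    item = rep(colnames(labels) %||% as.character(seq_len(ncol(labels))),
               each = nrow(labels)),
    label = as.vector(labels)
  )
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
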