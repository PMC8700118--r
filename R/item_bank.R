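#' Construct an item bank
#'
#' An item bank is a data frame with one row per item, holding the 2PL
#' measurement parameters (discrimination `a`, difficulty `b`), the item
#' format (constructed response `"CR"` or multiple choice `"MC"` with
#' `n_options` alternatives), and the missingness parameters of the
#' Mislevy-Wu response-indicator model (`beta`, `delta`): the probability of
#' responding to item i is `psi(xi - beta_i - delta_i * X)`.
#'
#' @param n_items Number of items (at least 2).
#' @param difficulty_range Closed interval over which difficulties are placed
#'   equidistantly, endpoints included.
#' @param discrimination Common item discrimination (slope), must be positive.
#' @param format Item formats, `"CR"` or `"MC"`, recycled to `n_items`.
#' @param n_options Number of response alternatives for MC items (`NA` for CR).
#' @param beta Missingness intercepts, recycled to `n_items`.
#' @param delta Missingness shifts for a correct response, recycled.
#' @return A data frame of class `item_bank` with columns `item_id`, `a`,
#'   `b`, `format`, `n_options`, `beta`, `delta`.
#' @examples
#' bank <- make_item_bank(20)
#' head(bank$b, 3)  # -2.000 -1.789 -1.579
#' @export
make_item_bank <- function(n_items, difficulty_range = c(-2, 2),
                           discrimination = 1, format = "CR",
                           n_options = NA_integer_, beta = 0, delta = 0) {
  if (n_items < 2) stop("an item bank needs at least 2 items", call. = FALSE)
  if (any(discrimination <= 0)) stop("discriminations must be positive", call. = FALSE)
  if (!all(is.finite(difficulty_range)) || length(difficulty_range) != 2)
    stop("difficulty_range must be a finite interval", call. = FALSE)
  b <- seq(difficulty_range[1], difficulty_range[2], length.out = n_items)
  format <- rep_len(format, n_items)
  if (!all(format %in% c("CR", "MC")))
    stop("item format must be 'CR' or 'MC'", call. = FALSE)
  n_options <- rep_len(as.integer(n_options), n_items)
  if (any(format == "MC" & (is.na(n_options) | n_options < 2)))
    stop("MC items require n_options >= 2", call. = FALSE)
  n_options[format == "CR"] <- NA_integer_
  bank <- data.frame(
    item_id = sprintf("I%03d", seq_len(n_items)),
    a = rep_len(discrimination, n_items),
    b = b,
    format = format,
    n_options = n_options,
    beta = rep_len(beta, n_items),
    delta = rep_len(delta, n_items),
    stringsAsFactors = FALSE
  )
  class(bank) <- c("item_bank", "data.frame")
  bank
}

#' Write and read item metadata
#'
#' Serializes an item bank as plain CSV (columns `item_id`, `format`,
#' `n_options`, `a`, `b`, `beta`, `delta`).
#'
#' @param bank An `item_bank`.
#' @param path File path.
#' @return `read_item_bank` returns an `item_bank`.
#' @export
write_item_bank <- function(bank, path) {
  utils::write.csv(as.data.frame(bank)[, c("item_id", "format", "n_options",
                                           "a", "b", "beta", "delta")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_item_bank
#' @export
read_item_bank <- function(path) {
  bank <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(bank) <- c("item_bank", "data.frame")
  bank
}
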