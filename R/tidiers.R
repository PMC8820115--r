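#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a hypothesis-test result
#'
#' @param x A `lat_test` object.
#' @param ... Unused.
#' @return A one-row tibble with columns `method`, `statistic`, `p_value`,
#'   `n`, `exact`, and any extra components the test carries (e.g. `se` for
#'   kappa, `df` for Kruskal-Wallis).
#' @method tidy lat_test
#' @export
tidy.lat_test <- function(x, ...) {
  base <- tibble::tibble(
    method = x$method,
    statistic = x$statistic,
    p_value = x$p_value,
    n = x$n,
    exact = x$exact
  )
  extra <- x[setdiff(names(x), c(names(base), "po", "pe"))]
  extra <- extra[vapply(extra, function(e) is.numeric(e) && length(e) == 1L, logical(1))]
  if (length(extra)) base <- dplyr::bind_cols(base, tibble::as_tibble(extra))
  base
}

#' @rdname tidy.lat_test
#' @method glance lat_test
#' @export
glance.lat_test <- function(x, ...) tidy.lat_test(x, ...)

# Serialize a lat_test (or NULL marker) to a plain list for JSON reports.
lat_test_record <- function(x) {
  if (is.null(x)) {
    return(list(omitted = TRUE))
  }
  rec <- list(
    method = x$method, statistic = x$statistic, p_value = x$p_value,
    n = x$n, exact = x$exact
  )
  if (!is.null(x$se)) rec$se <- x$se
  if (!is.null(x$percent_agreement)) rec$percent_agreement <- x$percent_agreement
  if (!is.null(x$df)) rec$df <- x$df
  rec
}
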