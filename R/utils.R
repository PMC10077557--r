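#' @importFrom rlang %||% abort warn .data
#' @importFrom stats predict rnorm runif prcomp plogis sd
#' @importFrom utils head
NULL

# clamp a numeric vector to [lower, upper] elementwise
clamp <- function(x, lower, upper) {
  pmin(pmax(x, lower), upper)
}

check_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_scalar_number(x, name)
  if (x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
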