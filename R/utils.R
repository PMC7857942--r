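#' @importFrom rlang %||% .data abort warn
#' @importFrom ggplot2 autoplot
#' @importFrom generics tidy glance
#' @importFrom stats plogis qlogis qnorm pnorm quantile median sd var cor
#'   rnorm runif rbinom rgamma rlnorm complete.cases setNames
NULL

utils::globalVariables(c("clinic", "app", "enrolled"))

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Round half away from zero
#'
#' Fixed-precision rounding that always rounds ties away from zero, the
#' convention used in printed clinical tables (so 56.925 -> 56.93), unlike
#' [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(1109 / 1948 * 100) # 56.93
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Derive a reproducible substream seed from a master seed and a stream name,
# so adding a table to the generator does not perturb existing draws.
# Kept below 2^31 - 1.
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 69621) %% 2147483647)
}

with_substream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  force(code)
}

# quantile type 7 (linear interpolation), the documented quartile convention
quartiles <- function(x) {
  q <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE, na.rm = TRUE)
  tibble::tibble(q1 = q[1], median = q[2], q3 = q[3])
}

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", what), class = "ecohortr_config_error")
  }
  invisible(x)
}
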