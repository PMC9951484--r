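#' @importFrom rlang %||% abort warn .data
#' @importFrom stats median model.matrix p.adjust pt qt rbinom rgamma rlnorm
#'   rnbinom rnorm sd t.test var setNames ks.test
#' @importFrom utils head
NULL

# internal: stop with a classed condition so callers/tests can be precise
stop_decomap <- function(msg, class = "decomap_error", ...) {
  rlang::abort(msg, class = c(class, "decomap_error"), ...)
}

assert_that <- function(ok, msg, class = "decomap_input_error") {
  if (!isTRUE(ok)) stop_decomap(msg, class = class)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

# log-normal parameterized by mean and coefficient of variation
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
}

# gamma noise around a positive mean with given CV; cv = 0 is deterministic
rgamma_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep_len(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}
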