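# Internal helpers shared across modules.

abort_ui <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "utilineq_error"), ...)
}

check_positive_weights <- function(weights, call_name) {
  if (length(weights) == 0L) {
    abort_ui(sprintf("`weights` must be non-empty in %s().", call_name),
             "utilineq_error_domain")
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    abort_ui(sprintf("All weights must be finite and > 0 in %s().", call_name),
             "utilineq_error_domain")
  }
  invisible(weights)
}

# Weighted mean with weights normalised to sum one.
wmean <- function(x, w) sum(w * x) / sum(w)

# Population-style weighted covariance: sum of normalised-weight
# cross-products about the weighted means (no small-sample correction).
wcov <- function(x, y, w) {
  wn <- w / sum(w)
  mx <- sum(wn * x)
  my <- sum(wn * y)
  sum(wn * (x - mx) * (y - my))
}

wvar <- function(x, w) wcov(x, x, w)
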