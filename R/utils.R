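# internal helpers shared across modules

geometric_mean <- function(x) exp(mean(log(x)))

# population variance (divide by n, not n-1): used where a closed-form
# "variance of k group means" is the documented contract
pop_var <- function(x) mean((x - mean(x))^2)

stop_config <- function(field, msg) {
  abort(sprintf("invalid configuration field `%s`: %s", field, msg),
        class = "crossclock_config_error")
}

stop_validation <- function(msg) {
  abort(msg, class = "crossclock_validation_error")
}

check_scalar_number <- function(x, field, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop_config(field, sprintf("must be a single finite number in [%s, %s]", lo, hi))
  }
  invisible(x)
}

check_positive_int <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 || x != round(x)) {
    stop_config(field, "must be a single positive integer")
  }
  invisible(as.integer(x))
}
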