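# Internal validation helpers. All user-facing validation failures signal a
# condition of class "telic_validation_error" so callers can test for them.

stop_invalid <- function(msg, class = "telic_validation_error", ...) {
  abort(msg, class = c(class, "telic_error"), ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_infinite = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number.", name))
  }
  if (!allow_infinite && !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be finite.", name))
  }
  if (x < lower || x > upper) {
    stop_invalid(sprintf("`%s` must be in [%s, %s], got %s.",
                         name, format(lower), format(upper), format(x)))
  }
  as.numeric(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x) ||
      x != trunc(x) || x < lower) {
    stop_invalid(sprintf("`%s` must be an integer >= %d.", name, lower))
  }
  as.integer(x)
}

# Coerce a policy given as a one-row data frame, a length-2 numeric, or a
# list(mu =, sigma =) into a validated one-row tibble.
as_policy <- function(x, name = "policy") {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) {
      stop_invalid(sprintf("`%s` must be a single policy (one row).", name))
    }
    p <- x
  } else if (is.numeric(x) && length(x) == 2L) {
    p <- tibble(mu = x[[1]], sigma = x[[2]])
  } else if (is.list(x) && all(c("mu", "sigma") %in% names(x))) {
    p <- tibble(mu = x$mu, sigma = x$sigma)
  } else {
    stop_invalid(sprintf(
      "`%s` must be a one-row data frame, numeric c(mu, sigma), or list.",
      name))
  }
  validate_policies(p, name = name)
  p[, c("mu", "sigma")]
}

validate_policies <- function(policies, name = "policies") {
  if (!is.data.frame(policies) || !all(c("mu", "sigma") %in% names(policies))) {
    stop_invalid(sprintf(
      "`%s` must be a data frame with columns `mu` and `sigma`.", name))
  }
  if (nrow(policies) == 0L) {
    stop_invalid(sprintf("`%s` must contain at least one policy.", name))
  }
  if (!all(is.finite(policies$mu)) || !all(is.finite(policies$sigma))) {
    stop_invalid(sprintf("`%s`: mu and sigma must be finite.", name))
  }
  if (any(policies$sigma <= 0)) {
    stop_invalid(sprintf("`%s`: sigma must be > 0.", name))
  }
  invisible(policies)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
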