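# Internal helpers shared across modules.

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Truncated-normal draws by inverse-CDF; degenerate sd rejected upstream.
rtnorm <- function(n, mean, sd, lower, upper) {
  stopifnot(sd > 0, lower < upper)
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Action labels: "C"/"D" in tables, 1/0 in the engine.
action_to_int <- function(a) {
  if (is.numeric(a)) {
    if (!all(a %in% c(0, 1))) abort("numeric actions must be 0/1")
    return(as.integer(a))
  }
  out <- ifelse(a == "C", 1L, ifelse(a == "D", 0L, NA_integer_))
  if (anyNA(out)) {
    bad <- unique(a[!a %in% c("C", "D")])
    abort(paste0("unknown action label(s): ", paste(bad, collapse = ", "),
                 " (expected \"C\" or \"D\")"))
  }
  out
}

int_to_action <- function(x) ifelse(x == 1L, "C", "D")

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == round(x) && x >= 0

check_prob <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    abort(paste0(what, " must lie in [0, 1]"))
  invisible(x)
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
child_seeds <- function(n) sample.int(.Machine$integer.max, n)
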