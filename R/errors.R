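# Classed conditions so callers (and the CLI) can distinguish failure modes.

sn_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "streamnet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

param_error  <- function(fmt, ...) sn_stop("streamnet_parameter_error", fmt, ...)
width_error  <- function(fmt, ...) sn_stop("streamnet_width_error", fmt, ...)
index_error  <- function(fmt, ...) sn_stop("streamnet_index_error", fmt, ...)
format_error <- function(fmt, ...) sn_stop("streamnet_format_error", fmt, ...)
parse_error  <- function(fmt, ...) sn_stop("streamnet_parse_error", fmt, ...)
io_error     <- function(fmt, ...) sn_stop("streamnet_io_error", fmt, ...)
usage_error  <- function(fmt, ...) sn_stop("streamnet_usage_error", fmt, ...)

# Node labels and pair indices are kept as doubles so they can exceed 2^31 - 1;
# arithmetic on them is exact only up to 2^53.
MAX_EXACT <- 2^53

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= min
}

check_n <- function(n, min = 1, what = "n") {
  if (!is_count(n, min)) {
    param_error("%s must be an integer >= %d (got %s)", what, min,
                paste(format(n), collapse = ","))
  }
  if (n > MAX_EXACT) {
    param_error("%s exceeds 2^53; node labels would lose integer exactness", what)
  }
  as.double(n)
}

check_prob <- function(p, what = "p") {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    param_error("%s must be a probability in [0, 1]", what)
  }
  as.double(p)
}
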