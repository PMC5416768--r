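# Classed error conditions so callers (and tests) can distinguish contract
# violations from genuine data problems. All conditions inherit from
# "rewirescreen_error".

stop_rs <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "rewirescreen_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != as.integer(x)) {
    stop_rs(sprintf("`%s` must be a single positive integer (got %s)",
                    name, deparse(x)), "rs_invalid_parameter")
  }
  as.integer(x)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_rs(sprintf("`%s` must be a single positive number", name),
            "rs_invalid_parameter")
  }
  as.numeric(x)
}

assert_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_rs("`seed` must be a single integer", "rs_invalid_parameter")
  }
  as.integer(seed)
}
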