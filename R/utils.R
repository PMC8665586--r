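# internal validation helpers

stop_invalid <- function(...) {
  stop(structure(
    class = c("abatn_invalid_parameter", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a single finite number")
  if (strict_lower && x <= lower)
    stop_invalid(name, " must be > ", lower)
  if (!strict_lower && x < lower)
    stop_invalid(name, " must be >= ", lower)
  if (strict_upper && x >= upper)
    stop_invalid(name, " must be < ", upper)
  if (!strict_upper && x > upper)
    stop_invalid(name, " must be <= ", upper)
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_invalid(name, " must be TRUE or FALSE")
  invisible(x)
}

# Derive a reproducible child seed from a master seed and a stream label.
# Keeps results independent across pipeline stages that share one master
# seed, and keeps every derived seed inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 69069 + h * 30011 + 104729) %% 2147483587L)
}
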