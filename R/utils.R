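# internal helpers shared across modules

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-unit child seed from a master seed. Keeps all values
# inside the 32-bit signed range R requires for set.seed().
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 1000003) %% 2147483647)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)

# days between two Date values as an integer
days_between <- function(from, to) as.integer(round(as.numeric(to) - as.numeric(from)))
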