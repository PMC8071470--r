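# Internal helpers shared across modules.

# Deterministic child seed for a named substream, kept inside 32-bit range so
# set.seed() accepts it on every platform.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h) %% .Machine$integer.max)
}

# Locale-independent lexicographic ranks for gene symbols; used as the
# deterministic tie-break when two genes have identical expression.
lex_rank <- function(x) {
  match(x, sort(unique(x), method = "radix"))
}

stop_gsreg <- function(msg, class) {
  abort(msg, class = c(class, "gsreg_error"))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
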