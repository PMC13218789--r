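# Internal helpers shared across modules.

# Unit separator: cannot occur in an allele string read from a delimited file.
.HAP_SEP <- "\x1f"

pgx_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pgxphaser_error", "error")))
}

pgx_parse_error      <- function(msg) pgx_error(msg, "pgx_parse_error")
pgx_validation_error <- function(msg) pgx_error(msg, "pgx_validation_error")
pgx_format_error     <- function(msg) pgx_error(msg, "pgx_format_error")
pgx_config_error     <- function(msg) pgx_error(msg, "pgx_config_error")
pgx_resolution_error <- function(msg) pgx_error(msg, "pgx_resolution_error")

hap_key <- function(h) paste(h, collapse = .HAP_SEP)

# Deterministic (locale-independent) total order on strings: map each string
# to its rank in the radix-sorted unique set.
key_ranks <- function(keys) {
  u <- sort(unique(keys), method = "radix")
  match(keys, u)
}

sort_radix <- function(x) sort(x, method = "radix")

# Run `code` with a private RNG stream; the caller's .Random.seed is restored.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

is_missing_call <- function(x) length(x) == 1L && is.na(x[[1L]])

`%||%` <- function(a, b) if (is.null(a)) b else a
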