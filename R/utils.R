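# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seeds derived from one root seed; kept below 2^31.
derive_seeds <- function(seed, n, salt = 0L) {
  stopifnot(n >= 1L)
  with_seed((as.numeric(seed) + 7919 * as.numeric(salt)) %% 2147483647,
            sample.int(2147483646L, n))
}

# Deterministic integer seed for a character label (e.g. a subject id).
label_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 131 + h) %% 2147483647)
}

stop_domain <- function(...) stop(..., call. = FALSE)
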