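# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL uses (and advances) the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic substream derivation: one global seed plus string labels
# (subject id, stage name, ...) -> a reproducible 31-bit seed.
derive_seed <- function(global_seed, ...) {
  labels <- paste(c(format(global_seed), ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(labels)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

# Round half away from zero (for positive window arithmetic: half up),
# unlike base round()'s round-half-even.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_npu <- function(...) stop(..., call. = FALSE)
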