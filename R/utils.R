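# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed from a master seed and a string tag, so independent
# stages (and independent parent pairs) get decoupled, reproducible streams.
# Kept below 2^31 - 1 to stay a valid R integer seed.
derive_seed <- function(master, ...) {
  tag <- paste(vapply(list(...), paste, character(1), collapse = "\r"),
               collapse = "\r")
  h <- 0
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% 2147483647
  as.integer((as.numeric(master) %% 2147483647 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Comma-separated truncation for error messages.
id_preview <- function(ids, n = 5L) {
  ids <- as.character(ids)
  if (length(ids) > n) {
    paste0(paste(ids[seq_len(n)], collapse = ", "), ", ... (",
           length(ids), " total)")
  } else {
    paste(ids, collapse = ", ")
  }
}
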