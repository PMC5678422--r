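# Deterministic child streams: one root seed per simulation; every
# stage/sample derives its own stream from (seed, string key) so adding a
# sample never perturbs another sample's draws.

.HASH_MOD <- 2147483629  # prime < 2^31

.hash_key <- function(key) {
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% .HASH_MOD
  h
}

#' Derive a reproducible child seed from a root seed and a string key
#'
#' @param seed integer root seed.
#' @param ... character/numeric components identifying the stream
#'   (stage name, sample id, day, ...).
#' @return an integer seed in `[1, 2^31)`.
#' @export
child_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, ""), collapse = "/")
  as.integer(((as.numeric(seed) %% .HASH_MOD) * 48271 + .hash_key(key)) %%
               .HASH_MOD + 1)
}

# Evaluate code under a local RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  set.seed(seed)
  force(code)
}
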