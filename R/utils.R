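# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a per-stage seed from the global run seed
#'
#' One global seed fans out deterministically to every pipeline stage via a
#' polynomial hash of the stage name, so each stage is individually
#' reproducible. Results stay below 2^31.
#'
#' @param seed integer global seed.
#' @param stage stage name, e.g. `"split"`, `"fit"`, `"cnn"`.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}
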