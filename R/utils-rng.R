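#' Derive a reproducible substream seed
#'
#' Hashes a master seed together with an arbitrary set of labels (stage
#' names, sample indices, iteration numbers) into an integer seed, so that
#' every stage of a pipeline run consumes an independent, documented RNG
#' substream while remaining fully reproducible from the single master seed.
#'
#' @param master integer master seed.
#' @param ... labels (coerced to character) identifying the substream.
#' @return an integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "subsample", 5000, 3)
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483587 # large prime < 2^31
  h <- abs(master) %% m
  key <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                      character(1)), collapse = "|")
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% m
  as.integer(h + 1)
}

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
# A NULL seed runs `code` in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}
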