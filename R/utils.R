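# Seed the RNG locally and restore the caller's stream afterwards, so
# generators are reproducible without clobbering user-level randomness.
.seededRNG <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}

# Log-spaced concentration series.
.logSpaced <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))
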