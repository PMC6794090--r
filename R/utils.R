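# Seed plumbing: all generators are pure functions of their seed. with_seed
# evaluates an expression under a local RNG state; derive_seed maps
# (master, index, salt) to a stream seed below 2^31 so per-fly seeds are
# decoupled from cohort size.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

derive_seed <- function(master, index, salt = 0L) {
  m <- 2147483647
  x <- (as.numeric(master) %% m)
  x <- (x * 48271 + as.numeric(index) * 16807 + as.numeric(salt) * 69621) %% m
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
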