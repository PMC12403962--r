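#' @useDynLib sepsubtype, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is restored afterwards so package functions never clobber
# user-level reproducibility.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stream of child seeds from a master seed
#'
#' Every stochastic step in the pipeline consumes a seed derived from the
#' master seed by this one scheme: seed the base RNG with `master + salt` and
#' draw `n` integers uniformly below 2^31. Identical `(master, salt)` always
#' yield the same children, and distinct salts give effectively independent
#' streams.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @param salt integer offset separating independent consumers.
#' @return integer vector of length `n`, each in `[1, 2^31 - 1]`.
#' @export
derive_seeds <- function(master, n, salt = 0L) {
  stopifnot(is.numeric(master), length(master) == 1, n >= 1)
  with_seed((as.integer(master) + as.integer(salt)) %% .Machine$integer.max,
            sample.int(.Machine$integer.max - 1L, n, replace = TRUE))
}

# Population (ddof = 0) standard deviation.
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
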