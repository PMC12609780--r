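# Internal helpers shared across modules.

# round half away from zero at stage boundaries (8-bit image semantics);
# inputs here are always non-negative
roundHalfUp <- function(x) floor(x + 0.5)

# coerce an Angiogram / BinaryMask / matrix to a plain matrix
asPixelMatrix <- function(x) {
  if (is(x, "Angiogram") || is(x, "BinaryMask")) x@pixels else x
}

# BinaryMask (or 0/1, 0/255, logical matrix) -> 0/1 integer matrix
mask01 <- function(x) {
  m <- asPixelMatrix(x)
  out <- matrix(0L, nrow(m), ncol(m))
  out[m != 0] <- 1L
  out
}

# evaluate expr with a private RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards (no hidden global state leaks)
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# md5 of an arbitrary R object, via its serialization (provenance hashes)
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}
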