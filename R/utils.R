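# Internal helpers shared across modules.

# ceiling(f * k) robust to binary-float noise (0.7 * 10 must give 7, not 8)
.ceilFrac <- function(f, k) {
  as.integer(ceiling(f * k - 1e-9))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the current stream untouched.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic per-component substream: adding replicates or stages never
# perturbs earlier draws. Kept strictly below 2^31.
.deriveSeed <- function(seed, stream) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + stream * 16807 + 12345) %%
               2147483647)
}

.trapz <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

.assertScalar01 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single number in [0, 1]", name), call. = FALSE)
  invisible(x)
}

# canonical unordered string pair key
.edgeKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}
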