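#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible sub-seed (kept below 2^31) from a base seed.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 2654435761 + 97 * as.double(k)) %% 2147483629
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}

vnorm <- function(x) sqrt(sum(x^2))

# Rows of `x` normalised to unit length.
unit_rows <- function(x) x / pmax(sqrt(rowSums(x^2)), .Machine$double.eps)
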