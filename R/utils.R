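# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_fraction <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) stopf("`%s` must be a single number in %s%g, %g%s, got %s",
                 name, if (lo_open) "(" else "[", lo, hi,
                 if (hi_open) ")" else "]", paste(format(x), collapse = ", "))
  invisible(x)
}

check_finite <- function(x, name) {
  if (!all(is.finite(x))) stopf("`%s` contains non-finite values", name)
  invisible(x)
}

## Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Row-wise L2 normalization of a matrix; zero rows are left as zeros.
l2_normalize_rows <- function(m) {
  m <- as.matrix(m)
  nrm <- sqrt(rowSums(m^2))
  nz <- nrm > 0
  m[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
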