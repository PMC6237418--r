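# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb
# the user's RNG stream.
with_seed <- function(seed, expr) {
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

# Normalize rows of an n x 2 matrix to unit length; zero rows left untouched
# (callers must handle them).
unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  ok <- nrm > 0
  m[ok, ] <- m[ok, , drop = FALSE] / nrm[ok]
  m
}

unit1 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

# Angle between two unit 2-vectors, in [0, pi].
angle_between <- function(a, b) {
  d <- sum(a * b)
  acos(max(-1, min(1, d)))
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

# Moore-Penrose pseudoinverse via SVD (used for DMD amplitudes).
pinv <- function(m, tol = NULL) {
  s <- svd(m)
  if (is.null(tol)) tol <- max(dim(m)) * .Machine$double.eps * max(s$d, 0)
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * Conj(t(s$u[, keep, drop = FALSE])))
}

# Complex-safe pseudoinverse: base svd() accepts complex input.
cpinv <- function(m, tol = NULL) {
  s <- La.svd(m)
  d <- s$d
  if (is.null(tol)) tol <- max(dim(m)) * .Machine$double.eps * max(d, 0)
  keep <- d > tol
  if (!any(keep)) return(matrix(0 + 0i, ncol(m), nrow(m)))
  # La.svd returns vt (= Conj(t(v)))
  v <- Conj(t(s$vt))
  v[, keep, drop = FALSE] %*%
    ((1 / d[keep]) * Conj(t(s$u[, keep, drop = FALSE])))
}
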