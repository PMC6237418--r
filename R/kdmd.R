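#' Kernel specification for DMD with reproducing kernels
#'
#' @param kind `"gaussian"` (radial basis function
#'   `exp(-||y_i - y_j||^2 / (2 sigma^2))`), `"linear"` (`y_i . y_j`) or
#'   `"polynomial"` (`(y_i . y_j + offset)^degree`).
#' @param bandwidth Gaussian width `sigma` (> 0); if `NULL` it is set per
#'   data set by the median heuristic ([median_bandwidth()]).
#' @param degree,offset polynomial kernel parameters.
#' @return A `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("gaussian", "linear", "polynomial"),
                        bandwidth = NULL, degree = 2, offset = 1) {
  kind <- match.arg(kind)
  if (!is.null(bandwidth)) stopifnot_scalar(bandwidth, "bandwidth", positive = TRUE)
  k <- list(kind = kind, bandwidth = bandwidth, degree = degree,
            offset = offset)
  class(k) <- "kernel_spec"
  k
}

#' Median-heuristic Gaussian bandwidth
#'
#' The bandwidth is the median of the pairwise Euclidean distances between
#' distinct snapshot columns.
#'
#' @param x a [snapshot_sequence()] or a p x tau numeric matrix of
#'   snapshot columns.
#' @return Scalar `sigma > 0`.
#' @export
median_bandwidth <- function(x) {
  m <- if (inherits(x, "snapshot_sequence")) x$values else as.matrix(x)
  d <- stats::dist(t(m))
  d <- d[d > 0]
  if (length(d) == 0) stop("all snapshots identical: zero bandwidth")
  stats::median(d)
}

# Kernel evaluation between snapshot columns of A (p x n) and B (p x m).
kernel_eval <- function(A, B, kernel) {
  switch(kernel$kind,
    linear = crossprod(A, B),
    polynomial = (crossprod(A, B) + kernel$offset)^kernel$degree,
    gaussian = {
      sigma <- kernel$bandwidth
      if (is.null(sigma)) stop("gaussian kernel needs a resolved bandwidth")
      d2 <- outer(colSums(A^2), colSums(B^2), "+") - 2 * crossprod(A, B)
      exp(-pmax(d2, 0) / (2 * sigma^2))
    })
}

# Resolve a kernel's bandwidth on a given data matrix (median heuristic).
resolve_kernel <- function(kernel, m) {
  if (kernel$kind == "gaussian" && is.null(kernel$bandwidth))
    kernel$bandwidth <- median_bandwidth(m)
  kernel
}

# Centering matrix H = I - 1_n (1_n has all entries 1/n).
centering_matrix <- function(n) diag(n) - matrix(1 / n, n, n)

#' Gram matrices for kernel DMD
#'
#' `G_yy[i, j] = k(y_i, y_j)` over the first `tau - 1` snapshots and
#' `G_yy'[i, j] = k(y_i, y_{j+1})`; both are centered on each side with
#' `H = I - 1` of size `tau - 1`.
#'
#' @param seq a [snapshot_sequence()] with `tau >= 3`.
#' @param kernel a [kernel_spec()]; an unset Gaussian bandwidth is resolved
#'   by the median heuristic on the first `tau - 1` snapshots.
#' @return List with `G_yy`, `G_yyp`, centered `G_yy_c`, `G_yyp_c`, the
#'   resolved `kernel`, and `n = tau - 1`.
#' @export
gram_matrices <- function(seq, kernel = kernel_spec("gaussian")) {
  stopifnot(inherits(seq, "snapshot_sequence"))
  Yfull <- seq$values
  tau <- ncol(Yfull)
  if (tau < 3) stop("kernel DMD needs at least 3 snapshots")
  M1 <- Yfull[, -tau, drop = FALSE]
  M2 <- Yfull[, -1, drop = FALSE]
  kernel <- resolve_kernel(kernel, M1)
  G_yy <- kernel_eval(M1, M1, kernel)
  G_yyp <- kernel_eval(M1, M2, kernel)
  if (!all(is.finite(G_yy)) || !all(is.finite(G_yyp)))
    stop("non-finite kernel values")
  H <- centering_matrix(tau - 1)
  list(G_yy = G_yy, G_yyp = G_yyp,
       G_yy_c = H %*% G_yy %*% H, G_yyp_c = H %*% G_yyp %*% H,
       kernel = kernel, n = tau - 1)
}

#' DMD with reproducing kernels
#'
#' Kernel analogue of [fit_dmd()]: the Koopman operator on the RKHS induced
#' by `kernel` is projected onto the leading kernel-PCA directions of the
#' centered Gram matrix. With the truncated eigendecomposition
#' `H G_yy H ~ B S B*` (S positive), the projected operator is
#' `Fhat = S^{-1/2} B* H G_yy' H B S^{-1/2}`, and its eigendecomposition
#' `Fhat = Tmat Lambda Tmat^{-1}` yields the Koopman eigenvalues; the rows
#' `b_j` of `Tmat^{-1}` give the mode coordinates in the kernel-PCA basis.
#' Rows of `Tmat^{-1}` are normalized to unit norm with their first
#' non-negligible entry made real-positive, fixing the arbitrary complex
#' scale.
#'
#' @param seq a [snapshot_sequence()] with `tau >= 3`.
#' @param kernel a [kernel_spec()].
#' @param rank number of kernel-PCA components `p`; default (and cap) the
#'   numerical rank of the centered Gram at relative eigenvalue threshold
#'   1e-12.
#' @return A `kdmd_result`: list with `eigenvalues` (complex), `frequencies`
#'   (Hz), `growth` (1/s), `Tmat`, `Tinv`, `B`, `S` (vector of retained
#'   Gram eigenvalues), `Fhat`, `rank`, `dt`, the resolved `kernel`, the
#'   snapshot matrix `M1` and Gram list `gram`.
#' @export
fit_kdmd <- function(seq, kernel = kernel_spec("gaussian"), rank = NULL) {
  gm <- gram_matrices(seq, kernel)
  eg <- eigen((gm$G_yy_c + t(gm$G_yy_c)) / 2, symmetric = TRUE)
  tol <- 1e-12 * max(eg$values, 0)
  num_rank <- sum(eg$values > tol)
  if (num_rank == 0) stop("centered Gram matrix is numerically zero")
  p <- if (is.null(rank)) num_rank else min(rank, num_rank)
  if (!is.null(rank) && rank > num_rank)
    warning(sprintf("rank %d exceeds Gram numerical rank %d; truncated",
                    rank, num_rank))
  B <- eg$vectors[, seq_len(p), drop = FALSE]
  S <- eg$values[seq_len(p)]
  Sih <- 1 / sqrt(S)
  # Fhat = S^{-1/2} B* H G_yy' H B S^{-1/2}
  Fhat <- (Sih * t(B)) %*% gm$G_yyp_c %*% B %*% diag(Sih, p)
  edec <- eigen(Fhat)
  lambda <- as.complex(edec$values)
  Tmat <- edec$vectors + 0i
  keep <- Mod(lambda) > 1e-12 * max(Mod(lambda))
  if (!all(keep)) {
    lambda <- lambda[keep]
    Tmat <- Tmat[, keep, drop = FALSE]
  }
  Tinv <- if (ncol(Tmat) == nrow(Fhat) && all(keep)) {
    solve(Tmat)
  } else {
    cpinv(Tmat)
  }
  # fix the arbitrary per-mode complex scale: make each row b_j of Tinv
  # unit-norm with real-positive leading entry, compensating on Tmat's
  # columns so Tinv %*% Tmat stays the identity
  for (j in seq_len(nrow(Tinv))) {
    rowj <- Tinv[j, ]
    nrm <- sqrt(sum(Mod(rowj)^2))
    if (nrm > 0) {
      cj <- 1 / nrm
      k <- which(Mod(rowj) > 1e-8 * nrm)[1]
      if (!is.na(k)) cj <- cj * Conj(rowj[k]) / Mod(rowj[k])
      Tinv[j, ] <- rowj * cj
      Tmat[, j] <- Tmat[, j] / cj
    }
  }
  fr <- dmd_frequencies(lambda, seq$dt)
  res <- list(eigenvalues = lambda, frequencies = fr$frequency,
              growth = fr$growth, Tmat = Tmat, Tinv = Tinv, B = B, S = S,
              Fhat = Fhat, rank = p, dt = seq$dt, kernel = gm$kernel,
              M1 = seq$values[, -ncol(seq$values), drop = FALSE], gram = gm)
  class(res) <- "kdmd_result"
  res
}

#' @export
print.kdmd_result <- function(x, ...) {
  cat(sprintf("Kernel DMD (%s): rank %d, %d eigenvalue(s), dt = %.4g s\n",
              x$kernel$kind, x$rank, length(x$eigenvalues), x$dt))
  invisible(x)
}

#' One-step spectral prediction from a kernel DMD fit
#'
#' Predicts the feature-space coordinates of the next snapshot by advancing
#' the current coordinates with the projected Koopman matrix, and reports
#' the mean relative one-step error over the fitted window. With the
#' orthonormal kernel-PCA basis `U = M1 H B S^{-1/2}`, the coordinates of
#' the snapshots and their one-step targets are `Z = U* M1 =
#' S^{-1/2} B* H G_yy` and `Z' = U* M2 = S^{-1/2} B* H G_yy'`; the error
#' compares `Fhat Z` against `Z'`. With the linear kernel this reduces to
#' the one-step error of a rank-limited DMD in the centered-data POD basis.
#'
#' @param result a `kdmd_result`.
#' @return List with `error` (scalar mean relative error) and the matrices
#'   `predicted`, `actual` (p x (tau - 1)).
#' @export
kdmd_one_step_error <- function(result) {
  gm <- result$gram
  Sih <- 1 / sqrt(result$S)
  H <- centering_matrix(gm$n)
  proj <- (Sih * t(result$B)) %*% H
  Z <- proj %*% gm$G_yy    # coords of phi(y_1)..phi(y_{tau-1})
  Zp <- proj %*% gm$G_yyp  # coords of phi(y_2)..phi(y_tau)
  pred <- result$Fhat %*% Z
  denom <- sqrt(mean(Mod(Zp)^2))
  err <- sqrt(mean(Mod(pred - Zp)^2)) / ifelse(denom > 0, denom, 1)
  list(error = err, predicted = pred, actual = Zp)
}
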