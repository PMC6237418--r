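#' Projected (SVD-based) dynamic mode decomposition
#'
#' Fits the best linear one-step propagator to a snapshot sequence and
#' eigendecomposes its projection onto the leading POD (SVD) modes. With
#' `Y = [y_1 .. y_{tau-1}]`, `Y' = [y_2 .. y_tau]` and the reduced SVD
#' `Y = U S V*`, the projected propagator is `Fhat = U* Y' V S^{-1}`; its
#' eigenpairs `(Lambda, W)` give the DMD eigenvalues and the exact modes
#' `Phi = Y' V S^{-1} W Lambda^{-1}`, and the amplitude vector solves
#' `psi = Phi^+ y_1`. Each mode evolves as a single complex exponential
#' `exp(omega_j t)` with `omega_j = log(lambda_j) / dt`.
#'
#' @param seq a [snapshot_sequence()] with `tau >= 3` columns.
#' @param rank SVD truncation rank; default the numerical rank of the
#'   singular spectrum at relative threshold `rank_tol`.
#' @param rank_tol relative singular-value threshold (default 1e-10).
#' @return A `dmd_result`: list with complex `eigenvalues`, `omega`
#'   (continuous exponents, 1/s), `frequencies` (Hz), `growth` (1/s),
#'   `modes` (p x r complex), `amplitudes` (complex r-vector), `rank`, `dt`,
#'   and retained SVD factors `U`, `d`, `V`.
#' @examples
#' A <- diag(c(0.9, 0.5))
#' y <- matrix(0, 2, 30); y[, 1] <- c(1, 2)
#' for (t in 2:30) y[, t] <- A %*% y[, t - 1]
#' fit <- fit_dmd(snapshot_sequence(y, dt = 0.1))
#' sort(Re(fit$eigenvalues))
#' @export
fit_dmd <- function(seq, rank = NULL, rank_tol = 1e-10) {
  stopifnot(inherits(seq, "snapshot_sequence"))
  Yfull <- seq$values
  tau <- ncol(Yfull)
  if (tau < 3) stop("DMD needs at least 3 snapshots")
  Y <- Yfull[, -tau, drop = FALSE]
  Yp <- Yfull[, -1, drop = FALSE]
  sv <- svd(Y)
  num_rank <- sum(sv$d > rank_tol * sv$d[1])
  if (num_rank == 0) stop("snapshot matrix is numerically zero")
  if (is.null(rank)) {
    r <- num_rank
  } else {
    r <- min(rank, min(nrow(Y), ncol(Y)))
    if (r > num_rank) {
      warning(sprintf("requested rank %d exceeds numerical rank %d; truncated",
                      r, num_rank))
      r <- num_rank
    }
  }
  U <- sv$u[, seq_len(r), drop = FALSE]
  d <- sv$d[seq_len(r)]
  V <- sv$v[, seq_len(r), drop = FALSE]
  # Fhat = U* Y' V S^{-1}
  YpVSi <- Yp %*% V %*% diag(1 / d, r)
  Fhat <- crossprod(U, YpVSi)
  eg <- eigen(Fhat)
  lambda <- as.complex(eg$values)
  W <- eg$vectors
  # Phi = Y' V S^{-1} W Lambda^{-1}; zero eigenvalues keep the unscaled column
  zero <- Mod(lambda) < .Machine$double.eps * max(Mod(lambda), 1)
  scl <- ifelse(zero, 1 + 0i, 1 / lambda)
  if (any(zero))
    warning(sprintf("%d zero eigenvalue(s): mode column(s) left unscaled",
                    sum(zero)))
  Phi <- YpVSi %*% W %*% diag(scl, r)
  psi <- as.vector(cpinv(Phi) %*% Yfull[, 1])
  fr <- dmd_frequencies(lambda, seq$dt)
  res <- list(eigenvalues = lambda, omega = log(as.complex(lambda)) / seq$dt,
              frequencies = fr$frequency, growth = fr$growth,
              modes = Phi, amplitudes = psi, rank = r, dt = seq$dt,
              U = U, d = d, V = V, feature_mode = seq$feature_mode)
  class(res) <- "dmd_result"
  res
}

#' @export
print.dmd_result <- function(x, ...) {
  cat(sprintf("DMD: rank %d, dt = %.4g s; |lambda| in [%.3g, %.3g]\n",
              x$rank, x$dt, min(Mod(x$eigenvalues)), max(Mod(x$eigenvalues))))
  invisible(x)
}

#' Temporal frequency and growth rate of DMD eigenvalues
#'
#' The discrete eigenvalue `lambda` maps to a continuous exponent
#' `log(lambda) / dt` whose imaginary part (principal branch) is the
#' angular frequency and whose real part is the growth rate; the temporal
#' frequency in Hz is `Im(log lambda) / (2 pi dt)`. A zero eigenvalue is a
#' fully decayed mode and is reported with `growth = -Inf`, `frequency = 0`.
#'
#' @param lambda complex vector of eigenvalues.
#' @param dt sampling interval, s.
#' @return List with numeric vectors `frequency` (Hz) and `growth` (1/s).
#' @export
dmd_frequencies <- function(lambda, dt) {
  stopifnot_scalar(dt, "dt", positive = TRUE)
  lg <- log(as.complex(lambda))
  f <- Im(lg) / (2 * pi * dt)
  g <- Re(lg) / dt
  zero <- Mod(lambda) == 0
  f[zero] <- 0
  g[zero] <- -Inf
  list(frequency = f, growth = g)
}

#' Reconstruct (or extrapolate) snapshots from a DMD fit
#'
#' `y(t) = sum_j phi_j exp(omega_j t) psi_j`, with `t` in seconds measured
#' from the first fitted snapshot; `t = (k - 1) * dt` reproduces snapshot
#' `k` (exactly, at full rank on linear data).
#'
#' @param result a `dmd_result`.
#' @param t numeric vector of times (s).
#' @return p x length(t) real matrix (imaginary residuals discarded; they
#'   are at round-off level for real input data).
#' @export
dmd_reconstruct <- function(result, t) {
  expo <- exp(outer(result$omega, t))        # r x length(t)
  Re(result$modes %*% (expo * result$amplitudes))
}

#' Temporal DMD spectrum
#'
#' Amplitude of each mode against its temporal frequency. Conjugate pairs
#' (real data) are merged into a single non-negative-frequency entry whose
#' amplitude is the pair sum. By default the amplitude of mode `j` is
#' `|psi_j| * ||phi_j||`; set `measure = "psi"` for `|psi_j|` alone.
#'
#' @param result a `dmd_result`.
#' @param measure `"psi_mode"` (default) or `"psi"`.
#' @return data.frame with columns `frequency` (Hz, >= 0), `amplitude`,
#'   `growth` (1/s), sorted by frequency.
#' @export
temporal_spectrum <- function(result, measure = c("psi_mode", "psi")) {
  measure <- match.arg(measure)
  amp <- switch(measure,
    psi_mode = Mod(result$amplitudes) *
      sqrt(colSums(Mod(result$modes)^2)),
    psi = Mod(result$amplitudes))
  f <- result$frequencies
  keep <- f >= 0
  # fold the amplitude of each negative-frequency conjugate partner onto
  # its non-negative twin
  out_f <- f[keep]
  out_a <- amp[keep]
  neg <- which(!keep)
  if (length(neg) > 0) {
    for (j in neg) {
      k <- which.min(abs(out_f + f[j]))
      out_a[k] <- out_a[k] + amp[j]
    }
  }
  ord <- order(out_f)
  data.frame(frequency = out_f[ord], amplitude = out_a[ord],
             growth = result$growth[keep][ord])
}

#' Band-averaged spatial mode power map
#'
#' Averages the elementwise power `|phi_j|^2` of all DMD modes whose
#' temporal frequency falls in `band`, and reshapes the result to the
#' feature layout (for nearest-sorted distance features: N rows = agents,
#' N-1 columns = neighbor rank, so column 1 is the nearest neighbor).
#'
#' @param result a `dmd_result`.
#' @param band numeric length-2 frequency interval in Hz (inclusive).
#' @param layout integer c(rows, cols) with `rows * cols == p`; default a
#'   single row.
#' @return Matrix of dimension `layout` with the band-mean mode power.
#' @export
spatial_mode_power <- function(result, band, layout = NULL) {
  stopifnot(length(band) == 2, band[1] <= band[2])
  sel <- which(result$frequencies >= band[1] & result$frequencies <= band[2])
  if (length(sel) == 0)
    stop(sprintf("no DMD modes with frequency in [%g, %g] Hz", band[1], band[2]))
  p <- nrow(result$modes)
  pw <- rowMeans(Mod(result$modes[, sel, drop = FALSE])^2)
  if (is.null(layout)) layout <- c(1, p)
  if (prod(layout) != p)
    stop("layout does not match the feature dimension")
  matrix(pw, nrow = layout[1], ncol = layout[2], byrow = TRUE)
}
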