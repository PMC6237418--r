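# Longitudinal and transverse dynamic structure factors of multi-agent
# trajectories, and the Brillouin-style dispersion fit of their peak ridge.

#' Longitudinal and transverse current modes at one wave vector
#'
#' `j_L(q, t) = sum_i (v_i . qhat) exp(i q . r_i)` (signed magnitude along
#' `qhat`) and `j_T(q, t)` the analogue with the component of `v_i`
#' perpendicular to `qhat`.
#'
#' @param traj a `trajectory_ensemble`.
#' @param q numeric length-2 wave vector (1/m), non-zero.
#' @return List with complex length-T vectors `jL`, `jT`.
#' @export
current_modes <- function(traj, q) {
  qn <- sqrt(sum(q^2))
  if (qn == 0) stop("|q| must be non-zero")
  qhat <- q / qn
  qperp <- c(-qhat[2], qhat[1])
  phase <- traj$positions[, , 1] * q[1] + traj$positions[, , 2] * q[2]  # T x N
  ph <- exp(1i * phase)
  vL <- traj$velocities[, , 1] * qhat[1] + traj$velocities[, , 2] * qhat[2]
  vT <- traj$velocities[, , 1] * qperp[1] + traj$velocities[, , 2] * qperp[2]
  if (is.null(dim(ph))) ph <- matrix(ph, nrow = length(traj$times))
  list(jL = rowSums(vL * ph), jT = rowSums(vT * ph))
}

#' Dynamic structure factor spectra
#'
#' For each wavenumber magnitude and each of `n_angles` equally spaced
#' directions, the longitudinal and transverse current series are Fourier
#' transformed in time and `S_a(q, w) = |j_a(q, w)|^2 dt / (2 pi N T)`;
#' spectra are averaged over directions and over trajectories (ensemble
#' trials). Negative-frequency content is folded onto the positive
#' frequency axis, so the reported one-sided spectrum satisfies
#' `sum_w S(q, w) dw = <|j(q, t)|^2> / N` exactly.
#'
#' @param trajectories a `trajectory_ensemble` or a list of them (trials).
#' @param q_values numeric vector of wavenumber magnitudes (1/m).
#' @param n_angles number of equally spaced wave-vector directions
#'   (default 16).
#' @param from optional analysis start time (s); defaults to each run's
#'   `analysis_start` when present.
#' @param window `"none"` (default) or `"hann"` temporal taper.
#' @return A `dsf_result`: list with `q` (1/m), `omega` (rad/s, one-sided),
#'   matrices `S_L`, `S_T` (length(q) x length(omega)), `dt`, `n_frames`.
#' @export
dsf_spectrum <- function(trajectories, q_values, n_angles = 16, from = NULL,
                         window = c("none", "hann")) {
  window <- match.arg(window)
  if (inherits(trajectories, "trajectory_ensemble"))
    trajectories <- list(trajectories)
  stopifnot(length(q_values) >= 1, all(q_values > 0))
  acc_L <- NULL; acc_T <- NULL
  dt <- trajectories[[1]]$dt
  nT <- NULL
  for (traj in trajectories) {
    f0 <- from
    if (is.null(f0)) f0 <- traj$params$analysis_start
    if (is.null(f0)) f0 <- 0
    idx <- which(traj$times >= f0)
    if (length(idx) < 2) stop("fewer than 2 frames in the analysis window")
    sub <- list(dt = traj$dt, times = traj$times[idx],
                positions = traj$positions[idx, , , drop = FALSE],
                velocities = traj$velocities[idx, , , drop = FALSE])
    class(sub) <- "trajectory_ensemble"
    T_ <- length(idx)
    if (is.null(nT)) nT <- T_
    T_ <- min(T_, nT)
    N <- dim(sub$positions)[2]
    w <- if (window == "hann") 0.5 * (1 - cos(2 * pi * (0:(T_ - 1)) / (T_ - 1)))
         else rep(1, T_)
    wnorm <- mean(w^2)
    half <- floor(T_ / 2)
    SL <- matrix(0, length(q_values), half + 1)
    ST <- matrix(0, length(q_values), half + 1)
    angles <- (seq_len(n_angles) - 1) * 2 * pi / n_angles
    for (qi in seq_along(q_values)) {
      for (a in angles) {
        q <- q_values[qi] * c(cos(a), sin(a))
        jm <- current_modes(sub, q)
        for (comp in c("jL", "jT")) {
          j <- jm[[comp]][seq_len(T_)] * w
          J <- stats::fft(j)
          S <- Mod(J)^2 * sub$dt / (2 * pi * N * T_ * wnorm)
          # fold negative-frequency bins (k > T/2, frequency -omega_{T-k})
          # onto their positive twins so all T bins are accounted for
          one <- S[seq_len(half + 1)]
          m_max <- T_ - half - 1
          if (m_max >= 1) {
            mm <- seq_len(m_max)
            one[mm + 1] <- one[mm + 1] + S[T_ - mm + 1]
          }
          if (comp == "jL") SL[qi, ] <- SL[qi, ] + one
          else ST[qi, ] <- ST[qi, ] + one
        }
      }
    }
    SL <- SL / n_angles
    ST <- ST / n_angles
    acc_L <- if (is.null(acc_L)) SL else acc_L + SL
    acc_T <- if (is.null(acc_T)) ST else acc_T + ST
  }
  acc_L <- acc_L / length(trajectories)
  acc_T <- acc_T / length(trajectories)
  omega <- 2 * pi * (0:(floor(nT / 2))) / (nT * dt)
  res <- list(q = q_values, omega = omega, S_L = acc_L, S_T = acc_T,
              dt = dt, n_frames = nT, n_angles = n_angles)
  class(res) <- "dsf_result"
  res
}

#' @export
print.dsf_result <- function(x, ...) {
  cat(sprintf("DSF: %d wavenumbers x %d frequencies (T = %d frames, %d angles)\n",
              length(x$q), length(x$omega), x$n_frames, x$n_angles))
  invisible(x)
}

#' Brillouin-style dispersion fit of the DSF peak ridge
#'
#' Locates `omega_shift(q) = argmax_{omega > 0} S(q, omega)` for every
#' wavenumber and fits the sound-like linear dispersion
#' `omega_shift = c |q|` through the origin by least squares. A peak ridge
#' sitting on the last frequency bin is flagged as possibly aliased.
#'
#' @param dsf a `dsf_result`.
#' @param component `"L"` (default) or `"T"`.
#' @return List with `c` (slope, m/s), `residual` (RMS of the fit, rad/s),
#'   `omega_shift` (rad/s per q), `edge_peak` (logical per q).
#' @export
dispersion_fit <- function(dsf, component = c("L", "T")) {
  component <- match.arg(component)
  S <- if (component == "L") dsf$S_L else dsf$S_T
  pos <- which(dsf$omega > 0)
  if (length(dsf$q) < 2) stop("need at least 2 wavenumbers")
  peak_idx <- apply(S[, pos, drop = FALSE], 1, which.max)
  omega_shift <- dsf$omega[pos][peak_idx]
  edge <- peak_idx == length(pos)
  if (any(edge))
    warning("peak at the frequency-grid edge for some q (possible aliasing)")
  cc <- sum(dsf$q * omega_shift) / sum(dsf$q^2)
  resid <- sqrt(mean((omega_shift - cc * dsf$q)^2))
  list(c = cc, residual = resid, omega_shift = omega_shift, edge_peak = edge)
}
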