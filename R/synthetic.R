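# Seeded fixture generators with analytically known ground truth, used to
# validate every analysis stage without external data.

#' Linear dynamical-system fixture
#'
#' `y_{t+1} = A y_t + noise`; the eigenvalues of `A` are the ground-truth
#' DMD spectrum.
#'
#' @param A p x p matrix.
#' @param y0 initial state (length p).
#' @param tau number of snapshots (>= 3).
#' @param noise_sd i.i.d. Gaussian observation-noise s.d. (default 0).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param dt nominal sampling interval, s.
#' @return A [snapshot_sequence()] with attribute `true_eigenvalues`.
#' @export
linear_fixture <- function(A, y0, tau, noise_sd = 0, seed = 1, dt = 0.1) {
  A <- as.matrix(A)
  p <- nrow(A)
  stopifnot(ncol(A) == p, length(y0) == p, tau >= 3)
  y <- matrix(0, p, tau)
  y[, 1] <- y0
  for (t in 2:tau) y[, t] <- A %*% y[, t - 1]
  if (noise_sd > 0)
    y <- y + with_seed(seed, matrix(stats::rnorm(p * tau, sd = noise_sd), p, tau))
  s <- snapshot_sequence(y, dt = dt, feature_mode = "linear_fixture",
                         provenance = sprintf("seed %d", seed))
  attr(s, "true_eigenvalues") <- eigen(A, only.values = TRUE)$values
  s
}

#' Weakly nonlinear fixture with known Koopman spectrum
#'
#' The discrete-time system `x1 <- lambda * x1; x2 <- mu * x2 + c * x1^2`
#' has a Koopman-invariant subspace spanned by `{x1, x2, x1^2}` on which
#' the operator acts with eigenvalues `{lambda, mu, lambda^2}` — a standard
#' analytically solvable benchmark for Koopman spectral methods. A kernel
#' DMD with a polynomial kernel of degree >= 2 recovers all three
#' eigenvalues.
#'
#' @param lambda,mu linear rates, `|lambda|, |mu| <= 1`.
#' @param cc quadratic coupling strength.
#' @param y0 initial state (length 2).
#' @param tau number of snapshots.
#' @param dt nominal sampling interval, s.
#' @return A [snapshot_sequence()] with attribute `true_eigenvalues`
#'   `c(lambda, mu, lambda^2)`.
#' @export
koopman_oscillator_fixture <- function(lambda = 0.95, mu = 0.5, cc = 1,
                                       y0 = c(1, 0.2), tau = 40, dt = 0.1) {
  stopifnot(abs(lambda) <= 1, abs(mu) <= 1, tau >= 3)
  y <- matrix(0, 2, tau)
  y[, 1] <- y0
  for (t in 2:tau) {
    y[1, t] <- lambda * y[1, t - 1]
    y[2, t] <- mu * y[2, t - 1] + cc * y[1, t - 1]^2
  }
  s <- snapshot_sequence(y, dt = dt, feature_mode = "koopman_oscillator")
  attr(s, "true_eigenvalues") <- c(lambda, mu, lambda^2)
  s
}

#' Ballistic trajectory fixture
#'
#' All agents share one constant velocity; the longitudinal dynamic
#' structure factor then peaks at `omega = |q| * speed` for `q` parallel to
#' the motion, so the fitted dispersion slope equals the speed.
#'
#' @param speed common speed, m/s (0 gives a static fixture).
#' @param heading direction angle, rad.
#' @param n_agents number of agents.
#' @param duration,dt time span and step, s.
#' @param box half-width of the uniform initial-position square, m.
#' @param seed integer seed.
#' @return A `trajectory_ensemble`.
#' @export
ballistic_fixture <- function(speed = 4, heading = 0, n_agents = 16,
                              duration = 10, dt = 0.01, box = 10, seed = 1) {
  stopifnot(speed >= 0)
  n_frames <- round(duration / dt)
  v <- speed * c(cos(heading), sin(heading))
  pos0 <- with_seed(seed, matrix(stats::runif(n_agents * 2, -box, box),
                                 n_agents, 2))
  times <- (seq_len(n_frames) - 1) * dt
  pos <- array(NA_real_, c(n_frames, n_agents, 2))
  vel <- array(NA_real_, c(n_frames, n_agents, 2))
  for (t in seq_len(n_frames)) {
    pos[t, , ] <- sweep(pos0, 2, v * times[t], "+")
    vel[t, , 1] <- v[1]
    vel[t, , 2] <- v[2]
  }
  tr <- list(dt = dt, times = times, positions = pos, velocities = vel,
             params = list(speed = speed, heading = heading,
                           analysis_start = 0, seed = seed),
             seed = seed)
  class(tr) <- "trajectory_ensemble"
  tr
}

# Smooth bounded random path: anchored AR(1)-filtered noise around a fixed
# point, continuous in time. Returns T x 2.
smooth_path <- function(T_, center, sd_move, dt) {
  ar <- exp(-dt / 1.5)  # ~1.5 s correlation time
  innov <- matrix(stats::rnorm(T_ * 2, sd = sd_move * sqrt(1 - ar^2)), T_, 2)
  out <- matrix(0, T_, 2)
  for (t in 2:T_) out[t, ] <- ar * out[t - 1, ] + innov[t, ]
  sweep(out, 2, center, "+")
}

#' Synthetic labeled game segments
#'
#' Generates a balanced two-class set of 5-attacker / 5-defender / ball
#' segments at 25 frames per second with lengths uniform in 3-8 s,
#' emulating tracked ball-game possessions. The class signal lives in the
#' *dynamics of the critical attacker-defender distances*, not in absolute
#' positions: every defender shadows its attacker at a gap whose time
#' course differs by class. In `"score"` segments the ball-handler's and
#' one off-ball attacker's defender gaps carry a slow (~0.5 Hz) oscillation
#' whose amplitude grows through the segment (the defense opening up);
#' in `"no_score"` segments defenders track tightly with small-amplitude
#' fast (~4 Hz) jitter. `class_effect` scales the slow-oscillation
#' amplitude; at 0 both classes are generated identically, so any
#' classifier is at chance. Formation centers and orientations are
#' randomized per segment, so raw Cartesian coordinates vary across
#' segments independently of class.
#'
#' @param m number of segments (>= 10).
#' @param class_effect slow-oscillation amplitude scale (default 1, m).
#' @param seed integer seed.
#' @param frame_rate frames per second (default 25).
#' @return A `segment_set` with balanced labels (within one).
#' @export
game_segment_generator <- function(m = 40, class_effect = 1, seed = 1,
                                   frame_rate = 25) {
  stopifnot(m >= 10, class_effect >= 0)
  with_seed(seed, {
    labels <- rep(c("score", "no_score"), length.out = m)
    segs <- lapply(seq_len(m), function(k) {
      T_ <- round(stats::runif(1, 3, 8) * frame_rate)
      dt <- 1 / frame_rate
      tt <- (seq_len(T_) - 1) * dt
      # formation: 5 attackers around a random center/orientation in the
      # attacking half (court ~ 14 x 15 m)
      center <- c(stats::runif(1, 4, 10), stats::runif(1, -4, 4))
      rot <- stats::runif(1, 0, 2 * pi)
      base_ang <- rot + 2 * pi * (0:4) / 5
      radius <- stats::runif(5, 4, 6)
      att <- array(NA_real_, c(T_, 5, 2))
      for (a in 1:5) {
        anchor <- center + radius[a] * c(cos(base_ang[a]), sin(base_ang[a]))
        att[, a, ] <- smooth_path(T_, anchor, sd_move = 0.4, dt = dt)
      }
      holder <- sample.int(5, 1)
      off_target <- sample(setdiff(1:5, holder), 1)  # off-ball signal carrier
      scored <- labels[k] == "score" && class_effect > 0
      def <- array(NA_real_, c(T_, 5, 2))
      for (a in 1:5) {
        # defender sits between its attacker and the goal (x = 14, y = 0),
        # at a gap g(t) whose dynamics carry the class signal
        phase <- stats::runif(1, 0, 2 * pi)
        if (scored && (a == holder || a == off_target)) {
          g <- 2 + class_effect * (0.3 + 1.2 * tt / max(tt)) *
            sin(2 * pi * 0.5 * tt + phase)
        } else {
          g <- 1.6 + 0.15 * sin(2 * pi * 4 * tt + phase)
        }
        g <- pmax(g, 0.3) + 0.05 * stats::rnorm(T_)
        g <- pmax(g, 0.2)
        goal <- c(14, 0)
        dirv <- sweep(-att[, a, ], 2, goal, "+")    # goal - attacker, T x 2
        nrm <- pmax(sqrt(rowSums(dirv^2)), 1e-6)
        def[, a, ] <- att[, a, ] + dirv / nrm * g
      }
      ball <- att[, holder, ]
      attack_segment(att, def, ball, rep(holder, T_), labels[k],
                     frame_rate = frame_rate, id = sprintf("synth_%03d", k))
    })
    segment_set(segs)
  })
}
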