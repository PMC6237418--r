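#' Parameters for the zonal schooling model
#'
#' Constructs and validates the parameter set of the metric zonal
#' (repulsion / orientation / attraction) schooling model. Each agent moves
#' at a constant individual speed and, at every time step, turns (by at most
#' `beta` radians) toward a desired direction determined by neighbors in
#' three concentric zones: repulsion (`dist < r_r`), orientation
#' (`r_r <= dist < r_o`) and attraction (`r_o <= dist < r_a`). The
#' orientation radius `r_o` is the control parameter that selects the
#' emergent regime: small values give a disordered swarm, intermediate
#' values a rotating torus, large values parallel (aligned) motion.
#'
#' @param n_agents number of agents (>= 2).
#' @param speed nominal constant speed, m/s.
#' @param speed_noise_sd dimensionless s.d. of per-agent speed variation;
#'   each agent's speed is `speed * (1 + speed_noise_sd * z)` with `z`
#'   standard normal, drawn once at initialization and fixed thereafter.
#' @param r_r,r_o,r_a zone radii in meters, `0 < r_r <= r_o <= r_a`.
#' @param beta maximum turning angle per time step, radians, in (0, pi].
#' @param dt integration time step, s.
#' @param boundary_radius radius of the circular arena in meters, or `Inf`
#'   for unbounded motion.
#' @param duration simulated time span, s.
#' @param analysis_start time after which the run is considered
#'   post-transient, s (metadata used by analysis helpers).
#' @param seed integer seed; the run is fully reproducible given the seed.
#'
#' @return An object of class `schooling_params` (a named list).
#' @examples
#' p <- schooling_params(n_agents = 8, duration = 1)
#' p$r_o
#' @export
schooling_params <- function(n_agents = 64, speed = 4, speed_noise_sd = 0.05,
                             r_r = 2, r_o = 10, r_a = 20, beta = 0.01,
                             dt = 0.01, boundary_radius = 25,
                             duration = 40, analysis_start = 10, seed = 1L) {
  stopifnot_scalar(speed, "speed", positive = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(beta, "beta", positive = TRUE)
  if (beta > pi) stop("`beta` must be in (0, pi]", call. = FALSE)
  if (!is.numeric(n_agents) || n_agents < 2)
    stop("`n_agents` must be >= 2", call. = FALSE)
  if (!(r_r > 0 && r_r <= r_o && r_o <= r_a))
    stop("zone radii must satisfy 0 < r_r <= r_o <= r_a", call. = FALSE)
  if (speed_noise_sd < 0) stop("`speed_noise_sd` must be >= 0", call. = FALSE)
  if (!is.numeric(boundary_radius) || boundary_radius <= 0)
    stop("`boundary_radius` must be > 0 (use Inf for unbounded)", call. = FALSE)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  p <- list(n_agents = as.integer(n_agents), speed = speed,
            speed_noise_sd = speed_noise_sd, r_r = r_r, r_o = r_o, r_a = r_a,
            beta = beta, dt = dt, boundary_radius = boundary_radius,
            duration = duration, analysis_start = analysis_start,
            seed = as.integer(seed))
  class(p) <- "schooling_params"
  p
}

#' @export
print.schooling_params <- function(x, ...) {
  cat("Zonal schooling parameters\n")
  cat(sprintf("  N = %d agents, speed %.3g m/s (sd %.3g), dt %.3g s\n",
              x$n_agents, x$speed, x$speed_noise_sd, x$dt))
  cat(sprintf("  zones r_r/r_o/r_a = %.3g/%.3g/%.3g m, beta %.3g rad\n",
              x$r_r, x$r_o, x$r_a, x$beta))
  cat(sprintf("  boundary %s m, duration %.3g s, seed %d\n",
              format(x$boundary_radius), x$duration, x$seed))
  invisible(x)
}

#' Initialize a swarm state
#'
#' Agents are placed uniformly in angle on a circle with radius drawn
#' uniformly in \[6, 16\] m from the arena center, the initial direction of
#' each agent is perpendicular to its position vector (counter-clockwise
#' tangent), and per-agent speeds are drawn once as
#' `speed * (1 + speed_noise_sd * z)`. Uses the current RNG stream; seed it
#' (or call [simulate_school()], which seeds from `params$seed`).
#'
#' @param params a [schooling_params()] object.
#' @return An object of class `swarm_state`: list with `time`, `positions`
#'   (N x 2, m), `directions` (N x 2 unit vectors), `speeds` (length N, m/s).
#' @export
init_state <- function(params) {
  n <- params$n_agents
  radius <- stats::runif(n, 6, 16)
  theta <- stats::runif(n, 0, 2 * pi)
  pos <- cbind(radius * cos(theta), radius * sin(theta))
  # tangential (perpendicular to the position vector), common handedness
  dirs <- cbind(-sin(theta), cos(theta))
  speeds <- params$speed * (1 + params$speed_noise_sd * stats::rnorm(n))
  speeds <- abs(speeds)  # guard against unphysical negative draws
  st <- list(time = 0, positions = pos, directions = dirs, speeds = speeds)
  class(st) <- "swarm_state"
  st
}

#' Desired direction of a single agent (zonal rule)
#'
#' Reference (per-agent) evaluation of the zonal interaction rule. If any
#' neighbor lies in the repulsion zone the desired direction is the
#' normalized sum of unit vectors pointing away from those neighbors and the
#' other zones are ignored. Otherwise the orientation term (normalized sum
#' of neighbor headings in the orientation shell) and the attraction term
#' (normalized sum of unit vectors toward neighbors in the attraction shell)
#' are averaged with weight 1/2 each when both shells are occupied. With no
#' neighbors in any zone the agent keeps its current heading.
#'
#' Coincident agents (zero pairwise distance) are treated as repulsion with
#' a random escape direction drawn from the current RNG stream.
#'
#' @param i agent index (1-based).
#' @param state a `swarm_state`.
#' @param params a [schooling_params()] object.
#' @return A unit 2-vector.
#' @export
desired_direction <- function(i, state, params) {
  pos <- state$positions
  d_i <- state$directions[i, ]
  rel <- sweep(pos, 2, pos[i, ])  # r_j - r_i
  dist <- sqrt(rowSums(rel^2))
  dist[i] <- Inf
  coincident <- which(dist == 0)
  if (length(coincident) > 0) {
    message(sprintf("agent %d coincides with %d neighbor(s); random repulsion",
                    i, length(coincident)))
    ang <- stats::runif(length(coincident), 0, 2 * pi)
    rel[coincident, ] <- cbind(cos(ang), sin(ang))
    dist[coincident] <- 1  # unit displacement stand-in
  }
  rep_idx <- which(dist < params$r_r)
  if (length(rep_idx) > 0) {
    s <- -colSums(rel[rep_idx, , drop = FALSE] / dist[rep_idx])
    if (sum(s^2) == 0) return(d_i)  # perfectly symmetric cancellation
    return(unit1(s))
  }
  ori_idx <- which(dist >= params$r_r & dist < params$r_o)
  att_idx <- which(dist >= params$r_o & dist < params$r_a)
  terms <- list()
  if (length(ori_idx) > 0) {
    s <- colSums(state$directions[ori_idx, , drop = FALSE])
    if (sum(s^2) > 0) terms <- c(terms, list(unit1(s)))
  }
  if (length(att_idx) > 0) {
    s <- colSums(rel[att_idx, , drop = FALSE] / dist[att_idx])
    if (sum(s^2) > 0) terms <- c(terms, list(unit1(s)))
  }
  if (length(terms) == 0) return(d_i)
  v <- Reduce(`+`, terms) / length(terms)
  if (sum(v^2) == 0) return(d_i)
  unit1(v)
}

#' Limit a heading change to a maximum turning angle
#'
#' Returns `d_desired` if the angle between the two unit vectors is at most
#' `beta`; otherwise `d_current` rotated by exactly `beta` toward
#' `d_desired`. For an exactly opposed desired direction (angle pi, side
#' undefined) the rotation is counter-clockwise, so results are
#' deterministic.
#'
#' @param d_current,d_desired unit 2-vectors.
#' @param beta maximum turn, radians.
#' @return A unit 2-vector at angle `min(theta, beta)` from `d_current`.
#' @export
limit_turn <- function(d_current, d_desired, beta) {
  theta <- angle_between(d_current, d_desired)
  if (theta <= beta) return(d_desired)
  cross_z <- d_current[1] * d_desired[2] - d_current[2] * d_desired[1]
  s <- if (cross_z >= 0) 1 else -1
  rot <- matrix(c(cos(beta), s * sin(beta), -s * sin(beta), cos(beta)), 2, 2)
  as.numeric(rot %*% d_current)
}

# Vectorized one-step desired directions for all agents; returns N x 2.
# Mirrors desired_direction() exactly (tested against it).
desired_directions_all <- function(state, params) {
  pos <- state$positions
  dirs <- state$directions
  n <- nrow(pos)
  dx <- outer(rep(1, n), pos[, 1]) - pos[, 1]   # dx[i, j] = x_j - x_i
  dy <- outer(rep(1, n), pos[, 2]) - pos[, 2]
  dist <- sqrt(dx^2 + dy^2)
  diag(dist) <- Inf
  co <- which(dist == 0, arr.ind = TRUE)
  if (nrow(co) > 0) {
    message(sprintf("%d coincident agent pair slot(s); random repulsion",
                    nrow(co)))
    ang <- stats::runif(nrow(co), 0, 2 * pi)
    dx[co] <- cos(ang); dy[co] <- sin(ang); dist[co] <- 1
  }
  ux <- dx / dist; uy <- dy / dist  # unit vectors toward neighbors
  ux[!is.finite(ux)] <- 0; uy[!is.finite(uy)] <- 0
  zr <- dist < params$r_r
  zo <- dist >= params$r_r & dist < params$r_o
  za <- dist >= params$r_o & dist < params$r_a
  out <- dirs
  has_rep <- rowSums(zr) > 0
  if (any(has_rep)) {
    rx <- -rowSums(zr * ux); ry <- -rowSums(zr * uy)
    nr <- sqrt(rx^2 + ry^2)
    ok <- has_rep & nr > 0
    out[ok, ] <- cbind(rx[ok], ry[ok]) / nr[ok]
  }
  free <- !has_rep
  if (any(free)) {
    ox <- zo %*% dirs[, 1]; oy <- zo %*% dirs[, 2]
    no <- sqrt(ox^2 + oy^2)
    ax <- rowSums(za * ux); ay <- rowSums(za * uy)
    na_ <- sqrt(ax^2 + ay^2)
    o_ok <- rowSums(zo) > 0 & no > 0
    a_ok <- rowSums(za) > 0 & na_ > 0
    tx <- ifelse(o_ok, ox / no, 0) + ifelse(a_ok, ax / na_, 0)
    ty <- ifelse(o_ok, oy / no, 0) + ifelse(a_ok, ay / na_, 0)
    k <- o_ok + a_ok
    any_term <- free & k > 0
    nt <- sqrt(tx^2 + ty^2)
    ok <- any_term & nt > 0
    out[ok, ] <- cbind(tx[ok], ty[ok]) / nt[ok]
  }
  out
}

# Vectorized limit_turn over all agents.
limit_turn_all <- function(cur, des, beta) {
  dotp <- pmin(1, pmax(-1, rowSums(cur * des)))
  theta <- acos(dotp)
  turn <- theta > beta
  if (!any(turn)) return(des)
  cz <- cur[, 1] * des[, 2] - cur[, 2] * des[, 1]
  s <- ifelse(cz >= 0, 1, -1)
  cb <- cos(beta); sb <- sin(beta)
  out <- des
  out[turn, 1] <- cb * cur[turn, 1] - s[turn] * sb * cur[turn, 2]
  out[turn, 2] <- s[turn] * sb * cur[turn, 1] + cb * cur[turn, 2]
  out
}

#' Advance a swarm state by one time step
#'
#' Synchronous update: desired directions are computed for every agent from
#' the current state, the turn is limited to `beta`, and positions advance
#' by `speed * dt` along the new heading. In a bounded arena, an agent whose
#' provisional next position would leave the circle has its desired
#' direction replaced by the unit vector toward the origin before the turn
#' limit is applied; should the limited turn still carry it outside, its
#' position is clamped radially to the boundary.
#'
#' @param state a `swarm_state`.
#' @param params a [schooling_params()] object.
#' @return The updated `swarm_state`.
#' @export
step_school <- function(state, params) {
  des <- desired_directions_all(state, params)
  newd <- limit_turn_all(state$directions, des, params$beta)
  newp <- state$positions + state$speeds * newd * params$dt
  rb <- params$boundary_radius
  if (is.finite(rb)) {
    out <- sqrt(rowSums(newp^2)) > rb
    if (any(out)) {
      toward <- -unit_rows(state$positions[out, , drop = FALSE])
      newd[out, ] <- limit_turn_all(state$directions[out, , drop = FALSE],
                                    toward, params$beta)
      newp[out, ] <- state$positions[out, , drop = FALSE] +
        state$speeds[out] * newd[out, , drop = FALSE] * params$dt
      r2 <- sqrt(rowSums(newp[out, , drop = FALSE]^2))
      clamp <- r2 > rb
      if (any(clamp)) {
        idx <- which(out)[clamp]
        newp[idx, ] <- newp[idx, , drop = FALSE] * (rb / r2[clamp])
      }
    }
  }
  st <- list(time = state$time + params$dt, positions = newp,
             directions = newd, speeds = state$speeds)
  class(st) <- "swarm_state"
  st
}

#' Simulate the zonal schooling model
#'
#' Runs the model for `round(duration / dt)` stored frames (the initial
#' state included), fully determined by `params$seed`.
#'
#' @param params a [schooling_params()] object.
#' @return An object of class `trajectory_ensemble`: list with `dt`, `times`
#'   (length T), `positions` (T x N x 2, m), `velocities` (T x N x 2, m/s),
#'   `params`, and `seed`. `velocities[t]` is the velocity that carries
#'   frame `t` to frame `t + 1` (the update turns first, then moves), so
#'   `positions[t+1] = positions[t] + velocities[t] * dt` exactly, except
#'   at rare boundary-clamp events; the last frame repeats its heading.
#' @examples
#' tr <- simulate_school(schooling_params(n_agents = 8, duration = 0.5))
#' dim(tr$positions)
#' @export
simulate_school <- function(params) {
  stopifnot(inherits(params, "schooling_params"))
  n_frames <- round(params$duration / params$dt)
  n <- params$n_agents
  pos <- array(NA_real_, c(n_frames, n, 2))
  vel <- array(NA_real_, c(n_frames, n, 2))
  with_seed(params$seed, {
    st <- init_state(params)
    for (t in seq_len(n_frames)) {
      pos[t, , ] <- st$positions
      if (t < n_frames) st <- step_school(st, params)
      vel[t, , ] <- st$speeds * st$directions
    }
  })
  tr <- list(dt = params$dt, times = (seq_len(n_frames) - 1) * params$dt,
             positions = pos, velocities = vel, params = params,
             seed = params$seed)
  class(tr) <- "trajectory_ensemble"
  tr
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("Trajectory ensemble: %d frames x %d agents, dt = %.4g s\n",
              dim(x$positions)[1], dim(x$positions)[2], x$dt))
  invisible(x)
}

#' Group order parameters
#'
#' Polarization `P = ||sum d_i|| / N` measures alignment; angular momentum
#' `M = ||sum u_ic x d_i|| / N` measures collective rotation about the group
#' centroid, where `u_ic` is the unit vector from the centroid to agent `i`
#' and the 2-D cross product is the scalar z-component. Both lie in
#' \[0, 1\]. Agents exactly at the centroid are skipped in `M` (with a
#' message).
#'
#' @param positions N x 2 matrix of positions (m).
#' @param directions N x 2 matrix of unit headings.
#' @return Named numeric vector `c(polarization, angular_momentum)`.
#' @export
order_parameters <- function(positions, directions) {
  n <- nrow(positions)
  stopifnot(n >= 2, nrow(directions) == n)
  pol <- sqrt(sum(colSums(directions)^2)) / n
  centroid <- colMeans(positions)
  rel <- sweep(positions, 2, centroid)
  rn <- sqrt(rowSums(rel^2))
  keep <- rn > 0
  if (!all(keep)) message(sprintf("%d agent(s) at centroid skipped", sum(!keep)))
  u <- rel[keep, , drop = FALSE] / rn[keep]
  cross_z <- u[, 1] * directions[keep, 2] - u[, 2] * directions[keep, 1]
  mom <- abs(sum(cross_z)) / n
  c(polarization = pol, angular_momentum = mom)
}

#' Order parameters over a trajectory window
#'
#' @param traj a `trajectory_ensemble`.
#' @param from start time (s); defaults to the run's `analysis_start` so
#'   that the initial transient is excluded.
#' @return A data.frame with columns `time`, `polarization`,
#'   `angular_momentum`.
#' @export
order_parameter_series <- function(traj, from = NULL) {
  if (is.null(from)) from <- traj$params$analysis_start
  if (is.null(from)) from <- 0
  idx <- which(traj$times >= from)
  sp <- sqrt(traj$velocities[, , 1]^2 + traj$velocities[, , 2]^2)
  res <- t(vapply(idx, function(t) {
    dirs <- cbind(traj$velocities[t, , 1], traj$velocities[t, , 2]) / sp[t, ]
    order_parameters(traj$positions[t, , ], dirs)
  }, numeric(2)))
  data.frame(time = traj$times[idx], polarization = res[, 1],
             angular_momentum = res[, 2])
}
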