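# File formats: trajectories and segments as plain CSV with JSON sidecars.
# All times in seconds, positions in meters; row order is canonicalized by
# (time, agent) on read, so files may be shuffled.

SCHEMA_TRAJECTORY <- "comodyn/trajectory/1"
SCHEMA_SEGMENT <- "comodyn/segment/1"

#' Write a trajectory ensemble to CSV
#'
#' Columns `time,agent,x,y,vx,vy` (SI units, 0-based agent indices), plus a
#' JSON sidecar `<path>.json` carrying the schema version, the seed and the
#' generating parameters.
#'
#' @param traj a `trajectory_ensemble`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  T_ <- dim(traj$positions)[1]
  n <- dim(traj$positions)[2]
  dt_tab <- data.table::data.table(
    time = rep(traj$times, each = n),
    agent = rep(0:(n - 1), times = T_),
    x = as.vector(t(traj$positions[, , 1])),
    y = as.vector(t(traj$positions[, , 2])),
    vx = as.vector(t(traj$velocities[, , 1])),
    vy = as.vector(t(traj$velocities[, , 2])))
  data.table::fwrite(dt_tab, path)
  meta <- list(schema = SCHEMA_TRAJECTORY, dt = traj$dt, n_agents = n,
               n_frames = T_, seed = traj$seed,
               params = unclass(traj$params))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trajectory ensemble from CSV
#'
#' Expects columns `time,agent,x,y` and optionally `vx,vy`; velocities are
#' computed by forward differences when absent. The time grid must be
#' regular and every agent present at every frame; violations raise
#' descriptive errors. If a JSON sidecar `<path>.json` exists its schema
#' version is checked and its metadata attached.
#'
#' @param path CSV path.
#' @return A `trajectory_ensemble`.
#' @export
read_trajectory <- function(path) {
  tab <- data.table::fread(path)
  need <- c("time", "agent", "x", "y")
  if (!all(need %in% names(tab)))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(setdiff(need, names(tab)), collapse = ", ")))
  for (cn in intersect(c("time", "x", "y", "vx", "vy"), names(tab))) {
    bad <- which(!is.finite(as.numeric(tab[[cn]])))
    if (length(bad) > 0)
      stop(sprintf("%s: non-numeric/non-finite `%s` at data row %d",
                   path, cn, bad[1]))
  }
  data.table::setorder(tab, time, agent)
  times <- sort(unique(tab$time))
  agents <- sort(unique(tab$agent))
  T_ <- length(times); n <- length(agents)
  if (nrow(tab) != T_ * n)
    stop(sprintf("%s: expected %d rows (%d frames x %d agents), found %d; missing agents per frame?",
                 path, T_ * n, T_, n, nrow(tab)))
  if (T_ < 2) stop(sprintf("%s: need at least 2 frames", path))
  dts <- diff(times)
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) >= 1e-9)
    stop(sprintf("%s: irregular sampling (max |dt_i - dt| = %.3g s)",
                 path, max(abs(dts - dt))))
  pos <- array(NA_real_, c(T_, n, 2))
  pos[, , 1] <- matrix(tab$x, T_, n, byrow = TRUE)
  pos[, , 2] <- matrix(tab$y, T_, n, byrow = TRUE)
  vel <- array(NA_real_, c(T_, n, 2))
  if (all(c("vx", "vy") %in% names(tab))) {
    vel[, , 1] <- matrix(tab$vx, T_, n, byrow = TRUE)
    vel[, , 2] <- matrix(tab$vy, T_, n, byrow = TRUE)
  } else {
    vel[-T_, , ] <- (pos[-1, , , drop = FALSE] - pos[-T_, , , drop = FALSE]) / dt
    vel[T_, , ] <- vel[T_ - 1, , ]
  }
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!identical(meta$schema, SCHEMA_TRAJECTORY))
      stop(sprintf("%s: schema `%s` does not match expected `%s`",
                   sidecar, format(meta$schema), SCHEMA_TRAJECTORY))
  }
  tr <- list(dt = dt, times = times, positions = pos, velocities = vel,
             params = meta$params, seed = meta$seed)
  class(tr) <- "trajectory_ensemble"
  tr
}

#' Write an attack segment to CSV + JSON sidecar
#'
#' CSV columns `frame,entity,role,x,y` with role in attacker/defender/ball;
#' sidecar `<path>.json` holds `schema`, `segment_id`, `label`,
#' `frame_rate` and the per-frame `ball_holder`.
#'
#' @param segment an [attack_segment()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_segment <- function(segment, path) {
  T_ <- dim(segment$attackers)[1]
  rows <- list()
  for (role in c("attacker", "defender")) {
    arr <- if (role == "attacker") segment$attackers else segment$defenders
    for (a in 1:5) {
      rows[[length(rows) + 1]] <- data.table::data.table(
        frame = seq_len(T_), entity = a - 1L, role = role,
        x = arr[, a, 1], y = arr[, a, 2])
    }
  }
  rows[[length(rows) + 1]] <- data.table::data.table(
    frame = seq_len(T_), entity = 0L, role = "ball",
    x = segment$ball[, 1], y = segment$ball[, 2])
  tab <- data.table::rbindlist(rows)
  data.table::setorder(tab, frame, role, entity)
  data.table::fwrite(tab, path)
  meta <- list(schema = SCHEMA_SEGMENT,
               segment_id = if (is.null(segment$id)) "" else segment$id,
               label = as.character(segment$label),
               frame_rate = segment$frame_rate,
               ball_holder = segment$ball_holder)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an attack segment written by [write_segment()]
#'
#' @param path CSV path (expects the JSON sidecar next to it).
#' @return An [attack_segment()].
#' @export
read_segment <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop(sprintf("missing sidecar %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!identical(meta$schema, SCHEMA_SEGMENT))
    stop(sprintf("%s: schema `%s` does not match expected `%s`",
                 sidecar, format(meta$schema), SCHEMA_SEGMENT))
  tab <- data.table::fread(path)
  T_ <- max(tab$frame)
  grab <- function(role) {
    arr <- array(NA_real_, c(T_, 5, 2))
    sub <- tab[tab$role == role, ]
    data.table::setorder(sub, frame, entity)
    arr[, , 1] <- matrix(sub$x, T_, 5, byrow = TRUE)
    arr[, , 2] <- matrix(sub$y, T_, 5, byrow = TRUE)
    arr
  }
  ball_tab <- tab[tab$role == "ball", ]
  data.table::setorder(ball_tab, frame)
  attack_segment(grab("attacker"), grab("defender"),
                 cbind(ball_tab$x, ball_tab$y),
                 meta$ball_holder, meta$label,
                 frame_rate = meta$frame_rate, id = meta$segment_id)
}

#' Read run configuration from a YAML (key: value) file
#'
#' @param path YAML file path.
#' @param defaults named list of defaults merged under the file's values.
#' @return Named list; always contains the resolved `seed`.
#' @export
read_config <- function(path, defaults = list(seed = 1)) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  out <- utils::modifyList(defaults, cfg)
  if (is.null(out$seed)) out$seed <- 1
  out
}
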