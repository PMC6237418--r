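#' Pairwise Euclidean distance matrix of one frame
#'
#' @param positions N x 2 matrix.
#' @return Symmetric N x N matrix with zero diagonal.
#' @export
pairwise_distances <- function(positions) {
  stopifnot(is.matrix(positions), ncol(positions) == 2,
            all(is.finite(positions)))
  as.matrix(stats::dist(positions))
}

#' Nearest-sorted distance snapshot
#'
#' For each agent, its distances to all other agents sorted ascending
#' (self excluded); rows concatenated row-major into one vector of length
#' `N * (N - 1)`. Sorting by nearest neighbors removes agent identity, so
#' the snapshot is invariant under any relabeling of the agents and varies
#' more smoothly in time than the fixed-order distance list.
#'
#' @param D an N x N distance matrix.
#' @return Numeric vector of length `N * (N - 1)`.
#' @export
sorted_distance_snapshot <- function(D) {
  n <- nrow(D)
  stopifnot(n >= 2, ncol(D) == n)
  rows <- lapply(seq_len(n), function(i) sort(D[i, -i]))
  unlist(rows, use.names = FALSE)
}

#' Build the observable (snapshot) matrix for DMD from a trajectory
#'
#' @param traj a `trajectory_ensemble`.
#' @param feature_mode one of `"sorted_distance"` (per-agent
#'   nearest-sorted distances, p = N(N-1)), `"fixed_distance"` (upper
#'   triangle of the distance matrix in fixed agent order, p = N(N-1)/2) or
#'   `"cartesian"` (stacked coordinates x1, y1, x2, y2, ..., p = 2N).
#' @param from,to optional time window (s, inclusive); default full run.
#' @return A `snapshot_sequence`: list with `values` (p x tau matrix,
#'   columns = time snapshots), `dt`, `feature_mode`, `provenance`.
#' @export
build_snapshot_sequence <- function(traj, feature_mode = c("sorted_distance",
                                                           "fixed_distance",
                                                           "cartesian"),
                                    from = NULL, to = NULL) {
  feature_mode <- match.arg(feature_mode)
  idx <- seq_along(traj$times)
  if (!is.null(from)) idx <- idx[traj$times[idx] >= from]
  if (!is.null(to)) idx <- idx[traj$times[idx] <= to]
  if (length(idx) < 2) stop("window contains fewer than 2 frames")
  n <- dim(traj$positions)[2]
  cols <- lapply(idx, function(t) {
    xy <- traj$positions[t, , , drop = TRUE]
    switch(feature_mode,
      sorted_distance = sorted_distance_snapshot(pairwise_distances(xy)),
      fixed_distance = {
        D <- pairwise_distances(xy)
        D[upper.tri(D)]
      },
      cartesian = as.numeric(t(xy)))
  })
  snapshot_sequence(do.call(cbind, cols), dt = traj$dt,
                    feature_mode = feature_mode,
                    provenance = sprintf("trajectory seed %s",
                                         format(traj$seed)))
}

#' Construct a snapshot sequence object
#'
#' @param values p x tau numeric matrix, columns ordered in time.
#' @param dt sampling interval, s.
#' @param feature_mode free-form tag describing the observable map.
#' @param provenance free-form source description.
#' @return A `snapshot_sequence`.
#' @export
snapshot_sequence <- function(values, dt, feature_mode = "raw",
                              provenance = "") {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("snapshot values must be finite")
  if (ncol(values) < 2) stop("a snapshot sequence needs tau >= 2 columns")
  s <- list(values = values, dt = dt, feature_mode = feature_mode,
            provenance = provenance)
  class(s) <- "snapshot_sequence"
  s
}

#' @export
print.snapshot_sequence <- function(x, ...) {
  cat(sprintf("Snapshot sequence: p = %d features x tau = %d frames, dt = %.4g s (%s)\n",
              nrow(x$values), ncol(x$values), x$dt, x$feature_mode))
  invisible(x)
}

#' Construct an attack segment
#'
#' A labeled 5-attacker / 5-defender / ball possession interval sampled at
#' `frame_rate` frames per second, as produced by player-tracking systems.
#'
#' @param attackers,defenders T x 5 x 2 arrays of positions (m).
#' @param ball T x 2 matrix of ball positions (m).
#' @param ball_holder length-T integer vector in 1..5: which attacker holds
#'   the ball at each frame.
#' @param label binary outcome, coerced to factor with levels
#'   `c("no_score", "score")`.
#' @param frame_rate frames per second (default 25).
#' @param id optional segment identifier.
#' @return An `attack_segment`.
#' @export
attack_segment <- function(attackers, defenders, ball, ball_holder, label,
                           frame_rate = 25, id = NULL) {
  stopifnot(length(dim(attackers)) == 3, length(dim(defenders)) == 3)
  if (dim(attackers)[2] < 5 || dim(defenders)[2] < 5)
    stop("an attack segment needs 5 attackers and 5 defenders")
  T_ <- dim(attackers)[1]
  stopifnot(T_ >= 2, dim(defenders)[1] == T_, nrow(ball) == T_,
            length(ball_holder) == T_, all(ball_holder %in% 1:5))
  label <- if (is.character(label) || is.factor(label)) {
    factor(as.character(label), levels = c("no_score", "score"))
  } else {
    factor(ifelse(as.numeric(label) > 0, "score", "no_score"),
           levels = c("no_score", "score"))
  }
  seg <- list(attackers = attackers, defenders = defenders, ball = ball,
              ball_holder = as.integer(ball_holder), label = label,
              frame_rate = frame_rate, id = id)
  class(seg) <- "attack_segment"
  seg
}

# Per-frame sorted 5x5 attacker-defender matrix and the attacker column
# order. Column 1 is the ball handler; remaining columns are the off-ball
# attackers by decreasing nearest-defender separation (ties broken by
# attacker index). Each column holds that attacker's five defender
# distances sorted nearest-first.
frame_game_matrix <- function(att, def, holder) {
  D <- sqrt(outer(att[, 1], def[, 1], "-")^2 +
            outer(att[, 2], def[, 2], "-")^2)  # 5 attackers x 5 defenders
  nearest <- apply(D, 1, min)
  off <- setdiff(1:5, holder)
  off <- off[order(-nearest[off], off)]
  ord <- c(holder, off)
  M <- apply(D[ord, , drop = FALSE], 1, sort)  # 5 x 5; column a = attacker ord[a]
  list(M = M, order = ord, D = D, nearest = nearest)
}

#' Critical attacker-defender distances of an attack segment
#'
#' Per frame: *ball-mark* = the ball handler's nearest-defender distance;
#' *ball-help* = the ball handler's second-nearest-defender distance;
#' *pass-mark* = the largest nearest-defender distance among the off-ball
#' attackers; *pass-help* = the second-largest such value.
#'
#' @param segment an [attack_segment()].
#' @return T x 4 matrix with columns `ball_mark`, `ball_help`, `pass_mark`,
#'   `pass_help`.
#' @export
critical_distances <- function(segment) {
  T_ <- dim(segment$attackers)[1]
  out <- matrix(NA_real_, T_, 4,
                dimnames = list(NULL, c("ball_mark", "ball_help",
                                        "pass_mark", "pass_help")))
  for (t in seq_len(T_)) {
    fg <- frame_game_matrix(segment$attackers[t, , ],
                            segment$defenders[t, , ],
                            segment$ball_holder[t])
    out[t, ] <- c(fg$M[1, 1], fg$M[2, 1], fg$M[1, 2], fg$M[1, 3])
  }
  out
}

#' Game-style input matrices for kernel DMD
#'
#' Builds the observable sequence for one attack segment in any of the nine
#' input variants: `critical_1` .. `critical_4` (ball-mark; + ball-help;
#' + pass-mark; + pass-help), `game_matrix_9` / `game_matrix_16` /
#' `game_matrix_25` (top-left 3x3 / 4x4 / full 5x5 block of the per-frame
#' sorted attacker-defender matrix, column-major), `euclidean25` (the 25
#' unsorted attacker x defender distances in fixed index order), and
#' `cartesian` (the 20 stacked player coordinates).
#'
#' @param segment an [attack_segment()].
#' @param variant one of the nine tags above.
#' @return A `snapshot_sequence` with `p` = 1, 2, 3, 4, 9, 16, 25, 25 or 20.
#' @export
game_distance_features <- function(segment,
                                   variant = c("critical_4", "critical_1",
                                               "critical_2", "critical_3",
                                               "game_matrix_9",
                                               "game_matrix_16",
                                               "game_matrix_25",
                                               "euclidean25", "cartesian")) {
  variant <- match.arg(variant)
  T_ <- dim(segment$attackers)[1]
  k_crit <- c(critical_1 = 1, critical_2 = 2, critical_3 = 3, critical_4 = 4)
  cols <- lapply(seq_len(T_), function(t) {
    att <- segment$attackers[t, , ]
    def <- segment$defenders[t, , ]
    if (variant == "cartesian")
      return(as.numeric(t(rbind(att, def))))
    fg <- frame_game_matrix(att, def, segment$ball_holder[t])
    switch(variant,
      critical_1 = , critical_2 = , critical_3 = , critical_4 = {
        cd <- c(fg$M[1, 1], fg$M[2, 1], fg$M[1, 2], fg$M[1, 3])
        cd[seq_len(k_crit[[variant]])]
      },
      game_matrix_9  = as.numeric(t(fg$M[1:3, 1:3])),
      game_matrix_16 = as.numeric(t(fg$M[1:4, 1:4])),
      game_matrix_25 = as.numeric(t(fg$M)),
      euclidean25    = as.numeric(t(fg$D)))
  })
  snapshot_sequence(do.call(cbind, cols), dt = 1 / segment$frame_rate,
                    feature_mode = variant,
                    provenance = if (is.null(segment$id)) "" else segment$id)
}

#' Extract labeled attack segments from a full game trajectory
#'
#' A segment starts at the first frame (after the previous shot) at which
#' all five attackers are inside the attacking half (`x > half_line`) and
#' ends exactly one second (`frame_rate` frames) before the shot. Shots for
#' which the attackers never assemble in the attacking half in time are
#' skipped with a warning.
#'
#' @param game list with T x 5 x 2 arrays `attackers`, `defenders`, a T x 2
#'   `ball` matrix and length-T `ball_holder`, sampled at `frame_rate` fps.
#' @param shots data.frame with columns `frame` (shot frame, 1-based) and
#'   `score` (logical or 0/1 outcome).
#' @param frame_rate frames per second (default 25).
#' @param half_line x-coordinate of the half-court line (default 0).
#' @return A `segment_set`: list of [attack_segment()]s with labels.
#' @export
extract_attack_segments <- function(game, shots, frame_rate = 25,
                                    half_line = 0) {
  T_ <- dim(game$attackers)[1]
  all_in <- vapply(seq_len(T_),
                   function(t) all(game$attackers[t, , 1] > half_line),
                   logical(1))
  segs <- list()
  prev_end <- 0L
  for (k in seq_len(nrow(shots))) {
    shot_frame <- shots$frame[k]
    end <- shot_frame - frame_rate  # 1 s before the shot
    cand <- which(all_in & seq_len(T_) > prev_end & seq_len(T_) < end)
    if (length(cand) == 0 || end - cand[1] < 1) {
      warning(sprintf("shot at frame %d: attackers never assembled; skipped",
                      shot_frame))
      prev_end <- shot_frame
      next
    }
    start <- cand[1]
    idx <- start:end
    segs[[length(segs) + 1]] <- attack_segment(
      attackers = game$attackers[idx, , , drop = FALSE],
      defenders = game$defenders[idx, , , drop = FALSE],
      ball = game$ball[idx, , drop = FALSE],
      ball_holder = game$ball_holder[idx],
      label = as.numeric(shots$score[k]),
      frame_rate = frame_rate,
      id = sprintf("segment_%03d", k))
    prev_end <- shot_frame
  }
  segment_set(segs)
}

#' Bundle attack segments into a set
#'
#' @param segments list of [attack_segment()]s.
#' @return A `segment_set` with `segments`, `labels` (factor) and `ids`.
#' @export
segment_set <- function(segments) {
  stopifnot(all(vapply(segments, inherits, logical(1), "attack_segment")))
  labels <- factor(vapply(segments, function(s) as.character(s$label),
                          character(1)), levels = c("no_score", "score"))
  ids <- vapply(seq_along(segments), function(i) {
    if (is.null(segments[[i]]$id)) sprintf("segment_%03d", i)
    else segments[[i]]$id
  }, character(1))
  ss <- list(segments = segments, labels = labels, ids = ids)
  class(ss) <- "segment_set"
  ss
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("Segment set: %d segments (%d score / %d no_score)\n",
              length(x$segments), sum(x$labels == "score"),
              sum(x$labels == "no_score")))
  invisible(x)
}
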