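test_that("pairwise distances are a valid metric matrix", {
  pos <- rbind(c(0, 0), c(1, 0), c(3, 0))
  D <- pairwise_distances(pos)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 3), ignore_attr = TRUE)
  expect_equal(D[1, 2], 1)
  expect_equal(D[1, 3], 3)
  expect_equal(D[2, 3], 2)
})

test_that("nearest-sorted snapshot flattens hand-sorted rows", {
  D <- pairwise_distances(rbind(c(0, 0), c(1, 0), c(3, 0)))
  expect_equal(sorted_distance_snapshot(D), c(1, 3, 1, 2, 2, 3))
  # rows non-decreasing
  set.seed(1)
  pos <- matrix(runif(20, 0, 10), 10, 2)
  v <- sorted_distance_snapshot(pairwise_distances(pos))
  m <- matrix(v, 10, 9, byrow = TRUE)
  expect_true(all(apply(m, 1, function(r) all(diff(r) >= 0))))
})

test_that("sorted snapshots are invariant under agent relabeling", {
  set.seed(7)
  pos <- matrix(runif(24, 0, 10), 12, 2)
  v1 <- sorted_distance_snapshot(pairwise_distances(pos))
  for (k in 1:5) {
    perm <- sample(12)
    v2 <- sorted_distance_snapshot(pairwise_distances(pos[perm, ]))
    # per-agent rows are permuted but the multiset of rows is identical;
    # sorting rows recovers exact equality
    m1 <- matrix(v1, 12, 11, byrow = TRUE)
    m2 <- matrix(v2, 12, 11, byrow = TRUE)
    expect_equal(m1[do.call(order, as.data.frame(m1)), ],
                 m2[do.call(order, as.data.frame(m2)), ])
  }
})

test_that("snapshot sequences expose the documented feature dimensions", {
  tr <- simulate_school(schooling_params(n_agents = 8, duration = 0.2, seed = 3))
  expect_equal(nrow(build_snapshot_sequence(tr, "sorted_distance")$values), 8 * 7)
  expect_equal(nrow(build_snapshot_sequence(tr, "fixed_distance")$values), 8 * 7 / 2)
  expect_equal(nrow(build_snapshot_sequence(tr, "cartesian")$values), 16)
  expect_error(build_snapshot_sequence(tr, "bogus"))
})

test_that("sorting stabilizes the distance series on a milling run", {
  tr <- simulate_school(schooling_params(n_agents = 24, r_o = 10,
                                         duration = 12, analysis_start = 8,
                                         seed = 4))
  ssort <- build_snapshot_sequence(tr, "sorted_distance", from = 8)
  sfix <- build_snapshot_sequence(tr, "fixed_distance", from = 8)
  rough <- function(s) mean(abs(s$values[, -1] - s$values[, -ncol(s$values)]))
  expect_lte(rough(ssort), rough(sfix))
})

# hand-built 5v5 frame: attacker a sits at x = 2a, defenders offset by a
# known gap; attacker 3 holds the ball
hand_segment <- function() {
  att <- array(0, c(2, 5, 2))
  def <- array(0, c(2, 5, 2))
  gaps <- c(1.0, 2.5, 0.5, 3.0, 1.5)
  for (a in 1:5) {
    att[, a, 1] <- 2 * a
    att[, a, 2] <- 0
    def[, a, 1] <- 2 * a
    def[, a, 2] <- gaps[a]
  }
  attack_segment(att, def, ball = att[, 3, ], ball_holder = c(3, 3),
                 label = 1)
}

test_that("critical distances match a brute-force evaluation", {
  seg <- hand_segment()
  cd <- critical_distances(seg)
  # brute force over all attacker-defender pairs
  att <- seg$attackers[1, , ]; def <- seg$defenders[1, , ]
  D <- as.matrix(stats::dist(rbind(att, def)))[1:5, 6:10]
  nearest <- apply(D, 1, min)
  nearest_sorted <- apply(D, 1, function(r) sort(r))
  expect_equal(unname(cd[1, "ball_mark"]), unname(nearest[3]))
  expect_equal(unname(cd[1, "ball_help"]), unname(nearest_sorted[2, 3]))
  off <- setdiff(1:5, 3)
  expect_equal(unname(cd[1, "pass_mark"]), unname(max(nearest[off])))
  expect_equal(unname(cd[1, "pass_help"]),
               unname(sort(nearest[off], decreasing = TRUE)[2]))
  # degenerate: every defender within eps of every attacker -> all four
  # critical distances collapse to the eps scale
  eps <- 1e-3
  th <- 2 * pi * (0:4) / 5
  cluster <- (eps / 4) * cbind(cos(th), sin(th))
  att <- array(0, c(2, 5, 2)); def <- array(0, c(2, 5, 2))
  for (t in 1:2) { att[t, , ] <- cluster; def[t, , ] <- -cluster }
  segg <- attack_segment(att, def, ball = att[, 1, ], ball_holder = c(1, 1),
                         label = 0)
  expect_true(all(critical_distances(segg) <= eps))
})

test_that("game feature variants have the documented dimensions", {
  seg <- hand_segment()
  dims <- c(critical_1 = 1, critical_2 = 2, critical_3 = 3, critical_4 = 4,
            game_matrix_9 = 9, game_matrix_16 = 16, game_matrix_25 = 25,
            euclidean25 = 25, cartesian = 20)
  for (v in names(dims))
    expect_equal(nrow(game_distance_features(seg, v)$values), unname(dims[v]),
                 info = v)
  # the 5x5 sorted matrix: column 1 is the ball handler's sorted distances
  s25 <- game_distance_features(seg, "game_matrix_25")
  # row-major flattening: first 5 entries are row 1 = nearest distances of
  # the ordered attackers; entry 1 is the ball-mark distance
  cd <- critical_distances(seg)
  expect_equal(s25$values[1, 1], unname(cd[1, "ball_mark"]))
  expect_equal(s25$values[2, 1], unname(cd[1, "pass_mark"]))
})

test_that("attack segments are cut 1 s before each shot", {
  T_ <- 700
  att <- array(0, c(T_, 5, 2))
  # attackers cross the half line x = 0 at frame 101
  for (a in 1:5) att[, a, 1] <- seq(-2, 12, length.out = T_)
  att[, , 2] <- 1
  game <- list(attackers = att, defenders = att + 0.5,
               ball = att[, 1, ], ball_holder = rep(1L, T_))
  shots <- data.frame(frame = c(300, 500, 650), score = c(1, 0, 1))
  set <- extract_attack_segments(game, shots, frame_rate = 25)
  expect_length(set$segments, 3)
  expect_equal(dim(set$segments[[1]]$attackers)[1],
               (300 - 25) - which(att[, 1, 1] > 0)[1] + 1)
  expect_equal(as.character(set$labels), c("score", "no_score", "score"))
  # attackers never crossing -> zero segments with a warning
  att2 <- att; att2[, 1, 1] <- -5
  game2 <- list(attackers = att2, defenders = att2 + 0.5,
                ball = att2[, 1, ], ball_holder = rep(1L, T_))
  w <- testthat::capture_warnings(set2 <- extract_attack_segments(game2, shots))
  expect_length(w, 3)
  expect_match(w, "skipped", all = TRUE)
  expect_length(set2$segments, 0)
})
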