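test_that("initial state honors the placement and heading protocol", {
  p <- schooling_params(n_agents = 64, seed = 11)
  st <- withr::with_seed(11, init_state(p))
  radii <- sqrt(rowSums(st$positions^2))
  expect_true(all(radii >= 6 & radii <= 16))
  # headings perpendicular to position vectors and unit norm
  dots <- abs(rowSums(st$positions * st$directions) / radii)
  expect_lt(max(dots), 1e-9)
  expect_equal(rowSums(st$directions^2), rep(1, 64), tolerance = 1e-12)
  # zero speed noise -> exactly the nominal speed
  p0 <- schooling_params(n_agents = 8, speed_noise_sd = 0)
  st0 <- withr::with_seed(1, init_state(p0))
  expect_identical(st0$speeds, rep(4, 8))
})

test_that("parameter validation rejects inconsistent zone radii", {
  expect_error(schooling_params(r_r = 5, r_o = 2), "zone radii")
  expect_error(schooling_params(beta = 4), "beta")
  expect_error(schooling_params(n_agents = 1), "n_agents")
})

make_state <- function(pos, dirs, speeds = rep(1, nrow(pos))) {
  st <- list(time = 0, positions = pos, directions = dirs, speeds = speeds)
  class(st) <- "swarm_state"
  st
}

unit_rows_for_test <- function(m) m / sqrt(rowSums(m^2))

test_that("zonal desired direction matches hand-evaluated cases", {
  p <- schooling_params(n_agents = 2, r_r = 1, r_o = 5, r_a = 20, beta = 0.5)
  # single repulsion neighbor at (0.5, 0) -> flee along (-1, 0)
  st <- make_state(rbind(c(0, 0), c(0.5, 0)), rbind(c(0, 1), c(0, 1)))
  expect_equal(desired_direction(1, st, p), c(-1, 0), tolerance = 1e-12)
  # two repulsion neighbors -> normalized -(1,0)-(0,1)
  p3 <- schooling_params(n_agents = 3, r_r = 1, r_o = 5, r_a = 20)
  st3 <- make_state(rbind(c(0, 0), c(0.5, 0), c(0, 0.5)),
                    rbind(c(0, 1), c(0, 1), c(0, 1)))
  expect_equal(desired_direction(1, st3, p3),
               c(-sqrt(2) / 2, -sqrt(2) / 2), tolerance = 1e-12)
  # orientation-only: one neighbor in the shell moving along (0, 1)
  st_o <- make_state(rbind(c(0, 0), c(3, 0)), rbind(c(1, 0), c(0, 1)))
  expect_equal(desired_direction(1, st_o, p), c(0, 1), tolerance = 1e-12)
  # attraction-only: neighbor at (3, 0) beyond r_o = 2
  p_a <- schooling_params(n_agents = 2, r_r = 1, r_o = 2, r_a = 20)
  expect_equal(desired_direction(1, st_o, p_a), c(1, 0), tolerance = 1e-12)
  # empty zones: keep current heading
  p_far <- schooling_params(n_agents = 2, r_r = 1, r_o = 2, r_a = 2.5)
  expect_equal(desired_direction(1, st_o, p_far), c(1, 0) * 0 + st_o$directions[1, ])
})

test_that("repulsion has absolute priority over the outer zones", {
  p <- schooling_params(n_agents = 4, r_r = 1, r_o = 5, r_a = 20)
  pos <- rbind(c(0, 0), c(0.5, 0), c(3, 2), c(10, -4))
  base <- make_state(pos, rbind(c(0, 1), c(0, 1), c(1, 0), c(0, -1)))
  d0 <- desired_direction(1, base, p)
  # perturbing orientation- and attraction-zone neighbors must not matter
  for (k in 1:5) {
    pos2 <- pos
    pos2[3, ] <- c(2 + k / 3, 1)
    pos2[4, ] <- c(8, k)
    st2 <- make_state(pos2, rbind(c(0, 1), c(0, 1), runif(2), runif(2)))
    st2$directions <- unit_rows_for_test(st2$directions)
    expect_equal(desired_direction(1, st2, p), d0, tolerance = 1e-12)
  }
})


test_that("turn limiting rotates by at most beta toward the target", {
  # within the limit: returned unchanged
  d <- limit_turn(c(1, 0), c(cos(0.3), sin(0.3)), beta = 0.5)
  expect_equal(d, c(cos(0.3), sin(0.3)))
  # beyond: rotate by exactly beta (counter-clockwise here)
  d2 <- limit_turn(c(1, 0), c(0, 1), beta = 0.698)
  expect_equal(d2, c(cos(0.698), sin(0.698)), tolerance = 1e-12)
  # clockwise target
  d3 <- limit_turn(c(1, 0), c(0, -1), beta = 0.2)
  expect_equal(d3, c(cos(0.2), -sin(0.2)), tolerance = 1e-12)
  # property: angle to current equals min(theta, beta), dot = cos(beta)
  set.seed(42)
  for (k in 1:20) {
    a <- runif(1, 0, 2 * pi); b <- runif(1, 0, 2 * pi); bet <- runif(1, 0.05, 1)
    cur <- c(cos(a), sin(a)); des <- c(cos(b), sin(b))
    out <- limit_turn(cur, des, bet)
    expect_equal(sum(out^2), 1, tolerance = 1e-12)
    theta <- acos(pmin(1, pmax(-1, sum(cur * des))))
    expect_equal(sum(out * cur), cos(min(theta, bet)), tolerance = 1e-9)
  }
})

test_that("an isolated unbounded agent moves in a straight line", {
  p <- schooling_params(n_agents = 2, r_r = 1, r_o = 2, r_a = 3,
                        boundary_radius = Inf, speed_noise_sd = 0,
                        duration = 1, dt = 0.01, seed = 2)
  st <- make_state(rbind(c(0, 0), c(100, 100)), rbind(c(1, 0), c(0, 1)),
                   speeds = c(4, 4))
  for (k in 1:50) st <- step_school(st, p)
  expect_equal(st$positions[1, ], c(50 * 4 * 0.01, 0), tolerance = 1e-9)
})

test_that("simulation invariants hold over a full seeded run", {
  p <- schooling_params(n_agents = 16, duration = 3, seed = 5)
  tr <- simulate_school(p)
  expect_equal(dim(tr$positions)[1], 300)
  speeds <- sqrt(tr$velocities[, , 1]^2 + tr$velocities[, , 2]^2)
  # constant per-agent speed at every frame
  expect_lt(max(abs(sweep(speeds, 2, speeds[1, ]))), 1e-9)
  # turn-angle bound per step
  vx <- tr$velocities[, , 1] / speeds
  vy <- tr$velocities[, , 2] / speeds
  dots <- vx[-1, ] * vx[-300, ] + vy[-1, ] * vy[-300, ]
  max_turn <- max(acos(pmin(1, pmax(-1, dots))))
  expect_lte(max_turn, p$beta + 1e-9)
  # boundary containment
  expect_true(all(sqrt(tr$positions[, , 1]^2 + tr$positions[, , 2]^2) <=
                    p$boundary_radius + 1e-9))
  # velocities consistent with position increments (no clamping here)
  dx <- tr$positions[-1, , 1] - tr$positions[-300, , 1]
  expect_lt(max(abs(dx - tr$velocities[-300, , 1] * p$dt)), 1e-8)
  # seeded determinism
  tr2 <- simulate_school(p)
  expect_identical(tr$positions, tr2$positions)
})

test_that("vectorized step agrees with the per-agent reference rule", {
  p <- schooling_params(n_agents = 12, r_r = 2, r_o = 6, r_a = 15, seed = 9)
  st <- withr::with_seed(9, init_state(p))
  des_vec <- comodyn:::desired_directions_all(st, p)
  des_ref <- t(vapply(1:12, function(i) desired_direction(i, st, p),
                      numeric(2)))
  expect_equal(des_vec, des_ref, tolerance = 1e-12)
})

test_that("order parameters behave as the alignment and milling metrics", {
  n <- 32
  pos <- cbind(runif(n), runif(n))
  dirs <- matrix(rep(c(0.6, 0.8), each = n), n, 2)
  op <- order_parameters(pos, dirs)
  expect_equal(unname(op["polarization"]), 1, tolerance = 1e-12)
  # evenly spread headings -> polarization ~ 0
  th <- 2 * pi * (0:(n - 1)) / n
  op2 <- order_parameters(pos, cbind(cos(th), sin(th)))
  expect_lt(op2["polarization"], 1e-10)
  # perfect counter-clockwise ring -> angular momentum 1
  ring <- cbind(cos(th), sin(th))
  tangent <- cbind(-sin(th), cos(th))
  op3 <- order_parameters(ring, tangent)
  expect_equal(unname(op3["angular_momentum"]), 1, tolerance = 1e-12)
})

test_that("the three orientation radii reproduce swarm, torus and parallel", {
  stats <- sapply(c(2, 10, 13), function(ro) {
    res <- sapply(1:2, function(sd) {
      tr <- cached_school_run(ro, sd)
      ops <- order_parameter_series(tr, from = 30)
      c(mean(ops$polarization), mean(ops$angular_momentum))
    })
    rowMeans(res)
  })
  colnames(stats) <- c("swarm", "torus", "parallel")
  expect_equal(unname(which.max(stats[2, ])), 2L)  # milling peaks at r_o = 10
  expect_equal(unname(which.max(stats[1, ])), 3L)  # alignment peaks at r_o = 13
  expect_lt(stats[1, "swarm"], 0.4)
  expect_lt(stats[2, "swarm"], 0.4)
})
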