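# Shared fixtures. Heavy schooling runs are cached per session so the
# acceptance tests can reuse them across blocks.

.sim_cache <- new.env(parent = emptyenv())

cached_school_run <- function(r_o, seed, duration = 40,
                              analysis_start = if (r_o == 10) 10 else 30) {
  key <- sprintf("ro%g_seed%d_dur%g", r_o, seed, duration)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_school(schooling_params(
      r_o = r_o, duration = duration, analysis_start = analysis_start,
      seed = seed))
  }
  .sim_cache[[key]]
}

rotation2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# Small random stable linear system (spectral radius < 1), reproducible.
random_stable_matrix <- function(p, seed, radius = 0.95) {
  set.seed(seed)
  A <- matrix(stats::rnorm(p * p, sd = 0.4), p, p)
  A / max(Mod(eigen(A, only.values = TRUE)$values)) * radius
}

# Sort complex values for spectrum comparison.
sort_complex <- function(z) z[order(Re(z), Im(z))]

expect_spectra_equal <- function(a, b, tol) {
  expect_equal(sort_complex(as.complex(a)), sort_complex(as.complex(b)),
               tolerance = tol)
}

# A snapshot sequence from a planar rotation with given angle per step,
# embedded in dim p via a fixed random isometry-ish map.
rotation_sequence <- function(theta, tau = 60, dt = 0.1, scale = 1,
                              start = c(1, 0.5)) {
  y <- matrix(0, 2, tau)
  y[, 1] <- start
  R <- scale * rotation2(theta)
  for (t in 2:tau) y[, t] <- R %*% y[, t - 1]
  snapshot_sequence(y, dt = dt, feature_mode = "rotation_fixture")
}
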