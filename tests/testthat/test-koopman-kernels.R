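# Two easily distinguished dynamical classes for kernel tests: fast vs
# slow rotations with small deterministic perturbations per instance.
rotation_class_sequences <- function(n_per_class, theta_fast = pi / 3,
                                     theta_slow = pi / 12, tau = 40) {
  seqs <- list()
  for (k in seq_len(n_per_class)) {
    seqs[[k]] <- rotation_sequence(theta_fast * (1 + 0.02 * k), tau = tau,
                                   start = c(1, 0.4 + 0.05 * k))
    seqs[[n_per_class + k]] <- rotation_sequence(theta_slow * (1 + 0.02 * k),
                                                 tau = tau,
                                                 start = c(1, 0.4 + 0.05 * k))
  }
  seqs
}

test_that("the self kernel of any fitted system is one", {
  set.seed(2)
  s <- snapshot_sequence(matrix(rnorm(80), 4), dt = 0.1)
  fit <- fit_kdmd(s, kernel_spec("gaussian"), rank = 6)
  pr <- subspace_products(fit, fit)
  expect_equal(pr$AA, pr$BB)
  expect_equal(dim(pr$AB), dim(pr$AA))
  expect_equal(pr$AB, pr$AA, tolerance = 1e-8)
  pk <- principal_angle_kernel(pr)
  expect_equal(pk$angles, rep(1, length(pk$angles)), tolerance = 1e-6)
  expect_equal(pk$kernel, 1, tolerance = 1e-6)
})

test_that("subspace product blocks have the contracted shapes", {
  set.seed(4)
  s1 <- snapshot_sequence(matrix(rnorm(60), 3), dt = 0.1)
  s2 <- snapshot_sequence(matrix(rnorm(90), 3), dt = 0.1)
  f1 <- fit_kdmd(s1, kernel_spec("gaussian"), rank = 5)
  f2 <- fit_kdmd(s2, kernel_spec("gaussian"), rank = 7)
  pr <- subspace_products(f1, f2)
  r1 <- length(f1$eigenvalues); r2 <- length(f2$eigenvalues)
  expect_equal(dim(pr$AA), c(r1, r1))
  expect_equal(dim(pr$BB), c(r2, r2))
  expect_equal(dim(pr$AB), c(r1, r2))
  expect_error(subspace_products(f1, fit_kdmd(s2, kernel_spec("linear"))),
               "different kernel families")
})

test_that("linear-kernel subspace products match explicit data-space modes", {
  A <- random_stable_matrix(3, seed = 21)
  s1 <- linear_fixture(A, c(1, 0.5, -0.2), 40, dt = 0.1)
  s2 <- linear_fixture(A, c(0.3, -1, 0.8), 50, dt = 0.1)
  f1 <- fit_kdmd(s1, kernel_spec("linear"))
  f2 <- fit_kdmd(s2, kernel_spec("linear"))
  pr <- subspace_products(f1, f2)
  # explicit path: center the concatenated data columns, form the cross
  # inner products, and sandwich with each system's own PCA/mode factors
  M <- cbind(f1$M1, f2$M1)
  Mc <- M - rowMeans(M)
  n1 <- ncol(f1$M1)
  G12 <- crossprod(Mc[, seq_len(n1)], Mc[, -seq_len(n1)])
  AB_explicit <- f1$Tinv %*% ((1 / sqrt(f1$S)) * t(f1$B)) %*% G12 %*%
    f2$B %*% diag(1 / sqrt(f2$S), length(f2$S)) %*% f2$Tmat
  expect_equal(pr$AB, AB_explicit, tolerance = 1e-8)
})

test_that("orthogonal mode subspaces give a zero kernel", {
  # two systems whose centered snapshots live in orthogonal coordinate
  # planes of R^4: their feature-space mode subspaces are orthogonal
  y1 <- rbind(rotation_sequence(pi / 6, tau = 30)$values, matrix(0, 2, 30))
  y2 <- rbind(matrix(0, 2, 30), rotation_sequence(pi / 5, tau = 30)$values)
  f1 <- fit_kdmd(snapshot_sequence(y1, dt = 0.1), kernel_spec("linear"))
  f2 <- fit_kdmd(snapshot_sequence(y2, dt = 0.1), kernel_spec("linear"))
  pk <- principal_angle_kernel(subspace_products(f1, f2))
  expect_lt(max(pk$angles), 1e-8)
  expect_equal(pk$kernel, 0, tolerance = 1e-8)
})

test_that("kernel matrices satisfy the metric-like contract", {
  seqs <- rotation_class_sequences(3, tau = 30)
  seqs[[7]] <- seqs[[1]]  # exact duplicate of the first segment
  km <- kernel_and_distance_matrix(seqs, kernel_spec("gaussian"), rank = 6)
  expect_equal(dim(km$K), c(7, 7))
  expect_equal(km$K, t(km$K), tolerance = 1e-8)
  expect_equal(diag(km$D), rep(0, 7), ignore_attr = TRUE)
  expect_true(all(km$D >= 0))
  expect_lt(km$D[1, 7], 1e-6)  # duplicated segment at distance zero
})

test_that("within-class spectral distances are smaller than between-class", {
  seqs <- rotation_class_sequences(4, tau = 40)
  km <- kernel_and_distance_matrix(seqs, kernel_spec("gaussian"), rank = 6)
  cls <- rep(c("fast", "slow"), each = 4)
  same <- outer(cls, cls, "==") & upper.tri(km$D)
  diff_ <- outer(cls, cls, "!=") & upper.tri(km$D)
  expect_lt(mean(km$D[same]), mean(km$D[diff_]))
})

test_that("principal-angle values are invariant to segment start shifts", {
  # all modes persist over the window: one slow real mode + a rotation pair
  blk <- rbind(c(0.98, 0, 0),
               cbind(0, 0.99 * rotation2(pi / 7)))
  Q <- qr.Q(qr(matrix(withr::with_seed(31, rnorm(9)), 3, 3)))
  A <- Q %*% blk %*% t(Q)
  full <- linear_fixture(A, c(1, -0.4, 0.7), 120, dt = 0.1)
  sa <- snapshot_sequence(full$values[, 1:60], dt = 0.1)
  sb <- snapshot_sequence(full$values[, 16:75], dt = 0.1)
  ref <- snapshot_sequence(full$values[, 5:70], dt = 0.1)
  fref <- fit_kdmd(ref, kernel_spec("linear"))
  ka <- principal_angle_kernel(subspace_products(fit_kdmd(sa, kernel_spec("linear")), fref))
  kb <- principal_angle_kernel(subspace_products(fit_kdmd(sb, kernel_spec("linear")), fref))
  expect_equal(ka$angles[1:3], kb$angles[1:3], tolerance = 1e-6)
})
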