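# Koopman spectral kernels: principal-angle (Binet-Cauchy type) similarity
# between two dynamical systems fitted by kernel DMD, built entirely from
# Gram matrices so the feature space never has to be materialized.

#' Subspace inner products between two kernel-DMD systems
#'
#' Computes the three blocks entering the principal-angle generalized
#' eigenproblem for systems i and j:
#' `A*A = Tinv_i S_i^{-1/2} B_i* H G_yy,ii H B_i S_i^{-1/2} T_i` (order
#' r_i), the analogous `B*B` (order r_j), and the cross block
#' `A*B = Tinv_i S_i^{-1/2} B_i* G_ij B_j S_j^{-1/2} T_j`, where `G_ij` is
#' the upper-right n_i x n_j block of the centered Gram matrix of the two
#' snapshot series concatenated in time (centered with `H` of size
#' n_i + n_j). An unset Gaussian bandwidth for the cross kernel is resolved
#' by the median heuristic on the concatenated data.
#'
#' @param ki,kj `kdmd_result`s fitted with the same kernel family.
#' @param cross_kernel optional [kernel_spec()] for the concatenated-series
#'   Gram; defaults to the family of `ki` with bandwidth re-resolved on the
#'   concatenated snapshots.
#' @return List with complex matrices `AA` (r_i x r_i), `BB` (r_j x r_j),
#'   `AB` (r_i x r_j).
#' @export
subspace_products <- function(ki, kj, cross_kernel = NULL) {
  stopifnot(inherits(ki, "kdmd_result"), inherits(kj, "kdmd_result"))
  if (ki$kernel$kind != kj$kernel$kind)
    stop("systems were fitted with different kernel families")
  self_block <- function(k) {
    Sih <- 1 / sqrt(k$S)
    X <- (Sih * t(k$B)) %*% k$gram$G_yy_c %*% k$B %*% diag(Sih, length(k$S))
    k$Tinv %*% X %*% k$Tmat
  }
  if (is.null(cross_kernel)) {
    cross_kernel <- ki$kernel
    if (cross_kernel$kind == "gaussian") cross_kernel$bandwidth <- NULL
  }
  M <- cbind(ki$M1, kj$M1)
  ni <- ncol(ki$M1); nj <- ncol(kj$M1)
  cross_kernel <- resolve_kernel(cross_kernel, M)
  G <- kernel_eval(M, M, cross_kernel)
  H <- centering_matrix(ni + nj)
  Gc <- H %*% G %*% H
  Gij <- Gc[seq_len(ni), ni + seq_len(nj), drop = FALSE]
  Sih_i <- 1 / sqrt(ki$S); Sih_j <- 1 / sqrt(kj$S)
  AB <- ki$Tinv %*% (Sih_i * t(ki$B)) %*% Gij %*%
    kj$B %*% diag(Sih_j, length(kj$S)) %*% kj$Tmat
  list(AA = self_block(ki), BB = self_block(kj), AB = AB)
}

#' Principal-angle kernel between two fitted systems
#'
#' Solves the generalized eigenproblem
#' \deqn{\begin{pmatrix}0 & (A^*B)^*\\ A^*B & 0\end{pmatrix} V =
#'       \lambda \begin{pmatrix}B^*B & 0\\ 0 & A^*A\end{pmatrix} V,}
#' whose spectrum comes in plus/minus pairs; the absolute values,
#' deduplicated and sorted descending, are the cosines of the principal
#' angles between the two systems' Koopman-mode subspaces. The top
#' `r_ij = min(r_i, r_j)` values (clipped to \[0, 1\]) are aggregated to a
#' scalar kernel: their product by default (the Binet-Cauchy determinant
#' form), or their sum.
#'
#' @param products list from [subspace_products()].
#' @param aggregation `"product"` (default) or `"sum"`.
#' @return List with `kernel` (scalar), `angles` (the r_ij eigenvalues,
#'   descending).
#' @export
principal_angle_kernel <- function(products, aggregation = c("product", "sum")) {
  aggregation <- match.arg(aggregation)
  AA <- products$AA; BB <- products$BB; AB <- products$AB
  ri <- nrow(AA); rj <- nrow(BB)
  lhs <- rbind(cbind(matrix(0i, rj, rj), Conj(t(AB))),
               cbind(AB, matrix(0i, ri, ri)))
  rhs <- rbind(cbind(BB, matrix(0i, rj, ri)),
               cbind(matrix(0i, ri, rj), AA))
  # regularize a numerically indefinite right-hand block
  tr <- Re(sum(diag(rhs)))
  rhs_r <- rhs + diag(1e-10 * max(abs(tr), 1), nrow(rhs))
  vals <- tryCatch(eigen(solve(rhs_r, lhs), only.values = TRUE)$values,
                   error = function(e) stop("generalized eigenproblem failed: ",
                                            conditionMessage(e)))
  av <- sort(Mod(vals), decreasing = TRUE)
  # spectrum comes in +/- pairs: keep one of each adjacent pair
  lam <- av[seq(1, length(av), by = 2)]
  rij <- min(ri, rj)
  lam <- lam[seq_len(min(rij, length(lam)))]
  lam <- pmin(pmax(lam, 0), 1)
  k <- switch(aggregation, product = prod(lam), sum = sum(lam))
  list(kernel = k, angles = lam)
}

#' Pairwise Koopman spectral kernel and distance matrices
#'
#' Fits every segment once with kernel DMD (fits are cached), computes all
#' pairwise principal-angle kernels, and derives the induced squared
#' feature-space distance
#' `dist(i, j) = k(A_i, A_i) + k(A_j, A_j) - 2 k(A_i, A_j)` (negative
#' values, possible through per-pair bandwidths, are clipped to zero with
#' a warning).
#'
#' @param sequences list of [snapshot_sequence()]s (e.g. from
#'   [game_distance_features()]), or a `segment_set` together with a
#'   `variant` to extract.
#' @param kernel a [kernel_spec()].
#' @param rank kernel-PCA rank passed to [fit_kdmd()].
#' @param aggregation passed to [principal_angle_kernel()].
#' @param variant feature variant when `sequences` is a `segment_set`.
#' @param ids optional segment identifiers.
#' @return A `koopman_kernel_matrix`: list with `K`, `D` (m x m), `ids`,
#'   `labels` (if a `segment_set` was given), `fits`, `excluded`.
#' @export
kernel_and_distance_matrix <- function(sequences, kernel = kernel_spec("gaussian"),
                                       rank = NULL,
                                       aggregation = c("product", "sum"),
                                       variant = "critical_4", ids = NULL) {
  aggregation <- match.arg(aggregation)
  labels <- NULL
  if (inherits(sequences, "segment_set")) {
    labels <- sequences$labels
    ids <- sequences$ids
    sequences <- lapply(sequences$segments, game_distance_features,
                        variant = variant)
  }
  m0 <- length(sequences)
  if (m0 < 2) stop("need at least 2 segments")
  ok <- vapply(sequences, function(s) ncol(s$values) >= 3, logical(1))
  if (!all(ok)) {
    warning(sprintf("%d segment(s) shorter than 3 frames excluded", sum(!ok)))
    sequences <- sequences[ok]
    labels <- labels[ok]
    if (!is.null(ids)) ids <- ids[ok]
  }
  m <- length(sequences)
  if (is.null(ids)) ids <- sprintf("segment_%03d", seq_len(m))
  fits <- lapply(sequences, fit_kdmd, kernel = kernel, rank = rank)
  K <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m)) {
    for (j in i:m) {
      pk <- principal_angle_kernel(subspace_products(fits[[i]], fits[[j]]),
                                   aggregation = aggregation)
      K[i, j] <- pk$kernel
      K[j, i] <- pk$kernel
    }
  }
  D <- outer(diag(K), diag(K), "+") - 2 * K
  if (any(D < 0)) {
    if (min(D) < -1e-6)
      warning(sprintf("negative squared distances down to %.3g clipped to 0",
                      min(D)))
    D[D < 0] <- 0
  }
  diag(D) <- 0
  out <- list(K = K, D = D, ids = ids, labels = labels, fits = fits,
              excluded = which(!ok))
  class(out) <- "koopman_kernel_matrix"
  out
}

#' @export
print.koopman_kernel_matrix <- function(x, ...) {
  cat(sprintf("Koopman spectral kernel matrix: %d segments\n", nrow(x$K)))
  invisible(x)
}
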