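# Classical MDS embedding of spectral-kernel distances and Gaussian
# naive-Bayes outcome prediction with stratified 5-fold cross-validation.

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, `B = -H D^2 H / 2`,
#' eigendecomposes it and returns the top `dims` coordinates with
#' non-negative eigenvalues. For exact Euclidean input distances the
#' embedded pairwise distances reproduce `D` (up to rotation/reflection).
#'
#' @param D symmetric distance matrix with zero diagonal. Note: the
#'   Koopman kernel pipeline produces *squared* feature-space distances;
#'   pass `sqrt(D)` of those when metric embedding of the induced distance
#'   is wanted, or the matrix itself to embed it as-is.
#' @param dims embedding dimension (default 2).
#' @return An `mds_embedding`: list with `points` (m x dims, centered),
#'   `eigenvalues` (all m), `stress` (relative residual of the embedded
#'   distances).
#' @export
classical_mds <- function(D, dims = 2) {
  D <- as.matrix(D)
  m <- nrow(D)
  stopifnot(ncol(D) == m, max(abs(D - t(D))) < 1e-8, all(abs(diag(D)) < 1e-8))
  H <- centering_matrix(m)
  B <- -0.5 * H %*% (D^2) %*% H
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  dims <- min(dims, m)
  lam <- eg$values[seq_len(dims)]
  lam_pos <- pmax(lam, 0)
  pts <- eg$vectors[, seq_len(dims), drop = FALSE] %*% diag(sqrt(lam_pos), dims)
  emb <- sqrt(pmax(outer(rowSums(pts^2), rowSums(pts^2), "+") -
                     2 * tcrossprod(pts), 0))
  denom <- sum(D^2)
  stress <- if (denom > 0) sqrt(sum((emb - D)^2) / denom) else 0
  res <- list(points = pts, eigenvalues = eg$values, stress = stress)
  class(res) <- "mds_embedding"
  res
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("MDS embedding: %d points in %d dims, stress %.3g\n",
              nrow(x$points), ncol(x$points), x$stress))
  invisible(x)
}

# Gaussian naive Bayes with a variance floor. x: matrix, y: factor.
gnb_train <- function(x, y, var_floor = 1e-9) {
  classes <- levels(droplevels(y))
  stats_by <- lapply(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    list(mean = colMeans(xi),
         var = pmax(apply(xi, 2, stats::var), var_floor),
         prior = nrow(xi) / nrow(x))
  })
  names(stats_by) <- classes
  stats_by
}

gnb_posterior <- function(model, x) {
  loglik <- vapply(model, function(m) {
    colSums(stats::dnorm(t(x), mean = m$mean, sd = sqrt(m$var), log = TRUE)) +
      log(m$prior)
  }, numeric(nrow(x)))
  if (is.null(dim(loglik))) loglik <- matrix(loglik, nrow = nrow(x))
  colnames(loglik) <- names(model)
  mx <- apply(loglik, 1, max)
  p <- exp(loglik - mx)
  p / rowSums(p)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over folds.
stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Cross-validated naive-Bayes prediction from a kernel matrix
#'
#' Each segment is represented by its row of the kernel matrix restricted
#' to the training-fold columns (similarities to the training set); a
#' Gaussian naive Bayes classifier with class priors from the training
#' folds predicts the held-out fold. The reported error is the median of
#' the fold error rates; confusion counts are pooled over folds. Folds are
#' stratified by label and fixed by `seed`, so results are deterministic.
#'
#' @param K m x m kernel (or similarity) matrix.
#' @param labels factor (or coercible) of length m with two levels.
#' @param folds number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param positive label treated as positive for the confusion counts;
#'   default the second factor level.
#' @param features `"kernel"` (default, rows of `K`) or `"distance"` (rows
#'   of a distance matrix passed as `K`).
#' @param var_floor Gaussian variance floor (default 1e-9).
#' @param fold_assign optional explicit fold assignment (integer vector in
#'   `1:folds`); overrides the seeded stratified assignment.
#' @return A `classification_report`: list with `fold_errors`,
#'   `median_error`, `confusion` (TP, TN, FP, FN), `posterior` (m x 2),
#'   `predicted`, `folds`, `positive`.
#' @export
nb_predict_cv <- function(K, labels, folds = 5, seed = 1, positive = NULL,
                          features = c("kernel", "distance"),
                          var_floor = 1e-9, fold_assign = NULL) {
  features <- match.arg(features)
  K <- as.matrix(K)
  m <- nrow(K)
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2) stop("need exactly two label classes")
  if (m < folds) stop("fewer segments than folds")
  if (min(table(labels)) < folds)
    stop("stratified folding impossible: a class has fewer members than folds")
  if (is.null(positive)) positive <- levels(labels)[2]
  fold_of <- if (is.null(fold_assign)) {
    with_seed(seed, stratified_folds(labels, folds))
  } else {
    stopifnot(length(fold_assign) == m, all(fold_assign %in% seq_len(folds)))
    as.integer(fold_assign)
  }
  posterior <- matrix(NA_real_, m, 2, dimnames = list(rownames(K),
                                                      levels(labels)))
  predicted <- factor(rep(NA, m), levels = levels(labels))
  fold_errors <- numeric(folds)
  for (f in seq_len(folds)) {
    test <- which(fold_of == f)
    train <- which(fold_of != f)
    X_train <- K[train, train, drop = FALSE]
    X_test <- K[test, train, drop = FALSE]
    model <- gnb_train(X_train, labels[train], var_floor)
    post <- gnb_posterior(model, X_test)
    posterior[test, colnames(post)] <- post
    pred <- factor(colnames(post)[max.col(post, ties.method = "first")],
                   levels = levels(labels))
    predicted[test] <- pred
    fold_errors[f] <- mean(pred != labels[test])
  }
  pos <- labels == positive
  ppos <- predicted == positive
  confusion <- c(TP = sum(ppos & pos), TN = sum(!ppos & !pos),
                 FP = sum(ppos & !pos), FN = sum(!ppos & pos))
  res <- list(fold_errors = fold_errors,
              median_error = stats::median(fold_errors),
              confusion = confusion, posterior = posterior,
              predicted = predicted, folds = folds, positive = positive,
              features = features)
  class(res) <- "classification_report"
  res
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Naive Bayes %d-fold CV: median error %.3f\n", x$folds,
              x$median_error))
  cat(sprintf("  confusion (positive = %s): TP %d TN %d FP %d FN %d\n",
              x$positive, x$confusion["TP"], x$confusion["TN"],
              x$confusion["FP"], x$confusion["FN"]))
  invisible(x)
}
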