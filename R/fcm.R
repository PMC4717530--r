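#' Euclidean distance matrix
#'
#' Pairwise Euclidean distances between the rows of `X`, the raw
#' environmental-space distances the fuzzy clustering operates on.
#'
#' @param X numeric matrix (n x d), no missing values.
#' @return Symmetric n x n matrix with zero diagonal.
#' @export
euclidean_distances <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows", call. = FALSE)
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite values in X",
                                           call. = FALSE)
  as.matrix(stats::dist(X, method = "euclidean"))
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centering plus eigendecomposition (Torgerson scaling). With
#' `dims = "auto"` all dimensions whose eigenvalue exceeds `1e-8` times
#' the largest are retained, so that for distances derived from Euclidean
#' coordinates the configuration reproduces the input distances exactly
#' (to numerical tolerance) and downstream clustering is unaffected by
#' the scaling step.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param dims number of dimensions, or `"auto"`.
#' @return Numeric matrix of coordinates (n x k) with attribute
#'   `eigenvalues`.
#' @export
classical_mds <- function(D, dims = "auto") {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(D)
  B <- -0.5 * scale(t(scale(t(D^2), center = TRUE, scale = FALSE)),
                    center = TRUE, scale = FALSE)
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  ev <- eg$values
  if (identical(dims, "auto")) {
    keep <- which(ev > 1e-8 * max(ev, 0))
    if (!length(keep)) keep <- 1L
  } else {
    keep <- seq_len(min(dims, n))
  }
  Y <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(pmax(ev[keep], 0)), length(keep))
  attr(Y, "eigenvalues") <- ev
  Y
}

#' Fuzzy C-means clustering
#'
#' Alternating minimization of the fuzzy objective
#' \deqn{J = \sum_i \sum_k u_{ik}^m \|x_i - c_k\|^2}
#' with membership update
#' \eqn{u_{ik} = [\sum_j (d_{ik}/d_{ij})^{2/(m-1)}]^{-1}} and weighted
#' centroid update. Memberships are initialized from a symmetric
#' Dirichlet(1) draw under the given seed. If a point coincides with one
#' or more centroids, its membership mass is split equally over the
#' zero-distance centroids. Iteration stops when the objective decreases
#' by less than `tol` or `max_iter` is reached; the objective sequence is
#' non-increasing.
#'
#' @param X numeric matrix (n x d).
#' @param K number of clusters (1 <= K <= n).
#' @param m fuzziness exponent (> 1).
#' @param seed integer seed for the membership initialization.
#' @param max_iter iteration cap.
#' @param tol absolute tolerance on the objective decrease.
#' @return An object of class `fcm_partition`: list with `memberships`
#'   (n x K, rows sum to 1), `centroids` (K x d), `m`, `objective`,
#'   `objective_trace`, `iterations`, `converged`.
#' @export
fcm <- function(X, K, m, seed = 1L, max_iter = 200L, tol = 1e-9) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite values in X",
                                           call. = FALSE)
  if (K > n) stop("K must not exceed the number of points", call. = FALSE)
  if (K < 1) stop("K must be positive", call. = FALSE)
  if (m <= 1) stop("fuzziness exponent m must exceed 1", call. = FALSE)
  set.seed(seed)
  U <- matrix(stats::rexp(n * K), n, K)
  U <- U / rowSums(U)
  J_trace <- numeric(0)
  J_prev <- Inf
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    Um <- U^m
    C <- (t(Um) %*% X) / colSums(Um)
    D2 <- outer(rowSums(X^2), rep(1, K)) - 2 * X %*% t(C) +
      outer(rep(1, n), rowSums(C^2))
    D2 <- pmax(D2, 0)
    J <- sum(Um * D2)
    J_trace <- c(J_trace, J)
    # membership update from current centroids
    zero <- D2 < .Machine$double.eps
    pow <- D2^(-1 / (m - 1))
    U_new <- pow / rowSums(pow)
    if (any(zero)) {
      zr <- which(rowSums(zero) > 0)
      for (i in zr) U_new[i, ] <- zero[i, ] / sum(zero[i, ])
    }
    U <- U_new
    if (abs(J_prev - J) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    J_prev <- J
  }
  structure(list(memberships = U, centroids = C, m = m,
                 objective = J_trace[length(J_trace)],
                 objective_trace = J_trace, iterations = iter,
                 K = K, converged = converged, seed = seed),
            class = "fcm_partition")
}

#' @export
print.fcm_partition <- function(x, ...) {
  cat(sprintf("Fuzzy C-means partition: K = %d, m = %g, J = %.6g, %d iteration(s)%s\n",
              x$K, x$m, x$objective, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
summary.fcm_partition <- function(object, ...) {
  lab <- hard_assign(object)
  cat(sprintf("Fuzzy C-means: K = %d, m = %g\n", object$K, object$m))
  cat("Hard cluster sizes:\n")
  print(table(cluster = lab))
  cat(sprintf("Objective J = %.6g after %d iterations\n",
              object$objective, object$iterations))
  invisible(object)
}

#' @export
plot.fcm_partition <- function(x, X = NULL, ...) {
  lab <- hard_assign(x)
  if (is.null(X)) {
    graphics::plot(x$objective_trace, type = "b", xlab = "iteration",
                   ylab = "objective J", main = "FCM convergence", ...)
  } else {
    Y <- classical_mds(euclidean_distances(X))
    graphics::plot(Y[, 1], Y[, min(2, ncol(Y))], col = lab, pch = 19,
                   xlab = "MDS 1", ylab = "MDS 2",
                   main = "FCM hard assignment", ...)
  }
  invisible(x)
}

#' Hard cluster assignment from a fuzzy partition
#'
#' Each point goes to its maximum-membership cluster; ties break toward
#' the lowest cluster index and the tie count is reported as an attribute.
#'
#' @param part an [fcm()] partition.
#' @return Integer label vector with attribute `ties`.
#' @export
hard_assign <- function(part) {
  U <- part$memberships
  lab <- max.col(U, ties.method = "first")
  rmax <- U[cbind(seq_len(nrow(U)), lab)]
  ties <- sum(rowSums(abs(U - rmax) < 1e-12) > 1)
  if (ties > 0) message(ties, " tied membership row(s); lowest index used")
  structure(lab, ties = ties)
}
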