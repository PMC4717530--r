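#' Principal component analysis of the environmental matrix
#'
#' Covariance-matrix PCA by default (centered, unscaled), mirroring the
#' raw-layer analysis; set `scale = TRUE` for correlation-matrix PCA. A
#' deterministic sign convention is applied: in every loading column the
#' largest-magnitude entry is positive.
#'
#' @param X numeric matrix (n x d).
#' @param center,scale centering/scaling flags (see [stats::prcomp()]).
#' @return An object of class `pca_result`: list with `loadings`
#'   (d x k, orthonormal columns), `scores` (n x k), `variance_fraction`
#'   (sums to 1), `sdev`, `center`, `scale`.
#' @export
pca <- function(X, center = TRUE, scale = FALSE) {
  X <- as.matrix(X)
  if (scale) {
    v <- apply(X, 2, stats::var)
    if (any(v == 0)) {
      stop("zero-variance column(s) with scale = TRUE: ",
           paste(colnames(X)[v == 0], collapse = ", "), call. = FALSE)
    }
  }
  p <- stats::prcomp(X, center = center, scale. = scale)
  flip <- apply(p$rotation, 2, function(col) {
    sign(col[which.max(abs(col))])
  })
  flip[flip == 0] <- 1
  loadings <- sweep(p$rotation, 2, flip, `*`)
  scores <- sweep(p$x, 2, flip, `*`)
  structure(list(loadings = loadings, scores = scores,
                 variance_fraction = p$sdev^2 / sum(p$sdev^2),
                 sdev = p$sdev,
                 center = if (isTRUE(center)) p$center else NULL,
                 scale = if (isTRUE(scale)) p$scale else NULL),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5, length(x$variance_fraction))
  cat("PCA:", ncol(x$scores), "components\n")
  cat("Variance fractions (first", k, "):",
      paste(sprintf("%.3f", x$variance_fraction[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Cluster centroids in principal-component space
#'
#' Per-cluster mean of the PC1 and PC2 scores.
#'
#' @param result a [pca()] result.
#' @param labels cluster label vector, one per score row.
#' @return Data frame with one row per cluster: `cluster`, `PC1`, `PC2`,
#'   and `n`; clusters with no members get `NA` centroids.
#' @export
cluster_centroids_in_pc_space <- function(result, labels) {
  stopifnot(length(labels) == nrow(result$scores))
  levs <- sort(unique(labels))
  out <- data.frame(cluster = levs,
                    PC1 = NA_real_, PC2 = NA_real_,
                    n = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(levs)) {
    sel <- labels == levs[i]
    out$n[i] <- sum(sel)
    if (out$n[i] > 0) {
      out$PC1[i] <- mean(result$scores[sel, 1])
      out$PC2[i] <- mean(result$scores[sel, min(2, ncol(result$scores))])
    }
  }
  out
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. The null distribution is exact
#' (enumeration via the Wilcoxon count distribution) when
#' `n1 * n2 <= 400` and there are no ties; otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used. If every value is identical across both samples, `p = 1` by
#' convention (flagged).
#'
#' @param x,y numeric samples.
#' @return List with `U` (the smaller of the two U statistics), `U_xy`,
#'   `U_yx`, `p` (two-sided), `p_less`, `p_greater`, `method`, and
#'   `degenerate` flag.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty",
                                     call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U_xy <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U_yx <- n1 * n2 - U_xy
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (length(ties) == 1L) {
    return(list(U = U_xy, U_xy = U_xy, U_yx = U_yx, p = 1,
                p_less = 1, p_greater = 1, method = "degenerate",
                degenerate = TRUE))
  }
  if (!has_ties && n1 * n2 <= 400) {
    p_less <- stats::pwilcox(U_xy, n1, n2)
    p_greater <- stats::pwilcox(U_yx, n1, n2)
    p <- min(1, 2 * min(p_less, p_greater))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    tie_term <- sum(ties^3 - ties)
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1))))
    z_less <- (U_xy - mu + 0.5) / sigma
    z_greater <- (U_yx - mu + 0.5) / sigma
    p_less <- stats::pnorm(z_less)
    p_greater <- stats::pnorm(z_greater)
    p <- min(1, 2 * min(p_less, p_greater))
    method <- "normal approximation (tie-corrected, continuity-corrected)"
  }
  list(U = min(U_xy, U_yx), U_xy = U_xy, U_yx = U_yx, p = p,
       p_less = p_less, p_greater = p_greater, method = method,
       degenerate = FALSE)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of `x` against Normal(mean(x), sd(x)), with
#' the asymptotic KS p value. Because the parameters are estimated from
#' the same data the p value is conservative (Lilliefors bias); a caveat
#' attribute records this.
#'
#' @param x numeric vector (n >= 5).
#' @return List with `D`, `p`, and `caveat`.
#' @export
ks_normality <- function(x) {
  if (length(x) < 5) stop("need at least 5 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(D = unname(kt$statistic), p = kt$p.value,
       caveat = "parameters estimated from the sample (Lilliefors bias); p is conservative")
}

#' Pairwise PC-score tests between clusters
#'
#' For every pair of clusters, Mann-Whitney U tests on the PC1 and PC2
#' scores (the non-parametric route, since PC scores routinely fail the
#' KS normality check).
#'
#' @param result a [pca()] result.
#' @param labels cluster labels per score row.
#' @return Data frame: `pair`, `component`, `U`, `p`.
#' @export
pairwise_pc_tests <- function(result, labels) {
  levs <- sort(unique(labels))
  out <- list()
  for (i in seq_along(levs)) for (j in seq_along(levs)) {
    if (j <= i) next
    for (pc in 1:2) {
      sc <- result$scores[, pc]
      mw <- mann_whitney_u(sc[labels == levs[i]], sc[labels == levs[j]])
      out[[length(out) + 1L]] <- data.frame(
        pair = paste(levs[i], levs[j], sep = "-"),
        component = paste0("PC", pc), U = mw$U, p = mw$p)
    }
  }
  do.call(rbind, out)
}
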