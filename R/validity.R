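#' Fuzzy cluster validity indices
#'
#' Computes the seven validity indices used for model selection, each
#' tagged with its optimization direction:
#' \itemize{
#' \item `PC` Bezdek's partition coefficient, \eqn{(1/n)\sum\sum u^2} (max);
#' \item `PE` Bezdek's partition entropy, \eqn{-(1/n)\sum\sum u \ln u} (min);
#' \item `XB` Xie-Beni, \eqn{J / (n \min_{k\ne l}\|c_k-c_l\|^2)} (min);
#' \item `Dunn` minimum between-cluster point distance over maximum
#'   within-cluster diameter, on the hard partition (max);
#' \item `FS` Fukuyama-Sugeno,
#'   \eqn{\sum_i\sum_k u_{ik}^m(\|x_i-c_k\|^2 - \|c_k-\bar x\|^2)} (min);
#' \item `FHV` fuzzy hypervolume, \eqn{\sum_k \sqrt{\det F_k}} with fuzzy
#'   covariance \eqn{F_k} (min);
#' \item `APD` average partition density,
#'   \eqn{(1/K)\sum_k (\sum_i u_{ik})/\sqrt{\det F_k}} (max).
#' }
#' Indices needing an inter-centroid distance (`XB`, `Dunn`) are `NaN`
#' when `K = 1`; hypervolume indices are `NA` when a fuzzy covariance is
#' numerically singular. Neither case is an error.
#'
#' @param part an [fcm()] partition fitted on `X`.
#' @param X the data matrix the partition was fitted on.
#' @return Named numeric vector of the seven indices, with attribute
#'   `direction` (named character, "max"/"min").
#' @export
validity_indices <- function(part, X) {
  X <- as.matrix(X)
  U <- part$memberships
  C <- part$centroids
  m <- part$m
  n <- nrow(U); K <- ncol(U)
  Um <- U^m
  D2 <- outer(rowSums(X^2), rep(1, K)) - 2 * X %*% t(C) +
    outer(rep(1, n), rowSums(C^2))
  D2 <- pmax(D2, 0)
  J <- sum(Um * D2)
  pc <- sum(U^2) / n
  pe <- -sum(ifelse(U > 0, U * log(U), 0)) / n
  if (K >= 2) {
    cd2 <- as.matrix(stats::dist(C))^2
    min_sep <- min(cd2[upper.tri(cd2)])
    xb <- J / (n * min_sep)
    lab <- max.col(U, ties.method = "first")
    pd <- as.matrix(stats::dist(X))
    inter <- Inf; intra <- 0
    for (k in seq_len(K)) {
      ik <- which(lab == k)
      if (length(ik) > 1) intra <- max(intra, max(pd[ik, ik]))
      for (l in seq_len(K)) {
        if (l <= k) next
        il <- which(lab == l)
        if (length(ik) && length(il)) {
          inter <- min(inter, min(pd[ik, il, drop = FALSE]))
        }
      }
    }
    dunn <- if (is.finite(inter) && intra > 0) inter / intra else NaN
  } else {
    xb <- NaN; dunn <- NaN
  }
  xbar <- colMeans(X)
  fs <- J - sum(colSums(Um) * rowSums(sweep(C, 2, xbar)^2))
  dets <- vapply(seq_len(K), function(k) {
    Xc <- sweep(X, 2, C[k, ])
    Fk <- crossprod(Xc * Um[, k], Xc) / sum(Um[, k])
    d <- det(Fk)
    if (!is.finite(d) || d <= 0) NA_real_ else d
  }, numeric(1))
  fhv <- if (anyNA(dets)) NA_real_ else sum(sqrt(dets))
  apd <- if (anyNA(dets)) NA_real_ else mean(colSums(U) / sqrt(dets))
  out <- c(PC = pc, PE = pe, XB = xb, Dunn = dunn, FS = fs, FHV = fhv,
           APD = apd)
  attr(out, "direction") <- c(PC = "max", PE = "min", XB = "min",
                              Dunn = "max", FS = "min", FHV = "min",
                              APD = "max")
  out
}

#' Validity sweep over cluster number and fuzziness
#'
#' Runs one [fcm()] fit per (K, m) combination (seed policy: the sweep
#' seed plus the combination index), scores each with the seven validity
#' indices, records every index's optimum, and selects the consensus
#' combination: the one "supported" by the most indices, where an index
#' supports the combinations ranked 1 or 2 (optimal or next-to-optimal)
#' in its direction. Ties break toward smaller K, then smaller m.
#'
#' @param X data matrix.
#' @param k_range integer vector of cluster numbers (default 2..15).
#' @param m_grid fuzziness grid (default 1.1..2.0 in steps of 0.1).
#' @param seed sweep seed.
#' @param max_iter,tol passed to [fcm()].
#' @return An object of class `validity_report`: list with `table`
#'   (one row per combination: K, m, the seven indices, `failed`),
#'   `optima` (per-index best K, m), `support` counts, and `consensus`
#'   (list with `K` and `m`).
#' @export
model_selection_sweep <- function(X, k_range = 2:15,
                                  m_grid = seq(1.1, 2.0, by = 0.1),
                                  seed = 1L, max_iter = 200L, tol = 1e-9) {
  if (!length(k_range) || !length(m_grid)) {
    stop("empty K range or m grid", call. = FALSE)
  }
  combos <- expand.grid(m = m_grid, K = as.integer(k_range),
                        KEEP.OUT.ATTRS = FALSE)[, c("K", "m")]
  idx_names <- c("PC", "PE", "XB", "Dunn", "FS", "FHV", "APD")
  tab <- cbind(combos, matrix(NA_real_, nrow(combos), length(idx_names),
                              dimnames = list(NULL, idx_names)),
               failed = FALSE)
  direction <- NULL
  for (i in seq_len(nrow(combos))) {
    res <- tryCatch({
      part <- fcm(X, K = combos$K[i], m = combos$m[i], seed = seed + i,
                  max_iter = max_iter, tol = tol)
      validity_indices(part, X)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      tab$failed[i] <- TRUE
    } else {
      tab[i, idx_names] <- as.numeric(res)
      if (is.null(direction)) direction <- attr(res, "direction")
    }
  }
  support <- integer(nrow(tab))
  optima <- list()
  for (nm in idx_names) {
    v <- tab[[nm]]
    if (all(!is.finite(v))) next
    sgn <- if (direction[[nm]] == "max") -1 else 1
    rk <- rank(sgn * v, ties.method = "min", na.last = "keep")
    top <- which(!is.na(rk) & rk <= 2)
    support[top] <- support[top] + 1L
    best <- which.min(rank(sgn * v, ties.method = "first",
                           na.last = "keep"))
    optima[[nm]] <- list(K = tab$K[best], m = tab$m[best],
                         value = v[best])
  }
  ord <- order(-support, tab$K, tab$m)
  cons <- ord[1]
  structure(list(table = tab, optima = optima, support = support,
                 consensus = list(K = tab$K[cons], m = tab$m[cons],
                                  n_support = support[cons]),
                 direction = direction, seed = seed),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("Validity sweep: %d combinations (K in %s, m in %s)\n",
              nrow(x$table), paste(range(x$table$K), collapse = ".."),
              paste(range(x$table$m), collapse = "..")))
  for (nm in names(x$optima)) {
    cat(sprintf("  %-5s (%s) optimum at K = %d, m = %.1f\n", nm,
                x$direction[[nm]], x$optima[[nm]]$K, x$optima[[nm]]$m))
  }
  cat(sprintf("Consensus: K = %d, m = %.1f (supported by %d index/indices)\n",
              x$consensus$K, x$consensus$m, x$consensus$n_support))
  invisible(x)
}
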