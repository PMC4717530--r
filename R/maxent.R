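#' Fit a simplified maximum-entropy niche model
#'
#' Presence-background maximum entropy with linear and quadratic feature
#' classes only. Every environmental variable is min-max standardized to
#' \[0, 1\] over the masked cells; its square is the quadratic feature.
#' The model maximizes the concave penalized log-likelihood
#' \deqn{\frac{1}{|P|}\sum_{i \in P} \lambda \cdot f(x_i) - \log Z(\lambda)
#'   - \beta \sum_j s_j |\lambda_j|}
#' where the background is the full set of masked cells and
#' \eqn{s_j = \mathrm{sd}_P(f_j)/\sqrt{|P|}} scales the L1 penalty per
#' feature. Optimization is by proximal (ISTA) gradient ascent with
#' backtracking; convergence is declared when the L1-subgradient
#' optimality residual falls below `tol` in the infinity norm.
#'
#' The raw output is the maxent distribution
#' \eqn{\exp(\lambda \cdot f)/Z} over masked cells (sums to 1); the
#' logistic output applies the entropy transform
#' \eqn{e^H \mathrm{raw}/(1 + e^H \mathrm{raw})} with \eqn{H} the entropy
#' of the raw distribution.
#'
#' @param presences 2-column matrix of 0-based (row, col) presence cells
#'   (must be masked cells; at least 5).
#' @param grid an [env_grid()].
#' @param beta non-negative L1 regularization multiplier.
#' @param tol convergence tolerance on the optimality residual.
#' @param max_iter iteration cap.
#' @return An object of class `maxent_enm`: list with `lambda` (feature
#'   weights), `features` (definition table), `logZ`, `entropy`, `raw`
#'   and `logistic` (vectors over masked cells, row-major), `cells`
#'   (masked cell indices), plus standardization ranges.
#' @export
fit_maxent <- function(presences, grid, beta = 1.0, tol = 1e-6,
                       max_iter = 1e5) {
  presences <- matrix(as.integer(presences), ncol = 2)
  if (nrow(presences) < 5) stop("need at least 5 presence cells",
                                call. = FALSE)
  cells <- grid_masked_cells(grid)
  key <- function(m) m[, 1] * grid$ncol + m[, 2]
  pres_idx <- match(key(presences), key(cells))
  if (anyNA(pres_idx)) stop("presence cells must lie inside the mask",
                            call. = FALSE)
  E <- grid_env_at(grid, cells)
  rng_lo <- apply(E, 2, min); rng_hi <- apply(E, 2, max)
  span <- pmax(rng_hi - rng_lo, .Machine$double.eps)
  S <- sweep(sweep(E, 2, rng_lo), 2, span, `/`)
  FZ <- cbind(S, S^2)
  feat_names <- c(paste0(colnames(E), ".lin"), paste0(colnames(E), ".quad"))
  colnames(FZ) <- feat_names
  FP <- FZ[pres_idx, , drop = FALSE]
  npres <- nrow(FP)
  fbar <- colMeans(FP)
  # per-feature penalty scale: SD over presences, floored so features
  # that are constant across presences (SD 0) cannot drive the weight to
  # infinity in separable configurations
  s_j <- pmax(apply(FP, 2, stats::sd), 0.05) / sqrt(npres)
  pen <- beta * s_j
  # FISTA (accelerated proximal gradient with function-value restart) on
  # the negated objective; momentum cuts the iteration count by orders of
  # magnitude relative to plain proximal steps
  smooth_obj <- function(lam) {
    eta <- as.numeric(FZ %*% lam)
    mx <- max(eta)
    sum(fbar * lam) - (mx + log(sum(exp(eta - mx))))
  }
  grad_at <- function(lam) {
    eta <- as.numeric(FZ %*% lam)
    w <- exp(eta - max(eta))
    fbar - as.numeric(crossprod(FZ, w / sum(w)))
  }
  full_obj <- function(lam) smooth_obj(lam) - sum(pen * abs(lam))
  lambda <- lambda_prev <- numeric(ncol(FZ))
  tk <- 1
  step <- 1
  converged <- FALSE
  iter <- 0L
  resid <- Inf
  obj_cur <- full_obj(lambda)
  repeat {
    iter <- iter + 1L
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- lambda + ((tk - 1) / tk_new) * (lambda - lambda_prev)
    gy <- grad_at(y)
    g0 <- smooth_obj(y)
    repeat {
      cand <- y + step * gy
      cand <- sign(cand) * pmax(abs(cand) - step * pen, 0)
      d <- cand - y
      if (smooth_obj(cand) >= g0 + sum(gy * d) - sum(d^2) / (2 * step) ||
          sqrt(sum(d^2)) < 1e-15) break
      step <- step / 2
    }
    lambda_prev <- lambda
    lambda <- cand
    tk <- tk_new
    obj_new <- full_obj(lambda)
    if (obj_new < obj_cur) tk <- 1  # adaptive restart
    obj_cur <- obj_new
    step <- min(step * 1.2, 1e3)
    if (iter %% 10L == 0L || iter <= 2L) {
      grad <- grad_at(lambda)
      resid <- ifelse(lambda != 0, abs(grad - pen * sign(lambda)),
                      pmax(abs(grad) - pen, 0))
      if (max(resid) < tol) { converged <- TRUE; break }
    }
    if (iter >= max_iter) break
  }
  if (!converged) {
    stop(sprintf(
      "maxent optimizer did not converge in %d iterations (residual %.3g)",
      as.integer(max_iter), max(resid)), call. = FALSE)
  }
  eta <- as.numeric(FZ %*% lambda)
  mx <- max(eta)
  logZ <- mx + log(sum(exp(eta - mx)))
  raw <- exp(eta - logZ)
  H <- -sum(ifelse(raw > 0, raw * log(raw), 0))
  logistic <- exp(H) * raw / (1 + exp(H) * raw)
  structure(list(lambda = setNames(as.numeric(lambda), feat_names),
                 features = data.frame(
                   variable = rep(colnames(E), 2),
                   class = rep(c("linear", "quadratic"), each = ncol(E))),
                 logZ = logZ, entropy = H, raw = raw, logistic = logistic,
                 cells = cells, presence_index = pres_idx, beta = beta,
                 range_lo = rng_lo, range_hi = rng_hi,
                 iterations = iter, converged = converged),
            class = "maxent_enm")
}

#' @export
print.maxent_enm <- function(x, ...) {
  cat(sprintf("Maximum-entropy niche model: %d features, beta = %g\n",
              length(x$lambda), x$beta))
  cat(sprintf("  %d presence cells over %d background cells; entropy H = %.4f\n",
              length(x$presence_index), nrow(x$cells), x$entropy))
  nz <- sum(x$lambda != 0)
  cat(sprintf("  %d non-zero weights; converged in %d iterations\n",
              nz, x$iterations))
  invisible(x)
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed from ranks (the Mann-Whitney
#' statistic) with midrank tie handling: wins plus half-ties over all
#' presence-background pairs.
#'
#' @param scores_presence,scores_background numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores_presence, scores_background) {
  n1 <- length(scores_presence); n2 <- length(scores_background)
  if (!n1 || !n2) stop("both score vectors must be non-empty", call. = FALSE)
  r <- rank(c(scores_presence, scores_background))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Bootstrap evaluation of a niche model
#'
#' Repeated random presence splits (default 70% training / 30% testing):
#' the model is refitted on the training cells and scored by the AUC of
#' the held-out presences against the full background. The model is
#' flagged for removal when the mean AUC falls below 0.7.
#'
#' @param presences 2-column matrix of 0-based presence cells (>= 10).
#' @param grid an [env_grid()].
#' @param replicates number of bootstrap replicates.
#' @param train_frac training fraction in (0, 1).
#' @param seed integer seed.
#' @param beta L1 regularization passed to [fit_maxent()].
#' @return List with `mean_auc`, `sd_auc`, `aucs` (per replicate), and
#'   `flag` ("keep" or "remove").
#' @export
bootstrap_eval <- function(presences, grid, replicates = 100L,
                           train_frac = 0.7, seed = 1L, beta = 1.0) {
  presences <- matrix(as.integer(presences), ncol = 2)
  n <- nrow(presences)
  if (n < 10) stop("need at least 10 presences for bootstrap evaluation",
                   call. = FALSE)
  set.seed(seed)
  aucs <- rep(NA_real_, replicates)
  for (r in seq_len(replicates)) {
    tr <- sample.int(n, max(5L, floor(train_frac * n)))
    te <- setdiff(seq_len(n), tr)
    if (!length(te)) {
      message("replicate ", r, " skipped: empty test split")
      next
    }
    mod <- fit_maxent(presences[tr, , drop = FALSE], grid, beta = beta)
    sc <- predict(mod, presences[te, , drop = FALSE], grid)
    aucs[r] <- auc(sc, mod$logistic)
  }
  ok <- aucs[!is.na(aucs)]
  m <- mean(ok)
  list(mean_auc = m, sd_auc = stats::sd(ok), aucs = aucs,
       flag = if (m < 0.7) "remove" else "keep")
}

#' Predict suitability at cells
#'
#' @param object a fitted `maxent_enm`.
#' @param cells 2-column matrix of 0-based (row, col) cells.
#' @param grid the [env_grid()] the model was fitted on.
#' @param type "logistic" (default) or "raw".
#' @param ... unused.
#' @return Numeric suitability vector.
#' @export
predict.maxent_enm <- function(object, cells, grid, type = "logistic", ...) {
  cells <- matrix(as.integer(cells), ncol = 2)
  key <- function(m) m[, 1] * grid$ncol + m[, 2]
  idx <- match(key(cells), key(object$cells))
  if (anyNA(idx)) stop("cells outside the fitted mask", call. = FALSE)
  switch(type, logistic = object$logistic[idx], raw = object$raw[idx],
         stop("unknown prediction type", call. = FALSE))
}

#' Maximum sensitivity-plus-specificity threshold
#'
#' Scans the sorted unique logistic suitability values as candidate
#' thresholds and returns the one maximizing training sensitivity
#' (fraction of presences at or above the threshold) plus specificity
#' (fraction of background cells below it, background treated as
#' pseudo-absence). Ties break toward the larger threshold.
#'
#' @param model a fitted `maxent_enm`.
#' @return The threshold, with attribute `sens_spec` (the achieved sum).
#' @export
max_sss_threshold <- function(model) {
  max_sss(model$logistic[model$presence_index], model$logistic)
}

#' @rdname max_sss_threshold
#' @param pres_scores,bg_scores logistic suitability of presences and of
#'   the background (pseudo-absences); candidate thresholds are the
#'   sorted unique values of both.
#' @export
max_sss <- function(pres_scores, bg_scores) {
  cand <- sort(unique(c(pres_scores, bg_scores)))
  best <- -Inf; best_tau <- cand[1]
  for (tau in cand) {
    v <- mean(pres_scores >= tau) + mean(bg_scores < tau)
    if (v >= best) { best <- v; best_tau <- tau }
  }
  structure(best_tau, sens_spec = best)
}

#' Binary range map from a threshold
#'
#' @param model a fitted `maxent_enm`.
#' @param tau logistic threshold.
#' @return Logical vector over the model's masked cells (row-major),
#'   `TRUE` where logistic suitability >= `tau`, with attribute `cells`.
#' @export
binarize <- function(model, tau) {
  structure(model$logistic >= tau, cells = model$cells)
}

#' Range overlap between binary maps
#'
#' Jaccard overlap: 100 x |X intersect Y| / |X union Y|. Both maps must
#' be defined on the same mask. With `metric = "smaller"` the denominator
#' is the smaller range instead.
#'
#' @param map_x,map_y logical vectors from [binarize()] on a shared mask.
#' @param metric "jaccard" (default) or "smaller".
#' @return Overlap percentage; `NaN` (flagged by a message) when both
#'   maps are empty.
#' @export
range_overlap <- function(map_x, map_y, metric = c("jaccard", "smaller")) {
  metric <- match.arg(metric)
  if (length(map_x) != length(map_y)) {
    stop("maps must share one mask", call. = FALSE)
  }
  inter <- sum(map_x & map_y)
  denom <- switch(metric,
                  jaccard = sum(map_x | map_y),
                  smaller = min(sum(map_x), sum(map_y)))
  if (denom == 0) {
    message("both ranges empty; overlap undefined")
    return(NaN)
  }
  100 * inter / denom
}

#' Predicted niche occupancy (PNO) profile
#'
#' The unit-area histogram of an environmental variable weighted by the
#' model's raw (normalized) suitability: bins span the variable's range
#' over masked cells, each bin weight is the summed raw suitability of
#' its cells, and weights are renormalized to sum to 1.
#'
#' @param model a fitted `maxent_enm`.
#' @param grid the [env_grid()] the model was fitted on.
#' @param variable environmental variable name.
#' @param bins number of bins (default 50).
#' @return An object of class `pno_profile`: list with `variable`,
#'   `edges` (length bins + 1), `mid`, and `weights` (sum to 1). A
#'   constant variable collapses to a single flagged bin.
#' @export
pno_profile <- function(model, grid, variable, bins = 50L) {
  if (!variable %in% unclass(env_variable_set())) {
    stop("unknown variable ", variable, call. = FALSE)
  }
  v <- grid_env_at(grid, model$cells)[, variable]
  lo <- min(v); hi <- max(v)
  if (hi - lo < .Machine$double.eps) {
    message("variable ", variable, " is constant; single-bin profile")
    return(structure(list(variable = variable, edges = c(lo, lo + 1),
                          mid = lo + 0.5, weights = 1, constant = TRUE),
                     class = "pno_profile"))
  }
  edges <- seq(lo, hi, length.out = bins + 1)
  bin <- pmin(findInterval(v, edges, rightmost.closed = TRUE), bins)
  w <- vapply(seq_len(bins), function(b) sum(model$raw[bin == b]),
              numeric(1))
  w <- w / sum(w)
  structure(list(variable = variable, edges = edges,
                 mid = (edges[-1] + edges[-length(edges)]) / 2,
                 weights = w, constant = FALSE), class = "pno_profile")
}

#' Weighted median of a PNO profile
#'
#' @param profile a [pno_profile()].
#' @return The suitability-weighted median of the variable.
#' @export
pno_median <- function(profile) {
  cw <- cumsum(profile$weights)
  profile$mid[which(cw >= 0.5)[1]]
}

#' @export
print.pno_profile <- function(x, ...) {
  cat(sprintf("PNO profile for %s: %d bins, weighted median %.4g\n",
              x$variable, length(x$weights), pno_median(x)))
  invisible(x)
}

#' @export
plot.pno_profile <- function(x, ...) {
  graphics::plot(x$mid, x$weights, type = "h", xlab = x$variable,
                 ylab = "suitability weight", main = "PNO profile", ...)
  invisible(x)
}
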