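#' Phylogenetic covariance matrix
#'
#' Under Brownian motion on an ultrametric tree the trait covariance of
#' tips i and j is the shared path length from the root to their MRCA;
#' the diagonal is the root age.
#'
#' @param tree a dated tree.
#' @return n x n matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree) {
  ape::vcv.phylo(tree)
}

#' Blomberg's K
#'
#' The ratio of the observed mean squared error of tip values around the
#' phylogenetically weighted mean (computed against the star phylogeny)
#' to the mean squared error under the tree's Brownian covariance,
#' standardized by its Brownian-motion expectation, so that K = 1 under
#' Brownian evolution, K < 1 for less similarity among relatives than
#' Brownian expectation, K > 1 for more.
#'
#' @param tree a dated tree (n >= 3 tips).
#' @param trait named numeric vector over the tips (variance > 0).
#' @return The K statistic.
#' @export
blomberg_k <- function(tree, trait) {
  n <- length(tree$tip.label)
  if (n < 3) stop("need at least 3 tips", call. = FALSE)
  x <- trait[tree$tip.label]
  if (anyNA(x)) stop("trait missing for some tips", call. = FALSE)
  if (stats::var(x) == 0) {
    warning("zero trait variance; K undefined")
    return(NaN)
  }
  V <- phylo_covariance(tree)
  Vi <- solve(V)
  one <- rep(1, n)
  denom_a <- as.numeric(t(one) %*% Vi %*% one)
  a_hat <- as.numeric(t(one) %*% Vi %*% x) / denom_a
  dev <- x - a_hat
  mse0 <- sum(dev^2) / (n - 1)
  mse <- as.numeric(t(dev) %*% Vi %*% dev) / (n - 1)
  expected <- (sum(diag(V)) - n / denom_a) / (n - 1)
  (mse0 / mse) / expected
}

#' Permutation test for phylogenetic signal
#'
#' The test statistic is the variance of the standardized
#' phylogenetically independent contrasts; observed contrast variance
#' lower than that of traits shuffled across the tips indicates signal.
#' One-sided by default:
#' \eqn{p = (1 + \#\{\mathrm{perm} \le \mathrm{obs}\})/(n_{perm}+1)}.
#'
#' @param tree a dated tree.
#' @param trait named numeric vector over tips.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param two_sided if `TRUE`, doubles the smaller tail.
#' @return The p value, with attribute `observed` (contrast variance).
#' @export
permutation_p <- function(tree, trait, n_perm = 999L, seed = 1L,
                          two_sided = FALSE) {
  x <- trait[tree$tip.label]
  if (anyNA(x)) stop("trait missing for some tips", call. = FALSE)
  obs <- stats::var(ape::pic(x, tree))
  set.seed(seed)
  vals <- as.numeric(x)  # strip names: pic would re-match shuffled names
  perm <- vapply(seq_len(n_perm), function(i) {
    stats::var(ape::pic(setNames(sample(vals), tree$tip.label), tree))
  }, numeric(1))
  p_low <- (1 + sum(perm <= obs)) / (n_perm + 1)
  p <- if (two_sided) {
    p_high <- (1 + sum(perm >= obs)) / (n_perm + 1)
    min(1, 2 * min(p_low, p_high))
  } else p_low
  structure(p, observed = obs)
}

#' Species trait table for signal testing
#'
#' Per-species traits: the median of each of the 20 environmental
#' variables over the species' localities, plus PC1 and PC2 set to the
#' principal-component centroid of the species' primary niche cluster
#' (so species sharing a cluster share identical PC traits, a deliberate
#' property of the trait construction).
#'
#' @param occ an [occurrence_table()].
#' @param labels per-record cluster labels (values "A"/"B"/"C" or
#'   integers).
#' @param pca_result a [pca()] of the same records.
#' @param coding a [apply_coding()] result giving each species' primary
#'   cluster via its counts.
#' @param species species to include (default: every species in `occ`);
#'   lets a tree's tip set select a subset while centroids still come
#'   from the full ordination.
#' @return Data frame, one row per species: `species`, 20 env medians,
#'   `PC1`, `PC2`.
#' @export
build_trait_table <- function(occ, labels, pca_result, coding,
                              species = unique(occ$species)) {
  stopifnot(length(labels) == nrow(occ))
  cents <- cluster_centroids_in_pc_space(pca_result, labels)
  E <- env_matrix(occ)
  no_rec <- setdiff(species, unique(occ$species))
  if (length(no_rec)) {
    stop("species without localities: ", paste(no_rec, collapse = ", "),
         call. = FALSE)
  }
  if (length(setdiff(species, coding$species))) {
    stop("species without coding: ",
         paste(setdiff(species, coding$species), collapse = ", "),
         call. = FALSE)
  }
  med <- t(vapply(species, function(sp) {
    apply(E[occ$species == sp, , drop = FALSE], 2, stats::median)
  }, numeric(ncol(E))))
  cnt <- as.matrix(coding[match(species, coding$species),
                          c("nA", "nB", "nC")])
  primary <- c("A", "B", "C")[max.col(cnt, ties.method = "first")]
  ci <- match(primary, cents$cluster)
  if (anyNA(ci)) stop("primary cluster missing from labels", call. = FALSE)
  out <- data.frame(species = species, med, PC1 = cents$PC1[ci],
                    PC2 = cents$PC2[ci], check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Phylogenetic signal over a tree ensemble
#'
#' Blomberg's K and the permutation p value for every trait on every
#' tree; summarized per trait as the median K, the median p, and the
#' percentage of trees on which the null of no signal is not rejected
#' (p > 0.05). Per-tree seeds are derived deterministically from the
#' master seed and tree index, so results do not depend on execution
#' order.
#'
#' @param ensemble a [tree_ensemble()].
#' @param traits a [build_trait_table()] data frame (column `species`
#'   matching the tip labels).
#' @param n_perm permutations per tree (default 999).
#' @param seed master seed.
#' @return An object of class `signal_result`: data frame with `trait`,
#'   `median_K`, `median_p`, `pct_not_rejecting`, `n_trees`.
#' @export
signal_over_trees <- function(ensemble, traits, n_perm = 999L, seed = 1L) {
  if (inherits(ensemble, "phylo")) ensemble <- tree_ensemble(list(ensemble))
  tipset <- sort(ensemble[[1]]$tip.label)
  if (!setequal(tipset, traits$species)) {
    stop("trait table species must match the tree tip set", call. = FALSE)
  }
  trait_names <- setdiff(names(traits), "species")
  res <- lapply(trait_names, function(tn) {
    tr <- setNames(traits[[tn]], traits$species)
    ks <- rep(NA_real_, length(ensemble))
    ps <- rep(NA_real_, length(ensemble))
    for (i in seq_along(ensemble)) {
      out <- tryCatch({
        k <- blomberg_k(ensemble[[i]], tr)
        p <- permutation_p(ensemble[[i]], tr, n_perm = n_perm,
                           seed = derive_seed(seed, i))
        c(k, p)
      }, error = function(e) {
        message("tree ", i, " skipped for trait ", tn, ": ",
                conditionMessage(e))
        c(NA_real_, NA_real_)
      })
      ks[i] <- out[1]; ps[i] <- out[2]
    }
    ok <- !is.na(ps)
    data.frame(trait = tn,
               median_K = stats::median(ks[ok]),
               median_p = stats::median(ps[ok]),
               pct_not_rejecting = 100 * mean(ps[ok] > 0.05),
               n_trees = sum(ok))
  })
  out <- do.call(rbind, res)
  class(out) <- c("signal_result", "data.frame")
  out
}
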