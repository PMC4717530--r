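#' Mk transition-rate parameter set
#'
#' Six instantaneous transition rates between the three niche states with
#' an optional constraint mask (rates fixed to zero), the exponential
#' hyperprior mean, and the root state prior (uniform by default, the
#' common Multistate choice).
#'
#' @param rates named numeric vector with entries `qAB`, `qAC`, `qBA`,
#'   `qBC`, `qCA`, `qCB` (per Ma).
#' @param constrained character vector of constrained pairs, e.g.
#'   `c("CA", "CB")`; those rates are forced to exactly zero.
#' @param mu hyperprior mean in (0, 30].
#' @param pi root state prior (length 3, summing to 1).
#' @return An object of class `mk_parameters`.
#' @export
mk_parameters <- function(rates, constrained = character(), mu = 1,
                          pi = c(1, 1, 1) / 3) {
  nm <- c("qAB", "qAC", "qBA", "qBC", "qCA", "qCB")
  stopifnot(all(nm %in% names(rates)), all(rates[nm] >= 0),
            mu > 0, length(pi) == 3, all(pi >= 0))
  rates <- rates[nm]
  constrained <- toupper(gsub("^q", "", constrained))
  bad <- setdiff(constrained, c("AB", "AC", "BA", "BC", "CA", "CB"))
  if (length(bad)) stop("unknown constrained pair(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  rates[paste0("q", constrained)] <- 0
  structure(list(rates = rates, constrained = constrained, mu = mu,
                 pi = pi / sum(pi)), class = "mk_parameters")
}

#' Transition probability matrix
#'
#' \eqn{P(t) = \exp(Qt)} with off-diagonal generator entries equal to the
#' rates and diagonals the negative row sums. Entries are clamped at zero
#' and rows renormalized to absorb eigendecomposition round-off; rows sum
#' to 1 within 1e-10.
#'
#' @param params an [mk_parameters()] (or a [sim_q()]).
#' @param t elapsed time in Ma (>= 0).
#' @return 3x3 matrix over states A, B, C.
#' @export
transition_matrix <- function(params, t) {
  if (t < 0) stop("t must be non-negative", call. = FALSE)
  Q <- if (inherits(params, "sim_q")) q_matrix(params)
       else q_matrix(setNames(params$rates,
                              c("qAB", "qAC", "qBA", "qBC", "qCA", "qCB")))
  P <- cpp_transition_matrix(Q, t)
  P <- P / rowSums(P)
  dimnames(P) <- list(c("A", "B", "C"), c("A", "B", "C"))
  P
}

# internal: indicator partial-likelihood rows for coded (possibly
# ambiguous) tips, ordered by the tree's tip labels
tip_partials_from_coding <- function(tree, coding) {
  states <- c("A", "B", "C")
  sets <- strsplit(coding$states, "|", fixed = TRUE)
  names(sets) <- coding$species
  missing <- setdiff(tree$tip.label, coding$species)
  if (length(missing)) {
    stop("tip(s) without coding: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  t(vapply(tree$tip.label, function(tp) {
    as.numeric(states %in% sets[[tp]])
  }, numeric(3)))
}

# internal: postorder edge representation for the C++ core
tree_for_cpp <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = matrix(as.integer(po$edge), ncol = 2),
       edge_length = as.numeric(po$edge.length),
       ntip = length(po$tip.label))
}

#' Pruning log-likelihood of coded tip states
#'
#' Felsenstein's pruning algorithm with ambiguous (polymorphic) tips:
#' each tip's partial likelihood is the indicator of its coded state set,
#' combined at the root with the root prior.
#'
#' @param tree a dated tree.
#' @param coding a [apply_coding()] result covering all tips.
#' @param params an [mk_parameters()].
#' @return Log-likelihood (natural log).
#' @export
pruning_log_likelihood <- function(tree, coding, params) {
  tp <- tip_partials_from_coding(tree, coding)
  tr <- tree_for_cpp(tree)
  Q <- q_matrix(setNames(params$rates,
                         c("qAB", "qAC", "qBA", "qBC", "qCA", "qCB")))
  cpp_pruning_loglik(tr$edge, tr$edge_length, tr$ntip, tp, Q, params$pi)
}

#' The transition-model family
#'
#' The eight models compared by the Bayes-factor analysis: the
#' unconstrained full model, the six single-rate-zero models, and the
#' model with both transitions out of state C set to zero.
#'
#' @return Named list of constraint vectors.
#' @export
mk_models <- function() {
  list(full = character(0),
       qAB0 = "AB", qAC0 = "AC", qBA0 = "BA",
       qBC0 = "BC", qCA0 = "CA", qCB0 = "CB",
       qC0 = c("CB", "CA"))
}

#' MCMC over Mk transition rates
#'
#' Metropolis-Hastings sampling of the six transition rates (and the tree
#' index when an ensemble is supplied) under an exponential rate prior
#' whose mean is itself sampled (uniform hyperprior on (0, hyper_max]).
#' Per iteration one move is chosen uniformly: a window perturbation of
#' one random unconstrained rate (width `ratedev`, negative proposals
#' rejected), a window update of the hyperprior mean, or a uniform redraw
#' of the tree index. Defaults mirror the study-scale settings
#' (see [analysis_config()]); reduced chains are obtained by passing a
#' smaller `generations`.
#'
#' @param trees a [tree_ensemble()] (or single dated tree).
#' @param coding a [apply_coding()] result for the shared tip set.
#' @param constrained constraint vector (see [mk_parameters()]), or a
#'   name from [mk_models()].
#' @param generations,burnin,thin,ratedev,hyper_max chain settings.
#' @param mu_window half-width of the hyperprior-mean proposal window.
#' @param pi root prior.
#' @param seed integer seed.
#' @return An object of class `mk_posterior`: list with `samples` (data
#'   frame: iteration, six rates, mu, tree, loglik), `acceptance`,
#'   `constrained`, `settings`, `data_signature`.
#' @export
mk_mcmc <- function(trees, coding, constrained = character(),
                    generations = 5050000, burnin = 50000, thin = 1000,
                    ratedev = 250, hyper_max = 30, mu_window = 2,
                    pi = c(1, 1, 1) / 3, seed = 1L) {
  if (inherits(trees, "phylo")) trees <- tree_ensemble(list(trees))
  if (is.character(constrained) && length(constrained) == 1 &&
      constrained %in% names(mk_models())) {
    constrained <- mk_models()[[constrained]]
  }
  constrained <- toupper(gsub("^q", "", constrained))
  nm <- c("AB", "AC", "BA", "BC", "CA", "CB")
  free <- !(nm %in% constrained)
  if (!any(free)) stop("at least one rate must be unconstrained",
                       call. = FALSE)
  cpp_trees <- lapply(trees, tree_for_cpp)
  partials <- lapply(trees, tip_partials_from_coding, coding = coding)
  set.seed(seed)
  init_mu <- stats::runif(1, 0, hyper_max)
  # start free rates at a modest fixed value: chains started from prior
  # draws can need very long burn-ins when the draw lands far above the
  # likelihood peak, which biases harmonic-mean estimates
  init_rates <- ifelse(free, 1, 0)
  res <- cpp_mcmc(cpp_trees, partials, free, generations, burnin, thin,
                  ratedev, hyper_max, mu_window, init_rates, init_mu,
                  sample.int(length(trees), 1) - 1L, pi / sum(pi))
  s <- as.data.frame(res$samples)
  names(s) <- c("iteration", paste0("q", nm), "mu", "tree", "loglik")
  if (any(vapply(paste0("q", constrained), function(cn) any(s[[cn]] != 0),
                 logical(1)))) {
    stop("internal error: constrained rate sampled non-zero")
  }
  structure(list(samples = s, acceptance = setNames(
    as.numeric(res$acceptance), c("rate", "mu", "tree")),
    constrained = constrained,
    settings = list(generations = generations, burnin = burnin,
                    thin = thin, ratedev = ratedev,
                    hyper_max = hyper_max, mu_window = mu_window,
                    seed = seed, pi = pi / sum(pi)),
    data_signature = paste(sort(trees[[1]]$tip.label), collapse = ";"),
    n_trees = length(trees)), class = "mk_posterior")
}

#' @export
print.mk_posterior <- function(x, ...) {
  cat(sprintf("Mk posterior: %d samples (%g generations, burn-in %g, thin %g)\n",
              nrow(x$samples), x$settings$generations, x$settings$burnin,
              x$settings$thin))
  if (length(x$constrained)) {
    cat("  constrained to zero:",
        paste0("q", x$constrained, collapse = ", "), "\n")
  }
  cat("  acceptance rates:",
      paste(sprintf("%s %.2f", names(x$acceptance), x$acceptance),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mk_posterior <- function(object, ...) {
  print(object)
  cat("Posterior rate means (per Ma):\n")
  print(round(coef(object), 4))
  hm <- harmonic_mean_log_ml(object)
  cat(sprintf("Harmonic-mean log marginal likelihood: %.3f (SE %.3f)\n",
              hm$logML, hm$SE))
  invisible(object)
}

#' @export
coef.mk_posterior <- function(object, ...) {
  colMeans(object$samples[, paste0("q", c("AB", "AC", "BA", "BC",
                                          "CA", "CB"))])
}

#' @export
plot.mk_posterior <- function(x, ...) {
  graphics::plot(x$samples$iteration, x$samples$loglik, type = "l",
                 xlab = "generation", ylab = "log-likelihood",
                 main = "Mk MCMC trace", ...)
  invisible(x)
}

#' Harmonic-mean log marginal likelihood
#'
#' \eqn{\log \hat m = -\log \mathrm{mean}(\exp(-\log L_s))} over the
#' post-burn-in samples, computed with log-sum-exp stabilization. The
#' standard error comes from a moving-block bootstrap (1000 resamples of
#' contiguous blocks), which respects the chain's autocorrelation. The
#' estimator is known to be high-variance; it is used for comparability
#' with the reference transition-model tests.
#'
#' @param posterior an [mk_mcmc()] posterior (>= 100 samples).
#' @param n_boot bootstrap resample count.
#' @return List with `logML` and `SE`.
#' @export
harmonic_mean_log_ml <- function(posterior, n_boot = 1000L) {
  ll <- if (inherits(posterior, "mk_posterior")) posterior$samples$loglik
        else as.numeric(posterior)
  n <- length(ll)
  if (n < 100) stop("need at least 100 post-burn-in samples", call. = FALSE)
  hm <- function(v) {
    neg <- -v
    m <- max(neg)
    -(m + log(mean(exp(neg - m))))
  }
  b <- max(1L, floor(sqrt(n)))
  nblocks <- ceiling(n / b)
  starts_max <- n - b + 1L
  boots <- vapply(seq_len(n_boot), function(i) {
    st <- sample.int(starts_max, nblocks, replace = TRUE)
    idx <- as.vector(outer(0:(b - 1L), st, `+`))[seq_len(n)]
    hm(ll[idx])
  }, numeric(1))
  list(logML = hm(ll), SE = stats::sd(boots))
}

#' Bayes-factor comparison of transition models
#'
#' \eqn{BF = 2(\log ML_{full} - \log ML_{model})} by harmonic-mean
#' marginal likelihoods, with the usual evidence categories: none (< 2),
#' positive (2-6), strong (6-10), very strong (> 10). Negative values
#' (constrained model preferred) are reported as-is.
#'
#' @param full the unconstrained-model posterior.
#' @param constrained named list of constrained-model posteriors.
#' @return An object of class `mk_model_comparison`: data frame with
#'   `model`, `constraint`, `logML`, `SE`, `BF`, `category`.
#' @export
bayes_factor_table <- function(full, constrained) {
  sig <- full$data_signature
  for (m in constrained) {
    if (!identical(m$data_signature, sig)) {
      stop("models were fitted to different data", call. = FALSE)
    }
  }
  hm_full <- harmonic_mean_log_ml(full)
  rows <- data.frame(model = "full", constraint = "",
                     logML = hm_full$logML, SE = hm_full$SE, BF = 0,
                     stringsAsFactors = FALSE)
  for (nm in names(constrained)) {
    hm <- harmonic_mean_log_ml(constrained[[nm]])
    rows <- rbind(rows, data.frame(
      model = nm,
      constraint = paste0("q", constrained[[nm]]$constrained,
                          collapse = ","),
      logML = hm$logML, SE = hm$SE,
      BF = 2 * (hm_full$logML - hm$logML)))
  }
  rows$category <- bf_category(rows$BF)
  class(rows) <- c("mk_model_comparison", "data.frame")
  rows
}

#' Evidence category of a Bayes factor
#' @param bf numeric vector of 2 log BF values.
#' @return Character vector: "none", "positive", "strong", "very strong".
#' @export
bf_category <- function(bf) {
  cut(bf, breaks = c(-Inf, 2, 6, 10, Inf),
      labels = c("none", "positive", "strong", "very strong"),
      right = FALSE) |> as.character()
}

#' Marginal ancestral state reconstruction
#'
#' For every retained posterior sample, each requested node is located as
#' the MRCA of its tip set on that sample's tree, its marginal state
#' probabilities are computed by the two-pass conditional-likelihood
#' algorithm under the sample's rates, and the reconstruction is the
#' average over samples (renormalized).
#'
#' @param posterior an [mk_mcmc()] posterior.
#' @param trees the [tree_ensemble()] the chain was run on.
#' @param coding tip-state coding.
#' @param node_specs named list of tip-label sets identifying nodes;
#'   defaults to all internal nodes of the first tree.
#' @return An object of class `ancestral_reconstruction`: data frame with
#'   `node`, `P_A`, `P_B`, `P_C`, `modal_state`, `modal_prob`, plus
#'   attribute `node_specs`.
#' @export
marginal_ancestral_states <- function(posterior, trees, coding,
                                      node_specs = NULL) {
  if (inherits(trees, "phylo")) trees <- tree_ensemble(list(trees))
  if (is.null(node_specs)) {
    ref <- trees[[1]]
    ntip <- length(ref$tip.label)
    ids <- (ntip + 1):(ntip + ref$Nnode)
    node_specs <- lapply(ids, function(nd) {
      ape::extract.clade(ref, nd)$tip.label
    })
    names(node_specs) <- paste0("node", ids)
  }
  if (any(!nzchar(names(node_specs))) || is.null(names(node_specs))) {
    names(node_specs) <- paste0("spec", seq_along(node_specs))
  }
  for (ns in node_specs) {
    if (!length(ns)) stop("empty node spec", call. = FALSE)
  }
  samples <- posterior$samples
  acc <- matrix(0, length(node_specs), 3,
                dimnames = list(names(node_specs), c("A", "B", "C")))
  for (ti in sort(unique(samples$tree))) {
    tree <- trees[[ti]]
    tr <- tree_for_cpp(tree)
    tp <- tip_partials_from_coding(tree, coding)
    ntip <- length(tree$tip.label)
    mrca <- vapply(node_specs, function(tps) {
      tps <- intersect(tps, tree$tip.label)
      if (length(tps) < 1) stop("node spec has no tips on tree",
                                call. = FALSE)
      if (length(tps) == 1) match(tps, tree$tip.label)
      else ape::getMRCA(tree, tps)
    }, integer(1))
    rows <- which(samples$tree == ti)
    for (i in rows) {
      Q <- q_matrix(c(qAB = samples$qAB[i], qAC = samples$qAC[i],
                      qBA = samples$qBA[i], qBC = samples$qBC[i],
                      qCA = samples$qCA[i], qCB = samples$qCB[i]))
      marg <- cpp_marginals(tr$edge, tr$edge_length, tr$ntip, tp, Q,
                            posterior$settings$pi)
      acc <- acc + marg[mrca, , drop = FALSE]
    }
  }
  acc <- acc / rowSums(acc)
  out <- data.frame(node = rownames(acc), P_A = acc[, 1], P_B = acc[, 2],
                    P_C = acc[, 3],
                    modal_state = c("A", "B", "C")[max.col(acc, "first")],
                    modal_prob = apply(acc, 1, max),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "node_specs") <- node_specs
  class(out) <- c("ancestral_reconstruction", "data.frame")
  out
}

#' Count and date niche transitions on a chronogram
#'
#' Scans every parent-child edge of the chronogram and records a
#' transition wherever the modal states differ. A tip's modal state is
#' its single coded state, or for polymorphic tips the coded state with
#' the higher locality count. The transition age is the child node's age
#' (0 for terminal edges), the Quaternary flag marks ages at or below the
#' boundary, and the filtered count keeps only edges whose child clade
#' has posterior support above `pp_filter` (terminal edges pass by
#' convention).
#'
#' @param recon a [marginal_ancestral_states()] result whose node specs
#'   cover all internal nodes of the chronogram.
#' @param chronogram the dated reference tree.
#' @param coding tip-state coding (with counts, for polymorphic tips).
#' @param pp_filter support threshold (default 0.95).
#' @param q_boundary Quaternary boundary in Ma (default 2.6).
#' @return An object of class `transition_summary`: list with `edges`
#'   (data frame of transitions), `counts` (directed-pair table over all
#'   transitions), `filtered_counts` (same, support-filtered),
#'   `n_total`, `n_filtered`, `n_quaternary_filtered`.
#' @export
count_transitions <- function(recon, chronogram, coding,
                              pp_filter = 0.95, q_boundary = 2.6) {
  ntip <- length(chronogram$tip.label)
  ages <- node_ages(chronogram)
  support <- attr(chronogram, "support")
  specs <- attr(recon, "node_specs")
  # modal state per node number
  modal <- character(ntip + chronogram$Nnode)
  for (i in seq_len(nrow(recon))) {
    nd <- specs[[recon$node[i]]]
    nd_id <- if (length(nd) == 1) match(nd, chronogram$tip.label)
             else ape::getMRCA(chronogram, nd)
    modal[nd_id] <- recon$modal_state[i]
  }
  if (any(modal[(ntip + 1):length(modal)] == "")) {
    stop("reconstruction does not cover all internal nodes", call. = FALSE)
  }
  sets <- strsplit(coding$states, "|", fixed = TRUE)
  names(sets) <- coding$species
  counts <- as.matrix(coding[, c("nA", "nB", "nC")])
  rownames(counts) <- coding$species
  for (i in seq_len(ntip)) {
    sp <- chronogram$tip.label[i]
    st <- sets[[sp]]
    if (is.null(st)) stop("tip without coding: ", sp, call. = FALSE)
    if (length(st) == 1) modal[i] <- st
    else {
      cnt <- counts[sp, match(st, c("A", "B", "C"))]
      modal[i] <- st[which.max(cnt)]
    }
  }
  rows <- list()
  for (e in seq_len(nrow(chronogram$edge))) {
    p <- chronogram$edge[e, 1]; ch <- chronogram$edge[e, 2]
    if (modal[p] == modal[ch]) next
    terminal <- ch <= ntip
    age <- ages[ch]
    child_pp <- if (terminal) NA_real_ else support[ch - ntip]
    passes <- terminal || (!is.na(child_pp) && child_pp > pp_filter)
    rows[[length(rows) + 1L]] <- data.frame(
      edge = e, from = modal[p], to = modal[ch],
      branch_class = if (terminal) "terminal" else "internal",
      age = age, quaternary = age <= q_boundary,
      child_support = child_pp, passes_filter = passes)
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(edge = integer(), from = character(), to = character(),
               branch_class = character(), age = numeric(),
               quaternary = logical(), child_support = numeric(),
               passes_filter = logical())
  pair <- function(df) {
    tab <- table(factor(paste0(df$from, "->", df$to),
                        levels = c("A->B", "A->C", "B->A", "B->C",
                                   "C->A", "C->B")))
    as.numeric(tab) |> setNames(names(tab))
  }
  filt <- edges[edges$passes_filter, , drop = FALSE]
  structure(list(edges = edges, counts = pair(edges),
                 filtered_counts = pair(filt),
                 n_total = nrow(edges), n_filtered = nrow(filt),
                 n_quaternary_filtered = sum(filt$quaternary)),
            class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  cat(sprintf("Transitions: %d total, %d on well-supported edges (%d of those Quaternary)\n",
              x$n_total, x$n_filtered, x$n_quaternary_filtered))
  print(x$filtered_counts)
  invisible(x)
}

#' Full transition-model comparison on a tree ensemble
#'
#' Runs the eight-model family ([mk_models()]) on the supplied ensemble
#' and coding and returns the Bayes-factor table; the machinery behind
#' the reference comparison of constrained transition models.
#'
#' @param trees a [tree_ensemble()].
#' @param coding tip-state coding.
#' @param seed integer seed (per-model seeds derived deterministically).
#' @param ... chain settings passed to [mk_mcmc()].
#' @return An `mk_model_comparison` with attribute `posteriors`.
#' @export
reproduce_transition_models <- function(trees, coding, seed = 1L, ...) {
  models <- mk_models()
  posts <- list()
  for (i in seq_along(models)) {
    posts[[names(models)[i]]] <-
      mk_mcmc(trees, coding, constrained = models[[i]],
              seed = derive_seed(seed, i), ...)
  }
  out <- bayes_factor_table(posts$full, posts[-1])
  attr(out, "posteriors") <- posts
  out
}
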