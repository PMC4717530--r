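test_that("transition matrices satisfy CTMC identities", {
  q <- random_sim_q(1)
  P0 <- transition_matrix(q, 0)
  expect_equal(P0, diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(transition_matrix(q, -1), "non-negative")

  # 2-state closed form embedded in the 3-state machinery
  a <- 0.7; b <- 0.4; t <- 1.3
  q2 <- sim_q(qAB = a, qBA = b)
  P <- transition_matrix(q2, t)
  expect_equal(P["A", "A"],
               b / (a + b) + a / (a + b) * exp(-(a + b) * t),
               tolerance = 1e-10)
  expect_equal(P["C", "C"], 1, tolerance = 1e-12)
})

test_that("transition matrices match two independent exponentials", {
  for (seed in 1:6) {
    q <- random_sim_q(seed)
    Q <- q_matrix(q)
    P <- transition_matrix(q, 0.7)
    # oracle 1: Pade scaling-and-squaring (Matrix)
    P_pade <- as.matrix(Matrix::expm(Q * 0.7))
    # oracle 2: eigendecomposition in R
    e <- eigen(Q * 0.7)
    P_eig <- Re(e$vectors %*% diag(exp(e$values)) %*% solve(e$vectors))
    expect_equal(P, P_pade, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(P, P_eig, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_true(all(P >= 0))
  }
})

test_that("fully ambiguous tips give log-likelihood zero", {
  tr <- sim_tree(8, 5.3, seed = 1)
  cod <- coding_of(setNames(rep("A|B|C", 8), tr$tip.label))
  par <- mk_parameters(c(qAB = 1, qAC = 0.5, qBA = 0.3, qBC = 0.2,
                         qCA = 0.1, qCB = 0.4))
  expect_equal(pruning_log_likelihood(tr, cod, par), 0, tolerance = 1e-10)
})

test_that("infinite branches reach the stationary limit", {
  star <- ape::read.tree(text = "(a:1e6,b:1e6,c:1e6,d:1e6,e:1e6);")
  cod <- coding_of(c(a = "A", b = "B", c = "C", d = "A", e = "B"))
  par <- mk_parameters(c(qAB = 1, qAC = 1, qBA = 1, qBC = 1,
                         qCA = 1, qCB = 1))
  expect_equal(pruning_log_likelihood(star, cod, par), 5 * log(1 / 3),
               tolerance = 1e-6)
})

test_that("pruning equals exhaustive enumeration on all 4-tip topologies", {
  # every labeled rooted binary shape over four tips, via ape
  topos <- phangorn::allTrees(4, rooted = TRUE)
  set.seed(42)
  states <- c("A", "B", "C", "A|C")
  for (ti in seq_along(topos)) {
    top <- topos[[ti]]  # multiPhylo extraction restores tip labels
    top$edge.length <- runif(nrow(top$edge), 0.1, 2)
    for (rep in 1:2) {
      q <- random_sim_q(sample.int(1e6, 1))
      tip_states <- setNames(sample(states, 4, replace = TRUE),
                             top$tip.label)
      par <- mk_parameters(setNames(as.numeric(q$rates),
                                    names(q$rates)))
      got <- pruning_log_likelihood(top, coding_of(tip_states), par)
      want <- enumerate_loglik(top, tip_states, q_matrix(q))
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("likelihood is invariant to re-rooting under reversible rates", {
  tr <- sim_tree(5, 4, seed = 3)
  cod <- coding_of(setNames(c("A", "B", "C", "A|B", "B"), tr$tip.label))
  par <- mk_parameters(c(qAB = 0.6, qAC = 0.4, qBA = 0.6, qBC = 0.9,
                         qCA = 0.4, qCB = 0.9))
  base <- pruning_log_likelihood(tr, cod, par)
  for (node in c(7, 8)) {
    rr <- ape::root(ape::unroot(tr), node = node, resolve.root = TRUE)
    expect_equal(pruning_log_likelihood(rr, cod, par), base,
                 tolerance = 1e-8)
  }
})

test_that("constraining a rate never raises the maximized likelihood", {
  tr <- sim_tree(20, 5.3, seed = 4)
  tips <- sim_discrete_character(tr, sim_q(1, 0.3, 1, 0.5, 0.1, 0.1,
                                           root = "A"), seed = 5)
  cod <- coding_of(tips)
  ll_of <- function(constrained) {
    fit <- optim(rep(0.5, 6), function(r) {
      r[constrained] <- 0
      -pruning_log_likelihood(tr, cod, mk_parameters(
        setNames(pmax(r, 0), c("qAB", "qAC", "qBA", "qBC", "qCA", "qCB"))))
    }, method = "Nelder-Mead", control = list(maxit = 2000))
    -fit$value
  }
  full <- ll_of(integer(0))
  for (j in 1:3) expect_lte(ll_of(j), full + 1e-6)
})

test_that("the sampler respects constraints and fixed trees", {
  tr <- sim_tree(10, 5.3, seed = 6)
  tips <- sim_discrete_character(tr, sim_q(1, 1, 1, 1, 1, 1), seed = 7)
  post <- mk_mcmc(tr, coding_of(tips), constrained = "qC0",
                  generations = 20000, burnin = 2000, thin = 20, seed = 1)
  expect_true(all(post$samples$qCA == 0))
  expect_true(all(post$samples$qCB == 0))
  expect_true(all(post$samples$tree == 1))
  expect_true(all(diff(post$samples$iteration) == 20))
  expect_true(all(post$samples$mu > 0 & post$samples$mu <= 30))
  expect_error(mk_mcmc(tr, coding_of(tips),
                       constrained = c("AB", "AC", "BA", "BC", "CA", "CB")),
               "unconstrained")
})

test_that("harmonic-mean marginal likelihoods match direct arithmetic", {
  expect_equal(harmonic_mean_log_ml(rep(-10, 150))$logML, -10)
  expect_equal(harmonic_mean_log_ml(rep(-10, 150))$SE, 0)
  expect_equal(harmonic_mean_log_ml(rep(c(log(1), log(1 / 3)), 75))$logML,
               log(0.5), tolerance = 1e-12)

  set.seed(8)
  ll <- rep(runif(10, -12, -2), 12)
  direct <- -log(mean(exp(-ll)))  # safe at these magnitudes
  expect_equal(harmonic_mean_log_ml(ll)$logML, direct, tolerance = 1e-12)
  expect_error(harmonic_mean_log_ml(rep(-1, 50)), "at least 100")
})

test_that("Bayes factors follow the 2 delta-logML arithmetic", {
  mk_fake <- function(logml, constrained = character()) {
    structure(list(samples = data.frame(loglik = rep(logml, 200)),
                   constrained = constrained, data_signature = "sig"),
              class = "mk_posterior")
  }
  cmp <- bayes_factor_table(mk_fake(-34.74),
                            list(qAB0 = mk_fake(-37.73, "AB"),
                                 same = mk_fake(-34.74, "AC")))
  expect_equal(cmp$BF[cmp$model == "qAB0"], 5.98, tolerance = 1e-9)
  expect_equal(cmp$category[cmp$model == "qAB0"], "positive")
  expect_equal(cmp$BF[cmp$model == "same"], 0)
  expect_equal(cmp$category[cmp$model == "same"], "none")

  # antisymmetry under swapping the two models
  a <- mk_fake(-30); b <- mk_fake(-33, "AB")
  bf_ab <- bayes_factor_table(a, list(m = b))$BF[2]
  b2 <- mk_fake(-33); a2 <- mk_fake(-30, "AB")
  bf_ba <- bayes_factor_table(b2, list(m = a2))$BF[2]
  expect_equal(bf_ab, -bf_ba)

  bad <- mk_fake(-31, "AB"); bad$data_signature <- "other"
  expect_error(bayes_factor_table(a, list(m = bad)), "different data")
  expect_equal(bf_category(c(-1, 3, 7, 15)),
               c("none", "positive", "strong", "very strong"))
})

test_that("marginal reconstructions honor limits and enumeration", {
  # zero-length cherry pins the MRCA to the tips' shared state
  tr <- ape::read.tree(text = "((a:1e-9,b:1e-9):2,c:2.000000001);")
  cod <- coding_of(c(a = "A", b = "A", c = "B"))
  post <- mk_mcmc(as_dated_tree(tr, tol = 1), cod,
                  generations = 5000, burnin = 500, thin = 50, seed = 2)
  rec <- marginal_ancestral_states(post, tree_ensemble(list(
    as_dated_tree(tr, tol = 1))), cod,
    node_specs = list(cherry = c("a", "b")))
  expect_equal(rec$P_A[rec$node == "cherry"], 1, tolerance = 1e-6)

  # saturation limit: uniform prior spreads mass evenly
  tr2 <- sim_tree(6, 5, seed = 9)
  tr2$edge.length <- tr2$edge.length * 1e5
  cod2 <- coding_of(setNames(c("A", "B", "C", "A", "B", "C"),
                             tr2$tip.label))
  Q <- q_matrix(sim_q(1, 1, 1, 1, 1, 1))
  trc <- phyloniche:::tree_for_cpp(tr2)
  marg <- phyloniche:::cpp_marginals(trc$edge, trc$edge_length, trc$ntip,
    phyloniche:::tip_partials_from_coding(tr2, cod2), Q, rep(1 / 3, 3))
  expect_equal(as.numeric(marg[7, ]), rep(1 / 3, 3), tolerance = 1e-4)
})

test_that("single-sample marginals equal exhaustive enumeration", {
  top <- ape::read.tree(text = "((a:0.8,b:1.1):0.6,(c:0.9,d:0.4):1.2);")
  tip_states <- c(a = "A", b = "B|C", c = "C", d = "A")
  q <- random_sim_q(17)
  Q <- q_matrix(q)
  trc <- phyloniche:::tree_for_cpp(top)
  marg <- phyloniche:::cpp_marginals(
    trc$edge, trc$edge_length, trc$ntip,
    phyloniche:::tip_partials_from_coding(top, coding_of(tip_states)),
    Q, rep(1 / 3, 3))

  # brute force: joint probability of every internal-state combination
  states <- c("A", "B", "C")
  Pm <- lapply(seq_len(nrow(top$edge)), function(e) {
    as.matrix(Matrix::expm(Q * top$edge.length[e]))
  })
  tip_sets <- strsplit(tip_states[top$tip.label], "|", fixed = TRUE)
  joint <- array(0, c(3, 3, 3))
  for (r in 1:3) for (u in 1:3) for (v in 1:3) {
    assign_int <- c(r, u, v)  # nodes 5, 6, 7
    prob <- 1 / 3
    for (e in seq_len(nrow(top$edge))) {
      par <- assign_int[top$edge[e, 1] - 4]
      ch <- top$edge[e, 2]
      prob <- prob * if (ch <= 4) {
        sum(Pm[[e]][par, match(tip_sets[[ch]], states)])
      } else Pm[[e]][par, assign_int[ch - 4]]
    }
    joint[r, u, v] <- prob
  }
  expect_equal(as.numeric(marg[5, ]),
               apply(joint, 1, sum) / sum(joint), tolerance = 1e-9)
  expect_equal(as.numeric(marg[6, ]),
               apply(joint, 2, sum) / sum(joint), tolerance = 1e-9)
  expect_equal(as.numeric(marg[7, ]),
               apply(joint, 3, sum) / sum(joint), tolerance = 1e-9)
})

test_that("transition counting matches a hand edge scan", {
  # forced single change on a 3-tip chronogram
  tr <- as_dated_tree(ape::read.tree(text = "((a:1,b:1)0.99:1.5,c:2.5);"))
  cod <- coding_of(c(a = "B", b = "A", c = "A"))
  cod$nA <- c(0, 5, 5); cod$nB <- c(5, 0, 0); cod$nC <- 0
  rec <- data.frame(node = c("root", "inner"),
                    P_A = c(0.9, 0.9), P_B = c(0.05, 0.05),
                    P_C = c(0.05, 0.05),
                    modal_state = c("A", "A"), modal_prob = c(0.9, 0.9))
  attr(rec, "node_specs") <- list(root = c("a", "b", "c"),
                                  inner = c("a", "b"))
  class(rec) <- c("ancestral_reconstruction", "data.frame")
  ts <- count_transitions(rec, tr, cod)
  expect_equal(ts$n_total, 1)
  expect_equal(unname(ts$counts["A->B"]), 1)
  expect_equal(ts$edges$branch_class, "terminal")
  expect_equal(ts$edges$age, 0)
  expect_true(ts$edges$quaternary)
  expect_equal(ts$n_quaternary_filtered, 1)
})

test_that("painted states on a simulated tree are counted exactly", {
  set.seed(30)
  tr <- sim_tree(30, 5.3, seed = 31)
  ntip <- 30
  # paint every node independently and count state changes by brute force
  paint <- sample(c("A", "B", "C"), ntip + tr$Nnode, replace = TRUE)
  cod <- coding_of(setNames(paint[1:ntip], tr$tip.label))
  cod$nA <- as.integer(cod$states == "A") * 3
  cod$nB <- as.integer(cod$states == "B") * 3
  cod$nC <- as.integer(cod$states == "C") * 3
  specs <- lapply((ntip + 1):(ntip + tr$Nnode), function(nd) {
    ape::extract.clade(tr, nd)$tip.label
  })
  names(specs) <- paste0("n", (ntip + 1):(ntip + tr$Nnode))
  rec <- data.frame(node = names(specs),
                    P_A = as.numeric(paint[(ntip + 1):(ntip + tr$Nnode)] == "A"),
                    P_B = as.numeric(paint[(ntip + 1):(ntip + tr$Nnode)] == "B"),
                    P_C = as.numeric(paint[(ntip + 1):(ntip + tr$Nnode)] == "C"))
  rec$modal_state <- paint[(ntip + 1):(ntip + tr$Nnode)]
  rec$modal_prob <- 1
  attr(rec, "node_specs") <- specs
  class(rec) <- c("ancestral_reconstruction", "data.frame")
  ts <- count_transitions(rec, tr, cod, pp_filter = 0, q_boundary = 2.6)
  manual <- sum(paint[tr$edge[, 1]] != paint[tr$edge[, 2]])
  expect_equal(ts$n_total, manual)
  ages <- node_ages(tr)
  manual_q <- sum(paint[tr$edge[, 1]] != paint[tr$edge[, 2]] &
                    ages[tr$edge[, 2]] <= 2.6)
  expect_equal(sum(ts$edges$quaternary), manual_q)
})

test_that("all-identical modal states yield zero transitions", {
  tr <- sim_tree(8, 5, seed = 12)
  cod <- coding_of(setNames(rep("B", 8), tr$tip.label))
  cod$nA <- 0; cod$nB <- 5; cod$nC <- 0
  specs <- lapply(9:15, function(nd) ape::extract.clade(tr, nd)$tip.label)
  names(specs) <- paste0("n", 9:15)
  rec <- data.frame(node = names(specs), P_A = 0, P_B = 1, P_C = 0,
                    modal_state = "B", modal_prob = 1)
  attr(rec, "node_specs") <- specs
  class(rec) <- c("ancestral_reconstruction", "data.frame")
  ts <- count_transitions(rec, tr, cod)
  expect_equal(ts$n_total, 0)
})
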