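test_that("phylogenetic covariance matches shared path lengths", {
  star <- as_dated_tree(ape::read.tree(text = "(a:3,b:3,c:3,d:3):0;"),
                        strict = FALSE)
  V <- phylo_covariance(star)
  expect_equal(V, 3 * diag(4), ignore_attr = TRUE)

  tr <- as_dated_tree(ape::read.tree(text = "((a:1,b:1):1,c:2);"))
  V2 <- phylo_covariance(tr)
  expect_equal(V2["a", "b"], 1)
  expect_equal(V2["a", "c"], 0)
  expect_equal(unname(diag(V2)), rep(2, 3))

  # brute-force path sums on a random tree
  tr3 <- sim_tree(8, 5, seed = 2)
  V3 <- phylo_covariance(tr3)
  ages <- node_ages(tr3)
  for (i in 1:8) for (j in 1:8) {
    expected <- if (i == j) root_age(tr3) else {
      mrca <- ape::getMRCA(tr3, c(tr3$tip.label[i], tr3$tip.label[j]))
      root_age(tr3) - ages[mrca]
    }
    expect_equal(V3[tr3$tip.label[i], tr3$tip.label[j]], expected,
                 tolerance = 1e-10)
  }
})

test_that("K equals 1 exactly on star trees", {
  star <- ape::read.tree(text = "(a:2,b:2,c:2,d:2,e:2);")
  set.seed(3)
  for (i in 1:5) {
    trait <- setNames(rnorm(5, sd = runif(1, 0.5, 5)), star$tip.label)
    expect_equal(blomberg_k(star, trait), 1, tolerance = 1e-10)
  }
})

test_that("K matches the picante reference implementation", {
  tr <- sim_tree(15, 5.3, seed = 4)
  set.seed(5)
  trait <- setNames(rnorm(15), tr$tip.label)
  expect_equal(blomberg_k(tr, trait),
               picante::Kcalc(trait[tr$tip.label], tr),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("K is invariant to affine trait transforms", {
  tr <- sim_tree(12, 5, seed = 6)
  set.seed(7)
  trait <- setNames(rnorm(12), tr$tip.label)
  k0 <- blomberg_k(tr, trait)
  expect_equal(blomberg_k(tr, 3.7 * trait - 11), k0, tolerance = 1e-10)
  expect_warning(kc <- blomberg_k(tr, setNames(rep(1, 12), tr$tip.label)),
                 "variance")
  expect_true(is.nan(kc))
})

test_that("clade-structured traits inflate K far above 1", {
  # deep two-clade tree with tiny within-clade variation
  tr <- as_dated_tree(ape::read.tree(text = paste0(
    "((a:0.1,b:0.1):4.9,(c:0.1,d:0.1):4.9);")))
  trait <- setNames(c(0, 0.01, 1, 1.01), c("a", "b", "c", "d"))
  expect_gt(blomberg_k(tr, trait), 2)
})

test_that("Brownian traits on a fixed tree calibrate K near 1", {
  tr <- sim_tree(30, 5.3, seed = 8)
  ks <- vapply(1:150, function(i) {
    set.seed(i)
    trait <- ape::rTraitCont(tr, model = "BM", sigma = 1)
    blomberg_k(tr, trait)
  }, numeric(1))
  expect_gt(mean(ks), 0.85)
  expect_lt(mean(ks), 1.15)
})

test_that("permutation p is calibrated under the null", {
  tr <- sim_tree(12, 5, seed = 9)
  ps <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    trait <- setNames(rnorm(12), tr$tip.label)
    as.numeric(permutation_p(tr, trait, n_perm = 99, seed = i))
  }, numeric(1))
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
})

test_that("clade-clustered traits are detected as signal", {
  ladder <- function(tips, h) {
    # strictly bifurcating ladder clade of depth h
    txt <- sprintf("%s:0.1", tips[1])
    for (i in seq_along(tips)[-1]) {
      txt <- sprintf("(%s,%s:%g):0.1", txt, tips[i], 0.1 * i)
    }
    txt
  }
  a <- ladder(paste0("a", 1:6), 0.1); b <- ladder(paste0("b", 1:6), 0.1)
  tr <- ape::read.tree(text = sprintf("(%s:4,%s:4);", a, b))
  trait <- setNames(c(rnorm(6, 0, 0.05), rnorm(6, 10, 0.05)),
                    tr$tip.label)
  p <- permutation_p(tr, trait, n_perm = 999, seed = 1)
  expect_lte(as.numeric(p), 0.01)

  # formula floor: a single forced-tie permutation
  p1 <- permutation_p(tr, trait, n_perm = 0, seed = 1)
  expect_equal(as.numeric(p1), 1)
})

test_that("the trait table combines medians and shared PC centroids", {
  occ <- make_occ(9, species = rep(c("s1", "s2", "s3"), each = 3))
  occ$alt <- c(1, 2, 100, 5, 5, 5, 7, 8, 9)
  X <- env_matrix(occ)
  p <- pca(X)
  lab <- c("A", "A", "A", "A", "A", "A", "B", "B", "B")
  cod <- apply_coding(data.frame(species = c("s1", "s2", "s3"),
                                 nA = c(3, 3, 0), nB = c(0, 0, 3),
                                 nC = c(0, 0, 0)))
  tt <- build_trait_table(occ, lab, p, cod)
  expect_equal(tt$alt, c(2, 5, 8))
  # species in the same cluster share identical PC traits
  expect_equal(tt$PC1[1], tt$PC1[2])
  expect_false(isTRUE(all.equal(tt$PC1[1], tt$PC1[3])))
  # brute-force group medians for every variable
  for (v in env_names()) {
    for (i in 1:3) {
      expect_equal(tt[[v]][i],
                   median(occ[[v]][occ$species == tt$species[i]]))
    }
  }
})

test_that("signal over an ensemble of identical trees collapses", {
  tr <- sim_tree(10, 5, seed = 10)
  ens <- tree_ensemble(list(tr, tr, tr))
  set.seed(11)
  traits <- data.frame(species = tr$tip.label, x = rnorm(10))
  res <- signal_over_trees(ens, traits, n_perm = 99, seed = 5)
  expect_equal(res$median_K, blomberg_k(tr, setNames(traits$x,
                                                     traits$species)),
               tolerance = 1e-10)
  expect_equal(res$n_trees, 3)
})

test_that("Brownian traits are rarely flagged over a tree ensemble", {
  ens <- tree_ensemble(lapply(1:40, function(s) sim_tree(15, 5.3,
                                                         seed = 400 + s)))
  set.seed(12)
  trait <- ape::rTraitCont(ens[[1]], model = "BM", sigma = 1)
  traits <- data.frame(species = names(trait), bm = as.numeric(trait))
  res <- signal_over_trees(ens, traits, n_perm = 199, seed = 13)
  expect_gte(res$pct_not_rejecting, 90)
})
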