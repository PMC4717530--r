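test_that("grid generation is deterministic in the seed", {
  g1 <- gen_env_grid(15, seed = 5)
  g2 <- gen_env_grid(15, seed = 5)
  expect_identical(g1$env, g2$env)
  expect_identical(g1$mask, g2$mask)
  g3 <- gen_env_grid(15, seed = 6)
  expect_false(identical(g1$env$alt, g3$env$alt))
  expect_error(gen_env_grid(9), "at least 10")
})

test_that("altitude and temperature are negatively correlated (lapse rule)", {
  g <- gen_env_grid(30, seed = 2)
  cells <- grid_masked_cells(g)
  E <- grid_env_at(g, cells)
  expect_lt(cor(E[, "alt"], E[, "bio1"]), 0)
})

test_that("the three regimes are separable and recovered by K-means", {
  g <- gen_env_grid(30, seed = 3)
  specs <- default_niche_specs(g)
  cents <- t(vapply(specs, `[[`, numeric(20), "centroid"))
  spreads <- vapply(specs, function(s) sqrt(sum(s$spread^2)), numeric(1))
  d <- as.matrix(dist(cents))
  expect_gt(min(d[upper.tri(d)]), 5 * mean(spreads))

  # regime centroids hard-cluster correctly under K-means with K = 3
  plan <- list(s1 = list(niche = "A", count = 60),
               s2 = list(niche = "B", count = 60),
               s3 = list(niche = "C", count = 60))
  occ <- gen_occurrences(g, specs, plan, seed = 4)
  km <- kmeans(env_matrix(occ), centers = cents)
  truth <- attr(occ, "true_niche")
  tab <- table(km$cluster, truth)
  # each cluster maps to exactly one regime
  expect_equal(sum(apply(tab, 1, max)), nrow(occ))
})

test_that("occurrence generation honors the species plan exactly", {
  g <- gen_env_grid(20, seed = 1)
  specs <- default_niche_specs(g)
  plan <- list(sp1 = list(niche = "A", count = 5),
               hildebrandtii_like = list(niche = c("A", "C"),
                                         count = c(17, 14)))
  occ <- gen_occurrences(g, specs, plan, seed = 2)
  expect_equal(sum(occ$species == "sp1"), 5)
  expect_equal(sum(occ$species == "hildebrandtii_like"), 31)
  truth <- attr(occ, "true_niche")
  expect_equal(as.vector(table(truth[occ$species == "hildebrandtii_like"])),
               c(17, 14))
  # records fall inside their niche anchors
  for (i in seq_len(nrow(occ))) {
    lab <- truth[i]
    a <- specs[[lab]]$anchor
    col <- floor((occ$lon[i] - g$xll) / g$cellsize)
    row <- g$nrow - 1 - floor((occ$lat[i] - g$yll) / g$cellsize)
    expect_true(row >= a[1] && row <= a[2] && col >= a[3] && col <= a[4])
  }
  expect_error(gen_occurrences(g, specs,
                               list(x = list(niche = "Z", count = 1))),
               "unknown niche")
})

test_that("generated occurrences survive write/read and schema checks", {
  g <- gen_env_grid(20, seed = 8)
  occ <- gen_occurrences(g, default_niche_specs(g),
                         paper_mimic_plan(10, seed = 3), seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(occ, f)
  back <- read_occurrences(f)
  expect_equal(nrow(back), nrow(occ))
  expect_equal(env_matrix(back), env_matrix(occ), tolerance = 1e-10)
})

test_that("the study-shaped plan matches the published count structure", {
  plan <- paper_mimic_plan(33, seed = 1)
  expect_length(plan, 33)
  counts <- vapply(plan, function(p) sum(p$count), numeric(1))
  expect_true(all(counts >= 1 & counts <= 148))
  n_poly <- sum(vapply(plan, function(p) length(p$niche) > 1, logical(1)))
  expect_gte(n_poly, 1)
})

test_that("simulated trees are ultrametric with exact root age", {
  tr <- sim_tree(30, root_age = 5.3, seed = 1)
  expect_equal(root_age(tr), 5.3, tolerance = 1e-9)
  depths <- ape::node.depth.edgelength(tr)[1:30]
  expect_lt(max(depths) - min(depths), 1e-9)
  supp <- attr(tr, "support")
  expect_true(all(supp >= 0.5 & supp <= 1))

  cherry <- sim_tree(2, root_age = 4, seed = 1)
  expect_equal(sort(cherry$edge.length), c(4, 4))

  expect_identical(ape::write.tree(sim_tree(10, 5.3, seed = 9)),
                   ape::write.tree(sim_tree(10, 5.3, seed = 9)))
  expect_error(sim_tree(1), "at least 2")
})

test_that("character simulation honors degenerate rate matrices", {
  tr <- sim_tree(12, 5.3, seed = 2)
  all_zero <- sim_q(root = "A")
  expect_true(all(sim_discrete_character(tr, all_zero, seed = 1) == "A"))
  absorbing <- sim_q(qAB = 2, qAC = 2, qBA = 2, qBC = 2, root = "C")
  expect_true(all(sim_discrete_character(tr, absorbing, seed = 1) == "C"))
})

test_that("two-state switch fraction matches the closed form", {
  # symmetric 2-state rate q on branches of length t: switch probability
  # (1 - exp(-2qt)) / 2
  q <- 0.35; t_br <- 1.7
  qq <- sim_q(qAB = q, qBA = q, root = "A")
  tr <- sim_tree(2, root_age = t_br, seed = 1)  # two independent branches
  n_sim <- 5000
  flips <- vapply(seq_len(n_sim), function(s) {
    sum(sim_discrete_character(tr, qq, seed = s) == "B")
  }, numeric(1))
  p_hat <- sum(flips) / (2 * n_sim)
  p_true <- (1 - exp(-2 * q * t_br)) / 2
  se <- sqrt(p_true * (1 - p_true) / (2 * n_sim))
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("tip-state frequencies on a star tree match exp(Qt)", {
  star <- ape::read.tree(text = paste0("(",
    paste(sprintf("t%d:2", 1:80), collapse = ","), ");"))
  q <- random_sim_q(11, max_rate = 0.8)
  counts <- c(A = 0, B = 0, C = 0)
  n_rep <- 150
  for (s in seq_len(n_rep)) {
    tips <- sim_discrete_character(star, q, seed = s)
    counts <- counts + table(factor(tips, c("A", "B", "C")))
  }
  freq <- counts / sum(counts)
  P <- as.matrix(Matrix::expm(q_matrix(q) * 2))  # independent oracle
  expected <- as.numeric(q$root %*% P)
  se <- sqrt(expected * (1 - expected) / (80 * n_rep))
  expect_true(all(abs(freq - expected) < 4 * se + 1e-3))
})
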