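test_that("background-matching presences yield the uniform model", {
  g <- test_grid()
  cells <- grid_masked_cells(g)
  mod <- fit_maxent(cells, g, beta = 0)
  expect_lt(max(abs(mod$lambda)), 1e-4)
  expect_equal(mod$raw, rep(1 / nrow(cells), nrow(cells)),
               tolerance = 1e-6)
  expect_equal(sum(mod$raw), 1, tolerance = 1e-9)
})

test_that("raw suitability always normalizes and entropy is consistent", {
  g <- test_grid()
  pres <- phyloniche:::anchor_cells(g, default_niche_specs(g)$C$anchor)
  mod <- fit_maxent(pres, g, beta = 1)
  expect_equal(sum(mod$raw), 1, tolerance = 1e-9)
  expect_equal(mod$entropy, -sum(mod$raw * log(mod$raw)), tolerance = 1e-9)
  expect_true(all(mod$logistic > 0 & mod$logistic < 1))
  expect_error(fit_maxent(pres[1:3, ], g), "at least 5")
})

test_that("the L1 path matches a one-dimensional brute-force optimum", {
  # grid with two cell types differing only in altitude; linear and
  # quadratic features coincide on {0,1}, so the optimum is determined
  # by the total weight, checked against golden-section search
  env <- lapply(setNames(seq_len(20), env_names()), function(i) {
    matrix(50, 4, 5)
  })
  env$alt <- matrix(rep(c(0, 1000), length.out = 20), 4, 5)
  g <- env_grid(env, mask = matrix(TRUE, 4, 5))
  cells <- grid_masked_cells(g)
  hi <- cells[g$env$alt[cells + 1] == 1000, ]
  mod <- fit_maxent(hi, g, beta = 0.05)
  total <- sum(mod$lambda[c("alt.lin", "alt.quad")])
  expect_lt(max(abs(mod$lambda[!grepl("^alt", names(mod$lambda))])), 1e-8)

  x <- as.numeric(g$env$alt[cells + 1] == 1000)
  n_hi <- sum(x)
  s <- max(sd(x[x == 1]), 0.05) / sqrt(n_hi)  # the model's penalty scale
  obj <- function(c_tot) {
    c_tot - log(sum(exp(c_tot * x))) - 0.05 * s * abs(c_tot)
  }
  opt <- optimize(obj, c(0, 200), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(total, opt, tolerance = 1e-4)
})

test_that("rank AUC equals the pair-counting definition", {
  expect_equal(auc(c(3, 4, 5), c(0, 1, 2)), 1)
  expect_equal(auc(c(1, 2, 3), c(1, 2, 3)), 0.5)

  set.seed(10)
  sp <- sample(1:15, 20, replace = TRUE)
  sb <- sample(5:20, 20, replace = TRUE)
  wins <- 0
  for (i in sp) for (j in sb) {
    wins <- wins + (i > j) + 0.5 * (i == j)
  }
  expect_equal(auc(sp, sb), wins / 400, tolerance = 1e-12)
  expect_error(auc(numeric(0), 1), "non-empty")
})

test_that("AUC is antisymmetric on tie-free scores", {
  set.seed(11)
  for (i in 1:5) {
    a <- rnorm(10); b <- rnorm(12)
    expect_equal(auc(a, b), 1 - auc(b, a), tolerance = 1e-12)
  }
})

test_that("the maxent objective is concave: common optimum from restarts", {
  g <- test_grid()
  pres <- phyloniche:::anchor_cells(g, default_niche_specs(g)$A$anchor)
  m1 <- fit_maxent(pres, g, beta = 1)
  # same solution when refit (deterministic from zero start) and when
  # presences are permuted (objective is permutation invariant)
  m2 <- fit_maxent(pres[rev(seq_len(nrow(pres))), ], g, beta = 1)
  expect_equal(m1$lambda, m2$lambda, tolerance = 1e-4)
})

test_that("bootstrap evaluation separates real niches from noise", {
  g <- test_grid()
  specs <- default_niche_specs(g)
  occ <- gen_occurrences(g, specs, list(s = list(niche = "C", count = 40)),
                         seed = 3)
  col <- floor((occ$lon - g$xll) / g$cellsize)
  row <- g$nrow - 1 - floor((occ$lat - g$yll) / g$cellsize)
  pres <- unique(cbind(row, col))
  ev <- bootstrap_eval(pres, g, replicates = 30, seed = 4)
  expect_gt(ev$mean_auc, 0.9)
  expect_equal(ev$flag, "keep")
  expect_equal(sum(!is.na(ev$aucs)), 30)

  # presences indistinguishable from background
  set.seed(5)
  allc <- grid_masked_cells(g)
  rand <- allc[sample(nrow(allc), 40), ]
  ev2 <- bootstrap_eval(rand, g, replicates = 30, seed = 6)
  expect_lt(abs(ev2$mean_auc - 0.5), 0.12)
  expect_equal(ev2$flag, "remove")
  expect_error(bootstrap_eval(pres[1:5, ], g), "at least 10")
})

test_that("the bootstrap honors the requested replicate count", {
  g <- test_grid()
  pres <- phyloniche:::anchor_cells(g, default_niche_specs(g)$B$anchor)[1:12, ]
  ev <- bootstrap_eval(pres, g, replicates = 100, seed = 1)
  expect_length(ev$aucs, 100)
})

test_that("max-SSS thresholding matches an exhaustive scan", {
  # separable case with the tie-toward-larger rule
  tau <- max_sss(rep(0.9, 5), rep(0.1, 20))
  expect_equal(as.numeric(tau), 0.9)
  expect_equal(attr(tau, "sens_spec"), 2)

  # presences identical to background: best achievable is 1
  tau2 <- max_sss(c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8))
  expect_equal(attr(tau2, "sens_spec"), 1)

  set.seed(12)
  ps <- round(runif(10), 2); bs <- round(runif(25), 2)
  tau3 <- max_sss(ps, bs)
  cand <- sort(unique(c(ps, bs)))
  vals <- vapply(cand, function(tt) mean(ps >= tt) + mean(bs < tt),
                 numeric(1))
  expect_equal(attr(tau3, "sens_spec"), max(vals))
  expect_equal(as.numeric(tau3), max(cand[vals == max(vals)]))
})

test_that("range overlap follows the Jaccard definition", {
  expect_equal(range_overlap(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE)),
               100)
  expect_equal(range_overlap(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  x <- rep(c(TRUE, FALSE), c(10, 5))
  y <- rep(c(TRUE, FALSE, TRUE, FALSE), c(5, 5, 5, 0))
  expect_equal(range_overlap(x, y), 100 * 5 / 15, tolerance = 1e-12)
  expect_message(v <- range_overlap(logical(3), logical(3)), "undefined")
  expect_true(is.nan(v))
  expect_error(range_overlap(logical(3), logical(4)), "mask")
})

test_that("PNO profiles are unit-area suitability histograms", {
  g <- test_grid()
  cells <- grid_masked_cells(g)
  uniform <- fit_maxent(cells, g, beta = 0)
  prof <- pno_profile(uniform, g, "alt", bins = 20)
  expect_equal(sum(prof$weights), 1, tolerance = 1e-9)
  v <- grid_env_at(g, cells)[, "alt"]
  h <- hist(v, breaks = prof$edges, plot = FALSE)
  expect_equal(prof$weights, h$counts / sum(h$counts), tolerance = 1e-6)

  # suitability concentrated on one cell puts unit mass in its bin
  conc <- uniform
  conc$raw <- c(1, rep(0, nrow(cells) - 1))
  prof2 <- pno_profile(conc, g, "alt", bins = 20)
  expect_equal(max(prof2$weights), 1)
  expect_equal(sum(prof2$weights > 0), 1)
  expect_error(pno_profile(uniform, g, "nope"), "unknown variable")
})

test_that("per-niche PNO altitude medians order highland above lowlands", {
  g <- gen_env_grid(30, seed = 21)
  specs <- default_niche_specs(g)
  meds <- vapply(c("A", "B", "C"), function(lab) {
    pres <- phyloniche:::anchor_cells(g, specs[[lab]]$anchor)
    mod <- fit_maxent(pres, g, beta = 1)
    pno_median(pno_profile(mod, g, "alt"))
  }, numeric(1))
  expect_gt(meds["C"], meds["A"])
  expect_gt(meds["C"], meds["B"])
})
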