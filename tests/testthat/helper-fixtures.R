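# Shared fixtures, all generated in code.

env_names <- function() unclass(env_variable_set())

# an occurrence table with arbitrary deterministic env values
make_occ <- function(n = 6, species = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(species)) species <- paste0("sp", rep_len(1:3, n))
  env <- matrix(rnorm(n * 20, mean = 100, sd = 10), n, 20,
                dimnames = list(NULL, env_names()))
  occurrence_table(species, lon = runif(n, 43, 50), lat = runif(n, -25, -12),
                   env = env)
}

# two well-separated Gaussian blobs in d dimensions
make_blobs <- function(n_per = 20, centers = rbind(c(0, 0), c(100, 100)),
                       sd = 1, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
    sweep(matrix(rnorm(n_per * ncol(centers), sd = sd), n_per), 2,
          centers[k, ], `+`)
  }))
  attr(X, "truth") <- rep(seq_len(nrow(centers)), each = n_per)
  X
}

# small synthetic grid shared by ENM tests
test_grid <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- gen_env_grid(24, seed = 99)
    g
  }
})

# random rate set with all six rates positive
random_sim_q <- function(seed, max_rate = 2) {
  set.seed(seed)
  r <- runif(6, 0.05, max_rate)
  sim_q(r[1], r[2], r[3], r[4], r[5], r[6])
}

# coding data frame from a named state vector like c(t1 = "A", t2 = "B|C")
coding_of <- function(states) {
  data.frame(species = names(states), states = unname(states),
             stringsAsFactors = FALSE)
}

# exhaustive Mk likelihood by summation over all internal-state
# assignments; independent of the pruning implementation
enumerate_loglik <- function(tree, tip_states, Q, pi = rep(1 / 3, 3)) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  edges <- tree$edge
  Pm <- lapply(seq_len(nrow(edges)), function(e) {
    as.matrix(Matrix::expm(Q * tree$edge.length[e]))
  })
  states <- c("A", "B", "C")
  tip_sets <- strsplit(tip_states[tree$tip.label], "|", fixed = TRUE)
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(1:3), nint)))
  for (g in seq_len(nrow(grid))) {
    assign_int <- grid[g, ]
    state_of <- function(node) {
      if (node <= ntip) NA_integer_ else assign_int[node - ntip]
    }
    prob <- pi[assign_int[1]]  # root = ntip + 1
    for (e in seq_len(nrow(edges))) {
      par <- state_of(edges[e, 1])
      ch <- edges[e, 2]
      if (ch <= ntip) {
        allowed <- match(tip_sets[[ch]], states)
        prob <- prob * sum(Pm[[e]][par, allowed])
      } else {
        prob <- prob * Pm[[e]][par, state_of(ch)]
      }
    }
    total <- total + prob
  }
  log(total)
}
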