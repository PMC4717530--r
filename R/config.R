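#' Analysis configuration
#'
#' One object carrying every tunable of the pipeline, with defaults at the
#' study-scale values: a cluster-number range of 2..15 crossed with a
#' fuzziness grid 1.1..2.0 (140 combinations), an Mk MCMC of 5,050,000
#' generations with 50,000 burn-in, a rate-proposal window (`ratedev`) of
#' 250, an exponential rate hyperprior whose mean moves on (0, 30], 100
#' ENM bootstrap replicates at a 70% training fraction, a clade-support
#' filter of 0.95 and a Quaternary boundary of 2.6 Ma.
#'
#' @param seed master seed; every stochastic stage derives its stream from
#'   it deterministically.
#' @param k_range integer vector of cluster numbers for the validity sweep.
#' @param m_grid numeric vector of fuzziness exponents (> 1).
#' @param mcmc list: `generations`, `burnin`, `thin`, `ratedev`,
#'   `hyper_max` (upper bound of the hyperprior-mean interval).
#' @param enm list: `replicates`, `train_frac`, `beta` (L1 regularization),
#'   `bins` (PNO bin count).
#' @param pp_filter posterior-probability filter for transition counting.
#' @param q_boundary Quaternary boundary in Ma.
#' @return An object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(seed = 1L,
                            k_range = 2:15,
                            m_grid = seq(1.1, 2.0, by = 0.1),
                            mcmc = list(),
                            enm = list(),
                            pp_filter = 0.95,
                            q_boundary = 2.6) {
  mc <- utils::modifyList(list(generations = 5050000L, burnin = 50000L,
                               thin = 1000L, ratedev = 250,
                               hyper_max = 30), mcmc)
  en <- utils::modifyList(list(replicates = 100L, train_frac = 0.7,
                               beta = 1.0, bins = 50L), enm)
  cfg <- list(seed = as.integer(seed), k_range = as.integer(k_range),
              m_grid = as.numeric(m_grid), mcmc = mc, enm = en,
              pp_filter = pp_filter, q_boundary = q_boundary)
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  stopifnot(length(cfg$k_range) >= 1, all(cfg$k_range >= 1),
            all(cfg$m_grid > 1),
            cfg$mcmc$generations > 0, cfg$mcmc$burnin >= 0,
            cfg$mcmc$thin > 0, cfg$mcmc$ratedev > 0,
            cfg$mcmc$hyper_max > 0,
            cfg$enm$replicates > 0,
            cfg$enm$train_frac > 0, cfg$enm$train_frac < 1,
            cfg$enm$beta >= 0, cfg$enm$bins >= 1,
            cfg$pp_filter >= 0, cfg$pp_filter <= 1,
            cfg$q_boundary > 0)
  invisible(cfg)
}

#' Read an analysis configuration from YAML
#'
#' Keys absent from the file keep their [analysis_config()] defaults.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(analysis_config, y[intersect(names(y), names(formals(analysis_config)))])
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  seed %d; K in {%s}; m in {%s}\n", x$seed,
              paste(range(x$k_range), collapse = "..")
              , paste(range(x$m_grid), collapse = "..")))
  cat(sprintf("  MCMC: %d generations, burn-in %d, thin %d, ratedev %g, hyperprior mean in (0, %g]\n",
              x$mcmc$generations, x$mcmc$burnin, x$mcmc$thin, x$mcmc$ratedev,
              x$mcmc$hyper_max))
  cat(sprintf("  ENM: %d bootstrap replicates, train fraction %g, beta %g, %d PNO bins\n",
              x$enm$replicates, x$enm$train_frac, x$enm$beta, x$enm$bins))
  cat(sprintf("  PP filter %g, Quaternary boundary %g Ma\n",
              x$pp_filter, x$q_boundary))
  invisible(x)
}

# internal: derive a reproducible 32-bit sub-seed from a master seed
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483647)
}
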