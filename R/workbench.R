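# Shared engineering: experiment configuration (YAML), reproducible seed
# derivation, run metadata, and small deterministic fixtures for tests and
# examples.

# Allowed keys and their defaults, per experiment kind. Defaults materialize
# the standard study conditions (total per-locus mutation rate 2e-9; editing
# C = 1, Q = 1, epsilon = 0, gamma0 = gamma1 = 1; splicing Q = 100,
# gamma0 = 0, gamma2 in {20, 50, 100}; sigma = 10; lambda = 1e-3).
.config_defaults <- function(experiment) {
  shared <- list(seed = 1L, mode = "editing", mu01 = 1e-9, mu10 = 1e-9,
                 C = 1, epsilon = 0, Q = 1, alpha = exp(1), gamma0 = 1,
                 gamma1 = 1, gamma2 = 20, sigma = 10, lambda = 1e-3)
  extra <- switch(
    experiment,
    equilibrium = list(beta = 1, error_rate = 0, n_sites = 1, v_hat = 1,
                       l = 1),
    scaling = list(Ne = 10^seq(2, 5, by = 0.5), l = c(2, 5, 10),
                   P0_opt = exp(1), t = 1e8),
    coevolve = list(Ne = 10^seq(2, 5, by = 0.5), l = 5, sigma_Q = c(2, 20),
                    n_lineages = 50, n_genes = 100, L = 1e8, Q_opt = 2,
                    U_Q = 1e-8, S_Q = 0.1, alpha = 1, epsilon = 1e-3),
    phylosim = list(Ne = 1e4, n_neutral = 10000, n_deleterious = 10000,
                    l_max = 10, C_mean = 0.1, epsilon = 1e-4, tree = NULL),
    stop("unknown experiment kind: ", experiment)
  )
  utils::modifyList(shared, extra)
}

#' Load and resolve an experiment configuration
#'
#' Reads a YAML file with an `experiment` key (`equilibrium`, `scaling`,
#' `coevolve`, or `phylosim`) and any subset of that experiment's parameters;
#' unknown keys are rejected by name, and every defaulted value is
#' materialized into the returned object so that saving it reproduces the
#' run exactly.
#'
#' @param path Path to a YAML configuration file.
#' @return A fully resolved named list of class `"gpd_config"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$experiment)) stop("config must name an 'experiment'")
  resolve_config(raw)
}

#' Resolve a configuration list against the experiment defaults
#'
#' @param config Named list containing at least `experiment`.
#' @return A fully resolved list of class `"gpd_config"`.
#' @export
resolve_config <- function(config) {
  experiment <- config$experiment
  defaults <- .config_defaults(experiment)
  unknown <- setdiff(names(config), c("experiment", names(defaults)))
  if (length(unknown) > 0L) {
    stop("unknown config key(s) for experiment '", experiment, "': ",
         paste(unknown, collapse = ", "))
  }
  out <- utils::modifyList(defaults, config[names(config) != "experiment"])
  structure(c(list(experiment = experiment), out), class = "gpd_config")
}

#' Save a resolved configuration as YAML
#'
#' @param config A `"gpd_config"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "gpd_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Derive a reproducible substream seed
#'
#' Deterministically maps a top-level seed and a stream index to a derived
#' seed in `[0, 2^31)`, so that parallel or re-ordered execution of lineages
#' and sites draws from fixed, named streams. The map is a linear congruence
#' with multipliers small enough that all arithmetic stays exact in doubles.
#'
#' @param seed Top-level integer seed.
#' @param stream Non-negative integer stream index.
#' @return A single integer seed.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, length(stream) == 1L, stream >= 0)
  p <- 2147483629
  as.integer((46337 * (seed %% p) + 30269 * (stream %% p) + 12345) %% p)
}

#' Run metadata for reproducibility
#'
#' @param config The resolved configuration (or any list of parameters).
#' @param seed The top-level seed used.
#' @param warnings Character vector of validity warnings raised by the run.
#' @return A list with the resolved config, seed, package version, R
#'   version, and timestamp.
#' @export
run_metadata <- function(config, seed, warnings = character(0)) {
  list(config = if (inherits(config, "gpd_config")) unclass(config) else config,
       seed = seed,
       package = "gpdevo",
       version = as.character(utils::packageVersion("gpdevo")),
       r_version = as.character(getRversion()),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       warnings = warnings)
}

#' Write run metadata as JSON
#'
#' @param meta A [run_metadata()] list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Toy fixture: a random tree with branch lengths
#'
#' @param n_tips Number of tips (4-8 covers the test range).
#' @param seed Integer seed.
#' @param scale Multiplier applied to `ape::rtree`'s uniform branch lengths.
#' @return A `phylo` tree.
#' @export
toy_tree <- function(n_tips = 4, seed = 1, scale = 1) {
  set.seed(seed)
  tr <- ape::rtree(n_tips)
  tr$edge.length <- tr$edge.length * scale
  tr
}

#' Toy fixture: the additive distance matrix of a tree
#'
#' Patristic (cophenetic) distances are exactly additive on the generating
#' tree, so neighbor joining must recover its topology from this matrix.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return A symmetric tip-by-tip distance matrix.
#' @export
toy_distance <- function(tree) {
  stats::cophenetic(tree)
}

#' Toy fixture: a small site panel
#'
#' @param n Number of sites per class.
#' @param seed Integer seed.
#' @param ... Passed through to [sample_site_panel()].
#' @return A `"site_panel"` data frame with `2 * n` sites.
#' @export
toy_panel <- function(n = 25, seed = 1, ...) {
  sample_site_panel(n_neutral = n, n_deleterious = n, seed = seed, ...)
}
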