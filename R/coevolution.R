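# Event-driven simulation of cis-trans coevolution: many genes subject to
# deleterious editing-type modification share one trans-factor whose value Q
# is under stabilizing selection through an independent function. Trans
# mutations arrive as an origin-fixation point process; between events each
# gene's cis-genotypic value evolves under its transition matrix.

#' Configuration of a coevolving lineage
#'
#' Defaults follow the coevolution study conditions: `n_genes = 100`
#' identical genes with `alpha = 1`, `gamma0 = 1`, `gamma1 = 1`, `C = 1`,
#' `sigma = 10`, `lambda = 1e-3`, `epsilon = 1e-3`; trans-factor
#' `Q_opt = 2`, `U_Q = 1e-8`, `S_Q = 0.1`, starting at its optimum; starting
#' cis-genotypic value `v0 = floor(l/2)` (the value with the largest
#' genotypic space, i.e. 1, 2, 5 for `l` = 2, 5, 10); total per-locus
#' mutation rate `2e-9`.
#'
#' @param Ne Effective population size.
#' @param l Number of cis-loci per gene.
#' @param L Branch length in time steps.
#' @param n_genes Number of genes subject to deleterious modification.
#' @param v0 Starting genotypic value (default `floor(l/2)`).
#' @param sigma_Q Width of the trans fitness function (2 = strong selection,
#'   20 = weak; `Inf` = neutral trans-factor).
#' @param Q_opt,U_Q,S_Q,Q0 Trans-factor parameters ([trans_factor()]);
#'   `Q0` defaults to `Q_opt`.
#' @param mu01,mu10 Per-locus cis mutation rates per time step.
#' @param alpha,gamma0,gamma1 Kinetic rates shared by all genes.
#' @param C,epsilon Architecture parameters shared by all genes.
#' @param sigma,lambda Selection parameters shared by all genes.
#' @param collapse_on_sample If `TRUE`, each gene's distribution is collapsed
#'   to the genotype sampled at a trans-mutation event; the default `FALSE`
#'   retains the full distribution and uses the sample only in that event's
#'   fitness evaluation.
#' @return An object of class `"lineage_config"`.
#' @export
lineage_config <- function(Ne, l = 5, L = 1e8, n_genes = 100,
                           v0 = NULL, sigma_Q = 20, Q_opt = 2,
                           U_Q = 1e-8, S_Q = 0.1, Q0 = Q_opt,
                           mu01 = 1e-9, mu10 = 1e-9,
                           alpha = 1, gamma0 = 1, gamma1 = 1,
                           C = 1, epsilon = 1e-3,
                           sigma = 10, lambda = 1e-3,
                           collapse_on_sample = FALSE) {
  if (is.null(v0)) v0 <- floor(l / 2)
  stopifnot(Ne >= 1, l >= 0, L >= 1, n_genes >= 1, v0 >= 0, v0 <= l,
            Q0 > 0, U_Q >= 0, gamma0 > 0, gamma1 > 0)
  # sequential-fixation validity for the cis chains
  theta <- 2 * Ne * (mu01 + mu10)
  if (theta >= 0.1) stop("2*Ne*(mu01+mu10) = ", signif(theta, 3), " >= 0.1")
  structure(
    list(Ne = Ne, l = as.integer(l), L = L, n_genes = as.integer(n_genes),
         v0 = as.integer(v0), sigma_Q = sigma_Q, Q_opt = Q_opt, U_Q = U_Q,
         S_Q = S_Q, Q0 = Q0, mu01 = mu01, mu10 = mu10, alpha = alpha,
         gamma0 = gamma0, gamma1 = gamma1, C = C, epsilon = epsilon,
         sigma = sigma, lambda = lambda,
         collapse_on_sample = isTRUE(collapse_on_sample)),
    class = "lineage_config"
  )
}

#' Simulate one coevolving lineage
#'
#' The number of trans mutations `m` is drawn from
#' `Poisson(2 * Ne * U_Q * L)` (redrawn in the unlikely case `m > L`), and
#' `m` distinct time steps are sampled uniformly and visited in order. At
#' each event one genotypic value per gene is sampled from its current
#' distribution; mutant (at `Q * exp(delta)`, `delta ~ Normal(0, S_Q)`) and
#' ancestral fitness are evaluated on those same sampled genotypes, so the
#' selection coefficient reflects only the change in `Q`. Fixation follows
#' [fixation_probability()]; a fixed mutation updates `Q` and rebuilds every
#' gene's transition matrix. After the final interval one genotypic value per
#' gene is sampled and its equilibrium `P_1` computed at the final `Q`.
#'
#' @param config A [lineage_config()].
#' @param seed Integer seed for this lineage (mandatory for
#'   reproducibility).
#' @return An object of class `"lineage_result"`: a list with `Q_final`,
#'   `v_final` (per gene), `P1` (per gene), `dist_final` (cis distribution at
#'   the end), `n_proposed`, `n_fixed`, and the `config`.
#' @export
simulate_lineage <- function(config, seed) {
  stopifnot(inherits(config, "lineage_config"))
  if (missing(seed)) stop("a seed is required for reproducible simulation")
  set.seed(seed)
  cfg <- config
  mean_m <- 2 * cfg$Ne * cfg$U_Q * cfg$L
  repeat {
    m <- stats::rpois(1L, mean_m)
    if (m <= cfg$L) break
  }
  times <- if (m > 0) sort(sample.int(cfg$L, m)) else integer(0)
  P0_opt <- cfg$alpha / cfg$gamma0
  res <- cpp_simulate_lineage(
    cfg$l, cfg$v0, cfg$n_genes, cfg$Ne, cfg$mu01, cfg$mu10, cfg$alpha,
    cfg$gamma0, cfg$gamma1, cfg$C, cfg$epsilon, cfg$sigma, cfg$lambda,
    P0_opt, cfg$Q0, cfg$Q_opt, cfg$sigma_Q, cfg$S_Q, cfg$L,
    as.numeric(times), cfg$collapse_on_sample
  )
  structure(c(res, list(config = cfg, seed = seed)),
            class = "lineage_result")
}

#' @export
print.lineage_result <- function(x, ...) {
  cat("coevolution lineage: Ne = ", x$config$Ne, ", l = ", x$config$l,
      ", L = ", format(x$config$L, scientific = TRUE), "\n",
      "  Q_final = ", format(x$Q_final, digits = 5),
      "  (", x$n_fixed, " of ", x$n_proposed,
      " trans mutations fixed)\n", sep = "")
  invisible(x)
}

#' Among-lineage mean of the final trans-genotypic value
#'
#' @param results A list of [simulate_lineage()] results.
#' @return The arithmetic mean of `Q_final` across lineages.
#' @export
qbar <- function(results) {
  if (length(results) == 0L) stop("empty list of lineage results")
  mean(vapply(results, function(r) r$Q_final, numeric(1L)))
}

#' Lineage-sharing statistic of modification events
#'
#' For each gene, the fraction of lineages in which the modified isoform is
#' present above `threshold` (`P_1 > threshold`); the statistic is the median
#' of those fractions across genes. With an even number of genes the
#' lower-middle order statistic is used, keeping the value on the lattice of
#' attainable lineage fractions.
#'
#' @param results A list of [simulate_lineage()] results sharing one gene
#'   panel.
#' @param threshold Abundance threshold (default 0.005).
#' @return The median lineage fraction, in `[0, 1]`.
#' @export
sharing_statistic <- function(results, threshold = 0.005) {
  if (length(results) == 0L) stop("empty list of lineage results")
  ng <- vapply(results, function(r) length(r$P1), integer(1L))
  if (length(unique(ng)) != 1L) {
    stop("lineages have mismatched gene panels")
  }
  P1 <- vapply(results, function(r) r$P1, numeric(ng[1L]))  # genes x lineages
  if (is.null(dim(P1))) P1 <- matrix(P1, nrow = 1L)
  frac <- rowMeans(P1 > threshold)
  sort(frac)[floor((length(frac) + 1) / 2)]
}

#' Grid of coevolution simulations
#'
#' Runs [simulate_lineage()] over a grid of `Ne`, `l` and `sigma_Q` with
#' `n_lineages` replicate lineages per cell, and summarizes the among-lineage
#' mean `Q` ([qbar()]) with its Monte-Carlo standard error and the
#' [sharing_statistic()].
#'
#' @param Ne Vector of effective population sizes (the study grid is
#'   `10^seq(2, 5, 0.5)`).
#' @param l Vector of cis-locus counts.
#' @param sigma_Q Vector of trans selection widths.
#' @param n_lineages Replicate lineages per cell.
#' @param L Simulation duration(s) in time steps.
#' @param seed Top-level seed; per-lineage seeds are derived with
#'   [substream_seed()].
#' @param ... Further arguments passed to [lineage_config()].
#' @return A long-format `data.frame` with columns `Ne, l, sigma_Q, L, qbar,
#'   qbar_se, sharing, n_lineages`.
#' @export
coevolution_experiment <- function(Ne = 10^seq(2, 5, by = 0.5), l = 5,
                                   sigma_Q = c(2, 20), n_lineages = 50,
                                   L = 1e8, seed = 1, ...) {
  grid <- expand.grid(Ne = Ne, l = l, sigma_Q = sigma_Q, L = L,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cfg <- lineage_config(Ne = g$Ne, l = g$l, sigma_Q = g$sigma_Q,
                          L = g$L, ...)
    res <- lapply(seq_len(n_lineages), function(k) {
      simulate_lineage(cfg, seed = substream_seed(seed, i * 1000L + k))
    })
    qs <- vapply(res, function(r) r$Q_final, numeric(1L))
    data.frame(Ne = g$Ne, l = g$l, sigma_Q = g$sigma_Q, L = g$L,
               qbar = mean(qs),
               qbar_se = stats::sd(qs) / sqrt(length(qs)),
               sharing = sharing_statistic(res),
               n_lineages = n_lineages)
  })
  do.call(rbind, rows)
}
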