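# Origin-fixation (sequential-fixation) Markov chain on the cis-genotypic
# value v in {0, ..., l}. One substitution at a time; valid when
# 2*Ne*(mu01+mu10) << 1. The chain's tridiagonal transition matrix combines
# diploid mutant supply with Kimura fixation probabilities.

#' Kinetics configuration helper
#'
#' Bundles the kinetic constants shared by the evolutionary modules.
#' `gamma2` is only used for splicing-type systems.
#'
#' @param alpha Production rate of `I_0`.
#' @param gamma0,gamma1,gamma2 Decay rates.
#' @return A plain list with class `"kinetics_config"`.
#' @export
kinetics_config <- function(alpha = 1, gamma0 = 1, gamma1 = 1, gamma2 = 20) {
  stopifnot(alpha >= 0, gamma0 >= 0, gamma1 > 0, gamma2 > 0)
  structure(list(alpha = alpha, gamma0 = gamma0, gamma1 = gamma1,
                 gamma2 = gamma2),
            class = "kinetics_config")
}

#' Selection configuration helper
#'
#' For editing-type events `P_opt` is the optimum of the functional unmodified
#' isoform `P_0`; if `NULL` it follows the rule `P_opt = alpha/gamma0` (the
#' abundance reached in the absence of modification). For splicing-type
#' events `P_opt` is the optimum of the functional spliced isoform `P_1`; if
#' `NULL` it is the `P_1` attained by the genotype fully committed to `I_1`
#' (`v = l`).
#'
#' @param sigma Width of the stabilizing fitness function for the functional
#'   isoform.
#' @param lambda Toxicity of the deleterious isoform.
#' @param P_opt Optional explicit optimum; `NULL` applies the mode rule.
#' @param exponent Deviation exponent passed to [fitness_stabilizing()].
#' @return A plain list with class `"selection_config"`.
#' @export
selection_config <- function(sigma = 10, lambda = 1e-3, P_opt = NULL,
                             exponent = c("squared", "linear")) {
  stopifnot(sigma > 0, lambda >= 0)
  structure(list(sigma = sigma, lambda = lambda, P_opt = P_opt,
                 exponent = match.arg(exponent)),
            class = "selection_config")
}

.resolve_p_opt <- function(sel, arch, kin, Q) {
  if (!is.null(sel$P_opt)) return(sel$P_opt)
  if (arch$mode == "editing") {
    if (kin$gamma0 <= 0) {
      stop("P_opt rule alpha/gamma0 needs gamma0 > 0; supply P_opt explicitly")
    }
    kin$alpha / kin$gamma0
  } else {
    b <- conversion_rate(arch, arch$l, Q)   # fully committed genotype
    st <- equilibrium_branching(kin$alpha, b,
                                c(kin$gamma0, kin$gamma1, kin$gamma2))
    st$abundances[2L]
  }
}

#' Fitness of every cis-genotypic value
#'
#' For each `v` in `0..l`: map the genotype to conversion rate(s) via the
#' architecture, solve the steady-state kinetics, and compose the mode's
#' fitness: editing-type `w = w0(P0) * w1(P1)` (stabilizing on the functional
#' unmodified isoform, toxicity on the modified one); splicing-type
#' `w = w1(P1) * w2(P2)`.
#'
#' @param arch A [cis_architecture()].
#' @param kin A [kinetics_config()].
#' @param sel A [selection_config()].
#' @param Q Trans-genotypic value.
#' @return Numeric vector of fitnesses, one per `v = 0..l`.
#' @export
genotype_fitness_profile <- function(arch, kin, sel, Q) {
  stopifnot(inherits(arch, "cis_architecture"),
            inherits(kin, "kinetics_config"),
            inherits(sel, "selection_config"))
  p_opt <- .resolve_p_opt(sel, arch, kin, Q)
  # a genotype that produces none of the stabilized isoform (reachable for
  # splicing with epsilon = 0 at v = 0) is effectively lethal: fitness 0
  stab <- function(P) {
    if (P <= 0) return(0)
    fitness_stabilizing(P, p_opt, sel$sigma, exponent = sel$exponent)
  }
  vapply(0:arch$l, function(v) {
    b <- conversion_rate(arch, v, Q)
    if (arch$mode == "editing") {
      st <- equilibrium_two_isoform(kin$alpha, b, kin$gamma0, kin$gamma1)
      stab(st$abundances[1L]) * fitness_toxicity(st$abundances[2L],
                                                 sel$lambda)
    } else {
      st <- equilibrium_branching(kin$alpha, b,
                                  c(kin$gamma0, kin$gamma1, kin$gamma2))
      stab(st$abundances[2L]) * fitness_toxicity(st$abundances[3L],
                                                 sel$lambda)
    }
  }, numeric(1L))
}

#' Build the origin-fixation transition matrix
#'
#' Row-stochastic tridiagonal matrix over `v = 0..l` with
#' `T[v, v+1] = 2*(l-v)*Ne*mu01 * Pr(fix | s_up)` and
#' `T[v, v-1] = 2*v*Ne*mu10 * Pr(fix | s_down)`, where the selection
#' coefficients come from adjacent fitness ratios and fixation probabilities
#' from [fixation_probability()]. The sequential-fixation approximation
#' requires `2*Ne*(mu01+mu10) < 0.01`: the builder warns beyond that and
#' errors at `>= 0.1`.
#'
#' @param fitness Non-negative fitness profile over `v = 0..l` (length
#'   `l + 1`); zero entries mark lethal genotypes.
#' @param Ne Effective population size.
#' @param mu01,mu10 Per-locus mutation rates per time step.
#' @return A `(l+1) x (l+1)` matrix of class `"transition_matrix"` with
#'   attributes `Ne`, `mu01`, `mu10`.
#' @export
build_transition_matrix <- function(fitness, Ne, mu01, mu10) {
  l <- length(fitness) - 1L
  stopifnot(l >= 0L, all(fitness >= 0), any(fitness > 0), Ne >= 1,
            mu01 >= 0, mu10 >= 0)
  # lethal genotypes (fitness 0) are floored so that selection coefficients
  # into them are -1 (fixation probability 0) and out of them effectively
  # infinite, without 0/0 in the ratios
  fitness <- pmax(fitness, 1e-300)
  theta <- 2 * Ne * (mu01 + mu10)
  if (theta >= 0.1) {
    stop("sequential-fixation model invalid: 2*Ne*(mu01+mu10) = ",
         signif(theta, 3), " >= 0.1")
  }
  if (theta >= 0.01) {
    warning("sequential-fixation approximation questionable: ",
            "2*Ne*(mu01+mu10) = ", signif(theta, 3), " >= 0.01")
  }
  Tm <- diag(1, l + 1L)
  if (l > 0L) {
    v <- 0:(l - 1L)
    s_up <- fitness[v + 2L] / fitness[v + 1L] - 1
    s_dn <- fitness[v + 1L] / fitness[v + 2L] - 1
    up <- 2 * (l - v) * Ne * mu01 * fixation_probability(Ne, s_up)
    dn <- 2 * (v + 1L) * Ne * mu10 * fixation_probability(Ne, s_dn)
    for (i in seq_len(l)) {
      Tm[i, i + 1L] <- up[i]
      Tm[i + 1L, i] <- dn[i]
    }
    diag(Tm) <- 1 - (rowSums(Tm) - 1)
    if (any(diag(Tm) < 0)) {
      stop("off-diagonal transition mass exceeds 1; the per-time-step ",
           "substitution probabilities violate the sequential-fixation ",
           "validity condition")
    }
  }
  structure(Tm, class = c("transition_matrix", "matrix"),
            Ne = Ne, mu01 = mu01, mu10 = mu10)
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("origin-fixation transition matrix over v = 0..", nrow(x) - 1L,
      " (Ne = ", attr(x, "Ne"), ")\n", sep = "")
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' Evolve a distribution over cis-genotypic values
#'
#' Computes `v_0 %*% T^t` by binary exponentiation (about `log2(t)` matrix
#' squarings, so `t = 1e8` is cheap). The result is renormalized whenever
#' accumulated round-off moves its sum away from 1 by more than `1e-12`.
#'
#' @param dist Probability vector over `v = 0..l` (sums to 1).
#' @param Tm Transition matrix from [build_transition_matrix()].
#' @param t Non-negative integer number of time steps (may be given as a
#'   double, e.g. `1e8`).
#' @return The evolved probability vector.
#' @export
evolve_distribution <- function(dist, Tm, t) {
  stopifnot(is.numeric(dist), length(dist) == nrow(Tm),
            all(dist >= 0), abs(sum(dist) - 1) < 1e-10)
  if (length(t) != 1L || t < 0 || t != round(t)) {
    stop("t must be a single non-negative integer")
  }
  v <- matrix(dist, nrow = 1L)
  P <- unclass(Tm)
  t <- round(t)
  while (t > 0) {
    if (t %% 2 == 1) v <- v %*% P
    t <- t %/% 2
    if (t > 0) P <- P %*% P
  }
  out <- pmax(as.numeric(v), 0)
  if (abs(sum(out) - 1) > 1e-12) out <- out / sum(out)
  out
}

#' Modification level implied by a genotypic value
#'
#' Evaluates the equilibrium modification level `f` for a (possibly
#' fractional) cis-genotypic value `v`: editing-type `f = beta/(beta+gamma1)`;
#' splicing-type `f = P_2/(P_1+P_2)` from the three-isoform steady state.
#'
#' @param arch A [cis_architecture()].
#' @param v Genotypic value(s) in `[0, l]` (vectorized).
#' @param Q Trans-genotypic value.
#' @param kin A [kinetics_config()].
#' @return Modification level(s) in `[0, 1]`.
#' @export
modification_level_at <- function(arch, v, Q, kin = kinetics_config()) {
  vapply(v, function(vi) {
    b <- conversion_rate(arch, vi, Q)
    if (arch$mode == "editing") {
      b / (b + kin$gamma1)
    } else {
      st <- equilibrium_branching(kin$alpha, b,
                                  c(kin$gamma0, kin$gamma1, kin$gamma2))
      modification_level(st, "splicing")
    }
  }, numeric(1L))
}

#' Mean modification level of an evolved distribution
#'
#' The headline statistic is the modification level evaluated at the expected
#' genotypic value, `f(E[v])` (the "phylogenetic mean"); the expectation of
#' the level itself, `E[f] = sum_v p(v) f(v)`, is reported alongside because
#' the two differ whenever `f` is nonlinear in `v`.
#'
#' @param dist Probability vector over `v = 0..l`.
#' @param arch A [cis_architecture()].
#' @param Q Trans-genotypic value.
#' @param kin A [kinetics_config()].
#' @return A list with `mean_v`, `f_mean_v` (primary), and `mean_f`.
#' @export
mean_modification_level <- function(dist, arch, Q, kin = kinetics_config()) {
  l <- arch$l
  stopifnot(length(dist) == l + 1L, all(dist >= 0),
            abs(sum(dist) - 1) < 1e-8)
  mean_v <- sum((0:l) * dist)
  f_v <- modification_level_at(arch, 0:l, Q, kin)
  list(mean_v = mean_v,
       f_mean_v = modification_level_at(arch, mean_v, Q, kin),
       mean_f = sum(dist * f_v))
}

#' Long-run mean modification level across a parameter grid
#'
#' Reproduces the scaling experiments: for every combination of `Ne`, `l`,
#' mutation-rate pair, and optimal expression level, evolve the cis-genotypic
#' value for `t` time steps from its mode-specific start (editing: `v = 0`;
#' splicing: `v = l`) and record the mean genotypic value and modification
#' level. Editing-type runs are parameterized by the optimal expression level
#' `P0_opt` with `alpha = P0_opt * gamma0`; splicing-type runs take `alpha`
#' directly (there `gamma0 = 0`).
#'
#' @param Ne Vector of effective population sizes.
#' @param l Vector of cis-locus counts.
#' @param mu01,mu10 Equal-length vectors of mutation-rate pairs (each index
#'   is one bias scenario).
#' @param P0_opt Vector of optimal expression levels (editing) or `alpha`
#'   values (splicing).
#' @param t Number of time steps.
#' @param mode `"editing"` or `"splicing"`.
#' @param Q,C,epsilon Architecture parameters.
#' @param sigma,lambda Selection parameters.
#' @param gamma0,gamma1,gamma2 Decay rates (`gamma0` defaults to 1 for
#'   editing and 0 for splicing).
#' @return A long-format `data.frame` with one row per grid point and columns
#'   `Ne, l, mu01, mu10, P0_opt, mean_v, f_mean_v, mean_f`.
#' @export
scaling_experiment <- function(Ne = 10^seq(2, 5, by = 0.5),
                               l = c(2, 5, 10),
                               mu01 = 1e-9, mu10 = 1e-9,
                               P0_opt = exp(1),
                               t = 1e8,
                               mode = c("editing", "splicing"),
                               Q = 1, C = 1, epsilon = 0,
                               sigma = 10, lambda = 1e-3,
                               gamma0 = NULL, gamma1 = 1, gamma2 = 20) {
  mode <- match.arg(mode)
  stopifnot(length(mu01) == length(mu10))
  if (is.null(gamma0)) gamma0 <- if (mode == "editing") 1 else 0
  grid <- expand.grid(Ne = Ne, l = l, bias = seq_along(mu01),
                      P0_opt = P0_opt, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    arch <- cis_architecture(g$l, mu01 = mu01[g$bias], mu10 = mu10[g$bias],
                             C = C, epsilon = epsilon, mode = mode)
    alpha <- if (mode == "editing") g$P0_opt * gamma0 else g$P0_opt
    kin <- kinetics_config(alpha = alpha, gamma0 = gamma0,
                           gamma1 = gamma1, gamma2 = gamma2)
    sel <- selection_config(sigma = sigma, lambda = lambda)
    w <- genotype_fitness_profile(arch, kin, sel, Q)
    Tm <- build_transition_matrix(w, g$Ne, arch$mu01, arch$mu10)
    start <- rep(0, g$l + 1L)
    start[if (mode == "editing") 1L else g$l + 1L] <- 1
    d <- evolve_distribution(start, Tm, t)
    m <- mean_modification_level(d, arch, Q, kin)
    data.frame(Ne = g$Ne, l = g$l, mu01 = mu01[g$bias], mu10 = mu10[g$bias],
               P0_opt = g$P0_opt, mean_v = m$mean_v,
               f_mean_v = m$f_mean_v, mean_f = m$mean_f)
  })
  do.call(rbind, rows)
}
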