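# Steady-state isoform kinetics.
#
# All solvers describe mass-action systems in which an unmodified isoform I_0
# is produced at rate alpha, converted to modified isoforms at per-molecule
# rates beta, and every isoform decays at rate gamma_i. Equilibria are
# obtained by direct linear solve; forward ODE integration is used only as a
# test oracle.

#' Construct a kinetic state
#'
#' A kinetic state holds equilibrium isoform abundances `P_0 .. P_n` together
#' with the modification level `f` when one is defined for the system's
#' topology (editing-type: `f = P_1/(P_0+P_1)`; splicing-type:
#' `f = P_2/(P_1+P_2)`).
#'
#' @param abundances Numeric vector of non-negative equilibrium abundances,
#'   ordered `P_0, P_1, ...`.
#' @param mode Modification type the default level refers to: `"editing"`,
#'   `"splicing"`, or `NA` when neither definition applies.
#' @param alpha Production rate of `I_0` (kept for flux diagnostics).
#' @param gammas Per-isoform decay rates (kept for flux diagnostics).
#' @return An object of class `"kinetic_state"`: a list with elements
#'   `abundances`, `level`, `mode`, `alpha`, `gammas`.
#' @export
kinetic_state <- function(abundances, mode = NA_character_, alpha = NA_real_,
                          gammas = NULL) {
  stopifnot(is.numeric(abundances), length(abundances) >= 1L)
  if (any(abundances < -1e-9)) {
    stop("negative equilibrium abundance: the kinetic system is not valid")
  }
  abundances <- pmax(abundances, 0)
  st <- structure(
    list(abundances = unname(abundances), level = NA_real_, mode = mode,
         alpha = alpha, gammas = gammas),
    class = "kinetic_state"
  )
  if (!is.na(mode)) {
    st$level <- modification_level(st, mode)
  }
  st
}

#' @export
print.kinetic_state <- function(x, ...) {
  n <- length(x$abundances)
  cat("Kinetic state with", n, "isoform(s)\n")
  cat("  P:", format(x$abundances, digits = 6), "\n")
  if (!is.na(x$mode)) {
    cat("  modification level f (", x$mode, "): ",
        format(x$level, digits = 6), "\n", sep = "")
  }
  invisible(x)
}

# Shared degenerate-system guard: reciprocal condition below tol means the
# steady state is not uniquely determined (e.g. an isoform with inflow but no
# outflow).
.check_nonsingular <- function(A, tol = 1e-12) {
  k <- tryCatch(kappa(A, exact = TRUE), error = function(e) Inf)
  if (!is.finite(k) || k <= 0 || 1 / k < tol) {
    stop("degenerate kinetic system: the steady-state linear system is ",
         "singular (every isoform with inflow needs gamma_i > 0 or an ",
         "outgoing conversion)")
  }
  invisible(TRUE)
}

.check_rates <- function(alpha, gammas, betas) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0) {
    stop("alpha must be a single non-negative production rate")
  }
  if (any(gammas < 0)) stop("decay rates gamma must be non-negative")
  if (any(betas < 0)) stop("conversion rates beta must be non-negative")
  invisible(TRUE)
}

#' Equilibrium of the two-isoform editing-type system
#'
#' Closed-form steady state of the system in which `I_0` (produced at rate
#' `alpha`, decaying at `gamma0`) is converted to `I_1` (decaying at
#' `gamma1`) at per-molecule rate `beta`:
#' `P_0 = alpha/(beta+gamma0)`, `P_1 = alpha*beta/(gamma1*(beta+gamma0))`,
#' and the editing level is `f = beta/(beta+gamma1)`.
#'
#' @param alpha Production rate of `I_0`.
#' @param beta Per-molecule conversion rate `I_0 -> I_1`.
#' @param gamma0,gamma1 Decay rates of `I_0` and `I_1`.
#' @return A [kinetic_state()] with `mode = "editing"`.
#' @examples
#' equilibrium_two_isoform(1, 1, 1, 1) # P = (0.5, 0.5), f = 0.5
#' @export
equilibrium_two_isoform <- function(alpha, beta, gamma0, gamma1) {
  .check_rates(alpha, c(gamma0, gamma1), beta)
  if (beta + gamma0 <= 0) {
    stop("degenerate kinetic system: beta + gamma0 must be positive")
  }
  if (gamma1 <= 0) {
    stop("degenerate kinetic system: gamma1 must be positive")
  }
  P0 <- alpha / (beta + gamma0)
  P1 <- alpha * beta / (gamma1 * (beta + gamma0))
  kinetic_state(c(P0, P1), mode = "editing", alpha = alpha,
                gammas = c(gamma0, gamma1))
}

#' Equilibrium of the branching (one-step, multi-isoform) system
#'
#' `I_0` is converted to `n` alternative isoforms `I_1 .. I_n` at rates
#' `betas[1] .. betas[n]`; each molecule of `I_0` is modified into exactly one
#' of them. With `n = 2` this is the splicing-type system (`I_1` functional,
#' `I_2` mis-processed) and the returned state carries the splicing level
#' `f = P_2/(P_1+P_2)`.
#'
#' @param alpha Production rate of `I_0`.
#' @param betas Conversion rates `I_0 -> I_i`, length `n`.
#' @param gammas Decay rates, length `n + 1` (`gamma_0 .. gamma_n`).
#' @return A [kinetic_state()]; `mode = "splicing"` when `n == 2`, `"editing"`
#'   when `n == 1`, otherwise `NA`.
#' @export
equilibrium_branching <- function(alpha, betas, gammas) {
  n <- length(betas)
  stopifnot(n >= 1L, length(gammas) == n + 1L)
  .check_rates(alpha, gammas, betas)
  A <- diag(c(sum(betas) + gammas[1L], -gammas[-1L]), nrow = n + 1L)
  A[-1L, 1L] <- betas
  .check_nonsingular(A)
  P <- solve(A, c(alpha, rep(0, n)))
  mode <- if (n == 2L) "splicing" else if (n == 1L) "editing" else NA_character_
  kinetic_state(P, mode = mode, alpha = alpha, gammas = gammas)
}

#' Equilibrium of the multi-step chain system
#'
#' Sequential modification `I_0 -> I_1 -> ... -> I_n`, where `I_i` is produced
#' by modifying `I_{i-1}` at rate `betas[i]`.
#'
#' @param alpha Production rate of `I_0`.
#' @param betas Conversion rates along the chain
#'   (`beta_{0->1}, ..., beta_{n-1->n}`), length `n`.
#' @param gammas Decay rates, length `n + 1`.
#' @return A [kinetic_state()] (`mode` is `NA` for `n > 1`; pass the state to
#'   [modification_level()] with an explicit mode if one applies).
#' @export
equilibrium_chain <- function(alpha, betas, gammas) {
  n <- length(betas)
  stopifnot(n >= 1L, length(gammas) == n + 1L)
  .check_rates(alpha, gammas, betas)
  # Lower-bidiagonal system: outflow of I_i is beta_{i->i+1} + gamma_i,
  # inflow is beta_{i-1->i} * P_{i-1}.
  out <- c(betas, 0) + gammas          # outflow coefficient of each isoform
  A <- diag(c(out[1L], -out[-1L]), nrow = n + 1L)
  for (i in seq_len(n)) A[i + 1L, i] <- betas[i]
  .check_nonsingular(A)
  P <- solve(A, c(alpha, rep(0, n)))
  mode <- if (n == 1L) "editing" else NA_character_
  kinetic_state(P, mode = mode, alpha = alpha, gammas = gammas)
}

#' Equilibrium of the uniform multi-site chain
#'
#' `n_sites` equivalent modifiable sites per molecule with a constant per-site
#' rate `beta`; isoform `I_i` carries `i` modified sites, so
#' `beta_{i->i+1} = (n_sites - i) * beta`.
#'
#' @param alpha Production rate of `I_0`.
#' @param beta Per-site modification rate.
#' @param n_sites Number of modifiable sites (`>= 1`).
#' @param gammas Decay rates, length `n_sites + 1`.
#' @return A [kinetic_state()].
#' @export
equilibrium_multisite <- function(alpha, beta, n_sites, gammas) {
  stopifnot(length(n_sites) == 1L, n_sites >= 1L)
  if (beta < 0) stop("conversion rates beta must be non-negative")
  equilibrium_chain(alpha, betas = (n_sites:1) * beta, gammas = gammas)
}

#' Equilibrium of the general conversion-matrix system
#'
#' Every isoform `I_i` may be converted to any other `I_j` at per-molecule
#' rate `beta_matrix[i+1, j+1]`. The steady state solves the full mass
#' balance: inflow `alpha` (into `I_0`) plus conversion inflow equals decay
#' plus conversion outflow for every isoform, which implies the flux identity
#' `alpha = sum(gammas * P)`.
#'
#' @param alpha Production rate of `I_0`.
#' @param beta_matrix Square matrix of conversion rates with zero diagonal;
#'   row `i`, column `j` is the rate `I_{i-1} -> I_{j-1}`.
#' @param gammas Decay rates, one per isoform.
#' @return A [kinetic_state()].
#' @export
equilibrium_general <- function(alpha, beta_matrix, gammas) {
  B <- as.matrix(beta_matrix)
  m <- nrow(B)
  stopifnot(ncol(B) == m, length(gammas) == m)
  if (any(diag(B) != 0)) stop("beta_matrix must have a zero diagonal")
  .check_rates(alpha, gammas, B)
  # M %*% P = b with M[i,i] = -(sum_j beta_ij + gamma_i), M[i,j] = beta_ji.
  M <- t(B)
  diag(M) <- -(rowSums(B) + gammas)
  .check_nonsingular(M)
  P <- solve(M, c(-alpha, rep(0, m - 1L)))
  kinetic_state(P, mode = NA_character_, alpha = alpha, gammas = gammas)
}

#' Equilibrium under alternative transcription
#'
#' Isoform identity is decided at transcription: with total transcription rate
#' `alpha`, `I_1` is transcribed with probability `error_rate` and `I_0`
#' otherwise, giving `P_0 = (1-E)*alpha/gamma0` and `P_1 = E*alpha/gamma1`.
#'
#' @param alpha Total transcription rate.
#' @param error_rate Probability `E` in `[0, 1]` that `I_1` is transcribed.
#' @param gamma0,gamma1 Decay rates (both must be positive).
#' @return A [kinetic_state()] with `mode = "editing"`.
#' @export
equilibrium_alt_transcription <- function(alpha, error_rate, gamma0, gamma1) {
  .check_rates(alpha, c(gamma0, gamma1), 0)
  if (error_rate < 0 || error_rate > 1) {
    stop("error_rate must lie in [0, 1]")
  }
  if (gamma0 <= 0 || gamma1 <= 0) {
    stop("degenerate kinetic system: gamma0 and gamma1 must be positive")
  }
  P0 <- (1 - error_rate) * alpha / gamma0
  P1 <- error_rate * alpha / gamma1
  kinetic_state(c(P0, P1), mode = "editing", alpha = alpha,
                gammas = c(gamma0, gamma1))
}

#' Modification level of a kinetic state
#'
#' Editing-type: `f = P_1/(P_0 + P_1)`, the modified fraction of the gene
#' product. Splicing-type: `f = P_2/(P_1 + P_2)`, the mis-processed fraction
#' of the processed product. If all abundances in the denominator are zero
#' (reachable only for genotypes with no modification activity at all) the
#' level is defined as 0 with a warning.
#'
#' @param state A [kinetic_state()] or a bare numeric abundance vector.
#' @param mode `"editing"` or `"splicing"`; defaults to the state's own mode.
#' @return The modification level, a fraction in `[0, 1]`.
#' @export
modification_level <- function(state, mode = NULL) {
  P <- if (inherits(state, "kinetic_state")) state$abundances else state
  if (is.null(mode)) {
    mode <- if (inherits(state, "kinetic_state")) state$mode else NA_character_
  }
  if (is.na(mode) || !mode %in% c("editing", "splicing")) {
    stop("mode must be \"editing\" or \"splicing\"")
  }
  if (mode == "editing") {
    stopifnot(length(P) >= 2L)
    num <- P[2L]
    den <- P[1L] + P[2L]
  } else {
    stopifnot(length(P) >= 3L)
    num <- P[3L]
    den <- P[2L] + P[3L]
  }
  if (den <= 0) {
    warning("all abundances in the denominator are zero; ",
            "modification level defined as 0")
    return(0)
  }
  num / den
}
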