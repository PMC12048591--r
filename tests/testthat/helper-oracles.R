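# Shared oracles and fixtures, all generated in code.

# Forward ODE integration of the general mass-action system: independent
# oracle for every equilibrium solver. B[i, j] is the conversion rate
# I_{i-1} -> I_{j-1}.
ode_equilibrium <- function(alpha, B, gammas, t_end = 2000, tol = 1e-10) {
  B <- as.matrix(B)
  derivs <- function(t, P, parms) {
    inflow <- c(alpha, rep(0, length(P) - 1L)) + as.numeric(t(B) %*% P)
    list(inflow - (rowSums(B) + gammas) * P)
  }
  out <- deSolve::ode(y = rep(0, length(gammas)), times = c(0, t_end),
                      func = derivs, parms = NULL,
                      rtol = tol, atol = tol)
  unname(out[nrow(out), -1L])
}

# Conversion matrix of a chain I_0 -> I_1 -> ... -> I_n.
chain_beta_matrix <- function(betas) {
  n <- length(betas) + 1L
  B <- matrix(0, n, n)
  for (i in seq_along(betas)) B[i, i + 1L] <- betas[i]
  B
}

# Conversion matrix of a branching system I_0 -> {I_1..I_n}.
branching_beta_matrix <- function(betas) {
  n <- length(betas) + 1L
  B <- matrix(0, n, n)
  B[1L, -1L] <- betas
  B
}

# A random well-posed general kinetic system (all gammas positive).
random_kinetic_system <- function(n_isoforms, seed) {
  set.seed(seed)
  B <- matrix(stats::runif(n_isoforms^2, 0, 2), n_isoforms)
  diag(B) <- 0
  list(alpha = stats::runif(1, 0.5, 3), B = B,
       gammas = stats::runif(n_isoforms, 0.5, 2))
}

# Stationary distribution of a finite Markov chain via its left eigenvector:
# independent oracle for long-run distributions.
stationary_distribution <- function(Tm) {
  e <- eigen(t(unclass(Tm)))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

# Study-condition defaults for a deleterious editing-type event.
editing_setup <- function(l, P0_opt = exp(1), mu01 = 1e-9, mu10 = 1e-9) {
  arch <- cis_architecture(l, mu01 = mu01, mu10 = mu10, C = 1, epsilon = 0,
                           mode = "editing")
  kin <- kinetics_config(alpha = P0_opt, gamma0 = 1, gamma1 = 1)
  sel <- selection_config(sigma = 10, lambda = 1e-3)
  list(arch = arch, kin = kin, sel = sel)
}
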