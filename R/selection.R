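# Fitness functions, selection coefficients and Kimura fixation
# probabilities (diploid convention throughout).

#' Gaussian stabilizing selection on an abundance
#'
#' Fitness of an isoform under stabilizing selection is a Gaussian function of
#' its log abundance: `exp(-(ln P - ln P_opt)^2 / (2 * sigma^2))`, maximal
#' (`= 1`) exactly at `P = P_opt`. The `exponent = "linear"` switch drops the
#' square, giving a form that is monotone in `ln P` rather than peaked at the
#' optimum; it is provided only for sensitivity checks.
#'
#' @param P Abundance (`> 0`; vectorized).
#' @param P_opt Optimal abundance (`> 0`).
#' @param sigma Width of the fitness function (`> 0`; `Inf` disables
#'   selection).
#' @param exponent `"squared"` (default, a true Gaussian) or `"linear"`.
#' @return Fitness in `(0, 1]` (the linear form may exceed 1 below the
#'   optimum).
#' @export
fitness_stabilizing <- function(P, P_opt, sigma,
                                exponent = c("squared", "linear")) {
  exponent <- match.arg(exponent)
  if (any(P <= 0)) stop("P must be positive (log-scale fitness)")
  if (P_opt <= 0) stop("P_opt must be positive")
  if (sigma <= 0) stop("sigma must be positive")
  if (is.infinite(sigma)) return(rep(1, length(P)))
  d <- log(P) - log(P_opt)
  if (exponent == "squared") d <- d^2
  exp(-d / (2 * sigma^2))
}

#' Toxicity selection on an abundance
#'
#' Fitness of a deleterious (toxic) isoform declines exponentially with its
#' abundance: `exp(-lambda * P)`. `lambda = 0` means the abundance is not
#' under selection.
#'
#' @param P Abundance (`>= 0`; vectorized).
#' @param lambda Toxicity parameter (`>= 0`).
#' @return Fitness in `(0, 1]`.
#' @export
fitness_toxicity <- function(P, lambda) {
  if (any(P < 0)) stop("P must be non-negative")
  if (lambda < 0) stop("lambda must be non-negative")
  exp(-lambda * P)
}

#' Stabilizing selection on the trans-genotypic value
#'
#' The trans-factor's contribution to fitness through functions independent of
#' the focal modification events: the same Gaussian-in-log form as
#' [fitness_stabilizing()], applied to `Q`.
#'
#' @param Q Trans-genotypic value (`> 0`).
#' @param Q_opt Optimal value (`> 0`).
#' @param sigma_Q Width of the fitness function (`> 0`, possibly `Inf`).
#' @param exponent Passed to [fitness_stabilizing()].
#' @return Fitness in `(0, 1]`.
#' @export
fitness_trans <- function(Q, Q_opt, sigma_Q,
                          exponent = c("squared", "linear")) {
  fitness_stabilizing(Q, Q_opt, sigma_Q, exponent = match.arg(exponent))
}

#' Multiplicative overall fitness
#'
#' Each isoform (and, in the coevolution model, the trans-factor) contributes
#' to fitness independently; overall fitness is the product of the
#' components. An empty component list is neutral (fitness 1).
#'
#' @param components Numeric vector or list of fitness components in
#'   `(0, 1]`.
#' @return The product of the components.
#' @export
overall_fitness <- function(components) {
  w <- unlist(components, use.names = FALSE)
  if (length(w) == 0L) return(1)
  if (any(w <= 0) || any(w > 1)) {
    stop("fitness components must lie in (0, 1]")
  }
  prod(w)
}

#' Selection coefficient of a mutant
#'
#' `s = w_mutant / w_ancestor - 1`.
#'
#' @param w_mutant Mutant fitness (`>= 0`).
#' @param w_ancestor Ancestral fitness (`> 0`).
#' @return The selection coefficient (`>= -1`).
#' @export
selection_coefficient <- function(w_mutant, w_ancestor) {
  if (any(w_ancestor <= 0)) stop("ancestral fitness must be positive")
  w_mutant / w_ancestor - 1
}

#' Kimura fixation probability of a new mutant (diploid)
#'
#' `Pr(fix) = (1 - exp(-2 s)) / (1 - exp(-4 Ne s))`, continuous at `s = 0`
#' where it equals the neutral value `1/(2 Ne)`. Evaluated with `expm1` so the
#' ratio is accurate to machine precision for arbitrarily small `|s|`;
#' strongly deleterious mutations (`-4 Ne s > 700`) are computed in log space
#' and underflow cleanly to 0.
#'
#' @param Ne Effective population size (`>= 1`).
#' @param s Selection coefficient(s), `>= -1` (vectorized).
#' @return Fixation probabilities in `[0, 1)`.
#' @export
fixation_probability <- function(Ne, s) {
  if (Ne < 1) stop("Ne must be at least 1")
  if (any(s < -1)) stop("s must be >= -1")
  p <- numeric(length(s))
  b <- -4 * Ne * s
  zero <- abs(s) < 1e-300   # below this 1-exp(-4*Ne*s) can denormalize to 0
  deep <- !zero & b > 700          # overflow guard, strongly deleterious
  ok <- !zero & !deep
  p[zero] <- 1 / (2 * Ne)
  # exp(2s(2Ne-1)) * (1 - exp(2s)) for 4*Ne*(-s) beyond exp() range
  p[deep] <- exp(2 * s[deep] * (2 * Ne - 1)) * (-expm1(2 * s[deep]))
  p[ok] <- expm1(-2 * s[ok]) / expm1(b[ok])
  p
}
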