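# Cis/trans genetic architecture: maps a cis-genotype (count of effector
# alleles at l equivalent loci) and a trans-genotypic value Q to the
# per-molecule conversion rate(s) beta.

#' Describe the cis-architecture of a modification event
#'
#' A modification event is controlled by `l` cis-loci, each carrying either an
#' effector allele (facilitates enzyme binding) or a null allele. All loci
#' have an equal, additive effect, so the genotypic value `v` is the effector
#' count and `v_max = l`. `C` scales the whole-molecule effect of the cis
#' genotype on the conversion rate and `epsilon` is the nonspecific
#' (genotype-independent) modification rate.
#'
#' @param l Number of cis-loci (non-negative integer; `l = 0` means the rate
#'   is purely nonspecific).
#' @param mu01 Per-locus mutation rate null -> effector, per time step.
#' @param mu10 Per-locus mutation rate effector -> null, per time step.
#' @param C Whole-molecule effect scale (`> 0`).
#' @param epsilon Nonspecific modification rate (`>= 0`).
#' @param mode `"editing"` (one conversion rate) or `"splicing"` (two
#'   inversely coupled rates).
#' @return An object of class `"cis_architecture"`.
#' @export
cis_architecture <- function(l, mu01 = 1e-9, mu10 = 1e-9, C = 1,
                             epsilon = 0, mode = c("editing", "splicing")) {
  mode <- match.arg(mode)
  stopifnot(length(l) == 1L, l >= 0, l == round(l))
  if (mu01 < 0 || mu10 < 0) stop("mutation rates must be non-negative")
  if (C <= 0) stop("C must be positive")
  if (epsilon < 0) stop("epsilon must be non-negative")
  structure(
    list(l = as.integer(l), mu01 = mu01, mu10 = mu10, C = C,
         epsilon = epsilon, mode = mode),
    class = "cis_architecture"
  )
}

#' @export
print.cis_architecture <- function(x, ...) {
  cat("cis-architecture (", x$mode, "-type): l = ", x$l,
      ", mu01 = ", x$mu01, ", mu10 = ", x$mu10,
      ", C = ", x$C, ", epsilon = ", x$epsilon, "\n", sep = "")
  invisible(x)
}

#' Normalized cis-genotypic value
#'
#' `v_hat = v / v_max` with `v_max = l` under equal additive effects. For
#' `l = 0` there is no cis control and `v_hat` is 0 by convention, so the
#' conversion rate reduces to the nonspecific rate `Q * epsilon`.
#'
#' @param v Count of effector alleles (may be fractional when evaluating at an
#'   expected genotypic value).
#' @param l Number of cis-loci.
#' @return `v / l`, a value in `[0, 1]` (0 when `l = 0`).
#' @export
normalized_cis_value <- function(v, l) {
  stopifnot(length(l) == 1L, l >= 0)
  if (any(v < 0 | v > l)) stop("v must lie in [0, l]")
  if (l == 0) return(rep(0, length(v)))
  v / l
}

#' Conversion rate(s) implied by a genotype
#'
#' Editing-type: `beta = Q * (C * v_hat + epsilon)`. Splicing-type: the same
#' loci control both outcomes with inversely correlated effects,
#' `beta_1 = Q * (C * v_hat + epsilon)` and
#' `beta_2 = Q * (C * (1 - v_hat) + epsilon)`.
#'
#' @param arch A [cis_architecture()].
#' @param v Cis-genotypic value (effector count, possibly fractional).
#' @param Q Trans-genotypic value (`> 0`).
#' @return For editing, a single rate `beta`; for splicing, a named vector
#'   `c(beta1, beta2)`.
#' @export
conversion_rate <- function(arch, v, Q) {
  stopifnot(inherits(arch, "cis_architecture"))
  if (Q <= 0) stop("Q must be positive")
  vhat <- normalized_cis_value(v, arch$l)
  b1 <- Q * (arch$C * vhat + arch$epsilon)
  if (arch$mode == "editing") {
    return(b1)
  }
  c(beta1 = b1, beta2 = Q * (arch$C * (1 - vhat) + arch$epsilon))
}

#' Describe the trans-factor
#'
#' The trans-genotypic value `Q` aggregates the modification enzyme's
#' expression level and catalytic efficiency; it scales the conversion rate of
#' every target. `Q` is under Gaussian stabilizing selection in log space
#' around `Q_opt` with width `sigma_Q`, mutates at rate `U_Q` per time step,
#' and each mutation perturbs `ln Q` by a `Normal(0, S_Q)` draw.
#'
#' @param Q Current trans-genotypic value (`> 0`).
#' @param Q_opt Optimal value (`> 0`).
#' @param sigma_Q Width of the fitness function (`> 0`, possibly `Inf` for a
#'   selectively neutral trans-factor).
#' @param U_Q Mutation rate affecting `Q`, per time step (`>= 0`).
#' @param S_Q Standard deviation of a mutation's effect on `ln Q` (`>= 0`).
#' @return An object of class `"trans_factor"`.
#' @export
trans_factor <- function(Q, Q_opt = 2, sigma_Q = 20, U_Q = 1e-8, S_Q = 0.1) {
  if (Q <= 0 || Q_opt <= 0) stop("Q and Q_opt must be positive")
  if (sigma_Q <= 0) stop("sigma_Q must be positive")
  if (U_Q < 0 || S_Q < 0) stop("U_Q and S_Q must be non-negative")
  structure(
    list(Q = Q, Q_opt = Q_opt, sigma_Q = sigma_Q, U_Q = U_Q, S_Q = S_Q),
    class = "trans_factor"
  )
}

#' @export
print.trans_factor <- function(x, ...) {
  cat("trans-factor: Q = ", x$Q, ", Q_opt = ", x$Q_opt,
      ", sigma_Q = ", x$sigma_Q, ", U_Q = ", x$U_Q, ", S_Q = ", x$S_Q,
      "\n", sep = "")
  invisible(x)
}
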