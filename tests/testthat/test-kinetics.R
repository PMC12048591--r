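test_that("two-isoform equilibrium matches the closed form and the ODE oracle", {
  # no conversion: everything stays unmodified
  st <- equilibrium_two_isoform(1, 0, 1, 1)
  expect_equal(st$abundances, c(1, 0))
  expect_equal(st$level, 0)

  # symmetric rates split the product evenly
  st <- equilibrium_two_isoform(1, 1, 1, 1)
  expect_equal(st$abundances, c(0.5, 0.5))
  expect_equal(st$level, 0.5)

  # generic rates: closed form against forward ODE integration
  st <- equilibrium_two_isoform(2, 0.3, 1, 0.5)
  expect_equal(st$abundances, c(2 / 1.3, 0.6 / 0.65), tolerance = 1e-12)
  ode <- ode_equilibrium(2, chain_beta_matrix(0.3), c(1, 0.5))
  expect_equal(st$abundances, ode, tolerance = 1e-6)
  expect_equal(st$level, 0.3 / 0.8, tolerance = 1e-12)
})

test_that("degenerate two-isoform systems raise explicit errors", {
  expect_error(equilibrium_two_isoform(1, 0, 0, 1), "degenerate")
  expect_error(equilibrium_two_isoform(1, 1, 1, 0), "degenerate")
  expect_error(equilibrium_two_isoform(-1, 1, 1, 1), "alpha")
})

test_that("branching equilibrium solves the splicing-type system", {
  # fully committed splicing genotype: beta1 = 100, beta2 = 0, gamma0 = 0
  st <- equilibrium_branching(1, c(100, 0), c(0, 1, 20))
  expect_equal(st$abundances, c(0.01, 1, 0), tolerance = 1e-12)
  frac0 <- st$abundances[1] / sum(st$abundances)
  expect_equal(frac0, 1 / 101, tolerance = 1e-12)

  # intermediate genotype, checked against a generic solve() oracle
  A <- rbind(c(100, 0, 0), c(50, -1, 0), c(50, 0, -20))
  oracle <- solve(A, c(1, 0, 0))
  st <- equilibrium_branching(1, c(50, 50), c(0, 1, 20))
  expect_equal(st$abundances, oracle, tolerance = 1e-12)
  expect_equal(st$abundances, c(0.01, 0.5, 0.025), tolerance = 1e-12)
  expect_equal(st$level, 0.025 / 0.525, tolerance = 1e-12)
  expect_equal(modification_level(st, "splicing"), 0.047619, tolerance = 1e-5)

  # single branch reduces to the two-isoform closed form
  st1 <- equilibrium_branching(1.7, 0.4, c(0.9, 1.1))
  st2 <- equilibrium_two_isoform(1.7, 0.4, 0.9, 1.1)
  expect_equal(st1$abundances, st2$abundances, tolerance = 1e-12)
})

test_that("chain equilibrium matches the multi-step closed form", {
  # n = 2 closed form: P0 = a/(b1+g0), P1 = a b1/((b1+g0)(b2+g1)), ...
  st <- equilibrium_chain(1, c(1, 1), c(1, 1, 1))
  expect_equal(st$abundances, c(0.5, 0.25, 0.25), tolerance = 1e-12)

  # broken chain reduces to the two-isoform system with I_2 absent
  st <- equilibrium_chain(1, c(0.7, 0), c(1, 1, 1))
  st2 <- equilibrium_two_isoform(1, 0.7, 1, 1)
  expect_equal(st$abundances, c(st2$abundances, 0), tolerance = 1e-12)

  # random 4-step chain agrees with the general-matrix solver
  set.seed(7)
  betas <- runif(4, 0.2, 2)
  gammas <- runif(5, 0.5, 2)
  st <- equilibrium_chain(1.3, betas, gammas)
  stg <- equilibrium_general(1.3, chain_beta_matrix(betas), gammas)
  expect_equal(st$abundances, stg$abundances, tolerance = 1e-10)
})

test_that("uniform multi-site chain solves the per-site rate model", {
  # n = 1 reduces to the two-isoform system
  st <- equilibrium_multisite(1, 0.8, 1, c(1, 1))
  st2 <- equilibrium_two_isoform(1, 0.8, 1, 1)
  expect_equal(st$abundances, st2$abundances, tolerance = 1e-12)

  # hand-solved n = 2 case: all three isoforms equally abundant
  st <- equilibrium_multisite(1, 1, 2, c(1, 1, 1))
  expect_equal(st$abundances, rep(1 / 3, 3), tolerance = 1e-12)
  stg <- equilibrium_general(1, chain_beta_matrix(c(2, 1)), c(1, 1, 1))
  expect_equal(st$abundances, stg$abundances, tolerance = 1e-12)

  # no modification at all
  st <- equilibrium_multisite(2, 0, 3, c(0.5, 1, 1, 1))
  expect_equal(st$abundances, c(4, 0, 0, 0), tolerance = 1e-12)
})

test_that("general solver handles arbitrary conversion topologies", {
  # first-row-only matrix is exactly the branching system
  betas <- c(0.3, 1.2, 0.05)
  gammas <- c(0.2, 1, 2, 0.7)
  stg <- equilibrium_general(1, branching_beta_matrix(betas), gammas)
  stb <- equilibrium_branching(1, betas, gammas)
  expect_equal(stg$abundances, stb$abundances, tolerance = 1e-12)

  # random dense 4-isoform systems agree with long-time ODE integration
  for (seed in 1:5) {
    sys <- random_kinetic_system(4, seed)
    st <- equilibrium_general(sys$alpha, sys$B, sys$gammas)
    ode <- ode_equilibrium(sys$alpha, sys$B, sys$gammas)
    expect_equal(st$abundances, ode, tolerance = 1e-6)
  }

  expect_error(equilibrium_general(1, matrix(c(1, 0, 0, 0), 2), c(1, 1)),
               "zero diagonal")
})

test_that("flux is conserved at every returned equilibrium", {
  # production of I_0 must equal total decay: alpha = sum(gamma_i * P_i)
  for (seed in 1:10) {
    sys <- random_kinetic_system(sample(2:5, 1), seed)
    st <- equilibrium_general(sys$alpha, sys$B, sys$gammas)
    expect_equal(sum(sys$gammas * st$abundances), sys$alpha,
                 tolerance = 1e-10)
  }
  st <- equilibrium_branching(2, c(1, 3), c(0.5, 1, 2))
  expect_equal(sum(c(0.5, 1, 2) * st$abundances), 2, tolerance = 1e-12)
  st <- equilibrium_chain(1.5, c(1, 2, 3), c(1, 0.5, 1, 4))
  expect_equal(sum(c(1, 0.5, 1, 4) * st$abundances), 1.5, tolerance = 1e-12)
})

test_that("scaling alpha scales abundances and leaves the level unchanged", {
  for (k in c(0.1, 2, 100)) {
    base <- equilibrium_two_isoform(1, 0.3, 0.7, 1.2)
    scaled <- equilibrium_two_isoform(k, 0.3, 0.7, 1.2)
    expect_equal(scaled$abundances, k * base$abundances, tolerance = 1e-12)
    expect_equal(scaled$level, base$level, tolerance = 1e-12)
  }
})

test_that("editing level is increasing in beta and decreasing in gamma1", {
  betas <- seq(0.1, 5, length.out = 20)
  f_beta <- vapply(betas,
                   function(b) equilibrium_two_isoform(1, b, 1, 1)$level,
                   numeric(1))
  expect_true(all(diff(f_beta) > 0))
  g1 <- seq(0.2, 5, length.out = 20)
  f_g1 <- vapply(g1,
                 function(g) equilibrium_two_isoform(1, 1, 1, g)$level,
                 numeric(1))
  expect_true(all(diff(f_g1) < 0))
})

test_that("alternative transcription splits the product by the error rate", {
  expect_equal(equilibrium_alt_transcription(1, 0, 1, 1)$abundances, c(1, 0))
  expect_equal(equilibrium_alt_transcription(2, 0.5, 1, 1)$abundances,
               c(1, 1))
  expect_equal(equilibrium_alt_transcription(3, 1, 1, 2)$abundances,
               c(0, 1.5))
  expect_error(equilibrium_alt_transcription(1, 0.5, 0, 1), "degenerate")
  expect_error(equilibrium_alt_transcription(1, 1.5, 1, 1), "error_rate")
})

test_that("modification level uses the mode's definition and guards zeros", {
  expect_equal(modification_level(c(1, 1), "editing"), 0.5)
  # rate-ratio identity: f = beta/(beta+gamma1)
  st <- equilibrium_two_isoform(1, 1, 1, 1)
  expect_equal(modification_level(st, "editing"), 1 / (1 + 1) * 1,
               tolerance = 1e-12)
  expect_equal(st$level, 1 / 2)
  expect_equal(modification_level(c(0.01, 0.5, 0.025), "splicing"),
               0.047619, tolerance = 1e-5)
  expect_warning(f0 <- modification_level(c(0, 0), "editing"), "zero")
  expect_equal(f0, 0)
  expect_error(modification_level(c(1, 1)), "mode")
})
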