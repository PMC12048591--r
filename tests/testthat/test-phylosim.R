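test_that("site panels have the stated composition and marginals", {
  p <- sample_site_panel(200, 300, seed = 1)
  expect_equal(nrow(p), 500)
  expect_equal(sum(p$class == "neutral"), 200)
  expect_equal(sum(p$class == "deleterious"), 300)
  expect_true(all(p$alpha > 0))
  expect_true(all(p$C > 0))
  expect_true(all(p$l %in% 0:10))

  # law of large numbers on the exponential scale parameter
  big <- sample_site_panel(10000, 0, seed = 2)
  se <- 0.1 / sqrt(10000)
  expect_lt(abs(mean(big$C) - 0.1), 3 * se)
  # and on the log-normal expression rate
  expect_lt(abs(mean(log(big$alpha))), 3 / sqrt(10000))

  # fixed seed reproduces the panel exactly
  expect_identical(sample_site_panel(50, 50, seed = 7),
                   sample_site_panel(50, 50, seed = 7))
})

test_that("tree simulation respects degenerate branch and mutation limits", {
  tree <- ape::read.tree(text = "((a:0,b:1000):1000,(c:1000,d:2000):0);")
  panel <- toy_panel(n = 10, seed = 3)
  # no mutation: every tip inherits the root genotype at every site
  m <- simulate_tree_panel(tree, panel, Ne = 1e3, mu01 = 0, mu10 = 0,
                           seed = 5)
  expect_true(all(m > 0))
  expect_equal(max(editing_distance_matrix(m)), 0)

  # zero-length terminal branch: a inherits its parent state surely, so with
  # mu = 0 removed, a and b still match when b's branch cannot move (l = 0)
  p0 <- sample_site_panel(5, 0, seed = 4, l_max = 0)
  m0 <- simulate_tree_panel(tree, p0, Ne = 1e3, seed = 5)
  expect_equal(m0["a", ], m0["b", ])  # l = 0 sites have no cis variation
  const <- attr(p0, "constants")
  f_expect <- const$Q * const$epsilon / (const$Q * const$epsilon + 1)
  expect_equal(unname(m0["c", ]), rep(f_expect, 5), tolerance = 1e-12)
})

test_that("coleoid preset runs give positive skewed editing levels", {
  tree <- coleoid_tree()
  expect_s3_class(tree, "phylo")
  expect_setequal(tree$tip.label,
                  c("octopus", "bimac", "squid", "cuttlefish"))
  expect_true(ape::is.ultrametric(tree))

  panel <- sample_site_panel(300, 300, seed = 11)
  m <- simulate_tree_panel(tree, panel, Ne = 1e4, mu01 = 1e-9, mu10 = 1e-9,
                           seed = 12)
  expect_true(all(m > 0))
  # right-skewed distribution of editing levels in each species
  for (tip in rownames(m)) {
    expect_gt(mean(m[tip, ]), median(m[tip, ]))
  }
  # deleterious sites sit lower than neutral sites and pile up more heavily
  # at very low (<1%) editing levels, the empirical signature of purifying
  # selection on the edited isoform
  del <- panel$class == "deleterious"
  expect_lt(mean(m[, del]), mean(m[, !del]))
  expect_lt(median(m[, del]), median(m[, !del]))
  expect_gt(mean(m[, del] < 0.01), mean(m[, !del] < 0.01))
})

test_that("log editing distances form a metric with the expected values", {
  m <- rbind(a = c(exp(1) * 0.2), b = c(0.2))
  expect_equal(editing_distance_matrix(m)["a", "b"], 1, tolerance = 1e-12)
  m <- rbind(a = c(0.1, 0.3), b = c(0.1, 0.3))
  expect_equal(editing_distance_matrix(m)["a", "b"], 0)
  expect_error(editing_distance_matrix(rbind(a = 0, b = 1)), "positive")

  # triangle inequality on a simulated matrix
  panel <- toy_panel(n = 20, seed = 21)
  sim <- simulate_tree_panel(coleoid_tree(), panel, Ne = 1e3, seed = 22)
  D <- editing_distance_matrix(sim)
  tips <- rownames(D)
  for (i in tips) for (j in tips) for (k in tips) {
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  }
})

test_that("neighbor joining recovers additive trees exactly", {
  # three taxa: branch lengths from the three-point formulas
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- neighbor_joining(D)
  expect_equal(ape::cophenetic.phylo(tr)[letters[1:3], letters[1:3]], D,
               ignore_attr = TRUE, tolerance = 1e-12)

  # random 4-8 taxon trees: topology and path lengths recovered from
  # their additive (cophenetic) distances
  for (trial in 1:100) {
    n <- sample(4:8, 1)
    tree <- toy_tree(n_tips = n, seed = trial)
    D <- toy_distance(tree)
    nj_tree <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(tree), nj_tree), 0,
                 ignore_attr = TRUE)
    back <- ape::cophenetic.phylo(nj_tree)[rownames(D), colnames(D)]
    expect_equal(back, D, tolerance = 1e-8)
  }

  expect_error(neighbor_joining(matrix(0, 2, 2)), "at least 3")
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "at least 3")
})

test_that("topology check scores the coleoid split and pair distances", {
  tr <- ape::read.tree(text = "((octopus:1,bimac:1):1,squid:2,cuttlefish:2);")
  D <- matrix(1, 4, 4, dimnames = list(
    c("octopus", "bimac", "squid", "cuttlefish"),
    c("octopus", "bimac", "squid", "cuttlefish")))
  diag(D) <- 0
  D["octopus", "bimac"] <- D["bimac", "octopus"] <- 0.1
  D["squid", "cuttlefish"] <- D["cuttlefish", "squid"] <- 0.5
  chk <- topology_check(tr, D)
  expect_true(chk$clade_ok)
  expect_true(chk$pair1_closer)

  wrong <- ape::read.tree(
    text = "((octopus:1,squid:1):1,bimac:2,cuttlefish:2);")
  expect_false(topology_check(wrong, D)$clade_ok)
  expect_error(topology_check(tr, D[1:3, 1:3]), "missing")
})

test_that("simulated coleoid editing recovers the species tree", {
  tree <- coleoid_tree()
  ok_clade <- logical(5)
  ok_pair <- logical(5)
  for (i in 1:5) {
    panel <- sample_site_panel(250, 250, seed = 100 + i)
    m <- simulate_tree_panel(tree, panel, Ne = 1e4, seed = 200 + i)
    D <- editing_distance_matrix(m)
    nj_tree <- neighbor_joining(D)
    chk <- topology_check(nj_tree, D)
    ok_clade[i] <- chk$clade_ok
    ok_pair[i] <- chk$pair1_closer
  }
  # strong phylogenetic signal: correct in the large majority of runs
  expect_gte(sum(ok_clade), 4)
  expect_gte(sum(ok_pair), 4)
})

test_that("longer branches do not shrink expected log-editing distances", {
  base <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  mean_dist <- function(scale) {
    tr <- base
    tr$edge.length <- tr$edge.length * scale
    d <- numeric(6)
    for (i in 1:6) {
      panel <- sample_site_panel(40, 0, seed = 300 + i)
      m <- simulate_tree_panel(tr, panel, Ne = 1e3, mu01 = 1e-6,
                               mu10 = 1e-6, seed = 400 + i)
      d[i] <- mean(editing_distance_matrix(m))
    }
    mean(d)
  }
  d_short <- mean_dist(1e4)
  d_mid <- mean_dist(1e5)
  d_long <- mean_dist(1e6)
  expect_lte(d_short, d_mid * 1.05)
  expect_lte(d_mid, d_long * 1.05)
})
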