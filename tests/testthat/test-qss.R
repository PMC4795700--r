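test_that("the complex graph has the 4-vertex, 8-edge double-cycle structure", {
  g <- build_gef_graph(fx$params, fx$pools)
  vs <- unique(c(g$from, g$to))
  expect_length(vs, 4)
  expect_identical(nrow(g), 8L)
  expect_true(all(table(g$from) == 2)) # out-degree 2 everywhere
  expect_true(all(table(g$to) == 2))   # in-degree 2 everywhere
  # nucleotide pools are folded into the numeric labels
  expect_equal(g$value[g$rate == "k4.gdp"],
               fx$params[["k4"]] * fx$pools[["gdp"]])
  expect_equal(g$value[g$rate == "k8.gtp"],
               fx$params[["k8"]] * fx$pools[["gtp"]])
})

test_that("spanning-tree enumeration matches the matrix-tree oracle", {
  g <- build_gef_graph(fx$params, fx$pools)
  vs <- unique(c(g$from, g$to))

  total <- 0L
  for (root in vs) {
    trees <- enumerate_spanning_trees(g, root)
    expect_true(all(vapply(trees, length, 0L) == 3)) # n-1 edges each
    expect_identical(anyDuplicated(lapply(trees, sort)), 0L)
    total <- total + length(trees)  # lengths are integer
    # every root of the 4-cycle admits exactly 4 trees
    expect_length(trees, 4)
    # weighted count agrees with det(L[-r,-r]) at random symbol values
    set.seed(1)
    gd <- runif(1, 0.5, 2); gt <- runif(1, 0.5, 2)
    w <- vapply(trees, function(idx) {
      lab <- g$value[idx] * ifelse(g$species[idx] == "g_gdp", gd,
                                   ifelse(g$species[idx] == "g_gtp", gt, 1))
      prod(lab)
    }, 0)
    expect_equal(sum(w), matrix_tree_weight(g, root, gd, gt),
                 tolerance = 1e-10)
  }
  expect_identical(total, 16L)

  # removing the k7 edge (irreversible variant) keeps every root reachable
  g6 <- g[g$rate != "k7", ]
  for (root in vs)
    expect_gt(length(enumerate_spanning_trees(g6, root)), 0)

  # minimal 2-vertex graph: one tree per root
  g2 <- data.frame(from = c("a", "b"), to = c("b", "a"),
                   rate = c("u", "v"), value = c(2, 3), species = c("", ""))
  expect_length(enumerate_spanning_trees(g2, "a"), 1)
  expect_length(enumerate_spanning_trees(g2, "b"), 1)
})

test_that("occupancy basis is symmetric for unit labels and normalises to e0", {
  b1 <- ones_bundle()
  rho <- occupancy_basis(build_gef_graph(b1$params, b1$pools))
  occ <- occupancies(rho, 1, 1, 0.4)
  expect_equal(unname(occ), rep(0.1, 4)) # uniform e0/4 by symmetry

  for (s in 1:5) {
    b <- sample_params(s)
    rho <- occupancy_basis(build_gef_graph(b$params, b$pools))
    occ <- occupancies(rho, 0.7, 1.3, 0.25)
    expect_equal(sum(occ), 0.25, tolerance = 1e-12)
    expect_true(all(occ > 0))
  }
})

test_that("occupancies agree with the clamped-substrate ODE oracle", {
  set.seed(5)
  for (s in 1:8) {
    b <- sample_params(s)
    rho <- occupancy_basis(build_gef_graph(b$params, b$pools))
    gd <- runif(1, 0.2, 5); gt <- runif(1, 0.2, 5)
    occ <- occupancies(rho, gd, gt, 0.1)
    ora <- clamped_occupancies(b$params, b$pools, gd, gt, 0.1)
    expect_lt(max(abs(occ[names(ora)] - ora) / ora), 1e-6)
  }
})

test_that("summary constants reproduce the reduced-model algebra", {
  sm <- summary_params(fx$params, fx$pools, fx$gtpase)
  kap <- kappa_ratio(fx$params, fx$pools)
  expect_equal(sm$kappa, kap)
  # kfwd is the forward-rate product with the GTP pool absorbed
  expect_equal(sm$kfwd, prod(fx$params[c("k1", "k3", "k6", "k8")]) *
                 fx$pools[["gtp"]])
  # numerator identities tying the rho coefficients to kfwd and kappa
  expect_equal(fx$params[["k6"]] * sm$K1t, sm$kfwd, tolerance = 1e-12)
  expect_equal(fx$params[["k5"]] * sm$K0 - fx$params[["k6"]] * sm$K2t,
               sm$kfwd * kap, tolerance = 1e-12)
  # denominator constants collect the full basis
  expect_equal(sm$K1, sm$K1d + sm$K1t + sm$K1g, tolerance = 1e-12)
  expect_equal(sm$K2, sm$K2d + sm$K2t + sm$K2g, tolerance = 1e-12)
  expect_equal(sm$Ks, sm$K0 / (sm$K1 * kap + sm$K2))
  expect_equal(sm$kappa_hat, sm$kfwd / fx$gtpase$kase)
  expect_error(summary_params(fx$params, fx$pools,
                              gtpase_spec("intrinsic", kase = 0)),
               "kappa_hat")
})

test_that("summary constants are homogeneous in the rates", {
  # scaling all eight rates by c scales kfwd by c^4 and leaves kappa fixed
  b <- sample_params(3)
  sm1 <- summary_params(b$params, b$pools)
  scaled <- do.call(gef_params, as.list(as.numeric(b$params) * 2))
  sm2 <- summary_params(scaled, b$pools)
  expect_equal(sm2$kfwd / sm1$kfwd, 16, tolerance = 1e-12)
  expect_equal(sm2$kappa, sm1$kappa, tolerance = 1e-12)
})

test_that("qss_rhs has the equilibrium root and is linear in e0", {
  sm <- summary_params(fx$params, fx$pools)
  kap <- sm$kappa
  expect_equal(qss_rhs(kap * 2.5, 2.5, 0.1, sm), 0)
  expect_equal(qss_rhs(4, 1, 0.2, sm), 2 * qss_rhs(4, 1, 0.1, sm))
  # Michaelis-Menten reduction at g_gtp = 0 without GTPase activity
  gd <- 3.3
  expect_equal(qss_rhs(gd, 0, 0.1, sm),
               sm$kfwd * gd * 0.1 / (sm$K0 + sm$K1 * gd))
})

test_that("reduced flux equals the full model flux at the QSS state", {
  set.seed(11)
  for (s in 1:20) {
    b <- sample_params(s)
    sm <- summary_params(b$params, b$pools)
    rho <- occupancy_basis(build_gef_graph(b$params, b$pools))
    gd <- runif(1, 0.2, 8); gt <- runif(1, 0.2, 8)
    occ <- occupancies(rho, gd, gt, 0.1)
    st <- system_state(e = occ[["E"]], e_gdp = occ[["E.Gd"]],
                       e_gtp = occ[["E.Gt"]], e_g = occ[["E.G"]],
                       g_gdp = gd, g_gtp = gt)
    full <- gef_rhs(st, b$params, b$pools)[["g_gtp"]]
    red <- qss_rhs(gd, gt, 0.1, sm)
    expect_equal(red, full, tolerance = 1e-6)
  }
})

test_that("the reduced model tracks the full model when e0 << g0", {
  g0 <- fx$totals[["g0"]]
  e0 <- 0.01 * g0
  sm <- summary_params(fx$params, fx$pools, fx$gtpase)
  ss0 <- numeric_steady_state(fx$params, fx$pools, system_totals(e0, g0), NULL)
  times <- seq(0, 30, length.out = 31)

  # perturb: start the GTPase-active dynamics from the exchange equilibrium
  st0 <- system_state(e = ss0[["e"]], e_gdp = ss0[["e_gdp"]],
                      e_gtp = ss0[["e_gtp"]], e_g = ss0[["e_g"]],
                      g_gdp = ss0[["g_gdp"]], g_gtp = ss0[["g_gtp"]])
  full <- simulate_mass_action(fx$params, fx$pools, fx$gtpase, st0, times)
  red <- simulate_qss(ss0[["g_gtp"]], g0, e0, sm, fx$gtpase, times)
  expect_lt(max(abs(full$g_gtp - red$g_gtp) / full$g_gtp), 0.01)
})

test_that("reduced and full steady states converge as e0/g0 -> 0", {
  g0 <- fx$totals[["g0"]]
  sm <- summary_params(fx$params, fx$pools)
  errs <- vapply(c(0.1, 0.01, 0.001), function(r) {
    e0 <- r * g0
    full <- numeric_steady_state(fx$params, fx$pools, system_totals(e0, g0),
                                 NULL)[["g_gtp"]]
    abs(qss_steady_state(g0, e0, sm) - full) / full
  }, 0)
  expect_lt(errs[2], 0.01)
  expect_true(all(diff(errs) < 0)) # monotone improvement
})
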