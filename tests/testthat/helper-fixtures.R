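# Shared fixtures and small oracles used across the test files.

fx <- gef_fixture()

# All-ones parameter bundle: symmetric rates, equal pools.
ones_bundle <- function() {
  list(params = gef_params(1, 1, 1, 1, 1, 1, 1, 1),
       pools = nucleotide_pools(1, 1),
       totals = system_totals(0.1, 1))
}

# Weighted matrix-tree oracle: the sum over directed spanning trees oriented
# toward root r of the product of edge weights equals det(L[-r, -r]) with
# L = D_out - W. Independent of the package's subset enumerator.
matrix_tree_weight <- function(graph, root, g_gdp = 1, g_gtp = 1) {
  vs <- unique(c(graph$from, graph$to))
  w <- graph$value * ifelse(graph$species == "g_gdp", g_gdp,
                            ifelse(graph$species == "g_gtp", g_gtp, 1))
  W <- matrix(0, length(vs), length(vs), dimnames = list(vs, vs))
  for (j in seq_len(nrow(graph)))
    W[graph$from[j], graph$to[j]] <- W[graph$from[j], graph$to[j]] + w[j]
  L <- diag(rowSums(W)) - W
  r <- match(root, vs)
  det(L[-r, -r, drop = FALSE])
}

# Clamped-substrate relaxation of the enzyme subsystem (the numerical oracle
# behind the King-Altman occupancies).
clamped_occupancies <- function(params, pools, g_gdp, g_gtp, e0,
                                horizon = 1e5) {
  tr <- gefcycle:::cpp_ode_clamped(c(e0, 0, 0, 0), c(0, horizon),
                                   as.numeric(params), as.numeric(pools),
                                   g_gdp, g_gtp, 1e-11, 1e-15, 1e8, 1L)
  stats::setNames(tr[2, ], c("E", "E.Gd", "E.Gt", "E.G"))
}

# Intrinsic GTPase rate placed in the responsive region: basal activation at
# `level` of the theoretical ceiling 1/(kappa + 1).
responsive_kase <- function(params, pools, g0, e0_basal = 0.1, level = 0.3) {
  kap <- kappa_ratio(params, pools)
  f <- function(lk) {
    smi <- summary_params(params, pools, gtpase_spec("intrinsic", kase = exp(lk)))
    active_fraction_intrinsic(e0_basal, g0, smi) - level / (kap + 1)
  }
  exp(uniroot(f, c(log(1e-12), log(1e12)))$root)
}
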