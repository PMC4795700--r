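#' Directed graph on the GEF complexes
#'
#' The King-Altman construction works on a graph whose vertices are the four
#' enzyme species (E, E.G_GDP, E.G_GTP, E.G) and whose edges are the
#' elementary reactions converting one into another. Each edge label is a rate
#' constant times, for a bimolecular step, the concentration of the partner
#' species. Partner free G protein concentrations stay symbolic (they are the
#' slow variables of the reduction); the buffered nucleotide pools are folded
#' into the numeric part of the label.
#'
#' @param params a [gef_params()] object
#' @param pools a [nucleotide_pools()] object
#' @return A data.frame of class `complex_graph` with columns `from`, `to`,
#'   `rate` (label name), `value` (numeric factor of the label) and `species`
#'   (`""`, `"g_gdp"` or `"g_gtp"` — the symbolic partner, if any).
#' @export
build_gef_graph <- function(params, pools) {
  k <- as.numeric(params)
  g <- data.frame(
    from = c("E", "E.Gd", "E.Gd", "E.G", "E", "E.Gt", "E.Gt", "E.G"),
    to = c("E.Gd", "E", "E.G", "E.Gd", "E.Gt", "E", "E.G", "E.Gt"),
    rate = c("k1", "k2", "k3", "k4.gdp", "k5", "k6", "k7", "k8.gtp"),
    value = c(k[1], k[2], k[3], k[4] * pools[["gdp"]],
              k[5], k[6], k[7], k[8] * pools[["gtp"]]),
    species = c("g_gdp", "", "", "", "g_gtp", "", "", ""),
    stringsAsFactors = FALSE)
  class(g) <- c("complex_graph", "data.frame")
  g
}

.graph_vertices <- function(graph) unique(c(graph$from, graph$to))

# A directed spanning tree oriented toward `root`: every non-root vertex has
# exactly one outgoing edge in the subset, the root has none, and following
# the outgoing edges from any vertex reaches the root (no cycles).
.is_in_tree <- function(graph, idx, root, vertices) {
  sub <- graph[idx, , drop = FALSE]
  if (any(sub$from == root)) return(FALSE)
  non_root <- setdiff(vertices, root)
  if (!setequal(sub$from, non_root) || anyDuplicated(sub$from) > 0)
    return(FALSE)
  nxt <- sub$to
  names(nxt) <- sub$from
  for (v in non_root) {
    cur <- v
    for (step in seq_along(vertices)) {
      cur <- nxt[[cur]]
      if (cur == root) break
    }
    if (cur != root) return(FALSE)
  }
  TRUE
}

#' Enumerate directed spanning trees oriented toward a root
#'
#' Brute-force enumeration over all (n-1)-edge subsets of the graph — the
#' complex graph has only 8 edges, so there are at most choose(8, 3) = 56
#' candidates. Each returned tree spans all vertices with every path directed
#' toward the root.
#'
#' @param graph a [build_gef_graph()] graph (or any edge data.frame with
#'   `from`/`to` columns)
#' @param root root vertex name
#' @return A list of integer vectors, each the row indices of one tree's edges.
#' @export
enumerate_spanning_trees <- function(graph, root) {
  vertices <- .graph_vertices(graph)
  if (!root %in% vertices) stop("enumerate_spanning_trees: unknown root ", root)
  m <- length(vertices) - 1L
  cand <- utils::combn(nrow(graph), m, simplify = FALSE)
  Filter(function(idx) .is_in_tree(graph, idx, root, vertices), cand)
}

# Tree product as a monomial c(const, g_gdp, g_gtp). Total degree in the
# symbols is at most one: only E's outgoing edges carry a symbolic factor and
# a directed tree contains at most one outgoing edge per vertex.
.tree_monomial <- function(graph, idx) {
  val <- prod(graph$value[idx])
  syms <- graph$species[idx]
  syms <- syms[syms != ""]
  mono <- c(const = 0, g_gdp = 0, g_gtp = 0)
  if (length(syms) == 0) mono[["const"]] <- val
  else if (length(syms) == 1) mono[[syms]] <- val
  else stop("tree monomial exceeds degree one in the free G protein symbols")
  mono
}

#' Spanning-tree occupancy basis
#'
#' For each vertex i, rho_i is the sum over the directed spanning trees rooted
#' at i of the product of the tree's edge labels. Every steady state of the
#' complex subsystem is proportional to rho, so the normalised occupancies are
#' X_i = rho_i / sum(rho) * e0. Because the free G protein concentrations are
#' symbolic, each rho_i is returned as a linear polynomial
#' `const + a*[G_GDP] + b*[G_GTP]`.
#'
#' @param graph a [build_gef_graph()] graph
#' @return An object of class `occupancy_basis`: a matrix with one row per
#'   vertex and columns `const`, `g_gdp`, `g_gtp`, plus attribute `trees`
#'   (the per-root tree counts).
#' @export
occupancy_basis <- function(graph) {
  vertices <- .graph_vertices(graph)
  rho <- matrix(0, length(vertices), 3,
                dimnames = list(vertices, c("const", "g_gdp", "g_gtp")))
  ntrees <- integer(length(vertices))
  names(ntrees) <- vertices
  for (v in vertices) {
    trees <- enumerate_spanning_trees(graph, v)
    ntrees[v] <- length(trees)
    for (idx in trees) rho[v, ] <- rho[v, ] + .tree_monomial(graph, idx)
  }
  if (all(rho == 0))
    stop("occupancy_basis: all spanning-tree weights are zero (degenerate rates)")
  structure(rho, trees = ntrees, class = c("occupancy_basis", "matrix"))
}

#' Evaluate complex occupancies at given free G protein concentrations
#'
#' @param basis an [occupancy_basis()]
#' @param g_gdp,g_gtp free G protein concentrations (uM)
#' @param e0 total GEF (uM)
#' @return Named vector of occupancies (uM), summing to `e0`.
#' @export
occupancies <- function(basis, g_gdp, g_gtp, e0) {
  w <- basis[, "const"] + basis[, "g_gdp"] * g_gdp + basis[, "g_gtp"] * g_gtp
  if (sum(w) <= 0) stop("occupancies: degenerate basis (zero total weight)")
  e0 * w / sum(w)
}

#' Summary parameters of the quasi-steady-state reduction
#'
#' Collects the coefficients of the rho polynomials into the constants of the
#' reduced model: denominator constants K0 (the constant term, from trees
#' rooted at E), K1 and K2 (coefficients of \[G_GDP\] and \[G_GTP\] summed over
#' all vertices); numerator constants K1d..K2g of the three complex-occupancy
#' equations; kfwd, the product of the forward kinetic rates with the GTP pool
#' absorbed (k1 k3 k8 \[GTP\] k6); kappa; the composite Ks = K0/(K1 kappa + K2);
#' and, for intrinsic GTPase activity, kappa_hat = kfwd/kase.
#'
#' @param params a [gef_params()] object
#' @param pools a [nucleotide_pools()] object
#' @param spec optional [gtpase_spec()]; `kappa_hat` is only defined for
#'   intrinsic mode with kase > 0
#' @return A list of class `summary_params`.
#' @export
summary_params <- function(params, pools, spec = NULL) {
  graph <- build_gef_graph(params, pools)
  rho <- occupancy_basis(graph)
  K0 <- rho["E", "const"]
  K1 <- sum(rho[, "g_gdp"])
  K2 <- sum(rho[, "g_gtp"])
  kfwd <- params[["k1"]] * params[["k3"]] * params[["k8"]] *
    pools[["gtp"]] * params[["k6"]]
  kap <- kappa_ratio(params, pools)
  kappa_hat <- NA_real_
  if (!is.null(spec) && spec$mode == "intrinsic") {
    if (spec$kase <= 0)
      stop("summary_params: kappa_hat undefined, intrinsic mode with kase = 0")
    kappa_hat <- kfwd / spec$kase
  }
  structure(list(
    K0 = K0, K1 = K1, K2 = K2,
    K1d = rho["E.Gd", "g_gdp"], K2d = rho["E.Gd", "g_gtp"],
    K1t = rho["E.Gt", "g_gdp"], K2t = rho["E.Gt", "g_gtp"],
    K1g = rho["E.G", "g_gdp"], K2g = rho["E.G", "g_gtp"],
    kfwd = kfwd, kappa = kap,
    Ks = K0 / (K1 * kap + K2),
    kappa_hat = kappa_hat,
    rho = unclass(rho)), class = "summary_params")
}

#' Right-hand side of the reduced (quasi-steady-state) model
#'
#' The single equation governing free GTP-bound G protein once the enzyme
#' complexes are held at their conditional steady state:
#' d\[G_GTP\]/dt = kfwd (\[G_GDP\] - kappa \[G_GTP\]) e0 /
#' (K0 + K1 \[G_GDP\] + K2 \[G_GTP\]) - f_GTPase.
#' Valid when e0 << g0 (mass held in complexes is neglected).
#'
#' @param g_gdp,g_gtp free G protein concentrations (uM)
#' @param e0 total GEF (uM)
#' @param summary a [summary_params()] object
#' @param spec optional [gtpase_spec()]
#' @return d\[G_GTP\]/dt in uM/s.
#' @export
qss_rhs <- function(g_gdp, g_gtp, e0, summary, spec = NULL) {
  den <- summary$K0 + summary$K1 * g_gdp + summary$K2 * g_gtp
  if (any(den <= 0)) stop("qss_rhs: degenerate denominator (K constants)")
  ex <- summary$kfwd * (g_gdp - summary$kappa * g_gtp) * e0 / den
  f <- if (is.null(spec)) 0 else gtpase_flux(g_gtp, spec)
  ex - f
}

#' Integrate the reduced model
#'
#' One-variable adaptive Cash-Karp integration of [qss_rhs()] with the closure
#' \[G_GDP\] = g0 - \[G_GTP\] (complex-held mass neglected, as the reduction
#' assumes).
#'
#' @param g_gtp0 initial free GTP-bound G protein (uM)
#' @param g0 total G protein (uM)
#' @param e0 total GEF (uM)
#' @param summary a [summary_params()] object
#' @param spec optional [gtpase_spec()]
#' @param times output time grid
#' @param rtol,atol integration tolerances
#' @return data.frame with columns time, g_gtp, g_gdp.
#' @export
simulate_qss <- function(g_gtp0, g0, e0, summary, spec = NULL, times,
                         rtol = 1e-9, atol = 1e-12) {
  f <- function(x) qss_rhs(g0 - x, x, e0, summary, spec)
  x <- g_gtp0
  t <- times[1]
  out <- numeric(length(times))
  out[1] <- x
  h <- 1e-4
  for (i in seq_along(times)[-1]) {
    tend <- times[i]
    while (t < tend) {
      h <- min(h, tend - t)
      # embedded RK45 (Cash-Karp) on a scalar ODE
      k1 <- f(x)
      k2 <- f(x + h * k1 / 5)
      k3 <- f(x + h * (3 * k1 + 9 * k2) / 40)
      k4 <- f(x + h * (3 * k1 / 10 - 9 * k2 / 10 + 6 * k3 / 5))
      k5 <- f(x + h * (-11 * k1 / 54 + 5 * k2 / 2 - 70 * k3 / 27 + 35 * k4 / 27))
      k6 <- f(x + h * (1631 * k1 / 55296 + 175 * k2 / 512 + 575 * k3 / 13824 +
                         44275 * k4 / 110592 + 253 * k5 / 4096))
      x5 <- x + h * (37 * k1 / 378 + 250 * k3 / 621 + 125 * k4 / 594 +
                       512 * k6 / 1771)
      x4 <- x + h * (2825 * k1 / 27648 + 18575 * k3 / 48384 +
                       13525 * k4 / 55296 + 277 * k5 / 14336 + k6 / 4)
      err <- abs(x5 - x4) / (atol + rtol * max(abs(x), abs(x5)))
      if (err <= 1) {
        t <- t + h
        x <- x5
        h <- h * min(5, max(0.2, 0.9 * err^-0.2))
      } else {
        h <- h * max(0.1, 0.9 * err^-0.25)
      }
      if (t + h == t) stop("simulate_qss: step size underflow")
    }
    out[i] <- x
  }
  data.frame(time = times, g_gtp = out, g_gdp = g0 - out)
}

#' Steady state of the reduced model
#'
#' Solves qss_rhs = 0 under \[G_GDP\] = g0 - \[G_GTP\] by bisection on
#' \[0, g0\] (the flux is positive at 0 and non-positive at g0, so a root
#' always exists).
#'
#' @inheritParams simulate_qss
#' @param tol root tolerance passed to [stats::uniroot()]
#' @return Steady-state free \[G_GTP\] (uM).
#' @export
qss_steady_state <- function(g0, e0, summary, spec = NULL, tol = 1e-12) {
  h <- function(x) qss_rhs(g0 - x, x, e0, summary, spec)
  if (e0 == 0 && is.null(spec)) return(NA_real_) # every state is steady
  lo <- 0
  hi <- g0
  if (h(lo) <= 0) return(0)
  uniroot(h, c(lo, hi), tol = tol * max(1, g0))$root
}
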