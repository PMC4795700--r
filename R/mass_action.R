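#' Construct a system state for the mass-action model
#'
#' The six dynamic species of the exchange cycle, in uM: free GEF `e`, the
#' three enzyme complexes `e_gdp` (E.G_GDP), `e_gtp` (E.G_GTP), `e_g`
#' (nucleotide-free E.G), and free G protein `g_gdp`, `g_gtp`.
#'
#' @param e,e_gdp,e_gtp,e_g,g_gdp,g_gtp species concentrations (uM)
#' @return Named numeric vector of class `system_state`.
#' @export
system_state <- function(e = 0, e_gdp = 0, e_gtp = 0, e_g = 0,
                         g_gdp = 0, g_gtp = 0) {
  structure(c(e = e, e_gdp = e_gdp, e_gtp = e_gtp, e_g = e_g,
              g_gdp = g_gdp, g_gtp = g_gtp), class = "system_state")
}

.state_names <- c("e", "e_gdp", "e_gtp", "e_g", "g_gdp", "g_gtp")

.gtpase_code <- function(spec) {
  if (is.null(spec)) return(c(0, 0, 0, 0))
  mode <- switch(spec$mode, none = 0, intrinsic = 1, gap = 2)
  c(mode, spec$kase, if (is.na(spec$km)) 0 else spec$km,
    if (is.na(spec$f0)) 0 else spec$f0)
}

#' GTPase inactivation flux
#'
#' Hydrolysis acts only on free GTP-bound G protein (the GEF-bound forms are
#' protected): zero flux in `"none"` mode, first-order kase * \[G_GTP\] for
#' intrinsic activity, and the Michaelis-Menten form
#' kase * \[G_GTP\] * f0 / (km + \[G_GTP\]) for GAP-mediated activity.
#'
#' @param g_gtp free GTP-bound G protein (uM), or a [system_state()]
#' @param spec a [gtpase_spec()]
#' @return Flux in uM/s (non-negative; zero when `g_gtp` is zero).
#' @export
gtpase_flux <- function(g_gtp, spec) {
  if (inherits(g_gtp, "system_state")) g_gtp <- g_gtp[["g_gtp"]]
  switch(spec$mode,
         none = 0 * g_gtp,
         intrinsic = spec$kase * g_gtp,
         gap = {
           if (any(spec$km + g_gtp == 0))
             stop("gtpase_flux: degenerate gap kinetics, km + [G_GTP] = 0")
           spec$kase * g_gtp * spec$f0 / (spec$km + g_gtp)
         })
}

#' Time derivative of the mass-action model
#'
#' The six coupled ODEs of the reversible GEF mechanism with pluggable GTPase
#' flux. Hydrolysis removes mass from free `g_gtp` and returns it to free
#' `g_gdp`; the nucleotide pools are buffered constants. Both conservation
#' laws (total GEF, total G protein) are built into the flow field: the
#' corresponding sums of derivative components vanish identically.
#'
#' @param state a [system_state()]
#' @param params a [gef_params()] object
#' @param pools a [nucleotide_pools()] object
#' @param spec a [gtpase_spec()] (or NULL for no GTPase activity)
#' @return Named numeric vector of derivatives (uM/s).
#' @export
gef_rhs <- function(state, params, pools, spec = NULL) {
  dy <- cpp_rhs_full(as.numeric(state[.state_names]), as.numeric(params),
                     as.numeric(pools), .gtpase_code(spec))
  names(dy) <- .state_names
  dy
}

#' Derive the artificial irreversible mechanism
#'
#' Disallows release of GTP from the E.G_GTP complex by setting k7 = 0,
#' leaving every other rate untouched. Idempotent.
#'
#' @param params a [gef_params()] object
#' @return The modified `gef_params` object.
#' @export
make_irreversible <- function(params) {
  params[["k7"]] <- 0
  params
}

#' Conserved totals of a state
#'
#' Total GEF e0 = e + e_gdp + e_gtp + e_g and total G protein
#' g0 = g_gdp + g_gtp + e_gdp + e_gtp + e_g. Both are first integrals of the
#' mass-action flow and are probed along every trajectory in the tests.
#'
#' @param state a [system_state()] or a data.frame of states (one row per
#'   time point, columns named as in [system_state()])
#' @return Named vector `c(e0 =, g0 =)`, or a two-column matrix for a
#'   data.frame input.
#' @export
conserved_totals <- function(state) {
  if (is.data.frame(state)) {
    cbind(e0 = state$e + state$e_gdp + state$e_gtp + state$e_g,
          g0 = state$g_gdp + state$g_gtp + state$e_gdp + state$e_gtp + state$e_g)
  } else {
    c(e0 = unname(state[["e"]] + state[["e_gdp"]] + state[["e_gtp"]] + state[["e_g"]]),
      g0 = unname(state[["g_gdp"]] + state[["g_gtp"]] + state[["e_gdp"]] +
                    state[["e_gtp"]] + state[["e_g"]]))
  }
}

#' Integrate the full mass-action model
#'
#' Adaptive Dormand-Prince 5(4) integration of the six-species system, with all
#' species dynamic (free GEF carried as a state variable).
#'
#' @param params,pools,spec model specification; `spec = NULL` means no GTPase
#'   activity
#' @param state0 initial [system_state()]
#' @param times numeric vector of output times (first element is t0)
#' @param rtol,atol relative and absolute integration tolerances
#' @param maxsteps step-count guard
#' @param method `"rk45"` (explicit Dormand-Prince, default) or `"ros23"`
#'   (L-stable Rosenbrock, for stiff rate regimes)
#' @return data.frame with columns time, e, e_gdp, e_gtp, e_g, g_gdp, g_gtp.
#' @export
simulate_mass_action <- function(params, pools, spec = NULL, state0, times,
                                 rtol = 1e-9, atol = 1e-12, maxsteps = 1e8,
                                 method = c("rk45", "ros23")) {
  method <- match.arg(method)
  stopifnot(length(times) >= 1, !is.unsorted(times))
  m <- cpp_ode_full(as.numeric(state0[.state_names]), as.numeric(times),
                    as.numeric(params), as.numeric(pools),
                    .gtpase_code(spec), rtol, atol, maxsteps,
                    if (method == "ros23") 1L else 0L)
  out <- as.data.frame(m)
  names(out) <- .state_names
  cbind(time = as.numeric(times), out)
}
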