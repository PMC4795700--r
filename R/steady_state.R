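#' Maximum steady-state proportion of active G protein
#'
#' Without GTPase activity a GEF drives the exchange cycle to detailed balance
#' with \[G_GDP\]/\[G_GTP\] = kappa; with e0 << g0 (negligible mass in
#' complexes) the active fraction is then 1/(kappa + 1). No GEF concentration
#' can push the system above this ceiling.
#'
#' @param kappa equilibrium inactive:active ratio (see [kappa_ratio()])
#' @return Fraction in (0, 1].
#' @export
max_active_fraction <- function(kappa) {
  stopifnot(kappa >= 0)
  1 / (kappa + 1)
}

#' Steady-state active fraction without GTPase activity
#'
#' At detailed balance the free G protein obeys \[G_GDP\] = kappa \[G_GTP\],
#' and the conservation of total G protein including the spanning-tree complex
#' occupancies closes the system into the quadratic
#' (kappa+1) x^2 + 2 b x - Ks g0 = 0 with b = (e0 - g0 + (kappa+1) Ks)/2 and
#' Ks = K0/(K1 kappa + K2). The positive root is evaluated in the
#' cancellation-free form x = Ks g0 / (b + sqrt(b^2 + (kappa+1) Ks g0)).
#'
#' The fraction equals 1/(kappa+1) in the limit e0 -> 0 and decreases strictly
#' as e0 grows: surplus GEF sequesters G protein into complexes.
#'
#' @param e0 total GEF (uM)
#' @param g0 total G protein (uM)
#' @param summary a [summary_params()] object
#' @return Free \[G_GTP\]/g0, a fraction in (0, 1\].
#' @export
active_fraction_no_gtpase <- function(e0, g0, summary) {
  kap <- summary$kappa
  Ks <- summary$Ks
  b <- 0.5 * (e0 - g0 + (kap + 1) * Ks)
  x <- Ks * g0 / (b + sqrt(b^2 + (kap + 1) * Ks * g0))
  x / g0
}

#' Sensitivity of steady-state active G protein to the quadratic coefficient b
#'
#' d\[G_GTP\]/db = (b / sqrt(b^2 + (kappa+1) Ks g0) - 1) / (kappa + 1), which
#' is strictly negative for positive Ks and g0. Since b depends on the GEF
#' total only through b = (e0 - g0 + (kappa+1)Ks)/2 (so db/de0 = 1/2 > 0),
#' the steady-state concentration of active G protein strictly decreases as
#' GEF is added — a GEF alone is inhibitory.
#'
#' @param b quadratic half-linear coefficient (uM); for a given GEF total use
#'   b = (e0 - g0 + (kappa+1) Ks)/2
#' @param summary a [summary_params()] object
#' @param g0 total G protein (uM)
#' @return The (negative) derivative d\[G_GTP\]/db.
#' @export
dgtp_db <- function(b, summary, g0) {
  kap <- summary$kappa
  (b / sqrt(b^2 + (kap + 1) * summary$Ks * g0) - 1) / (kap + 1)
}

#' Steady-state active fraction with intrinsic GTPase activity
#'
#' Balancing the reduced exchange flux against first-order hydrolysis
#' (f_GTPase = kase \[G_GTP\]) under g0 = \[G_GDP\] + \[G_GTP\] gives
#' (K2 - K1) x^2 + 2 bhat x - kappa_hat g0 e0 = 0 with
#' bhat = (K0 + K1 g0 + (kappa+1) kappa_hat e0)/2 and kappa_hat = kfwd/kase.
#' The admissible root (the one in \[0, g0\]) is evaluated in the
#' cancellation-free form x = kappa_hat g0 e0 / (bhat + sqrt(bhat^2 +
#' (K2 - K1) kappa_hat g0 e0)), which also covers the degenerate linear case
#' K2 = K1 continuously.
#'
#' The fraction rises from 0 (hydrolysis dominates, kappa_hat e0 -> 0) toward
#' the ceiling 1/(kappa+1) (exchange dominates, kappa_hat e0 -> Inf): GTPase
#' activity suppresses the activation state and added GEF counteracts the
#' suppression.
#'
#' @param e0 total GEF (uM)
#' @param g0 total G protein (uM)
#' @param summary a [summary_params()] object with `kappa_hat` defined (i.e.
#'   built with an intrinsic [gtpase_spec()])
#' @return Free \[G_GTP\]/g0, a fraction in \[0, 1/(kappa+1)\].
#' @export
active_fraction_intrinsic <- function(e0, g0, summary) {
  if (is.na(summary$kappa_hat))
    stop("active_fraction_intrinsic: kappa_hat undefined; build summary_params with an intrinsic gtpase_spec")
  kh <- summary$kappa_hat
  a <- summary$K2 - summary$K1
  bhat <- 0.5 * (summary$K0 + summary$K1 * g0 + (summary$kappa + 1) * kh * e0)
  c0 <- kh * g0 * e0
  if (c0 == 0) return(0)
  x <- c0 / (bhat + sqrt(bhat^2 + a * c0))
  min(max(x, 0), g0) / g0
}

#' Numerical steady state of the full mass-action model
#'
#' Relaxes the full six-species model by integration and polishes the result
#' with a damped Newton iteration on the conservation-reduced system (unknowns
#' e_gdp, e_gtp, e_g, g_gtp; free GEF and g_gdp recovered from the totals, so
#' both conservation laws hold exactly in the result). Convergence requires
#' the residual max|rhs| <= tol * max(e0, g0) per second.
#'
#' @param params,pools,spec model specification (`spec = NULL`: no GTPase)
#' @param totals a [system_totals()] object
#' @param state0 optional initial [system_state()]; defaults to all GEF free
#'   and all G protein GDP-bound
#' @param tol convergence tolerance (relative to max(e0, g0)), default 1e-10
#' @param t_max relaxation horizon cap (s)
#' @param rtol,atol integration tolerances for the relaxation phase
#' @return The steady [system_state()], with attribute `residual`.
#' @export
numeric_steady_state <- function(params, pools, totals, spec = NULL,
                                 state0 = NULL, tol = 1e-10, t_max = 1e6,
                                 rtol = 1e-8, atol = 1e-12) {
  # relaxation runs on the L-stable method: random log-uniform rate draws are
  # routinely stiff and the explicit stepper would be stability-limited

  e0 <- totals[["e0"]]
  g0 <- totals[["g0"]]
  if (is.null(state0))
    state0 <- system_state(e = e0, g_gdp = g0)
  scale <- max(e0, g0, .Machine$double.eps)

  if (e0 == 0) {
    # no enzyme: complexes stay empty; GTPase (if any) drains g_gtp to g_gdp
    g_gtp <- if (is.null(spec) || spec$mode == "none") state0[["g_gtp"]] else 0
    st <- system_state(g_gdp = g0 - g_gtp, g_gtp = g_gtp)
    attr(st, "residual") <- max(abs(gef_rhs(st, params, pools, spec)))
    return(st)
  }

  residual <- function(z) {
    bound <- z[1] + z[2] + z[3]
    st <- c(e = e0 - bound, e_gdp = z[1], e_gtp = z[2], e_g = z[3],
            g_gdp = g0 - z[4] - bound, g_gtp = z[4])
    dy <- cpp_rhs_full(as.numeric(st), as.numeric(params), as.numeric(pools),
                       .gtpase_code(spec))
    dy[c(2, 3, 4, 6)]
  }
  # Pseudo-transient continuation (regularized Newton with an SER update of
  # the pseudo-time step): far from the solution the iteration follows the
  # physical relaxation path, near it the regularization vanishes and the
  # scheme becomes pure Newton. Convergence is declared on either the flux
  # residual (<= tol * scale) or the concentration update (Newton step norm):
  # in slow-kinetics regimes a tiny flux residual can hide a sizable
  # concentration error, and in fast-kinetics regimes the flux noise floor
  # sits far above `tol` while the state is already converged.
  newton <- function(z) {
    jac <- function(z, F) {
      J <- matrix(0, 4, 4)
      for (j in 1:4) {
        dz <- max(1e-8 * abs(z[j]), 1e-12 * scale)
        zp <- z; zp[j] <- zp[j] + dz
        J[, j] <- (residual(zp) - F) / dz
      }
      J
    }
    in_bounds <- function(zn)
      all(zn > -1e-13 * scale) && sum(zn[1:3]) <= e0 * (1 + 1e-12) &&
      zn[4] + sum(zn[1:3]) <= g0 * (1 + 1e-12)
    laststep <- Inf
    done <- function(z, F) list(z = z, res = max(abs(F)),
                                ok = max(abs(F)) <= tol * scale ||
                                  laststep <= 1e-11 * scale)
    # Phase 1: plain non-monotone Newton, unconstrained. Intermediate iterates
    # may leave the physical region (the mass-action polynomials are defined
    # everywhere) and the residual may transiently grow; the endpoint is
    # accepted only if it is physical and converged.
    zz <- z
    F <- residual(zz)
    for (iter in 1:50) {
      if (!all(is.finite(F)) || max(abs(zz)) > 1e9 * scale) break
      if (max(abs(F)) <= 1e-15 * scale) break
      J <- jac(zz, F)
      step <- tryCatch(solve(J, -F), error = function(e) NULL)
      if (is.null(step)) break
      zz <- zz + step
      F <- residual(zz)
      if (max(abs(step)) <= 1e-13 * scale) break
    }
    if (all(is.finite(zz)) && in_bounds(zz)) {
      zc <- pmax(zz, 0)
      Fc <- residual(zc)
      if (max(abs(Fc)) <= tol * scale) {
        laststep <- 0
        return(done(zc, Fc))
      }
    }

    # Phase 2: bounded pseudo-transient continuation from the relaxed state.
    F <- residual(z)
    mu <- 0 # pure Newton until it misbehaves
    for (iter in 1:200) {
      if (max(abs(F)) <= 1e-15 * scale) return(done(z, F))
      J <- jac(z, F)
      step <- tryCatch(solve(J - mu * diag(4), -F), error = function(e) NULL)
      if (is.null(step)) {
        if (mu == 0) mu <- max(abs(diag(J))) * 1e-8 + 1e-12
        mu <- mu * 4
        next
      }
      zn <- z + step
      Fn <- if (in_bounds(zn)) residual(pmax(zn, 0)) else NULL
      if (!is.null(Fn) && max(abs(Fn)) < max(abs(F))) {
        laststep <- max(abs(step))
        z <- pmax(zn, 0)
        mu <- mu * max(abs(Fn)) / max(abs(F)) # SER: relax toward pure Newton
        F <- Fn
        if (max(abs(F)) <= tol * scale || laststep <= 1e-11 * scale)
          return(done(z, F))
      } else {
        if (mu == 0) mu <- max(abs(diag(J))) * 1e-3 + 1e-12
        else mu <- mu * 4
        if (mu > 1e12 * (max(abs(diag(J))) + 1)) return(done(z, F))
      }
    }
    done(z, F)
  }

  st <- as.numeric(state0[.state_names])
  t_relax <- 10
  repeat {
    tr <- cpp_ode_full(st, c(0, t_relax), as.numeric(params),
                       as.numeric(pools), .gtpase_code(spec),
                       rtol, atol, 1e8, 1L)
    st <- tr[2, ]
    z <- pmax(st[c(2, 3, 4, 6)], 0)
    sol <- newton(z)
    if (sol$ok || t_relax >= t_max) break
    t_relax <- t_relax * 10
  }
  if (!sol$ok)
    stop(sprintf(paste0("numeric_steady_state: no convergence ",
                        "(residual %.3e after t = %g s relaxation)"),
                 sol$res, t_relax))
  z <- sol$z
  bound <- z[1] + z[2] + z[3]
  out <- system_state(e = e0 - bound, e_gdp = z[1], e_gtp = z[2], e_g = z[3],
                      g_gdp = g0 - z[4] - bound, g_gtp = z[4])
  attr(out, "residual") <- sol$res
  out
}
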