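#' Kinetic rate constants of the reversible GEF mechanism
#'
#' The exchange cycle E <-> E.G_GDP <-> E.G <-> E.G_GTP <-> E is parameterised
#' by eight elementary rate constants. Units are micromolar and seconds
#' throughout: bimolecular rates (`k1`, `k4`, `k5`, `k8`) in /uM/s, unimolecular
#' rates (`k2`, `k3`, `k6`, `k7`) in /s.
#'
#' @param k1 association of free GEF with GDP-bound G protein (/uM/s)
#' @param k2 dissociation of the E.G_GDP complex (/s)
#' @param k3 GDP release from E.G_GDP, giving the nucleotide-free E.G (/s)
#' @param k4 GDP rebinding to E.G (/uM/s)
#' @param k5 association of free GEF with GTP-bound G protein (/uM/s)
#' @param k6 dissociation of the E.G_GTP complex (/s)
#' @param k7 GTP release from E.G_GTP (/s); setting `k7 = 0` yields the
#'   artificial irreversible mechanism
#' @param k8 GTP binding to E.G (/uM/s)
#' @return An object of class `gef_params` (a named numeric vector).
#' @seealso [make_irreversible()], [kappa_ratio()], [sample_params()]
#' @export
gef_params <- function(k1, k2, k3, k4, k5, k6, k7, k8) {
  k <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4,
         k5 = k5, k6 = k6, k7 = k7, k8 = k8)
  storage.mode(k) <- "double"
  structure(k, class = "gef_params")
}

#' Buffered guanine nucleotide pools
#'
#' GDP and GTP are held at constant concentration (buffered pools); they enter
#' the rate laws as fixed factors on the nucleotide-binding steps and are never
#' dynamic species.
#'
#' @param gdp,gtp pool concentrations in uM; both must be strictly positive
#' @return An object of class `nucleotide_pools`.
#' @export
nucleotide_pools <- function(gdp, gtp) {
  structure(c(gdp = as.numeric(gdp), gtp = as.numeric(gtp)),
            class = "nucleotide_pools")
}

#' Total GEF and G protein concentrations
#'
#' @param e0 total GEF (uM)
#' @param g0 total G protein (uM)
#' @return An object of class `system_totals`.
#' @export
system_totals <- function(e0, g0) {
  structure(c(e0 = as.numeric(e0), g0 = as.numeric(g0)),
            class = "system_totals")
}

#' GTPase activity specification
#'
#' Selects the inactivation flux f_GTPase applied to free GTP-bound G protein:
#' `"none"` gives zero flux, `"intrinsic"` first-order hydrolysis
#' kase * \[G_GTP\], and `"gap"` the Michaelis-Menten form
#' kase * \[G_GTP\] * f0 / (km + \[G_GTP\]) where f0 is the total GAP
#' concentration.
#'
#' @param mode one of `"none"`, `"intrinsic"`, `"gap"`
#' @param kase first-order (intrinsic, /s) or catalytic (gap, /s) rate
#' @param km Michaelis constant (uM, gap mode)
#' @param f0 total GAP concentration (uM, gap mode)
#' @return An object of class `gtpase_spec`.
#' @export
gtpase_spec <- function(mode = c("none", "intrinsic", "gap"),
                        kase = 0, km = NA_real_, f0 = NA_real_) {
  mode <- match.arg(mode)
  if (mode == "gap") {
    if (is.na(km)) stop("gtpase_spec: gap mode requires 'km'")
    if (is.na(f0)) stop("gtpase_spec: gap mode requires 'f0'")
  }
  structure(list(mode = mode, kase = as.numeric(kase),
                 km = as.numeric(km), f0 = as.numeric(f0)),
            class = "gtpase_spec")
}

#' Validate a kinetic parameter bundle
#'
#' Checks all structural invariants: rate constants non-negative, nucleotide
#' pools strictly positive, totals non-negative, and (when given) a coherent
#' GTPase specification. Errors name the offending field.
#'
#' @param params a [gef_params()] object
#' @param pools a [nucleotide_pools()] object
#' @param totals a [system_totals()] object
#' @param gtpase optional [gtpase_spec()]
#' @return The bundle, invisibly, if valid; otherwise an error.
#' @export
validate_bundle <- function(params, pools, totals, gtpase = NULL) {
  for (nm in names(params)) {
    v <- params[[nm]]
    if (!is.finite(v) || v < 0)
      stop(sprintf("invalid parameter %s = %g: rates must be finite and >= 0",
                   nm, v))
  }
  for (nm in names(pools)) {
    v <- pools[[nm]]
    if (!is.finite(v) || v <= 0)
      stop(sprintf("invalid pool %s = %g: nucleotide pools must be > 0", nm, v))
  }
  for (nm in names(totals)) {
    v <- totals[[nm]]
    if (!is.finite(v) || v < 0)
      stop(sprintf("invalid total %s = %g: totals must be >= 0", nm, v))
  }
  if (!is.null(gtpase)) {
    if (!inherits(gtpase, "gtpase_spec")) stop("invalid gtpase: not a gtpase_spec")
    for (nm in c("kase", "km", "f0")) {
      v <- gtpase[[nm]]
      if (!is.na(v) && v < 0)
        stop(sprintf("invalid gtpase field %s = %g: must be >= 0", nm, v))
    }
  }
  invisible(list(params = params, pools = pools, totals = totals,
                 gtpase = gtpase))
}

#' Equilibrium ratio of inactive to active G protein imposed by a GEF
#'
#' kappa is the ratio of the product of the backward-path rate constants
#' (k5, k7, k4, k2) to the product of the forward-path rate constants
#' (k1, k3, k8, k6), multiplied by \[GDP\]/\[GTP\]. In the absence of GTPase
#' activity the exchange cycle relaxes to detailed balance with
#' \[G_GDP\]/\[G_GTP\] = kappa, independent of the GEF and G protein totals;
#' 1/(kappa + 1) is then the maximum attainable active fraction.
#'
#' A zero backward rate gives kappa = 0 (the irreversible limit). A zero
#' forward rate leaves kappa undefined and is an error.
#'
#' @param params a [gef_params()] object
#' @param pools a [nucleotide_pools()] object
#' @return kappa, a dimensionless scalar.
#' @export
kappa_ratio <- function(params, pools) {
  fwd <- params[["k1"]] * params[["k3"]] * params[["k8"]] * params[["k6"]]
  bwd <- params[["k5"]] * params[["k7"]] * params[["k4"]] * params[["k2"]]
  if (fwd <= 0)
    stop("kappa_ratio: undefined, a forward rate (k1, k3, k6, k8) is zero")
  bwd / fwd * pools[["gdp"]] / pools[["gtp"]]
}

#' Synthetic kinetic parameter sets
#'
#' Draws a reproducible, thermodynamically valid parameter bundle: the eight
#' rate constants and both nucleotide pools are sampled log-uniformly, and the
#' totals fix the enzyme-limited regime e0 << g0 in which the quasi-steady-state
#' reduction is valid. This generator stands in for measured rate-constant
#' tables; the defaults span the range commonly reported for small-GTPase /
#' exchange-factor enzymology (rates 1e-2 to 1e2, pools 10 to 1000 uM).
#'
#' @param seed integer seed; the same seed always returns the same bundle
#' @param log_range length-2 range for the rate constants (log-uniform)
#' @param pool_range length-2 range for the nucleotide pools (log-uniform)
#' @param e0 total GEF (uM), default 0.1 (the basal level of the stimulation
#'   protocol)
#' @param g0_factor g0 = g0_factor * e0, default 100 so that e0 << g0
#' @return A list with elements `params`, `pools`, `totals`.
#' @export
sample_params <- function(seed, log_range = c(1e-2, 1e2),
                          pool_range = c(10, 1000),
                          e0 = 0.1, g0_factor = 100) {
  stopifnot(length(log_range) == 2, all(log_range > 0),
            length(pool_range) == 2, all(pool_range > 0))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  k <- exp(runif(8, log(log_range[1]), log(log_range[2])))
  p <- exp(runif(2, log(pool_range[1]), log(pool_range[2])))
  params <- gef_params(k[1], k[2], k[3], k[4], k[5], k[6], k[7], k[8])
  pools <- nucleotide_pools(p[1], p[2])
  totals <- system_totals(e0, g0_factor * e0)
  validate_bundle(params, pools, totals)
  list(params = params, pools = pools, totals = totals)
}

#' Default parameter fixture (synthetic stand-in)
#'
#' A fixed, documented parameter bundle used by the examples, the protocol
#' suite and the tests. The magnitudes are chosen to resemble a fast, abundant
#' small-GTPase exchange system (association near the diffusion-limited regime,
#' rapid complex turnover, physiological nucleotide pools with GTP in roughly
#' 10-fold excess over GDP, an abundant G protein and scarce GEF). They are a
#' synthetic stand-in, not measured constants for any particular system.
#'
#' The fixture gives kappa = 0.4, hence a maximum active fraction
#' 1/(kappa+1) ~ 0.71, and a basal enzyme load e0/g0 = 0.01 well inside the
#' quasi-steady-state regime. The intrinsic GTPase rate places the basal system
#' in the responsive (sigmoidal) part of the dose-response curve.
#'
#' @return A list with elements `params`, `pools`, `totals`, `gtpase`
#'   (intrinsic mode) and `gap` (GAP-mediated mode).
#' @export
gef_fixture <- function() {
  params <- gef_params(k1 = 10, k2 = 20, k3 = 5, k4 = 1,
                       k5 = 10, k6 = 20, k7 = 20, k8 = 1)
  pools <- nucleotide_pools(gdp = 50, gtp = 500)
  totals <- system_totals(e0 = 0.1, g0 = 10)
  gtpase <- gtpase_spec("intrinsic", kase = 0.1)
  gap <- gtpase_spec("gap", kase = 5, km = 1, f0 = 0.5)
  validate_bundle(params, pools, totals, gtpase)
  list(params = params, pools = pools, totals = totals,
       gtpase = gtpase, gap = gap)
}

#' Serialise a parameter bundle to flat-key JSON
#'
#' Keys: k1..k8, gdp, gtp, e0, g0 and optionally gtpase.mode, gtpase.kase,
#' gtpase.km, gtpase.f0. This is also the CLI config format.
#'
#' @param bundle list with `params`, `pools`, `totals` and optional `gtpase`
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_params_json <- function(bundle, path) {
  x <- c(as.list(unclass(bundle$params)),
         as.list(unclass(bundle$pools)),
         as.list(unclass(bundle$totals)))
  if (!is.null(bundle$gtpase)) {
    g <- bundle$gtpase
    x[["gtpase.mode"]] <- g$mode
    x[["gtpase.kase"]] <- g$kase
    if (!is.na(g$km)) x[["gtpase.km"]] <- g$km
    if (!is.na(g$f0)) x[["gtpase.f0"]] <- g$f0
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a parameter bundle from flat-key JSON
#'
#' @param path file written by [write_params_json()] (or hand-edited config)
#' @return A validated list with `params`, `pools`, `totals`, `gtpase`
#'   (NULL when absent from the file).
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c(paste0("k", 1:8), "gdp", "gtp", "e0", "g0")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("config missing required field(s): ", paste(miss, collapse = ", "))
  params <- do.call(gef_params, as.list(vapply(paste0("k", 1:8),
                                               function(n) as.numeric(x[[n]]), 0)))
  pools <- nucleotide_pools(x$gdp, x$gtp)
  totals <- system_totals(x$e0, x$g0)
  gtpase <- NULL
  if (!is.null(x[["gtpase.mode"]])) {
    gtpase <- gtpase_spec(x[["gtpase.mode"]],
                          kase = x[["gtpase.kase"]] %||% 0,
                          km = x[["gtpase.km"]] %||% NA_real_,
                          f0 = x[["gtpase.f0"]] %||% NA_real_)
  }
  validate_bundle(params, pools, totals, gtpase)
  list(params = params, pools = pools, totals = totals, gtpase = gtpase)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
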