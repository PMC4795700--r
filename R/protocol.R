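#' Piecewise-constant GEF stimulation protocol
#'
#' Describes a stimulation experiment as ordered segments of total GEF level.
#' A segment flagged `removal` models washout of free GEF: free enzyme is held
#' at zero while the bound complexes exceed the target total, so the effective
#' enzyme total declines continuously as complexes dissociate until it reaches
#' the target (the only reading of GEF removal that keeps total enzyme
#' continuous and monotone).
#'
#' @param start segment start times (s), strictly increasing, first must be 0
#' @param e0 total GEF level per segment (uM), all >= 0
#' @param removal logical per segment: washout semantics?
#' @param t_end simulation horizon (s)
#' @param n_out number of points of the output grid over \[0, t_end\]
#' @return An object of class `stimulation_protocol`.
#' @export
stimulation_protocol <- function(start, e0, removal = rep(FALSE, length(start)),
                                 t_end = 30, n_out = 601) {
  stopifnot(length(start) == length(e0), length(removal) == length(start))
  if (is.unsorted(start, strictly = TRUE))
    stop("stimulation_protocol: segment start times must be strictly increasing")
  if (start[1] != 0) stop("stimulation_protocol: first segment must start at 0")
  if (any(e0 < 0)) stop("stimulation_protocol: e0 levels must be >= 0")
  if (t_end <= start[length(start)])
    stop("stimulation_protocol: t_end must exceed the last segment start")
  structure(list(start = start, e0 = e0, removal = as.logical(removal),
                 t_end = t_end, n_out = as.integer(n_out)),
            class = "stimulation_protocol")
}

#' The canonical stimulation protocol
#'
#' Basal e0 = 0.1 for 0 <= t < 10, a 10-fold step to e0 = 1.0 for
#' 10 <= t < 20, then washout of free GEF back to e0 = 0.1 for t >= 20,
#' horizon 30 s.
#'
#' @param n_out output grid size
#' @return A [stimulation_protocol()].
#' @export
canonical_protocol <- function(n_out = 601) {
  stimulation_protocol(start = c(0, 10, 20), e0 = c(0.1, 1.0, 0.1),
                       removal = c(FALSE, FALSE, TRUE),
                       t_end = 30, n_out = n_out)
}

#' Simulate a stimulation protocol
#'
#' Integrates the five bound/free G protein species with free GEF computed
#' algebraically from the enzyme conservation law, e = e0(t) - (e_gdp + e_gtp
#' + e_g), clamped at zero during washout segments. The run starts from the
#' numerical steady state at the first segment's GEF level, and the integrator
#' is restarted at each segment boundary so level switches are handled exactly.
#'
#' @param params,pools,spec model specification (`spec = NULL`: no GTPase)
#' @param totals a [system_totals()]; `e0` is overridden segment-wise by the
#'   protocol, `g0` is the G protein total
#' @param protocol a [stimulation_protocol()]
#' @param rtol,atol integration tolerances
#' @param method `"rk45"` or `"ros23"` (see [simulate_mass_action()])
#' @return A data.frame of class `gef_timeseries` with columns time, e, e_gdp,
#'   e_gtp, e_g, g_gdp, g_gtp and attributes `protocol`, `params`, `pools`,
#'   `spec`, `g0`.
#' @export
run_protocol <- function(params, pools, spec = NULL, totals, protocol,
                         rtol = 1e-9, atol = 1e-12,
                         method = c("rk45", "ros23")) {
  method <- match.arg(method)
  g0 <- totals[["g0"]]
  seg_start <- protocol$start
  seg_end <- c(seg_start[-1], protocol$t_end)
  grid <- seq(0, protocol$t_end, length.out = protocol$n_out)

  ss <- numeric_steady_state(params, pools,
                             system_totals(protocol$e0[1], g0), spec)
  y <- as.numeric(ss[c("e_gdp", "e_gtp", "e_g", "g_gdp", "g_gtp")])

  times_out <- numeric(0)
  states_out <- NULL
  for (s in seq_along(seg_start)) {
    e0s <- protocol$e0[s]
    rem <- protocol$removal[s]
    bound <- sum(y[1:3])
    if (!rem && e0s < bound - 1e-12 * max(1, bound))
      stop(sprintf(paste0("run_protocol: segment %d sets e0 = %g below the ",
                          "bound-complex mass %g without removal semantics"),
                   s, e0s, bound))
    inside <- grid > seg_start[s] & grid <= seg_end[s]
    t_seg <- unique(c(seg_start[s], grid[inside], seg_end[s]))
    m <- cpp_ode_protocol(y, t_seg, as.numeric(params), as.numeric(pools),
                          .gtpase_code(spec), e0s, rem, rtol, atol, 1e8,
                          if (method == "ros23") 1L else 0L)
    keep <- t_seg %in% grid[inside]
    if (s == 1) { # include t = 0
      times_out <- 0
      states_out <- m[1, , drop = FALSE]
      e0_of <- e0s
      rem_of <- rem
    }
    times_out <- c(times_out, t_seg[keep])
    states_out <- rbind(states_out, m[keep, , drop = FALSE])
    e0_of <- c(e0_of, rep(e0s, sum(keep)))
    rem_of <- c(rem_of, rep(rem, sum(keep)))
    y <- m[nrow(m), ]
  }

  bound <- states_out[, 1] + states_out[, 2] + states_out[, 3]
  e <- e0_of - bound
  e[rem_of] <- pmax(0, e[rem_of])
  out <- data.frame(time = times_out, e = e,
                    e_gdp = states_out[, 1], e_gtp = states_out[, 2],
                    e_g = states_out[, 3], g_gdp = states_out[, 4],
                    g_gtp = states_out[, 5])
  attr(out, "protocol") <- protocol
  attr(out, "params") <- params
  attr(out, "pools") <- pools
  attr(out, "spec") <- spec
  attr(out, "g0") <- g0
  class(out) <- c("gef_timeseries", "data.frame")
  out
}

#' Classify the response of a trajectory over a stimulation window
#'
#' Compares free \[G_GTP\] at the end of the window with its value at the
#' start; a change exceeding `threshold` (default 1e-6 * g0, robust to
#' integrator noise) is classified `"activated"` or `"inhibited"`, anything
#' smaller `"flat"`.
#'
#' @param ts a `gef_timeseries` from [run_protocol()]
#' @param window length-2 numeric, the stimulated time window (s)
#' @param threshold classification deadband (uM)
#' @return One of `"activated"`, `"inhibited"`, `"flat"`.
#' @export
classify_response <- function(ts, window = c(10, 20),
                              threshold = 1e-6 * attr(ts, "g0")) {
  gt0 <- ts$g_gtp[which.min(abs(ts$time - window[1]))]
  gt1 <- ts$g_gtp[which.min(abs(ts$time - window[2]))]
  d <- gt1 - gt0
  if (d > threshold) "activated" else if (d < -threshold) "inhibited" else "flat"
}

#' The six-panel stimulation suite
#'
#' Runs the canonical protocol for every combination of mechanism
#' (irreversible, i.e. k7 = 0, vs reversible) and GTPase activity (none,
#' intrinsic, GAP-mediated), mirroring a 2 x 3 panel layout: A/B/C are the
#' irreversible mechanism with none/intrinsic/GAP GTPase, D/E/F the reversible
#' mechanism in the same order. Each panel is classified with
#' [classify_response()].
#'
#' @param params,pools,totals model specification (reversible rates; the
#'   irreversible variant is derived internally via [make_irreversible()])
#' @param intrinsic,gap [gtpase_spec()] objects for the two GTPase-active
#'   columns
#' @param protocol a [stimulation_protocol()], default [canonical_protocol()]
#' @param rtol,atol integration tolerances
#' @param method `"rk45"` or `"ros23"` (see [simulate_mass_action()])
#' @return List with `panels` (named list of `gef_timeseries`) and
#'   `classification` (named character vector).
#' @export
fig2_suite <- function(params, pools, totals, intrinsic, gap,
                       protocol = canonical_protocol(),
                       rtol = 1e-9, atol = 1e-12,
                       method = c("rk45", "ros23")) {
  method <- match.arg(method)
  irrev <- make_irreversible(params)
  cases <- list(
    A = list(p = irrev, s = NULL),
    B = list(p = irrev, s = intrinsic),
    C = list(p = irrev, s = gap),
    D = list(p = params, s = NULL),
    E = list(p = params, s = intrinsic),
    F = list(p = params, s = gap))
  panels <- lapply(cases, function(cs)
    run_protocol(cs$p, pools, cs$s, totals, protocol, rtol, atol, method))
  window <- c(protocol$start[2], protocol$start[3])
  cls <- vapply(panels, classify_response, "", window = window)
  list(panels = panels, classification = cls)
}

#' Steady-state dose-response sweep over the GEF total
#'
#' For each GEF level the analytic quasi-steady-state fraction
#' ([active_fraction_no_gtpase()] or [active_fraction_intrinsic()]) is paired
#' with the full mass-action steady state ([numeric_steady_state()]), plus the
#' total mass held in GEF.G protein complexes.
#'
#' @param params,pools model specification
#' @param g0 total G protein (uM)
#' @param mode `"no_gtpase"` or `"intrinsic"`
#' @param e0_grid GEF totals to sweep (uM)
#' @param spec intrinsic [gtpase_spec()] (required for `mode = "intrinsic"`)
#' @return data.frame with columns e0, analytic, numeric (active fractions),
#'   complexes (uM bound G protein) and, for intrinsic mode, kappa_hat_e0.
#' @export
fig3_sweep <- function(params, pools, g0, mode = c("no_gtpase", "intrinsic"),
                       e0_grid, spec = NULL) {
  mode <- match.arg(mode)
  if (mode == "intrinsic" && (is.null(spec) || spec$mode != "intrinsic"))
    stop("fig3_sweep: intrinsic mode requires an intrinsic gtpase_spec")
  summ <- summary_params(params, pools, spec)
  rows <- lapply(e0_grid, function(e0) {
    ana <- if (mode == "no_gtpase")
      active_fraction_no_gtpase(e0, g0, summ)
    else
      active_fraction_intrinsic(e0, g0, summ)
    ss <- numeric_steady_state(params, pools, system_totals(e0, g0),
                               if (mode == "no_gtpase") NULL else spec)
    data.frame(e0 = e0, analytic = ana, numeric = ss[["g_gtp"]] / g0,
               complexes = ss[["e_gdp"]] + ss[["e_gtp"]] + ss[["e_g"]])
  })
  out <- do.call(rbind, rows)
  if (mode == "intrinsic") out$kappa_hat_e0 <- summ$kappa_hat * out$e0
  out
}

#' Write a trajectory as CSV with provenance header
#'
#' Header comment lines (prefixed `#`) record the parameter provenance and any
#' seed, followed by a standard CSV table: columns time, e, e_gdp, e_gtp, e_g,
#' g_gdp, g_gtp. Output is deterministic (no timestamps), so identical inputs
#' produce byte-identical files.
#'
#' @param ts a `gef_timeseries` (or plain data.frame of the same shape)
#' @param path output file
#' @param meta named character vector of extra provenance lines (e.g. seed)
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(ts, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  params <- attr(ts, "params")
  if (!is.null(params))
    writeLines(sprintf("# params: %s",
                       paste(sprintf("%s=%.17g", names(params),
                                     as.numeric(params)), collapse = " ")), con)
  for (nm in names(meta)) writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  utils::write.csv(as.data.frame(unclass(ts))[
    , c("time", "e", "e_gdp", "e_gtp", "e_g", "g_gdp", "g_gtp")],
    con, row.names = FALSE)
  invisible(path)
}
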