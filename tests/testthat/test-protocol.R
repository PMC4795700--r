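test_that("stimulation_protocol validates its segments", {
  expect_error(stimulation_protocol(c(0, 10, 10), c(1, 2, 3)), "increasing")
  expect_error(stimulation_protocol(c(5, 10), c(1, 2)), "start at 0")
  expect_error(stimulation_protocol(c(0, 10), c(1, -2)), ">= 0")
  expect_error(stimulation_protocol(c(0, 10), c(1, 2), t_end = 10), "t_end")
  p <- canonical_protocol()
  expect_equal(p$e0, c(0.1, 1.0, 0.1))
  expect_equal(p$start, c(0, 10, 20))
  expect_true(p$removal[3] && !any(p$removal[1:2]))
})

test_that("a constant protocol started at steady state stays flat", {
  pr <- stimulation_protocol(0, 0.1, FALSE, t_end = 20, n_out = 41)
  ts <- run_protocol(fx$params, fx$pools, fx$gtpase, fx$totals, pr)
  expect_lt(diff(range(ts$g_gtp)) / ts$g_gtp[1], 1e-7)
  expect_lt(diff(range(ts$e_gdp)) / ts$e_gdp[1], 1e-7)
})

test_that("the canonical step inhibits without GTPase and activates with it", {
  tsD <- run_protocol(fx$params, fx$pools, NULL, fx$totals, canonical_protocol())
  expect_identical(classify_response(tsD), "inhibited")

  tsE <- run_protocol(fx$params, fx$pools, fx$gtpase, fx$totals,
                      canonical_protocol())
  tsF <- run_protocol(fx$params, fx$pools, fx$gap, fx$totals,
                      canonical_protocol())
  expect_identical(classify_response(tsE), "activated")
  expect_identical(classify_response(tsF), "activated")
  # relaxation back toward basal after washout
  gt20 <- tsE$g_gtp[which.min(abs(tsE$time - 20))]
  expect_lt(tsE$g_gtp[nrow(tsE)], gt20)
})

test_that("washout semantics: effective e0 is continuous, monotone, exact", {
  ts <- run_protocol(fx$params, fx$pools, NULL, fx$totals, canonical_protocol())
  etot <- ts$e + ts$e_gdp + ts$e_gtp + ts$e_g
  post <- ts$time >= 20
  expect_true(all(diff(etot[post]) <= 1e-12))      # non-increasing
  expect_equal(etot[length(etot)], 0.1, tolerance = 1e-9) # reaches the target
  expect_true(all(ts$e[post] >= 0))
  # before washout the total follows the protocol level exactly
  expect_equal(unique(round(etot[ts$time > 10 & ts$time <= 20], 9)), 1)
})

test_that("reversible/no-GTPase returns to the pre-stimulus steady state", {
  ss <- numeric_steady_state(fx$params, fx$pools, fx$totals, NULL)
  pr <- stimulation_protocol(c(0, 10, 20), c(0.1, 1, 0.1), c(FALSE, FALSE, TRUE),
                             t_end = 80, n_out = 161)
  ts <- run_protocol(fx$params, fx$pools, NULL, fx$totals, pr)
  last <- ts[nrow(ts), ]
  expect_equal(last$g_gtp, ss[["g_gtp"]], tolerance = 0.01)
  expect_equal(last$g_gdp, ss[["g_gdp"]], tolerance = 0.01)
})

test_that("fig2_suite reproduces the qualitative panel classification", {
  suite <- fig2_suite(fx$params, fx$pools, fx$totals, fx$gtpase, fx$gap)
  expect_identical(unname(suite$classification[c("B", "C", "E", "F")]),
                   rep("activated", 4))
  expect_identical(unname(suite$classification[["D"]]), "inhibited")

  # endpoint compositions of the GTPase-free panels differ substantially
  g0 <- fx$totals[["g0"]]
  endA <- suite$panels$A[nrow(suite$panels$A), ]
  endD <- suite$panels$D[nrow(suite$panels$D), ]
  expect_lt(endA$g_gdp, 1e-8 * g0) # irreversible: GDP side empty
  expect_equal(endD$g_gdp / endD$g_gtp, kappa_ratio(fx$params, fx$pools),
               tolerance = 0.01)   # reversible: kappa ratio preserved

  # g0 conserved at every output point of every panel
  for (ts in suite$panels) {
    tot <- ts$g_gdp + ts$g_gtp + ts$e_gdp + ts$e_gtp + ts$e_g
    expect_lt(max(abs(tot - g0)) / g0, 1e-8)
  }
})

test_that("a protocol stepping e0 below the bound mass is rejected", {
  # drive lots of enzyme into complexes, then demand a lower total without
  # washout semantics
  pr <- stimulation_protocol(c(0, 5), c(1, 0.01), c(FALSE, FALSE),
                             t_end = 10, n_out = 21)
  expect_error(run_protocol(fx$params, fx$pools, NULL, fx$totals, pr),
               "without removal")
})

test_that("stimulation sign is reproduced across random parameter sets", {
  # the headline qualitative result, in each system's own time units: window
  # lengths scale with the hydrolysis time 1/kase and the GTPase strength sits
  # in the responsive region (basal activation at 30% of the ceiling)
  for (s in 1:6) {
    b <- sample_params(s, g0_factor = 1000)
    g0 <- b$totals[["g0"]]
    kap <- kappa_ratio(b$params, b$pools)
    kase <- responsive_kase(b$params, b$pools, g0)
    sp <- gtpase_spec("intrinsic", kase = kase)
    Tw <- 12 / kase
    pr <- stimulation_protocol(c(0, Tw, 2 * Tw), c(0.1, 1, 0.1),
                               c(FALSE, FALSE, TRUE), t_end = 3 * Tw,
                               n_out = 61)
    thr <- 1e-6 * g0 / (kap + 1)
    tsN <- run_protocol(b$params, b$pools, NULL, b$totals, pr,
                        rtol = 1e-7, method = "ros23")
    tsA <- run_protocol(b$params, b$pools, sp, b$totals, pr,
                        rtol = 1e-7, method = "ros23")
    expect_identical(classify_response(tsN, c(Tw, 2 * Tw), thr), "inhibited")
    expect_identical(classify_response(tsA, c(Tw, 2 * Tw), thr), "activated")
  }
})

test_that("CSV export is deterministic and carries provenance", {
  pr <- stimulation_protocol(0, 0.1, FALSE, t_end = 2, n_out = 11)
  ts <- run_protocol(fx$params, fx$pools, fx$gtpase, fx$totals, pr)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_timeseries_csv(ts, f1, meta = c(seed = "7"))
  write_timeseries_csv(ts, f2, meta = c(seed = "7"))
  expect_identical(readLines(f1), readLines(f2))
  head <- readLines(f1, n = 3)
  expect_match(head[1], "^# params:")
  expect_match(head[2], "^# seed: 7")
  body <- utils::read.csv(f1, comment.char = "#")
  expect_identical(names(body),
                   c("time", "e", "e_gdp", "e_gtp", "e_g", "g_gdp", "g_gtp"))
  expect_equal(body$g_gtp, ts$g_gtp, tolerance = 1e-12)
})
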