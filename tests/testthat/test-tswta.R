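# Single ts-WTA synapse pair: efficacy map, activation, pulse updates and
# the two competition laws.

test_that("efficacy is strictly decreasing with near-zero top-rail value", {
  p <- defaultParams
  expect_equal(efficacy(p@vfgMin, p), 1)
  expect_lte(efficacy(p@vfgMax, p), 0.01 * efficacy(p@vfgMin, p))
  # any ordered pair in range, including the documented init points
  for (pair in list(c(4.8, 5.1), c(5.1, 5.5), c(4.0, 6.0), c(4.8, 4.81)))
    expect_gt(efficacy(pair[1], p), efficacy(pair[2], p))
  expect_error(efficacy(p@vfgMin - 0.5, p), "range")
  expect_error(efficacy(p@vfgMax + 0.5, p), "range")
})

test_that("activation is zero without drive, capped at iB, and complementary", {
  p <- defaultParams
  st <- tsWtaState(4.9, 5.3, p)
  expect_identical(cellActivation(st, FALSE, FALSE, p), 0)
  expect_error(cellActivation(st, TRUE, TRUE, p), "complementarity")
  # strongest synapse against an eliminated competitor attains the cap
  stTop <- tsWtaState(p@vfgMin, p@vfgMax, p)
  expect_equal(cellActivation(stTop, TRUE, FALSE, p), p@iB, tolerance = 1e-4)
  # eliminated synapse against a strong one: below 1% of the cap
  expect_lte(cellActivation(stTop, FALSE, TRUE, p), 0.01 * p@iB)
  # resource cap holds for random states
  set.seed(1)
  for (i in 1:50) {
    st <- tsWtaState(runif(1, 4, 6), runif(1, 4, 6), p)
    expect_lte(cellActivation(st, TRUE, FALSE, p), p@iB)
    expect_lte(cellActivation(st, FALSE, TRUE, p), p@iB)
  }
})

test_that("pulse updates follow the threshold-linear injection/tunneling rule", {
  p <- defaultParams
  st <- tsWtaState(5.0, 5.2, p)
  # feedback at threshold: active synapse is a fixed point, inactive leaks
  at <- applyPulse(st, "S1", p@thetaFb, p)
  expect_equal(at@vfg1, 5.0)
  expect_equal(at@vfg2, 5.2 + p@etaLeak)
  # strong feedback strengthens (vfg decreases)
  expect_lt(applyPulse(st, "S1", 1, p)@vfg1, 5.0)
  # zero feedback repeatedly: active synapse climbs to the top rail
  s <- st
  for (i in 1:500) s <- applyPulse(s, "S1", 0, p)
  expect_equal(s@vfg1, p@vfgMax)
  expect_error(applyPulse(st, "S1", -0.1, p), "feedbackLevel")
})

test_that("equal stimulation lets the stronger-biased synapse win (law 1)", {
  p <- defaultParams
  out <- runCompetition(tsWtaState(4.9, 5.3, p), alternatingSchedule(250), p)
  expect_identical(out@winner, "S1")
  expect_false(is.na(out@pulsesToDecision))
  # property over seeds: any gap >= 0.1 V within the init band
  winners <- vapply(1:25, function(s) {
    set.seed(s)
    gap <- runif(1, 0.1, 0.5)
    v1 <- runif(1, 4.8, 5.5 - gap)
    runCompetition(tsWtaState(v1, v1 + gap, p), alternatingSchedule(250),
                   p)@winner
  }, character(1))
  expect_true(all(winners == "S1"))
})

test_that("3x stimulation overrides a small adverse bias (law 2)", {
  p <- defaultParams
  out <- runCompetition(tsWtaState(5.00, 5.05, p),
                        alternatingSchedule(250, ratio = 3L), p)
  expect_identical(out@winner, "S2")
  winners <- vapply(1:25, function(s) {
    set.seed(s)
    gap <- runif(1, 0, 0.1)
    v1 <- runif(1, 4.8, 5.4)
    runCompetition(tsWtaState(v1, v1 + gap, p),
                   alternatingSchedule(250, 3L), p)@winner
  }, character(1))
  expect_true(all(winners == "S2"))
})

test_that("exact ties resolve deterministically to the first-pulsed synapse", {
  p <- defaultParams
  out1 <- runCompetition(tsWtaState(5.1, 5.1, p), alternatingSchedule(200), p)
  out2 <- runCompetition(tsWtaState(5.1, 5.1, p), alternatingSchedule(200), p)
  expect_identical(out1@winner, out2@winner)
  expect_identical(out1@winner, "S1")
})

test_that("schedules with simultaneous pulses are rejected", {
  p <- defaultParams
  bad <- matrix(c(1, 1, 0, 1), 2, 2)
  expect_error(runCompetition(tsWtaState(5, 5.2, p), bad, p), "simultaneous")
  expect_error(runCompetition(tsWtaState(5, 5.2, p), c(1L, 3L), p), "indices")
})

test_that("trajectories stay clipped and the gap diverges monotonically", {
  p <- defaultParams
  set.seed(42)
  for (i in 1:10) {
    gap <- runif(1, 0.1, 0.5)
    v1 <- runif(1, 4.8, 5.5 - gap)
    out <- runCompetition(tsWtaState(v1, v1 + gap, p),
                          alternatingSchedule(250), p)
    tr <- out@trajectory
    expect_true(all(tr >= p@vfgMin - 1e-12 & tr <= p@vfgMax + 1e-12))
    # after the last sign change of (vfg1 - vfg2), |gap| is non-decreasing
    # at full-cycle granularity (every second pulse)
    cyc <- tr[seq(1, nrow(tr), by = 2), ]
    g <- cyc[, 1] - cyc[, 2]
    flips <- which(sign(g[-1]) != sign(g[-length(g)]))
    from <- if (length(flips)) max(flips) + 1L else 1L
    expect_true(all(diff(abs(g[from:length(g)])) >= -1e-12))
  }
})
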