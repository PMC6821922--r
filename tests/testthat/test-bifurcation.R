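test_that("iterated map composes the reduced map", {
  expect_equal(nthIterate(97, 1, 1.8, 6), reducedMap(97, 1.8, 6))
  # three sub-threshold accumulation steps
  expect_equal(nthIterate(50, 3, 3.2, 6), 80)
  # beta = 0 reduces exactly to the uncoupled map
  S <- seq(-10, 105, by = 0.7)
  p <- modelParams(RC = 1.7)
  expect_equal(reducedMap(S, 1.7, 0), stepUncoupled(S, p)$S, tolerance = 1e-12)
})

test_that("period detection classifies constant, periodic and chaotic orbits", {
  expect_identical(orbitPeriod(detectPeriod(rep(4.2, 30))), 1L)
  orb <- rep(c(84.45, 94.45, 99.94), 12)
  s <- detectPeriod(orb)
  expect_identical(orbitPeriod(s), 3L)
  expect_equal(orbitPoints(s), c(84.45, 94.45, 99.94))
  # uncoupled map with expanding flowering branch: no stable cycle
  # (non-integer RC; at exact integers the double-precision orbit is
  # absorbed by an exactly representable border cycle)
  expect_true(is.na(orbitPeriod(reducedAttractor(2.7, 0))))
  expect_true(is.na(orbitPeriod(reducedAttractor(3.3, 0))))
  expect_error(detectPeriod(numeric(0)), "empty")
})

test_that("third-iterate near-tangencies appear just below the period-3 window", {
  tp <- findTangencyPoints(RC = 1.6171, beta = 6, n = 3)
  tang <- tp[!tp$crossing, ]
  expect_equal(nrow(tang), 3)
  # values frozen from bracketed minimisation of |f^3(S) - S| at 1e-9
  expect_equal(tang$S, c(84.47994, 94.47994, 99.94148), tolerance = 1e-4)
  expect_true(all(tang$gap > 0 & tang$gap < 1e-3))
  # the unstable period-1 fixed point shows up as a true crossing
  cross <- tp[tp$crossing, ]
  expect_equal(nrow(cross), 1)
  fp <- cross$S
  expect_equal(reducedMap(fp, 1.6171, 6), fp, tolerance = 1e-6)
  # tangency consistency: the three points form one near-3-cycle
  s <- sort(tang$S)
  expect_equal(reducedMap(s[1], 1.6171, 6), s[2], tolerance = 1e-2)
  expect_equal(reducedMap(s[2], 1.6171, 6), s[3], tolerance = 1e-2)
  expect_equal(reducedMap(s[3], 1.6171, 6), s[1], tolerance = 1e-2)
})

test_that("inside the window the third iterate crosses transversally", {
  tp <- findTangencyPoints(RC = 1.8, beta = 6, n = 3)
  expect_gte(sum(tp$crossing), 3)   # stable 3-cycle plus companions
  att <- reducedAttractor(1.8, 6)
  expect_identical(orbitPeriod(att), 3L)
  # the attractor points are among the crossings
  for (s in orbitPoints(att))
    expect_lt(min(abs(tp$S[tp$crossing] - s)), 1e-4)
})

test_that("uncoupled map has its fixed point crossing at the closed-form location", {
  tp <- findTangencyPoints(RC = 0.5, beta = 0, n = 1)
  expect_true(any(tp$crossing))
  expect_equal(tp$S[tp$crossing], 100 - 0.5 * 10 / 1.5, tolerance = 1e-6)
})

test_that("period-adding: integer cost ratios carry period Q+1 at strong coupling", {
  for (Q in 1:3)
    expect_identical(orbitPeriod(reducedAttractor(Q, 6)), Q + 1L)
})

test_that("window-edge scan semantics", {
  # scanning a range wholly inside the period-3 window returns its lower bound
  e <- periodWindowEdge(3, 6, RCrange = c(1.70, 1.75), resolution = 1e-2,
                        nTransient = 5000)
  expect_equal(e$RC, 1.70)
  expect_identical(orbitPeriod(e$attractor), 3L)
  expect_error(periodWindowEdge(5, 6, RCrange = c(1.7, 1.8),
                                resolution = 1e-2, nTransient = 2000),
               "no period-5 window")
})

test_that("uncoupled fixed point loses stability at unit cost ratio", {
  cc <- criticalCostRatio()
  expect_equal(cc$RC, 1, tolerance = 1e-8)
  expect_equal(cc$slope, -1, tolerance = 1e-4)
})

test_that("border derivatives: accumulation slope 1, flowering slope -RC or 0", {
  d0 <- borderDerivatives(RC = 2, beta = 0)
  expect_equal(d0$left, 1, tolerance = 1e-9)
  expect_equal(d0$right, -2, tolerance = 1e-9)
  d6 <- borderDerivatives(RC = 2, beta = 6)
  expect_equal(d6$left, 1, tolerance = 1e-9)
  expect_equal(d6$right, 0, tolerance = 1e-9)
})

test_that("density diagrams are column-normalised and resolve attractors", {
  p <- modelParams(beta = 6, eI = 0, N = 15, Ttransient = 500,
                   Trecord = 30, seed = 9)
  sc <- densityBifurcation(p, RCgrid = c(0.7, 2.0), nBins = 60)
  d <- scanDensities(sc)
  expect_equal(colSums(d), c(1, 1), ignore_attr = TRUE)
  # RC = 2: the period-3 attractor occupies exactly 3 bins
  expect_identical(scanStats(sc)$support[2], 3L)
  # phase densities live on (-pi, pi]
  sc2 <- densityBifurcation(p, RCgrid = 2, variable = "thetaCs", nBins = 36)
  expect_equal(sum(scanDensities(sc2)), 1)
  expect_equal(range(sc2@breaks), c(-pi, pi))
})

test_that("state classification separates desync, period-2 and period-3 regimes", {
  expect_identical(classifyState(0.4, c(`2` = 0.9, `3` = 0.05)), "I")
  expect_identical(classifyState(1.0, c(`2` = 0.9, `3` = 0.05)), "II")
  expect_identical(classifyState(0.95, c(`2` = 0.26, `3` = 0.73)), "III")
  expect_error(classifyState(1, c(0.5, 0.5)), "names")
})

test_that("beta-RC sweep labels the three states on a coarse grid", {
  sc <- sweepBetaRc(betaGrid = c(0, 6), RCgrid = c(1.0, 2.0),
                    replicates = 2L, seed = 5L, N = 30,
                    Ttransient = 500)
  st <- scanStats(sc)
  expect_equal(nrow(st), 4)
  expect_true(all(st$FIN >= 0 & st$FIN <= 1))
  expect_true(all(st[paste0("FP", 2:6)] >= 0 & st[paste0("FP", 2:6)] <= 1))
  # uncoupled cells never reach strong synchrony; coupled ones do
  expect_true(all(st$state[st$beta == 0] == "I"))
  expect_true(all(st$state[st$beta == 6] %in% c("II", "III")))
  # at (RC = 2, beta = 6) period 3 beats period 2 under noise
  i <- which(st$beta == 6 & st$RC == 2)
  expect_gt(st$FP3[i], st$FP2[i])
})
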