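test_that("a pure period-3 cosine yields exactly the three fundamental phases", {
  t <- 1:15
  x <- matrix(cos(2 * pi * t / 3), nrow = 1)
  ph <- hilbertPhase(x)
  th <- phaseMatrix(ph)[1, ]
  want <- Arg(exp(2i * pi * t / 3))   # 2pi/3, -2pi/3, 0 cycling
  expect_equal(th, want, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sort(unique(round(th, 6))),
               round(c(-2 * pi / 3, 0, 2 * pi / 3), 6))
  expect_equal(amplitudeMatrix(ph)[1, ], rep(1, 15),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("phases match the explicit DFT-sum analytic signal", {
  set.seed(21)
  for (T in c(8, 15)) {
    x <- runif(T, 0, 9)
    got <- hilbertPhase(matrix(x, 1))
    a <- oracleAnalytic(x - mean(x))
    expect_equal(phaseMatrix(got)[1, ], Arg(a), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(amplitudeMatrix(got)[1, ], Mod(a), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("phases are invariant to offset and positive scaling", {
  set.seed(4)
  x <- matrix(runif(30, 0, 9), nrow = 2)
  base <- phaseMatrix(hilbertPhase(x))
  expect_equal(phaseMatrix(hilbertPhase(x + 7)), base, tolerance = 1e-9)
  expect_equal(phaseMatrix(hilbertPhase(x * 3.7)), base, tolerance = 1e-9)
  # wrap invariant
  expect_true(all(abs(base) <= pi + 1e-12))
})

test_that("constant series are flagged invalid and propagate as off-years", {
  x <- rbind(rep(5, 10), c(9, rep(0, 9)))
  expect_warning(ph <- hilbertPhase(x), "constant")
  expect_false(any(validMask(ph)[1, ]))
  expect_true(all(validMask(ph)[2, ]))
  expect_warning(f <- onFlagsPhase(ph), "off-years")
  expect_true(all(flagsMatrix(f)[1, ] == 0))
})

test_that("amplitude flags threshold strictly at the temporal mean", {
  expect_equal(flagsMatrix(onFlagsAmplitude(matrix(c(3, 0, 0, 3, 0, 0), 1))),
               matrix(c(1L, 0L, 0L, 1L, 0L, 0L), 1), ignore_attr = TRUE)
  expect_equal(flagsMatrix(onFlagsAmplitude(matrix(c(5, 1, 1, 5, 1, 1, 5), 1))),
               matrix(c(1L, 0L, 0L, 1L, 0L, 0L, 1L), 1), ignore_attr = TRUE)
  # ties and constants resolve to off
  expect_true(all(flagsMatrix(onFlagsAmplitude(matrix(2, 3, 4))) == 0))
})

test_that("phase flags use strict |theta| < pi/2 with boundary off", {
  th <- matrix(c(0, pi / 2, pi, -pi / 4, -2 * pi / 3), 1)
  ph <- new("PhaseEnsemble", theta = th, amplitude = abs(th),
            valid = matrix(TRUE, 1, 5))
  expect_equal(flagsMatrix(onFlagsPhase(ph)),
               matrix(c(1L, 0L, 0L, 1L, 0L), 1), ignore_attr = TRUE)
  # the period-3 fundamental cycle flags as on/off/off
  th3 <- matrix(rep(c(0, 2 * pi / 3, -2 * pi / 3), 4), 1)
  ph3 <- new("PhaseEnsemble", theta = th3, amplitude = th3 * 0 + 1,
             valid = matrix(TRUE, 1, 12))
  expect_equal(flagsMatrix(onFlagsPhase(ph3))[1, ],
               rep(c(1L, 0L, 0L), 4), ignore_attr = TRUE)
})

test_that("flag agreement counts matching entries", {
  a <- matrix(c(1, 0, 1, 0), 2)
  expect_equal(flagAgreement(a, a), 1)
  expect_equal(flagAgreement(a, 1 - a), 0)
  expect_equal(flagAgreement(a, matrix(c(1, 0, 0, 0), 2)), 0.75)
  expect_error(flagAgreement(a, matrix(0, 3, 3)), "shape")
})

test_that("amplitude and phase on-year definitions coincide on model output", {
  # moderate grid over coupling strength and cost ratio, both noise levels
  for (eI in c(0, 0.2)) {
    for (beta in c(0, 4, 8)) {
      for (RC in c(0.8, 1.6, 2.4, 3.6)) {
        sp <- simulatedSeries(RC = RC, beta = beta, eI = eI, N = 20,
                              seed = 5, Ttransient = 500)
        ph <- suppressWarnings(hilbertPhase(sp))
        a <- suppressWarnings(flagAgreement(onFlagsPhase(ph),
                                            onFlagsAmplitude(sp)))
        expect_equal(a, 1.0,
                     info = sprintf("eI=%g beta=%g RC=%g", eI, beta, RC))
      }
    }
  }
})

test_that("population phase of the synchronised period-3 run repeats the fundamental cycle", {
  sp <- simulatedSeries(RC = 2, beta = 6, eI = 0, N = 15, seed = 2)
  Theta <- populationPhase(hilbertPhase(sp))
  fund <- sort(round(c(0, 2 * pi / 3, -2 * pi / 3), 4))
  expect_equal(sort(unique(round(Theta, 4))), fund, tolerance = 1e-3)
  # all trees share one phase, so the median is that common phase
  th <- phaseMatrix(hilbertPhase(sp))
  expect_equal(apply(th, 2, function(v) diff(range(v))), rep(0, 15),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("order parameter measures coherence of a phase sample", {
  expect_equal(orderParameter(rep(1.2, 50))$r, 1)
  expect_equal(orderParameter(c(0, 2 * pi / 3, -2 * pi / 3))$r, 0,
               tolerance = 1e-12)
  expect_equal(orderParameter(c(0, pi / 2))$r, sqrt(2) / 2, tolerance = 1e-12)
  # invariant under global rotation
  set.seed(8)
  th <- runif(40, -pi, pi)
  expect_equal(orderParameter(th)$r, orderParameter(th + 0.9)$r,
               tolerance = 1e-12)
  expect_error(orderParameter(numeric(0)), "empty")
})
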