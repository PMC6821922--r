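test_that("uncoupled step follows the two-branch resource budget", {
  p <- modelParams(RC = 1)
  # below threshold: pure accumulation, no flowering
  expect_equal(stepUncoupled(50, p), list(S = 60, Cf = 0))
  # above threshold: excess spent, reserve reset to LT - RC * Cf
  expect_equal(stepUncoupled(95, p), list(S = 95, Cf = 5))
  # analytic fixed point S* = LT - RC * P0 / (1 + RC)
  p2 <- modelParams(RC = 0.5)
  Sstar <- 100 - 0.5 * 10 / 1.5
  expect_equal(Sstar, 96.6666667, tolerance = 1e-7)
  expect_equal(stepUncoupled(Sstar, p2)$S, Sstar, tolerance = 1e-12)
})

test_that("coupled step reduces to the synchronised 1-D map and kills lone flowering", {
  p <- modelParams(N = 5, RC = 1.6171, beta = 6)
  # identical trees, noise off: equals the reduced map applied to the common S
  S <- rep(99.9438, 5)
  st <- stepCoupled(S, p)
  expect_equal(st$S, rep(reducedMap(99.9438, 1.6171, 6), 5), tolerance = 1e-12)
  # full-precision closed form LT - RC * Cf^(beta+1) / P0^beta
  expect_equal(st$S[1], 100 - 1.6171 * 9.9438^7 / 10^6, tolerance = 1e-12)
  expect_equal(st$S[1], 84.452, tolerance = 1e-2)
  # a tree flowering alone gets no outcross pollen: Y = Ca = Cs = 0
  st2 <- stepCoupled(c(95, 50, 50, 50, 50), p)
  expect_gt(st2$Cf[1], 0)
  expect_equal(st2$Y[1], 0)
  expect_equal(st2$Ca[1], 0)
  expect_equal(st2$Cs[1], 0)
  # coupling undefined for a single tree
  expect_error(stepCoupled(95, p), "N < 2")
  expect_error(modelParams(N = 1, beta = 6), "N >= 2")
})

test_that("coupled step matches a straight-line scalar oracle over random states", {
  set.seed(99)
  for (k in 1:50) {
    N <- sample(2:10, 1)
    p <- modelParams(N = N, RC = runif(1, 0, 4), beta = sample(0:8, 1),
                     eI = runif(1, 0, 0.3), eC = runif(1, 0, 0.3))
    for (rep in 1:20) {
      S <- runif(N, -20, 130)
      sigma <- rnorm(1); delta <- rnorm(N)
      got <- stepCoupled(S, p, sigma, delta)
      want <- oracleStepCoupled(S, p@P0, p@LT, p@RC, p@beta, p@eI, p@eC,
                                sigma, delta)
      for (nm in names(want))
        expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12)
    }
  }
})

test_that("resource accounting is exact whenever the threshold is crossed", {
  set.seed(7)
  p <- modelParams(N = 8, RC = 2, beta = 6, eI = 0.2)
  S <- runif(8, 0, 100)
  for (t in 1:50) {
    sigma <- rnorm(1); delta <- rnorm(8)
    PS <- p@P0 * (1 + p@eC * sigma) * (1 + p@eI * delta)
    st <- stepCoupled(S, p, sigma, delta)
    crossed <- S + PS > p@LT
    expect_identical(st$S[crossed],
                     (S + PS - st$Cf - st$Ca)[crossed])
    expect_identical(st$S[!crossed], (S + PS)[!crossed])
    S <- st$S
  }
})

test_that("simulation is seed-reproducible and honours the documented noise order", {
  p <- modelParams(RC = 2, beta = 6, eI = 0.2, N = 12, seed = 31,
                   Ttransient = 50, Trecord = 10)
  t1 <- simulateGCM(p)
  t2 <- simulateGCM(p)
  expect_identical(t1@Cs, t2@Cs)
  expect_identical(t1@S, t2@S)

  # replay: uniform initial reserves, then per year one common draw followed
  # by the individual draws in tree order, stepped through stepCoupled
  set.seed(p@seed)
  S <- runif(p@N, 0, p@LT)
  Ttot <- p@Ttransient + p@Trecord
  draws <- matrix(rnorm(Ttot * (p@N + 1)), nrow = Ttot, byrow = TRUE)
  for (t in seq_len(Ttot)) {
    st <- stepCoupled(S, p, draws[t, 1], draws[t, -1])
    S <- st$S
  }
  expect_equal(unname(t1@S[, p@Trecord]), S, tolerance = 1e-12)
})

test_that("beta = 0 simulation equals independent uncoupled trees under matched noise", {
  p <- modelParams(RC = 2.5, beta = 0, eI = 0.15, N = 6, seed = 11,
                   Ttransient = 20, Trecord = 12)
  traj <- simulateGCM(p)
  set.seed(p@seed)
  S <- runif(p@N, 0, p@LT)
  Ttot <- p@Ttransient + p@Trecord
  draws <- matrix(rnorm(Ttot * (p@N + 1)), nrow = Ttot, byrow = TRUE)
  Cf <- matrix(0, p@N, p@Trecord)
  for (t in seq_len(Ttot)) {
    for (i in seq_len(p@N)) {   # each tree alone: Y = 1 when beta = 0
      PS <- p@P0 * (1 + p@eI * draws[t, 1 + i])
      ex <- max(0, S[i] + PS - p@LT)
      S[i] <- S[i] + PS - ex - p@RC * ex
      if (t > p@Ttransient) Cf[i, t - p@Ttransient] <- ex
    }
  }
  expect_equal(unname(traj@Cf), Cf, tolerance = 1e-12)
  expect_equal(unname(traj@Cs), Cf, tolerance = 1e-12)  # Y = 1 throughout
})

test_that("common noise alone preserves exact synchrony", {
  p <- modelParams(RC = 2, beta = 6, eI = 0, eC = 0.2, N = 10, seed = 3,
                   Ttransient = 0, Trecord = 200)
  traj <- simulateGCM(p, S0 = 55)   # identical initial reserves
  spread <- apply(traj@S, 2, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("noise-free simulation in the period-3 window synchronises onto the reduced orbit", {
  p <- modelParams(RC = 2, beta = 6, N = 25, seed = 17)
  traj <- simulateGCM(p)
  spread <- apply(traj@S, 2, function(v) diff(range(v)))
  expect_true(all(spread == 0))                       # full synchrony
  att <- detectPeriod(traj@S[1, ], tol = 1e-8)
  expect_identical(orbitPeriod(att), 3L)              # period-3 orbit
  # trajectory equals the reduced-map orbit continued from the same state
  expect_equal(traj@S[1, 2], reducedMap(traj@S[1, 1], 2, 6), tolerance = 1e-10)
})
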