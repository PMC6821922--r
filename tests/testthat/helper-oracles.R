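# Independent reference implementations used as oracles. All are literal,
# scalar, unoptimised transcriptions of the defining formulas, kept free of
# any code shared with the package internals.

# One year of the coupled model, scalar loops only.
oracleStepCoupled <- function(S, P0, LT, RC, beta, eI, eC, sigma, delta) {
  N <- length(S)
  PS <- numeric(N); Cf <- numeric(N)
  for (i in 1:N) {
    PS[i] <- P0 * (1 + eC * sigma) * (1 + eI * delta[i])
    excess <- S[i] + PS[i] - LT
    Cf[i] <- if (excess > 0) excess else 0
  }
  Y <- numeric(N); Ca <- numeric(N); Cs <- numeric(N); Snew <- numeric(N)
  for (i in 1:N) {
    acc <- 0
    for (j in 1:N) if (j != i) acc <- acc + Cf[j]
    Y[i] <- if (beta == 0) 1 else (acc / ((N - 1) * P0))^beta
    Ca[i] <- RC * Cf[i] * Y[i]
    Cs[i] <- Cf[i] * Y[i]
    if (S[i] + PS[i] <= LT) {
      Snew[i] <- S[i] + PS[i]
    } else {
      Snew[i] <- S[i] + PS[i] - Cf[i] - Ca[i]
    }
  }
  list(S = Snew, Cf = Cf, Ca = Ca, Cs = Cs, Y = Y)
}

# Literal O(N^2 T) double sum over ordered pairs for the in-phase fraction.
oracleInPhase <- function(x) {
  N <- nrow(x); T <- ncol(x)
  fInT <- numeric(T - 1)
  for (t in 1:(T - 1)) {
    fi <- numeric(N)
    for (i in 1:N) {
      s <- 0
      for (j in 1:N) {
        if (j == i) next
        di <- x[i, t + 1] - x[i, t]
        dj <- x[j, t + 1] - x[j, t]
        phi <- di * dj
        h <- if (phi > 0) 1 else if (di == 0 && dj == 0) 1 else 0
        s <- s + h
      }
      fi[i] <- s / (N - 1)
    }
    fInT[t] <- mean(fi)
  }
  list(fInT = fInT, FIN = mean(fInT))
}

# Analytic signal by explicit O(T^2) DFT sums (no fft).
oracleAnalytic <- function(x) {
  n <- length(x)
  X <- vapply(0:(n - 1), function(k)
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)), complex(1))
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Xh <- X * h
  vapply(0:(n - 1), function(t)
    sum(Xh * exp(2i * pi * (0:(n - 1)) * t / n)) / n, complex(1))
}

# Shared fixture: a standard simulated production ensemble.
simulatedSeries <- function(RC = 2, beta = 6, eI = 0.2, N = 30, seed = 1,
                            Trecord = 15, Ttransient = 1000) {
  seedProduction(simulateGCM(modelParams(
    RC = RC, beta = beta, eI = eI, N = N, seed = seed,
    Trecord = Trecord, Ttransient = Ttransient)))
}
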