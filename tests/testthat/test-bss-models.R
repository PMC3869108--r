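test_that("instantaneous reconstruction is the matrix product with shape checks", {
  expect_equal(reconstruct_instantaneous(matrix(1), matrix(c(2, 3), 1)),
               matrix(c(2, 3), 1))
  W0 <- matrix(0, 3, 2); S <- matrix(rnorm(2 * 5), 2, 5)
  expect_equal(reconstruct_instantaneous(W0, S), matrix(0, 3, 5))
  expect_equal(reconstruct_instantaneous(matrix(c(1, 1), 1),
                                         rbind(c(1, 0), c(0, 1))),
               matrix(c(1, 1), 1))
  expect_error(reconstruct_instantaneous(matrix(1, 2, 3), matrix(1, 2, 4)),
               "dimensions")
})

test_that("band-limited shift: identity, exact circular shifts, analytic sinusoid", {
  s <- rnorm(32)
  expect_identical(shift_source(s, 0), s)
  for (k in c(1, 7, 31)) {
    shifted <- shift_source(s, k)
    expect_equal(shifted, s[((seq_along(s) - 1 - k) %% 32) + 1],
                 tolerance = 1e-12)
  }
  t <- 0:99
  s <- sin(2 * pi * 3 * t / 100)
  expect_equal(shift_source(s, 0.5), sin(2 * pi * 3 * (t - 0.5) / 100),
               tolerance = 1e-6)
  expect_error(shift_source(s, -1), "tau")
  expect_error(shift_source(s, 100), "tau")
})

test_that("delayed reconstruction reduces to the instantaneous case and matches an oversampled oracle", {
  set.seed(7)
  J <- 3; I <- 2; T <- 50
  W <- matrix(rnorm(J * I), J, I)
  S <- matrix(rnorm(I * T), I, T)
  expect_equal(reconstruct_delayed(W, S, matrix(0, J, I)), W %*% S)
  # single source, integer delay = circular shift
  s1 <- matrix(rnorm(T), 1)
  out <- reconstruct_delayed(matrix(1), s1, matrix(3))
  expect_equal(as.numeric(out), s1[1, ((0:(T - 1) - 3) %% T) + 1],
               tolerance = 1e-12)
  # fractional delays vs a 100x oversampled interpolation oracle
  ov <- 100
  # fractional delays on the oracle's fine grid (multiples of 1/ov samples)
  tau <- matrix(sample(0:(10 * ov - 1), J * I) / ov, J, I)
  Xd <- reconstruct_delayed(W, S, tau)
  # oversample each source on a fine grid by zero-padding its spectrum
  oversample <- function(s) {
    Tf <- length(s); n <- Tf * ov
    sf <- fft(s)
    half <- floor(Tf / 2)
    big <- complex(n)
    big[1:(half + 1)] <- sf[1:(half + 1)]
    big[(n - half + 1):n] <- sf[(Tf - half + 1):Tf]
    if (Tf %% 2 == 0) { # split the Nyquist bin symmetrically
      big[half + 1] <- sf[half + 1] / 2
      big[n - half + 1] <- sf[half + 1] / 2
    }
    Re(fft(big, inverse = TRUE)) / Tf
  }
  fine <- lapply(seq_len(I), function(i) oversample(S[i, ]))
  oracle <- matrix(0, J, T)
  for (j in seq_len(J)) for (i in seq_len(I)) {
    idx <- ((round((0:(T - 1) - tau[j, i]) * ov) %% (T * ov)) + 1)
    oracle[j, ] <- oracle[j, ] + W[j, i] * fine[[i]][idx]
  }
  expect_lt(max(abs(Xd - oracle)), 1e-5)
})

test_that("gaussian log-likelihood matches the elementwise normal density", {
  expect_equal(log_likelihood(matrix(1), matrix(1), 1), -0.5 * log(2 * pi))
  # residual norm^2 = 2, J*T = 2
  expect_equal(log_likelihood(matrix(c(1, 1), 1), matrix(c(0, 0), 1), 1),
               -1 - log(2 * pi))
  set.seed(3)
  X <- matrix(rnorm(12), 3); Xh <- matrix(rnorm(12), 3)
  expect_equal(log_likelihood(X, Xh, 0.7),
               sum(dnorm(X, Xh, 0.7, log = TRUE)))
  expect_error(log_likelihood(X, Xh, 0), "sigma_n")
  expect_error(log_likelihood(X, Xh[, 1:3], 1), "shapes")
})

test_that("ICA log-normalizer: Gaussian limit, translation invariance, Monte Carlo check", {
  expect_equal(ica_log_normalizer(0, 2, 0), 0.5 * log(2 * pi * 4))
  expect_equal(ica_log_normalizer(-3, 1.3, 0.8), ica_log_normalizer(5, 1.3, 0.8))
  # importance estimate: Z = E_{N(0,sigma^2)}[cosh(u)^lam] * sqrt(2 pi sigma^2)
  set.seed(11)
  u <- rnorm(1e6)
  w <- exp(0.5 * (abs(u) + log1p(exp(-2 * abs(u))) - log(2)))
  mc <- mean(w); se <- sd(w) / sqrt(length(w))
  est <- log(mc) + 0.5 * log(2 * pi)
  expect_lt(abs(ica_log_normalizer(0, 1, 0.5) - est), 3 * se / mc)
})

test_that("log-prior: normalization at the mode, delay term, ICA density integrates to 1", {
  J <- 3; I <- 2; T <- 10
  phi <- hyper_params(sigma_n = 1, sigma_w = 2, mu = 0.5, sigma = 1.5)
  theta0 <- parameter_set(matrix(0, J, I), matrix(phi$mu, I, T))
  lp <- log_prior(theta0, phi, model_spec("PPCA", I))
  expect_equal(lp, -(I * T / 2) * log(2 * pi * phi$sigma^2) -
                 (J * I / 2) * log(2 * pi * phi$sigma_w^2))
  # AMM with tau = 0 adds J*I*log(1/gamma) relative to the same SIM prior
  kern <- kernel_matrix(T, 100, 5, amplitude = phi$sigma^2)
  set.seed(2)
  theta1 <- parameter_set(matrix(rnorm(J * I), J, I), matrix(rnorm(I * T), I, T))
  lp_sim <- log_prior(theta1, phi, model_spec("SIM", I, 5), kern)
  lp_amm <- log_prior(theta1, phi, model_spec("AMM", I, 5), kern)
  expect_equal(lp_amm - lp_sim, J * I * log(1 / phi$gamma))
  # ICA source prior integrates to 1 per coordinate
  phi_ica <- hyper_params(sigma = 1.2, lam = 0.6)
  lz <- ica_log_normalizer(0, phi_ica$sigma, phi_ica$lam)
  dens <- function(s) exp(-s^2 / (2 * phi_ica$sigma^2) +
                            phi_ica$lam * log(cosh(s)) - lz)
  expect_equal(integrate(dens, -20, 20, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-7)
  # errors: bundle mismatches
  expect_error(log_prior(theta1, phi, model_spec("SIM", I, 5)), "kernel")
  expect_error(log_prior(theta1, phi, model_spec("PPCA", I), kern), "bundle")
})

test_that("ICA prior with lam = 0 equals the PPCA prior; delays restricted to AMM", {
  set.seed(4)
  theta <- parameter_set(matrix(rnorm(6), 3, 2), matrix(rnorm(20), 2, 10))
  phi <- hyper_params(mu = 0.3, sigma = 0.8, lam = 0)
  expect_equal(log_prior(theta, phi, model_spec("ICA", 2)),
               log_prior(theta, phi, model_spec("PPCA", 2)))
  theta_tau <- parameter_set(theta$W, theta$S, matrix(1, 3, 2))
  expect_error(log_prior(theta_tau, phi, model_spec("PPCA", 2)), "AMM")
})

test_that("log-likelihood is maximized over sigma_n at the rms residual", {
  set.seed(9)
  X <- matrix(rnorm(40), 4); Xh <- matrix(rnorm(40), 4)
  s_hat <- sqrt(mean((X - Xh)^2))
  ll_hat <- log_likelihood(X, Xh, s_hat)
  for (f in c(0.5, 0.9, 1.1, 2))
    expect_lt(log_likelihood(X, Xh, f * s_hat), ll_hat)
})
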