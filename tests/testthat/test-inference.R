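test_that("SVD initialization reconstructs exact low-rank data and is deterministic", {
  d <- make_rank_data(J = 6, T = 40, I = 2, seed = 2)
  init <- initialize_parameters(d$X, model_spec("PPCA", 2), seed = 1)
  # the initializer works on row-centered data (the models assume it)
  Xc <- d$X$values - rowMeans(d$X$values)
  rel <- sum((Xc - init$W %*% init$S)^2) / sum(Xc^2)
  expect_lt(rel, 1e-8)
  init2 <- initialize_parameters(d$X, model_spec("PPCA", 2), seed = 1)
  expect_identical(init, init2)
  expect_error(initialize_parameters(d$X, model_spec("PPCA", 7)), "n_sources")
})

test_that("delay-scan initialization recovers a known shift between signals", {
  set.seed(8)
  s <- generate_sources(1, cutoff_hz = 8, seed = 3)[1, ]
  X <- signal_matrix(rbind(s, shift_source(s, 7)), fs = 100)
  init <- initialize_parameters(X, model_spec("AMM", 1, 5), seed = 1)
  # brute-force oracle: best integer lag between the two signals
  cc <- sapply(0:99, function(l) sum(X$values[2, ] * shift_source(s, l)))
  expect_equal(which.max(cc) - 1, 7)
  expect_equal((init$tau[2, 1] - init$tau[1, 1]) %% 100, 7)
})

test_that("negative log joint is the sum of its two terms and rejects bad input", {
  d <- make_rank_data(J = 4, T = 20, I = 2, noise_sd = 0.2, seed = 5)
  spec <- model_spec("SIM", 2, f0 = 10)
  theta <- initialize_parameters(d$X, spec, seed = 1)
  phi <- hyper_params(sigma_n = 0.2, sigma_w = 1, mu = 0, sigma = 1)
  kern <- kernel_matrix(20, 100, 10, amplitude = 1)
  expect_equal(negative_log_joint(d$X, theta, phi, spec, kern),
               -log_likelihood(d$X$values, theta$W %*% theta$S, 0.2) -
                 log_prior(theta, phi, spec, kern))
  expect_error(parameter_set(matrix(NaN, 4, 2), theta$S), "finite")
})

test_that("the objective decreases from a perturbed point back toward a noiseless optimum", {
  set.seed(10)
  J <- 5; I <- 1; T <- 30
  W <- matrix(rnorm(J), J, 1); S <- matrix(rnorm(T), 1, T)
  X <- signal_matrix(W %*% S, fs = 100)
  spec <- model_spec("PPCA", 1)
  phi <- hyper_params(sigma_n = 1e-3, sigma_w = 10, mu = 0, sigma = 10)
  at_opt <- negative_log_joint(X, parameter_set(W, S), phi, spec)
  perturbed <- parameter_set(W + 0.1, S + 0.1)
  expect_gt(negative_log_joint(X, perturbed, phi, spec), at_opt)
})

test_that("MAP optimization is monotone, respects a converged start, and hits the ridge solution", {
  d <- make_rank_data(J = 5, T = 25, I = 2, noise_sd = 0.3, seed = 6)
  spec <- model_spec("PPCA", 2)
  phi <- hyper_params(sigma_n = 0.3, sigma_w = 1.2, mu = 0, sigma = 1)
  init <- initialize_parameters(d$X, spec, seed = 1)
  res <- map_optimize(d$X, init, phi, spec)
  expect_true(all(diff(res$trace) <= 0))
  # restarting from the optimum stays there
  res2 <- map_optimize(d$X, res$theta, phi, spec)
  expect_lt(abs(res2$value - res$value), 1e-6 * abs(res$value) + 1e-6)
  # W-only sub-problem has the closed-form ridge solution
  S_fix <- d$S
  theta0 <- parameter_set(matrix(0, 5, 2), S_fix)
  resW <- map_optimize(d$X, theta0, phi, spec,
                       opts = fit_options(lbfgs_factr = 1e4), free = "W")
  A <- S_fix %*% t(S_fix) / phi$sigma_n^2 + diag(1 / phi$sigma_w^2, 2)
  W_ridge <- t(solve(A, S_fix %*% t(d$X$values) / phi$sigma_n^2))
  expect_lt(max(abs(resW$theta$W - W_ridge)), 1e-6)
})

test_that("hyperparameter updates match their closed forms", {
  d <- make_rank_data(J = 4, T = 20, I = 2, seed = 7)
  spec <- model_spec("PPCA", 2)
  Xc <- signal_matrix(d$X$values - rowMeans(d$X$values), 100)
  theta <- initialize_parameters(Xc, spec, seed = 1)
  phi <- update_hyperparameters(Xc, theta, spec)
  expect_equal(phi$sigma_n, 1e-4)  # exact rank-2 data: floored residual
  theta_pm1 <- parameter_set(matrix(c(1, -1, 1, -1), 2, 2),
                             matrix(rnorm(8), 2, 4))
  phi2 <- update_hyperparameters(signal_matrix(matrix(0, 2, 4), 100),
                                 theta_pm1, model_spec("PPCA", 2))
  expect_equal(phi2$sigma_w, 1)
  expect_equal(phi2$mu, mean(theta_pm1$S))
  # exponential delay mean recovery at J*I = 1e4
  set.seed(20)
  J <- 100; I <- 100; T <- 1000
  tau <- matrix(rexp(J * I, 1 / 20), J, I)
  tau[tau >= T] <- T - 1
  th <- structure(list(W = matrix(0, J, I), S = matrix(0, I, T), tau = tau),
                  class = "parameter_set")
  Xz <- signal_matrix(matrix(0, J, T), 100)
  phi3 <- update_hyperparameters(Xz, th, model_spec("AMM", I, 5))
  expect_lt(abs(phi3$gamma - 20), 3 * 20 / sqrt(J * I))
})

test_that("full fits recover noiseless ground truth and are reproducible", {
  ds <- generate_dataset("SIM", cutoff_hz = 5, I_true = 2, noise_level = 0,
                         J = 8, seed = 31)
  fit <- fit_model(ds$X_noisy, model_spec("SIM", 2, f0 = 5),
                   fit_options(seed = 1))
  expect_gt(r_squared(ds$X_noiseless$values, reconstruct_fit(fit)), 0.999)
  fit2 <- fit_model(ds$X_noisy, model_spec("SIM", 2, f0 = 5),
                    fit_options(seed = 1))
  expect_identical(fit$theta, fit2$theta)
  expect_identical(fit$neg_log_joint, fit2$neg_log_joint)
})

test_that("an ICA fit with lam frozen at 0 matches the PPCA fit objective", {
  d <- make_rank_data(J = 5, T = 30, I = 2, noise_sd = 0.2, seed = 12)
  phi <- hyper_params(sigma_n = 0.25, sigma_w = 1, mu = 0, sigma = 1, lam = 0)
  init <- initialize_parameters(d$X, model_spec("PPCA", 2), seed = 1)
  res_p <- map_optimize(d$X, init, phi, model_spec("PPCA", 2))
  res_i <- map_optimize(d$X, init, phi, model_spec("ICA", 2))
  expect_lt(abs(res_p$value - res_i$value), 1e-6 * abs(res_p$value))
})

test_that("AMM fits recover pairwise delay differences on delayed ground truth", {
  set.seed(14)
  S <- generate_sources(1, cutoff_hz = 5, seed = 15)
  tau_true <- matrix(c(0, 4, 9, 13, 6), 5, 1)
  W <- matrix(runif(5, 2, 6), 5, 1)
  X <- signal_matrix(reconstruct_delayed(W, S, tau_true), fs = 100)
  fit <- fit_model(X, model_spec("AMM", 1, f0 = 5), fit_options(seed = 1))
  dd_true <- outer(tau_true[, 1], tau_true[, 1], "-")
  dd_est <- outer(fit$theta$tau[, 1], fit$theta$tau[, 1], "-")
  # delays are identified modulo the (periodic) grid length
  circ <- (dd_est - dd_true) %% 100
  expect_lt(max(pmin(circ, 100 - circ)), 1)
})
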