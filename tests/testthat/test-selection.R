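test_that("BIC and AIC formulas and their crossing point", {
  expect_equal(bic_score(-100, 10, 100), 200 + 10 * log(100))
  expect_equal(bic_score(-50, 0, 1000), 100)
  expect_equal(aic_score(-100, 10), 220)
  expect_equal(aic_score(-50, 0), 100)
  # AIC - BIC = dim * (2 - log N): AIC is the harsher penalty iff N < e^2
  for (N in c(2, 7)) expect_gt(aic_score(-10, 3), bic_score(-10, 3, N))
  for (N in c(8, 100)) expect_lt(aic_score(-10, 3), bic_score(-10, 3, N))
})

test_that("LAP score components: unit case and degenerate-direction clipping", {
  out <- lap_score(0, 0, matrix(2 * pi))
  expect_equal(out$total, 0)
  expect_equal(out$log_posterior_volume, 0)
  # one flat direction is clipped, not fatal
  H <- diag(c(4, 0))
  expect_silent(lap_score(-1, -1, H))
  expect_error(lap_score(0, 0, diag(c(-1, -2))), "positive")
})

test_that("analytic Hessian blocks match a finite-difference oracle", {
  set.seed(21)
  J <- 3; I <- 2; T <- 12
  X <- signal_matrix(matrix(rnorm(J * T), J, T), fs = 100)
  for (fam in c("PPCA", "ICA", "SIM")) {
    spec <- model_spec(fam, I, f0 = if (fam == "SIM") 20 else Inf)
    phi <- hyper_params(sigma_n = 0.6, sigma_w = 1.4, mu = 0.2, sigma = 1.1,
                        lam = if (fam == "ICA") 0.4 else 0)
    theta <- parameter_set(matrix(rnorm(J * I), J, I),
                           matrix(rnorm(I * T), I, T))
    kern <- if (fam == "SIM") kernel_matrix(T, 100, 20, phi$sigma^2) else NULL
    H <- neg_log_joint_hessian(X, theta, phi, spec, kern)
    v0 <- primsel:::.flatten_theta(theta, spec)
    h <- 1e-5
    grad_at <- function(v) {
      th <- primsel:::.unflatten_theta(v, spec, J, T)
      primsel:::.nlj_grad_full(th, X, phi, spec, kern)
    }
    Hfd <- sapply(seq_along(v0), function(p) {
      vp <- v0; vm <- v0; vp[p] <- vp[p] + h; vm[p] <- vm[p] - h
      (grad_at(vp) - grad_at(vm)) / (2 * h)
    })
    Hfd <- (Hfd + t(Hfd)) / 2
    expect_lt(max(abs(H - Hfd)) / max(abs(Hfd)), 1e-4)
  }
})

test_that("the Hessian at a fitted optimum has no substantially negative eigenvalue", {
  d <- make_rank_data(J = 5, T = 25, I = 2, noise_sd = 0.3, seed = 22)
  fit <- fit_model(d$X, model_spec("PPCA", 2), fit_options(seed = 1))
  Xc <- signal_matrix(d$X$values - rowMeans(d$X$values), 100)
  H <- neg_log_joint_hessian(Xc, fit$theta, fit$phi, fit$spec)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  F_dim <- nrow(H)
  expect_gt(min(ev), -1e-6 * sum(diag(H)) / F_dim)
})

test_that("LAP approaches BIC as the number of data points grows", {
  # fixed-dimension sub-model (known sources, W free) on growing T
  set.seed(23)
  J <- 4; I <- 2
  gap_per_n <- sapply(c(25, 250, 2500), function(T) {
    S <- matrix(rnorm(I * T), I, T)
    W <- matrix(rnorm(J * I), J, I)
    sn <- 0.5; sw <- 1.5
    X <- signal_matrix(W %*% S + matrix(rnorm(J * T, sd = sn), J, T), 100)
    phi <- hyper_params(sigma_n = sn, sigma_w = sw)
    A <- S %*% t(S) / sn^2 + diag(1 / sw^2, I)
    Wmap <- t(solve(A, S %*% t(X$values) / sn^2))
    theta <- parameter_set(Wmap, S)
    ll <- log_likelihood(X$values, Wmap %*% S, sn)
    lp <- -sum(Wmap^2) / (2 * sw^2) - (J * I / 2) * log(2 * pi * sw^2)
    H <- neg_log_joint_hessian(X, theta, phi, model_spec("PPCA", I),
                               free = "W")
    lap <- lap_score(ll, lp, H)$total
    bic <- bic_score(ll, J * I, J * T)
    abs(-2 * lap - bic) / (J * T)
  })
  expect_true(all(diff(gap_per_n) < 0))
  expect_lt(gap_per_n[3], 0.05)
})

test_that("grid selection enumerates candidates, collapses pPCA, and records failures", {
  d <- make_rank_data(J = 4, T = 25, I = 1, noise_sd = 0.3, seed = 24)
  sel <- select_model(d$X, families = c("PPCA", "SIM"), I_range = 1:2,
                      f0_grid = c(8, 15, Inf), opts = fit_options(seed = 1))
  # SIM at f0 = Inf *is* pPCA: 2 I x (2 finite f0 + one shared pPCA row)
  expect_equal(nrow(sel$candidates), 6)
  expect_equal(sum(sel$candidates$family == "PPCA"), 2)
  expect_s3_class(sel$winner_lap, "model_spec")
  # an infeasible candidate (I > min(J, T)) is recorded, never fatal
  sel2 <- select_model(d$X, families = "PPCA", I_range = c(1, 10),
                       f0_grid = Inf, opts = fit_options(seed = 1))
  expect_true(any(!is.na(sel2$candidates$error)))
  expect_equal(sel2$winner_lap$n_sources, 1)
  expect_error(select_model(d$X, families = "PPCA", I_range = integer(0)),
               "non-empty")
})

test_that("score ties break toward parsimony (smaller I, then smaller f0)", {
  df <- data.frame(family = c("SIM", "SIM", "PPCA"), I = c(2, 1, 1),
                   f0 = c(5, 10, Inf), lap = c(100, 100, 100 - 1),
                   stringsAsFactors = FALSE)
  idx <- primsel:::.pick_winner(df, "lap", maximize = TRUE)
  expect_equal(idx, 2L)  # same score: the I = 1 candidate wins
  df$lap <- c(100, 100 + 2e-6 * 100, 99)
  idx2 <- primsel:::.pick_winner(df, "lap", maximize = TRUE)
  expect_equal(idx2, 2L)  # outside tie tolerance: the higher score wins
})

test_that("SIM at f0 = Inf reproduces the PPCA evidence exactly (nesting identity)", {
  ds <- generate_dataset("SIM", cutoff_hz = 5, I_true = 2, noise_level = 0.15,
                         J = 6, seed = 25)
  Xc <- signal_matrix(ds$X_noisy$values - rowMeans(ds$X_noisy$values), 100)
  lap_of <- function(spec) {
    fit <- fit_model(ds$X_noisy, spec, fit_options(seed = 1))
    H <- neg_log_joint_hessian(Xc, fit$theta, fit$phi, spec)
    lap_score(fit$loglik, fit$logprior, H)$total
  }
  l_sim <- lap_of(model_spec("SIM", 2, Inf))
  l_ppca <- lap_of(model_spec("PPCA", 2))
  expect_equal(l_sim, l_ppca)
})
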