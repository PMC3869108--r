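# Shared fixture builders; everything is generated in code at test time.

# A tiny instantaneous dataset of known rank with optional iid noise.
make_rank_data <- function(J = 6, T = 40, I = 2, noise_sd = 0, seed = 1,
                           fs = 100) {
  set.seed(seed)
  W <- matrix(rnorm(J * I), J, I)
  S <- matrix(rnorm(I * T), I, T)
  X <- W %*% S + if (noise_sd > 0) matrix(rnorm(J * T, sd = noise_sd), J, T)
       else 0
  list(X = signal_matrix(X, fs), W = W, S = S)
}

# Hand-built experiment record with a given winner per criterion.
make_record <- function(gen_family, cutoff_hz, I_true, winners, J = 10,
                        noise_level = 0) {
  sel <- structure(list(candidates = data.frame()), class = "selection_result")
  for (crit in names(winners)) {
    w <- winners[[crit]]
    sel[[paste0("winner_", crit)]] <-
      model_spec(w$family, w$I, if (is.null(w$f0)) Inf else w$f0)
  }
  list(generator = list(family = gen_family, cutoff_hz = cutoff_hz,
                        I_true = I_true, J = J, noise_level = noise_level),
       selection = sel)
}

# Closed-form log marginal likelihood of the fixed-source linear-Gaussian
# sub-model: rows x_j ~ N(0, sigma_w^2 S'S + sigma_n^2 I).
gaussian_submodel_evidence <- function(X, S, sigma_n, sigma_w) {
  T <- ncol(X)
  Sig <- sigma_w^2 * t(S) %*% S + diag(sigma_n^2, T)
  ch <- chol(Sig)
  sum(apply(X, 1, function(x)
    -0.5 * sum(backsolve(ch, x, transpose = TRUE)^2) -
      sum(log(diag(ch))) - (T / 2) * log(2 * pi)))
}
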