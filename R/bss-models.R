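#' Model specification
#'
#' Identifies one candidate generative model: the family, the number of
#' sources I, and (for the smoothness-regularized families) the wave-kernel
#' cutoff frequency f0. PPCA and ICA are instantaneous mixtures with
#' i.i.d. source priors and carry `f0 = Inf`; SIM adds a wave-kernel
#' Gaussian-process prior over each source's time course; AMM additionally
#' allows one delay per (signal, source) pair.
#'
#' @param family one of `"PPCA"`, `"ICA"`, `"SIM"`, `"AMM"`.
#' @param n_sources integer number of sources I >= 1.
#' @param f0 cutoff frequency in Hz (finite only for SIM/AMM; `Inf` means
#'   no smoothness constraint).
#' @return A `model_spec` object.
#' @export
model_spec <- function(family = c("PPCA", "ICA", "SIM", "AMM"),
                       n_sources = 1L, f0 = Inf) {
  family <- match.arg(family)
  n_sources <- as.integer(n_sources)
  if (n_sources < 1L) stop("n_sources must be >= 1")
  if (family %in% c("PPCA", "ICA") && is.finite(f0))
    stop(family, " has no smoothness cutoff; use f0 = Inf")
  if (!(f0 > 0)) stop("f0 must be positive (Hz) or Inf")
  structure(list(family = family, n_sources = n_sources, f0 = as.numeric(f0)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  f0 <- if (is.finite(x$f0)) paste0(x$f0, " Hz") else "none (f0 = Inf)"
  cat(sprintf("<model_spec> %s, I = %d sources, smoothness cutoff: %s\n",
              x$family, x$n_sources, f0))
  invisible(x)
}

#' Model parameters Theta
#'
#' The per-model free parameters: mixing weights W (J x I), source values S
#' (I x T, sampled on the undelayed time grid) and, for AMM only, delays
#' tau (J x I, in samples, support [0, T)). Non-AMM families carry an
#' all-zero tau for uniformity.
#'
#' @param W numeric J x I weight matrix.
#' @param S numeric I x T source matrix.
#' @param tau numeric J x I delay matrix in samples, or `NULL` for zeros.
#' @return A `parameter_set` object.
#' @export
parameter_set <- function(W, S, tau = NULL) {
  W <- as.matrix(W); S <- as.matrix(S)
  J <- nrow(W); I <- ncol(W); T <- ncol(S)
  if (nrow(S) != I)
    stop("shape mismatch: W is ", J, "x", I, " but S has ", nrow(S), " rows")
  if (is.null(tau)) tau <- matrix(0, J, I) else tau <- as.matrix(tau)
  if (!all(dim(tau) == c(J, I)))
    stop("tau must be ", J, "x", I, ", got ", nrow(tau), "x", ncol(tau))
  if (any(!is.finite(W)) || any(!is.finite(S)) || any(!is.finite(tau)))
    stop("parameter values must be finite")
  if (any(tau < 0) || any(tau >= T)) stop("delays must lie in [0, T)")
  structure(list(W = unname(W), S = unname(S), tau = unname(tau)),
            class = "parameter_set")
}

#' Hyperparameters Phi
#'
#' The hyperparameters shared by all families: observation-noise sd
#' `sigma_n`, weight-prior sd `sigma_w`, source-prior mean `mu` and sd
#' `sigma` (for SIM/AMM, `sigma^2` doubles as the wave-kernel amplitude so
#' the GP prior nests the i.i.d. PPCA prior at f0 = Inf), the ICA natural
#' parameter `lam` tilting the Gaussian source prior toward
#' non-Gaussianity, and the AMM delay-prior mean `gamma` (samples).
#'
#' @param sigma_n noise sd (> 0).
#' @param sigma_w weight-prior sd (> 0).
#' @param mu source-prior mean.
#' @param sigma source-prior sd / kernel amplitude sd (> 0).
#' @param lam ICA contrast natural parameter (0 for PPCA).
#' @param gamma delay-prior mean in samples (> 0).
#' @return A `hyper_params` object.
#' @export
hyper_params <- function(sigma_n = 1, sigma_w = 1, mu = 0, sigma = 1,
                         lam = 0, gamma = 20) {
  for (nm in c("sigma_n", "sigma_w", "sigma", "gamma")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0) stop(nm, " must be positive and finite")
  }
  if (!is.finite(mu) || !is.finite(lam)) stop("mu and lam must be finite")
  structure(list(sigma_n = sigma_n, sigma_w = sigma_w, mu = mu,
                 sigma = sigma, lam = lam, gamma = gamma),
            class = "hyper_params")
}

#' Instantaneous linear reconstruction
#'
#' The noiseless generative map of the instantaneous mixture families:
#' predicted signals are the matrix product W S.
#'
#' @param W J x I weight matrix.
#' @param S I x T source matrix.
#' @return J x T matrix of predicted signals.
#' @examples
#' reconstruct_instantaneous(matrix(1), matrix(c(2, 3), 1))
#' @export
reconstruct_instantaneous <- function(W, S) {
  W <- as.matrix(W); S <- as.matrix(S)
  if (ncol(W) != nrow(S))
    stop("inner dimensions disagree: W is ", nrow(W), "x", ncol(W),
         ", S is ", nrow(S), "x", ncol(S))
  W %*% S
}

## Frequency index vector for length-T FFTs: 0, 1, ..., floor(T/2),
## then the negative frequencies.
.fft_freqs <- function(T) {
  half <- floor(T / 2)
  if (T %% 2 == 0) c(0:half, -( (half - 1):1 )) else c(0:half, -(half:1))
}

## Unvalidated periodic band-limited shift; tau may be any finite real
## (wrapped implicitly by the phase factor's periodicity in T).
.shift_fft <- function(s, tau) {
  T <- length(s)
  if (tau == 0) return(s)
  k <- .fft_freqs(T)
  ph <- exp(-2i * pi * k * tau / T)
  # real-output correction for the unpaired Nyquist bin of even T
  if (T %% 2 == 0) ph[T / 2 + 1] <- cos(pi * tau)
  Re(stats::fft(stats::fft(s) * ph, inverse = TRUE)) / T
}

## Derivative of .shift_fft with respect to tau (exact, spectral).
.shift_fft_dtau <- function(s, tau) {
  T <- length(s)
  k <- .fft_freqs(T)
  dph <- (-2i * pi * k / T) * exp(-2i * pi * k * tau / T)
  if (T %% 2 == 0) dph[T / 2 + 1] <- -pi * sin(pi * tau)
  Re(stats::fft(stats::fft(s) * dph, inverse = TRUE)) / T
}

#' Delay a source by a fractional number of samples
#'
#' Evaluates the periodic band-limited (Whittaker-Shannon) interpolant of
#' `s` at times t - tau on the sampling grid, i.e. a circular shift that is
#' exact for integer delays and smooth (differentiable in `tau`) for
#' fractional ones. Implemented as an FFT phase shift; the unpaired
#' Nyquist bin of even-length grids is handled so the output stays real.
#'
#' @param s numeric vector of length T (one source's sampled values).
#' @param tau delay in samples, in `[0, T)`.
#' @return The shifted length-T vector.
#' @examples
#' s <- sin(2 * pi * 3 * (0:99) / 100)
#' shift_source(s, 10)[11]  # equals s[1]
#' @export
shift_source <- function(s, tau) {
  T <- length(s)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau))
    stop("tau must be a finite scalar")
  if (tau < 0 || tau >= T) stop("tau must lie in [0, T); got ", tau)
  .shift_fft(as.numeric(s), tau)
}

#' Delayed (anechoic) reconstruction
#'
#' The noiseless generative map of the anechoic mixture model: signal j is
#' the weighted sum over sources i of source i delayed by tau[j, i]
#' samples. With all delays zero this reduces exactly to
#' [reconstruct_instantaneous()].
#'
#' @param W J x I weight matrix.
#' @param S I x T source matrix.
#' @param tau J x I delay matrix in samples, each in `[0, T)`.
#' @return J x T matrix of predicted signals.
#' @export
reconstruct_delayed <- function(W, S, tau) {
  W <- as.matrix(W); S <- as.matrix(S); tau <- as.matrix(tau)
  J <- nrow(W); I <- ncol(W); T <- ncol(S)
  if (nrow(S) != I)
    stop("inner dimensions disagree: W is ", J, "x", I,
         ", S is ", nrow(S), "x", T)
  if (!all(dim(tau) == c(J, I)))
    stop("tau must be ", J, "x", I, ", got ", nrow(tau), "x", ncol(tau))
  if (any(tau < 0) || any(tau >= T)) stop("delays must lie in [0, T)")
  if (all(tau == 0)) return(W %*% S)
  Sf <- t(apply(S, 1L, stats::fft))            # I x T complex, one fft per source
  if (I == 1L) Sf <- matrix(Sf, 1L)
  k <- .fft_freqs(T)
  X <- matrix(0, J, T)
  for (j in seq_len(J)) {
    acc <- complex(T)
    for (i in seq_len(I)) {
      ph <- exp(-2i * pi * k * tau[j, i] / T)
      if (T %% 2 == 0) ph[T / 2 + 1] <- cos(pi * tau[j, i])
      acc <- acc + W[j, i] * (Sf[i, ] * ph)
    }
    X[j, ] <- Re(stats::fft(acc, inverse = TRUE)) / T
  }
  X
}

#' Gaussian observation log-likelihood
#'
#' Log-density of the observed signals under i.i.d. Gaussian observation
#' noise with sd `sigma_n` around the model reconstruction:
#' `-||X - Xhat||_F^2 / (2 sigma_n^2) - (J T / 2) log(2 pi sigma_n^2)`.
#'
#' @param X a `signal_matrix` or a plain J x T matrix.
#' @param Xhat J x T matrix of reconstructed signals.
#' @param sigma_n noise sd (> 0).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(X, Xhat, sigma_n) {
  Xv <- if (inherits(X, "signal_matrix")) X$values else as.matrix(X)
  Xhat <- as.matrix(Xhat)
  if (!all(dim(Xv) == dim(Xhat)))
    stop("X and Xhat shapes differ: ", paste(dim(Xv), collapse = "x"),
         " vs ", paste(dim(Xhat), collapse = "x"))
  if (!is.finite(sigma_n) || sigma_n <= 0) stop("sigma_n must be > 0")
  n <- length(Xv)
  -sum((Xv - Xhat)^2) / (2 * sigma_n^2) - (n / 2) * log(2 * pi * sigma_n^2)
}

## Numerically stable log cosh.
.log_cosh <- function(u) abs(u) + log1p(exp(-2 * abs(u))) - log(2)

#' Log-normalizer of the ICA source prior
#'
#' The ICA source prior is a Gaussian tilted by a contrast function G with
#' natural parameter lambda:
#' `p(s) = exp(-(s - mu)^2 / (2 sigma^2) + lam G(s - mu)) / Z`.
#' We use the standard negentropy contrast `G(u) = log cosh(u)`. This
#' function returns `log Z(mu, sigma, lam)`, computed by adaptive
#' quadrature over +/- 12 sigma around the mode; by translation invariance
#' the result does not depend on `mu`.
#'
#' @param mu source-prior mean (unused beyond the interface; the
#'   normalizer is translation invariant).
#' @param sigma source-prior sd (> 0).
#' @param lam natural parameter (any finite real).
#' @return Scalar `log Z`.
#' @examples
#' ica_log_normalizer(0, 1, 0)  # log sqrt(2*pi)
#' @export
ica_log_normalizer <- function(mu, sigma, lam) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (!is.finite(lam)) stop("lam must be finite")
  if (lam == 0) return(0.5 * log(2 * pi * sigma^2))
  expo <- function(u) -u^2 / (2 * sigma^2) + lam * .log_cosh(u)
  # peel off the maximum exponent so the integrand is O(1)
  grid <- seq(-12 * sigma, 12 * sigma, length.out = 4001L)
  m <- max(expo(grid))
  if (!is.finite(m)) stop("non-finite ICA prior exponent")
  val <- stats::integrate(function(u) exp(expo(u) - m),
                          lower = -12 * sigma, upper = 12 * sigma,
                          rel.tol = 1e-10, abs.tol = 0,
                          subdivisions = 500L)
  if (!is.finite(val$value) || val$value <= 0)
    stop("ICA normalizer quadrature failed")
  m + log(val$value)
}

#' Log-prior of the model parameters
#'
#' Sum of the family's source log-prior, the i.i.d. zero-mean Gaussian
#' weight log-prior (sd `sigma_w`) and, for AMM, the exponential delay
#' log-prior with mean `gamma` (density `(1/gamma) exp(-tau/gamma)`).
#' Source priors by family: PPCA, i.i.d. `N(mu, sigma^2)`; ICA, the
#' contrast-tilted density of [ica_log_normalizer()]; SIM/AMM, a
#' Gaussian-process log-density per source row under the wave-kernel Gram
#' matrix supplied in `kernel`.
#'
#' @param theta a `parameter_set`.
#' @param phi a `hyper_params`.
#' @param spec a `model_spec`.
#' @param kernel a `kernel_bundle` from [kernel_matrix()]; required iff the
#'   family is SIM or AMM.
#' @return Scalar log-prior density.
#' @export
log_prior <- function(theta, phi, spec, kernel = NULL) {
  stopifnot(inherits(theta, "parameter_set"), inherits(phi, "hyper_params"),
            inherits(spec, "model_spec"))
  fam <- spec$family
  kind <- .src_prior_kind(spec)
  if (kind == "gp") {
    if (is.null(kernel)) stop(fam, " prior requires a kernel bundle")
  } else if (!is.null(kernel) && !(fam %in% c("SIM", "AMM"))) {
    stop(fam, " prior takes no kernel bundle")
  }
  S <- theta$S; W <- theta$W
  lp_S <- switch(kind,
    gauss = -sum((S - phi$mu)^2) / (2 * phi$sigma^2) -
      (length(S) / 2) * log(2 * pi * phi$sigma^2),
    ica = {
      u <- S - phi$mu
      sum(-u^2 / (2 * phi$sigma^2) + phi$lam * .log_cosh(u)) -
        length(S) * ica_log_normalizer(phi$mu, phi$sigma, phi$lam)
    },
    gp = {
      mu_vec <- rep(phi$mu, ncol(S))
      sum(apply(S, 1L, gp_log_density, mu_vec = mu_vec, bundle = kernel))
    })
  lp_W <- sum(stats::dnorm(W, 0, phi$sigma_w, log = TRUE))
  lp_tau <- 0
  if (fam == "AMM") {
    lp_tau <- sum(-log(phi$gamma) - theta$tau / phi$gamma)
  } else if (any(theta$tau != 0)) {
    stop("non-zero delays are only valid for the AMM family")
  }
  lp_S + lp_W + lp_tau
}
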