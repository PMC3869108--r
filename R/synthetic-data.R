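#' Band-limited source generation
#'
#' Draws each source as T i.i.d. standard normal samples low-pass filtered
#' with a 6th-order Butterworth filter applied forward and backward
#' (zero phase, so the effective rolloff is 12th order). At the default
#' T = 100 samples and fs = 100 Hz each source spans one second,
#' mimicking band-limited kinematic trajectories.
#'
#' @param I number of sources.
#' @param T number of time points.
#' @param fs sampling rate (Hz).
#' @param cutoff_hz Butterworth cutoff (Hz), must be below fs/2.
#' @param seed integer RNG seed.
#' @return I x T matrix of source values.
#' @export
generate_sources <- function(I, T = 100L, fs = 100, cutoff_hz, seed = 1L) {
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("cutoff_hz must lie in (0, fs/2)")
  bf <- signal::butter(6, cutoff_hz / (fs / 2), type = "low")
  set.seed(seed)
  S <- matrix(stats::rnorm(I * T), I, T)
  t(apply(S, 1L, function(s) signal::filtfilt(bf, s)))
}

## Delay draws: exponential with mean `mean_delay` samples, re-drawn in
## the rare event of a draw at or beyond T (support of the delay
## parameterization is [0, T)).
.draw_delays <- function(n, mean_delay, T) {
  d <- stats::rexp(n, rate = 1 / mean_delay)
  while (any(bad <- d >= T)) d[bad] <- stats::rexp(sum(bad), rate = 1 / mean_delay)
  d
}

#' Mix sources into noiseless ground-truth signals
#'
#' Mixing weights are drawn uniformly on `[-10, 10]`. For the SIM family
#' the noiseless data are the instantaneous mixture W S; for AMM each
#' (signal, source) pair additionally receives a delay drawn from an
#' exponential distribution with mean 20 samples (kept continuous, applied
#' by periodic band-limited interpolation). No observation noise is added
#' here.
#'
#' @param S I x T source matrix from [generate_sources()].
#' @param J number of signals/trials.
#' @param family `"SIM"` or `"AMM"`.
#' @param seed integer RNG seed.
#' @param mean_delay exponential delay mean in samples (AMM).
#' @return A list with `X_noiseless` (J x T matrix) and `true_params`
#'   (a `parameter_set`).
#' @export
generate_mixture <- function(S, J, family = c("SIM", "AMM"), seed = 1L,
                             mean_delay = 20) {
  family <- match.arg(family)
  S <- as.matrix(S)
  I <- nrow(S); T <- ncol(S)
  set.seed(seed)
  W <- matrix(stats::runif(J * I, -10, 10), J, I)
  if (family == "AMM") {
    tau <- matrix(.draw_delays(J * I, mean_delay, T), J, I)
    X <- reconstruct_delayed(W, S, tau)
  } else {
    tau <- matrix(0, J, I)
    X <- W %*% S
  }
  list(X_noiseless = X, true_params = parameter_set(W, S, tau))
}

#' Multivariate coefficient of determination
#'
#' Total-variation-based R^2 between a noiseless data set and its noisy
#' version: `1 - ||X_noiseless - X_noisy||_F^2 / ||X_noiseless -
#' Xbar||_F^2`, where `Xbar` repeats the across-trial mean time course in
#' every row (the trace-of-covariance reading of total variation). The
#' noise level used throughout the benchmark is `1 - R^2`.
#'
#' @param X_noiseless J x T noiseless matrix.
#' @param X_noisy J x T noisy matrix of the same shape.
#' @return Scalar R^2.
#' @export
r_squared <- function(X_noiseless, X_noisy) {
  X_noiseless <- as.matrix(X_noiseless); X_noisy <- as.matrix(X_noisy)
  if (!all(dim(X_noiseless) == dim(X_noisy)))
    stop("shapes differ: ", paste(dim(X_noiseless), collapse = "x"), " vs ",
         paste(dim(X_noisy), collapse = "x"))
  xbar <- colMeans(X_noiseless)
  denom <- sum(sweep(X_noiseless, 2L, xbar)^2)
  if (denom == 0) stop("zero total variation in the noiseless data")
  1 - sum((X_noiseless - X_noisy)^2) / denom
}

#' Add signal-dependent Gaussian noise
#'
#' Adds zero-mean Gaussian noise whose standard deviation scales with the
#' instantaneous signal magnitude: `sd = alpha * |x(t)|`. Entries where
#' the signal is exactly zero receive no noise.
#'
#' @param X J x T signal matrix.
#' @param alpha noise slope (>= 0).
#' @param seed integer RNG seed.
#' @return Noisy J x T matrix.
#' @export
add_signal_dependent_noise <- function(X, alpha, seed = 1L) {
  if (!is.finite(alpha) || alpha < 0) stop("alpha must be >= 0")
  X <- as.matrix(X)
  if (alpha == 0) return(X)
  set.seed(seed)
  X + stats::rnorm(length(X), mean = 0, sd = alpha * abs(X))
}

#' Calibrate the signal-dependent noise slope to a target noise level
#'
#' Starting from alpha = 0, the slope is increased by a fixed increment
#' (default 0.001). At each step one fresh noise realization is drawn and
#' `1 - R^2` computed; the slope is accepted once the mean level over the
#' last ten consecutive computations has reached the target while staying
#' within `tol` of it. Averaging ten consecutive computations (rather than
#' accepting the first single draw that touches the target) suppresses the
#' first-passage bias of the draw-to-draw scatter in `1 - R^2`, which is
#' comparable to `tol` at these data sizes. A target of 0 returns 0
#' immediately.
#'
#' @param X_noiseless J x T noiseless matrix.
#' @param target_level desired `1 - R^2` in `[0, 1)`.
#' @param seed integer RNG seed.
#' @param step slope increment per iteration.
#' @param tol acceptance tolerance on `1 - R^2`.
#' @param max_steps failure cap on the number of increments.
#' @return Calibrated slope alpha.
#' @export
calibrate_noise_slope <- function(X_noiseless, target_level, seed = 1L,
                                  step = 0.001, tol = 0.01,
                                  max_steps = 1e5L) {
  if (target_level < 0 || target_level >= 1)
    stop("target_level must lie in [0, 1)")
  if (target_level == 0) return(0)
  X_noiseless <- as.matrix(X_noiseless)
  set.seed(seed)
  level_once <- function(alpha) {
    Xn <- X_noiseless + stats::rnorm(length(X_noiseless),
                                     sd = alpha * abs(X_noiseless))
    1 - r_squared(X_noiseless, Xn)
  }
  alpha <- 0
  recent <- rep(NA_real_, 10L)
  for (k in seq_len(max_steps)) {
    alpha <- alpha + step
    recent[(k - 1L) %% 10L + 1L] <- level_once(alpha)
    if (k >= 10L) {
      lev10 <- mean(recent)
      if (lev10 >= target_level && lev10 <= target_level + tol) return(alpha)
    }
  }
  stop("noise calibration failed to stabilize within ", max_steps, " steps")
}

## Deterministic child-seed derivation: a small multiplicative mix that
## stays below 2^31 and within exact double arithmetic.
.child_seed <- function(master, ...) {
  ks <- c(master, ...)
  x <- 11
  for (k in ks) x <- (x * 7919 + (as.numeric(k) * 1e4) %% 104729 + 1) %% 2038074743
  as.integer(x + 1)
}

#' One synthetic ground-truth dataset
#'
#' Generates band-limited sources, mixes them (instantaneously or with
#' exponential delays), calibrates the signal-dependent noise slope to the
#' target noise level and draws the final noisy data.
#'
#' @param family `"SIM"` or `"AMM"`.
#' @param cutoff_hz Butterworth cutoff for source generation (Hz).
#' @param I_true generating number of sources.
#' @param noise_level target `1 - R^2` (0 for noiseless data).
#' @param J number of trials.
#' @param seed integer seed for this dataset.
#' @param T,fs grid length and sampling rate.
#' @return A `ground_truth_dataset`: `X_noisy`, `X_noiseless` (both
#'   `signal_matrix`), `true_params`, and a `generator` record (family,
#'   I_true, cutoff_hz, noise_level, J, alpha, achieved_noise_level,
#'   seed).
#' @export
generate_dataset <- function(family = c("SIM", "AMM"), cutoff_hz = 5,
                             I_true = 2L, noise_level = 0, J = 10L,
                             seed = 1L, T = 100L, fs = 100) {
  family <- match.arg(family)
  S <- generate_sources(I_true, T = T, fs = fs, cutoff_hz = cutoff_hz,
                        seed = .child_seed(seed, 1))
  mix <- generate_mixture(S, J, family, seed = .child_seed(seed, 2))
  alpha <- 0; achieved <- 0
  X_noisy <- mix$X_noiseless
  if (noise_level > 0) {
    alpha <- calibrate_noise_slope(mix$X_noiseless, noise_level,
                                   seed = .child_seed(seed, 3))
    X_noisy <- add_signal_dependent_noise(mix$X_noiseless, alpha,
                                          seed = .child_seed(seed, 4))
    achieved <- 1 - r_squared(mix$X_noiseless, X_noisy)
  }
  structure(list(
    X_noisy = signal_matrix(X_noisy, fs),
    X_noiseless = signal_matrix(mix$X_noiseless, fs),
    true_params = mix$true_params,
    generator = list(family = family, I_true = as.integer(I_true),
                     cutoff_hz = cutoff_hz, noise_level = noise_level,
                     J = as.integer(J), alpha = alpha,
                     achieved_noise_level = achieved, seed = as.integer(seed),
                     T = as.integer(T), fs = fs)),
    class = "ground_truth_dataset")
}

#' @export
print.ground_truth_dataset <- function(x, ...) {
  g <- x$generator
  cat(sprintf(paste0("<ground_truth_dataset> %s, I = %d, cutoff = %g Hz, ",
                     "noise 1-R^2 = %g (achieved %.3f), J = %d\n"),
              g$family, g$I_true, g$cutoff_hz, g$noise_level,
              g$achieved_noise_level, g$J))
  invisible(x)
}

#' Benchmark configuration
#'
#' The full factorial ground-truth design: 2 generator families (SIM/AMM)
#' x 2 source cutoffs (5/10 Hz) x 4 source counts (1-4) x 3 noise levels
#' (0/0.15/0.3) = 48 conditions, each instantiated at J in {5, 10, 25}
#' trials with 20 replicate datasets per (condition, J).
#'
#' @param families generator families.
#' @param cutoffs_hz source cutoffs (Hz).
#' @param I_true_range generating source counts.
#' @param noise_levels target `1 - R^2` values.
#' @param J_list trial counts.
#' @param replicates replicate datasets per (condition, J).
#' @param T,fs grid length and sampling rate.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(families = c("SIM", "AMM"),
                             cutoffs_hz = c(5, 10),
                             I_true_range = 1:4,
                             noise_levels = c(0, 0.15, 0.3),
                             J_list = c(5, 10, 25),
                             replicates = 20L, T = 100L, fs = 100) {
  structure(list(families = families, cutoffs_hz = cutoffs_hz,
                 I_true_range = as.integer(I_true_range),
                 noise_levels = noise_levels, J_list = as.integer(J_list),
                 replicates = as.integer(replicates), T = as.integer(T),
                 fs = fs),
            class = "benchmark_config")
}

#' Enumerate the benchmark conditions
#'
#' @param config a `benchmark_config`.
#' @return Data frame with one row per generator condition (family x
#'   cutoff x I_true x noise level) and a condition index.
#' @export
benchmark_conditions <- function(config = benchmark_config()) {
  df <- expand.grid(noise_level = config$noise_levels,
                    I_true = config$I_true_range,
                    cutoff_hz = config$cutoffs_hz,
                    family = config$families,
                    stringsAsFactors = FALSE)
  df <- df[, c("family", "cutoff_hz", "I_true", "noise_level")]
  df$condition <- seq_len(nrow(df))
  df
}

#' Generate the ground-truth benchmark
#'
#' Enumerates the full factorial design of [benchmark_conditions()] times
#' trial counts times replicates, deriving a deterministic child seed per
#' dataset from the master seed so any single dataset can be regenerated
#' in isolation. Optionally writes every dataset to `out_dir`
#' (noisy/noiseless CSVs, truth arrays, metadata JSON).
#'
#' @param config a `benchmark_config`.
#' @param master_seed integer master seed.
#' @param conditions optional subset of rows from
#'   [benchmark_conditions()] to generate (default: all).
#' @param J_list optional override of the trial counts.
#' @param replicates optional override of the replicate count.
#' @param out_dir optional output directory.
#' @return A list of `ground_truth_dataset` objects (invisibly when
#'   `out_dir` is given).
#' @export
generate_benchmark <- function(config = benchmark_config(), master_seed = 1L,
                               conditions = NULL, J_list = NULL,
                               replicates = NULL, out_dir = NULL) {
  cond <- benchmark_conditions(config)
  if (!is.null(conditions)) cond <- cond[cond$condition %in% conditions, ]
  if (is.null(J_list)) J_list <- config$J_list
  if (is.null(replicates)) replicates <- config$replicates
  out <- list()
  for (ci in seq_len(nrow(cond))) {
    for (J in J_list) {
      for (rep_i in seq_len(replicates)) {
        seed <- .child_seed(master_seed, cond$condition[ci], J, rep_i)
        ds <- generate_dataset(cond$family[ci], cond$cutoff_hz[ci],
                               cond$I_true[ci], cond$noise_level[ci],
                               J = J, seed = seed, T = config$T,
                               fs = config$fs)
        ds$generator$condition <- cond$condition[ci]
        ds$generator$replicate <- rep_i
        ds$generator$master_seed <- as.integer(master_seed)
        out[[length(out) + 1L]] <- ds
      }
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (ds in out) write_dataset(ds, out_dir)
    return(invisible(out))
  }
  out
}

#' Write one dataset to a directory
#'
#' Layout per dataset: `<stem>_noisy.csv`, `<stem>_noiseless.csv` (each
#' with a JSON sampling-rate sidecar), `<stem>_{W,S,tau}.csv` truth
#' arrays, and `<stem>_meta.json` with the full generator record.
#'
#' @param ds a `ground_truth_dataset`.
#' @param dir output directory.
#' @return The dataset stem path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "ground_truth_dataset"))
  g <- ds$generator
  stem <- file.path(dir, sprintf("%s_c%gHz_I%d_n%g_J%d_r%s",
                                 g$family, g$cutoff_hz, g$I_true,
                                 g$noise_level, g$J,
                                 if (is.null(g$replicate)) "x" else g$replicate))
  write_signal_matrix(ds$X_noisy, paste0(stem, "_noisy.csv"))
  write_signal_matrix(ds$X_noiseless, paste0(stem, "_noiseless.csv"))
  for (nm in c("W", "S", "tau"))
    utils::write.table(format(ds$true_params[[nm]], digits = 17, trim = TRUE),
                       paste0(stem, "_", nm, ".csv"), sep = ",",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(g, paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}
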