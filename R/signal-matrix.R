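#' Signal matrix container
#'
#' A `signal_matrix` holds J observed signals (or trials) sampled at T
#' equally spaced time points, together with the sampling rate and the
#' per-signal means recorded when the data were centered. Rows are
#' signals/trials, columns are time points on the grid t_m = m/fs,
#' m = 0, ..., T-1 (seconds).
#'
#' @param values numeric J x T matrix of signal values (all finite).
#' @param fs sampling rate in Hz (positive scalar).
#' @param per_signal_mean optional length-J vector of means removed from
#'   each row; defaults to zeros (data not yet centered).
#' @return An object of class `signal_matrix` with elements `values`,
#'   `fs` and `per_signal_mean`.
#' @examples
#' x <- signal_matrix(matrix(rnorm(200), 2, 100), fs = 100)
#' dim(x$values)
#' @export
signal_matrix <- function(values, fs, per_signal_mean = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("signal values must be numeric")
  J <- nrow(values); T <- ncol(values)
  if (J < 1L) stop("signal matrix needs at least one row (J >= 1)")
  if (T < 2L) stop("signal matrix needs at least two time points (T >= 2)")
  if (!all(is.finite(values))) stop("signal values must all be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive finite scalar (Hz)")
  if (is.null(per_signal_mean)) per_signal_mean <- numeric(J)
  if (length(per_signal_mean) != J)
    stop("per_signal_mean must have length J = ", J)
  structure(
    list(values = unname(values), fs = as.numeric(fs),
         per_signal_mean = as.numeric(per_signal_mean)),
    class = "signal_matrix"
  )
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> J = %d signals x T = %d time points @ %g Hz\n",
              nrow(x$values), ncol(x$values), x$fs))
  invisible(x)
}

#' @export
dim.signal_matrix <- function(x) dim(x$values)

#' Remove the per-signal mean
#'
#' Subtracts each row's mean and records it in `per_signal_mean`, so that
#' reconstructions can be reported on the original scale. The generative
#' models assume zero-mean signals; fitting always operates on centered
#' data.
#'
#' @param x a `signal_matrix`.
#' @return A centered `signal_matrix`.
#' @export
center_signals <- function(x) {
  stopifnot(inherits(x, "signal_matrix"))
  m <- rowMeans(x$values)
  signal_matrix(x$values - m, x$fs, per_signal_mean = x$per_signal_mean + m)
}

#' Read a signal matrix from disk
#'
#' Supports two on-disk forms: a CSV file (rows = signals, columns = time
#' points, header row `t0,...,t{T-1}`) with a JSON sidecar
#' `<path>.meta.json` carrying `{"fs_hz": <Hz>}`, or an `.rds` file
#' containing a `signal_matrix` object directly.
#'
#' @param path path to the `.csv` or `.rds` file.
#' @return A `signal_matrix`.
#' @export
read_signal_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    x <- readRDS(path)
    if (!inherits(x, "signal_matrix")) stop("rds file does not hold a signal_matrix")
    return(x)
  }
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("signal CSV has no data rows: ", path)
  vals <- as.matrix(raw)
  if (!is.numeric(vals)) stop("non-numeric cells in signal CSV: ", path)
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path))
    stop("missing sampling-rate sidecar (expected ", meta_path, ")")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$fs_hz)) stop("sidecar ", meta_path, " lacks key 'fs_hz'")
  psm <- if (!is.null(meta$per_signal_mean)) meta$per_signal_mean else NULL
  signal_matrix(vals, fs = meta$fs_hz, per_signal_mean = psm)
}

#' Write a signal matrix to disk
#'
#' Inverse of [read_signal_matrix()]: writes the CSV (header `t0...t{T-1}`,
#' full double precision) plus the JSON metadata sidecar.
#'
#' @param x a `signal_matrix`.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(x, path) {
  stopifnot(inherits(x, "signal_matrix"))
  T <- ncol(x$values)
  df <- as.data.frame(x$values)
  names(df) <- paste0("t", seq_len(T) - 1L)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(fs_hz = x$fs, per_signal_mean = x$per_signal_mean),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
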