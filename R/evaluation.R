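## Extract the winning spec for one record/criterion, or NULL.
.record_winner <- function(record, criterion) {
  sel <- record$selection
  w <- sel[[paste0("winner_", criterion)]]
  w
}

.check_records <- function(records) {
  if (length(records) == 0L) stop("empty record list")
  invisible(TRUE)
}

#' Model-type classification rate
#'
#' Fraction of experiment records whose selected model family matches the
#' generating family (SIM or AMM). A pPCA or ICA selection counts as an
#' incorrect detection for either generator; recall that the f0 = Inf
#' member of the SIM model column *is* the pPCA model, so "SIM selected
#' with no smoothness constraint" is scored as pPCA.
#'
#' @param records list of experiment records, each with `generator`
#'   (metadata from [generate_dataset()]) and `selection`
#'   (a `selection_result`).
#' @param criterion `"lap"`, `"bic"` or `"aic"`.
#' @return Scalar classification rate in `[0, 1]`.
#' @export
classification_rate <- function(records, criterion = c("lap", "bic", "aic")) {
  criterion <- match.arg(criterion)
  .check_records(records)
  correct <- vapply(records, function(r) {
    w <- .record_winner(r, criterion)
    !is.null(w) && w$family == r$generator$family
  }, logical(1))
  mean(correct)
}

#' Source-count estimation error
#'
#' Per-record difference between the selected and generating number of
#' sources, `delta_I = I_selected - I_true`, summarized as mean and
#' (n-1)-denominator standard deviation.
#'
#' @inheritParams classification_rate
#' @return List with `mean`, `sd`, `n` and the raw `delta` values.
#' @export
source_count_error <- function(records, criterion = c("lap", "bic", "aic")) {
  criterion <- match.arg(criterion)
  .check_records(records)
  delta <- vapply(records, function(r) {
    w <- .record_winner(r, criterion)
    if (is.null(w)) return(NA_real_)
    w$n_sources - r$generator$I_true
  }, numeric(1))
  delta <- delta[!is.na(delta)]
  if (length(delta) == 0L) stop("no records with a valid selection")
  list(mean = mean(delta), sd = stats::sd(delta), n = length(delta),
       delta = delta)
}

#' Temporal-smoothness estimation error
#'
#' Per-record difference between the selected and generating cutoff
#' frequency, `delta_f0 = f0_selected - cutoff_hz` (Hz). Records whose
#' winner carries no finite cutoff (a pPCA/ICA selection, i.e. "no
#' smoothness constraint") cannot contribute a finite deviation; with
#' `exclude_infinite = TRUE` (default) they are dropped from the mean/sd
#' and reported in `n_excluded`, otherwise their presence is an error.
#'
#' @inheritParams classification_rate
#' @param exclude_infinite drop infinite-f0 selections (and count them)
#'   rather than failing.
#' @return List with `mean`, `sd`, `n`, `n_excluded` and the raw `delta`
#'   values (Hz).
#' @export
smoothness_error <- function(records, criterion = c("lap", "bic", "aic"),
                             exclude_infinite = TRUE) {
  criterion <- match.arg(criterion)
  .check_records(records)
  f0_sel <- vapply(records, function(r) {
    w <- .record_winner(r, criterion)
    if (is.null(w)) return(NA_real_)
    w$f0
  }, numeric(1))
  gen <- vapply(records, function(r) r$generator$cutoff_hz, numeric(1))
  keep <- !is.na(f0_sel) & is.finite(f0_sel)
  n_excl <- sum(!is.na(f0_sel) & !is.finite(f0_sel))
  if (n_excl > 0 && !exclude_infinite)
    stop(n_excl, " records selected a model without a finite cutoff")
  delta <- f0_sel[keep] - gen[keep]
  if (length(delta) == 0L) stop("all records excluded from smoothness error")
  list(mean = mean(delta), sd = stats::sd(delta), n = length(delta),
       n_excluded = n_excl, delta = delta)
}

#' Summary tables over an experiment
#'
#' Aggregates experiment records into three tables keyed by (J, generator
#' family, noise level, criterion): model-type classification rate,
#' source-count error (mean +/- sd) and smoothness error (mean +/- sd,
#' with exclusion counts). Every record is weighted equally. Rows are
#' ordered deterministically.
#'
#' @param records list of experiment records.
#' @param criteria criteria to tabulate.
#' @return List of data frames `classification`, `source_count`,
#'   `smoothness`.
#' @export
summarize_experiment <- function(records, criteria = c("lap", "bic", "aic")) {
  .check_records(records)
  key <- vapply(records, function(r)
    paste(r$generator$J, r$generator$family, r$generator$noise_level,
          sep = "|"), character(1))
  groups <- split(seq_along(records), key)
  rows_cls <- list(); rows_src <- list(); rows_f0 <- list()
  for (g in names(sort(groups |> vapply(function(i) i[1], numeric(1))))) {
    idx <- groups[[g]]
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    base <- list(J = as.integer(parts[1]), family = parts[2],
                 noise_level = as.numeric(parts[3]), n_records = length(idx))
    for (crit in criteria) {
      rec <- records[idx]
      rows_cls[[length(rows_cls) + 1L]] <- c(base, criterion = crit,
        rate = classification_rate(rec, crit))
      sce <- tryCatch(source_count_error(rec, crit), error = function(e) NULL)
      if (!is.null(sce))
        rows_src[[length(rows_src) + 1L]] <- c(base, criterion = crit,
          mean = sce$mean, sd = sce$sd)
      sme <- tryCatch(smoothness_error(rec, crit), error = function(e) NULL)
      if (!is.null(sme))
        rows_f0[[length(rows_f0) + 1L]] <- c(base, criterion = crit,
          mean = sme$mean, sd = sme$sd, n_excluded = sme$n_excluded)
    }
  }
  tab <- function(rows) if (length(rows))
    do.call(rbind, lapply(rows, function(r) as.data.frame(r))) else NULL
  list(classification = tab(rows_cls), source_count = tab(rows_src),
       smoothness = tab(rows_f0))
}

#' Gait study design arithmetic
#'
#' Size of the human-gait data set layout the pipeline is designed to
#' ingest: actors x walking styles x repetitions gives the trial count,
#' and each trial contributes one time series per recorded lower-body
#' flexion angle, each time-normalized to a fixed number of samples.
#'
#' @param n_actors number of actors.
#' @param n_styles walking styles per actor.
#' @param n_reps repetitions per style.
#' @param n_angles flexion angles per trial.
#' @param T samples per time-normalized gait cycle.
#' @return List with `n_trials`, `n_series` and `T`.
#' @export
gait_design <- function(n_actors = 6L, n_styles = 3L, n_reps = 3L,
                        n_angles = 8L, T = 100L) {
  n_trials <- n_actors * n_styles * n_reps
  list(n_trials = n_trials, n_series = n_trials * n_angles, T = T)
}

#' Run model selection over a list of datasets
#'
#' Applies [select_model()] to each dataset's noisy signals and pairs the
#' result with the generator metadata, producing the records consumed by
#' the evaluation metrics.
#'
#' @param datasets list of `ground_truth_dataset` objects.
#' @param families,I_range,f0_grid selection grid (see [select_model()]).
#' @param opts a `fit_options`.
#' @return List of records (`generator`, `selection`).
#' @export
run_selection_experiment <- function(datasets,
                                     families = c("PPCA", "ICA", "SIM", "AMM"),
                                     I_range = 1:8, f0_grid = c(1:15, Inf),
                                     opts = fit_options()) {
  lapply(datasets, function(ds) {
    sel <- select_model(ds$X_noisy, families = families, I_range = I_range,
                        f0_grid = f0_grid, opts = opts)
    list(generator = ds$generator, selection = sel)
  })
}

#' Scaled-down smoothness-estimation experiment
#'
#' Generates replicate ground-truth datasets for one generator family and
#' estimates the temporal-smoothness cutoff: for every dataset and every
#' candidate source count separately, the best cutoff among the candidate
#' smoothness settings (including "no constraint") is selected by LAP
#' within the generating family, and the deviation from the generating
#' Butterworth cutoff is recorded. Deviations are then summarized as mean
#' +/- sd marginalized across generating and analysis source counts (one
#' record per dataset x analysis source count). Replicates alternate
#' between the generating cutoffs and source counts.
#'
#' @param family generator family (`"SIM"` or `"AMM"`).
#' @param J number of trials.
#' @param noise_level target `1 - R^2`.
#' @param n_replicates replicate datasets (split across the cutoffs).
#' @param cutoffs_hz generating cutoffs to alternate over.
#' @param I_true_range generating source counts to alternate over.
#' @param I_range analysis source counts to marginalize over.
#' @param f0_grid candidate cutoffs (Hz, may include `Inf`).
#' @param opts a `fit_options`.
#' @param master_seed master seed for dataset generation.
#' @return List with `records` (one per dataset x analysis I) and the
#'   [smoothness_error()] summary under the LAP criterion.
#' @export
run_smoothness_experiment <- function(family = "SIM", J = 10L,
                                      noise_level = 0, n_replicates = 10L,
                                      cutoffs_hz = c(5, 10),
                                      I_true_range = 1:2,
                                      I_range = 1:2,
                                      f0_grid = c(1:15, Inf),
                                      opts = fit_options(),
                                      master_seed = 1L) {
  datasets <- lapply(seq_len(n_replicates), function(r) {
    cutoff <- cutoffs_hz[(r - 1L) %% length(cutoffs_hz) + 1L]
    I_true <- I_true_range[(r - 1L) %% length(I_true_range) + 1L]
    generate_dataset(family, cutoff, I_true, noise_level, J = J,
                     seed = .child_seed(master_seed, 7, r))
  })
  records <- list()
  for (ds in datasets) {
    for (I in I_range) {
      sel <- select_model(ds$X_noisy, families = family, I_range = I,
                          f0_grid = f0_grid, opts = opts)
      records[[length(records) + 1L]] <-
        list(generator = c(ds$generator, list(I_analysis = I)),
             selection = sel)
    }
  }
  list(records = records, lap = smoothness_error(records, "lap"))
}

#' Scaled-down model-type classification experiment
#'
#' Generates replicate datasets from one generator family and runs the
#' full model-type selection (all four families; candidate cutoffs at the
#' two generating values, mirroring the classification setup), returning
#' the classification rate under each criterion.
#'
#' @inheritParams run_smoothness_experiment
#' @param families analysis families entered into the selection grid.
#' @return List with `records` and per-criterion classification rates.
#' @export
run_classification_experiment <- function(family = "SIM", J = 10L,
                                          noise_level = 0,
                                          n_replicates = 10L,
                                          cutoffs_hz = c(5, 10),
                                          I_true_range = 1:2,
                                          I_range = 1:3,
                                          families = c("PPCA", "ICA",
                                                       "SIM", "AMM"),
                                          opts = fit_options(),
                                          master_seed = 1L) {
  datasets <- lapply(seq_len(n_replicates), function(r) {
    cutoff <- cutoffs_hz[(r - 1L) %% length(cutoffs_hz) + 1L]
    I_true <- I_true_range[(r - 1L) %% length(I_true_range) + 1L]
    generate_dataset(family, cutoff, I_true, noise_level, J = J,
                     seed = .child_seed(master_seed, 11, r))
  })
  records <- run_selection_experiment(datasets, families = families,
                                      I_range = I_range,
                                      f0_grid = cutoffs_hz, opts = opts)
  list(records = records,
       rate = c(lap = classification_rate(records, "lap"),
                bic = classification_rate(records, "bic"),
                aic = classification_rate(records, "aic")))
}
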