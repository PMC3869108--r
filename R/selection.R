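## Build the T x T circulant matrix of the periodic band-limited shift by
## tau samples (columns are shifted unit impulses).
.shift_matrix <- function(T, tau) {
  e1 <- c(1, numeric(T - 1L))
  d <- .shift_fft(e1, tau %% T)
  idx <- (outer(seq_len(T) - 1L, seq_len(T) - 1L, "-") %% T) + 1L
  matrix(d[idx], T, T)
}

#' Hessian of the negative log joint at the MAP point
#'
#' Assembles the F x F matrix of second derivatives of
#' [negative_log_joint()] with respect to the flattened parameters,
#' evaluated at `theta_star`. All weight and source blocks (including the
#' cross blocks) are analytic; every block involving a delay is obtained
#' by central finite differences of the analytic gradient (step 1e-4
#' samples). The result is symmetrized as `(H + t(H)) / 2`.
#'
#' Parameter order matches the internal flattening: `vec(W)`
#' (column-major), then the sources row by row, then `vec(tau)` for AMM.
#'
#' @param X a `signal_matrix` (already centered, as used in fitting).
#' @param theta_star the fitted `parameter_set`.
#' @param phi the `hyper_params` at which the fit was scored.
#' @param spec a `model_spec`.
#' @param kernel optional precomputed `kernel_bundle`.
#' @param free character subset of `c("W", "S", "tau")`: which blocks are
#'   treated as free parameters (the Hessian is restricted to them).
#' @return Symmetric F x F matrix.
#' @export
neg_log_joint_hessian <- function(X, theta_star, phi, spec, kernel = NULL,
                                  free = c("W", "S", "tau")) {
  stopifnot(inherits(X, "signal_matrix"), inherits(theta_star, "parameter_set"))
  free <- match.arg(free, c("W", "S", "tau"), several.ok = TRUE)
  if (spec$family != "AMM") free <- setdiff(free, "tau")
  J <- nrow(X$values); T <- ncol(X$values); I <- spec$n_sources
  if (is.null(kernel)) kernel <- .kernel_for(spec, phi, T, X$fs)
  W <- theta_star$W; S <- theta_star$S; tau <- theta_star$tau
  inv_sn2 <- 1 / phi$sigma_n^2
  delayed <- spec$family == "AMM" && any(tau != 0)
  b <- .theta_blocks(spec, J, T)
  n_all <- J * I + I * T + length(b$tau)
  iW <- function(j, i) (i - 1L) * J + j
  iS <- function(i) J * I + (i - 1L) * T + seq_len(T)

  # shifted sources u_ji and shift operators
  if (delayed) {
    D <- vector("list", J * I)
    U <- array(0, c(J, I, T))
    for (j in seq_len(J)) for (i in seq_len(I)) {
      Dm <- .shift_matrix(T, tau[j, i])
      D[[(i - 1L) * J + j]] <- Dm
      U[j, i, ] <- Dm %*% S[i, ]
    }
    Xhat <- matrix(0, J, T)
    for (j in seq_len(J)) Xhat[j, ] <- colSums(W[j, ] * matrix(U[j, , ], I, T))
  } else {
    Xhat <- W %*% S
  }
  R <- X$values - Xhat

  H <- matrix(0, n_all, n_all)
  # W-W blocks
  for (i in seq_len(I)) for (ip in seq_len(I)) {
    g <- if (delayed) {
      vapply(seq_len(J), function(j) sum(U[j, i, ] * U[j, ip, ]), numeric(1))
    } else rep(sum(S[i, ] * S[ip, ]), J)
    blk <- diag(g * inv_sn2, J)
    H[iW(seq_len(J), i), iW(seq_len(J), ip)] <- blk
  }
  diag(H)[seq_len(J * I)] <- diag(H)[seq_len(J * I)] + 1 / phi$sigma_w^2

  # S-S blocks
  WtW <- crossprod(W)
  for (i in seq_len(I)) for (ip in seq_len(I)) {
    blk <- if (delayed) {
      M <- matrix(0, T, T)
      for (j in seq_len(J)) {
        if (W[j, i] != 0 && W[j, ip] != 0)
          M <- M + W[j, i] * W[j, ip] *
            crossprod(D[[(i - 1L) * J + j]], D[[(ip - 1L) * J + j]])
      }
      M * inv_sn2
    } else {
      diag(WtW[i, ip] * inv_sn2, T)
    }
    H[iS(i), iS(ip)] <- blk
  }
  # source-prior curvature
  for (i in seq_len(I)) {
    P <- switch(.src_prior_kind(spec),
      gauss = diag(1 / phi$sigma^2, T),
      ica = diag(1 / phi$sigma^2 -
                   phi$lam / cosh(S[i, ] - phi$mu)^2, T),
      kernel$K_inv)
    H[iS(i), iS(i)] <- H[iS(i), iS(i)] + P
  }

  # W-S cross blocks
  for (j in seq_len(J)) for (i in seq_len(I)) {
    u_ji <- if (delayed) U[j, i, ] else S[i, ]
    for (ip in seq_len(I)) {
      v <- if (delayed) {
        crossprod(D[[(ip - 1L) * J + j]], u_ji)[, 1L] * W[j, ip]
      } else {
        W[j, ip] * S[i, ]
      }
      if (ip == i) {
        v <- v - if (delayed) crossprod(D[[(i - 1L) * J + j]], R[j, ])[, 1L] else R[j, ]
      }
      H[iW(j, i), iS(ip)] <- inv_sn2 * v
      H[iS(ip), iW(j, i)] <- inv_sn2 * v
    }
  }

  # delay blocks by central differences of the analytic gradient
  if (spec$family == "AMM" && length(b$tau)) {
    h <- 1e-4
    grad_at <- function(th) .nlj_grad_full(th, X, phi, spec, kernel)
    for (p in seq_along(b$tau)) {
      full_p <- b$tau[p]
      thp <- theta_star; thm <- theta_star
      col <- (p - 1L) %/% J + 1L; row <- (p - 1L) %% J + 1L
      thp$tau[row, col] <- thp$tau[row, col] + h
      thm$tau[row, col] <- thm$tau[row, col] - h
      gcol <- (grad_at(thp) - grad_at(thm)) / (2 * h)
      H[, full_p] <- gcol
      H[full_p, ] <- gcol
    }
  }

  keep <- sort(unlist(b[free], use.names = FALSE))
  H <- H[keep, keep, drop = FALSE]
  H <- (H + t(H)) / 2
  if (any(!is.finite(H))) stop("non-finite entries in the Hessian")
  H
}

#' Laplace-approximation evidence score (LAP)
#'
#' The Laplace approximation to the log marginal likelihood at the MAP
#' point: `loglik + logprior + (F/2) log(2 pi) - log|H| / 2`, where H is
#' the Hessian of the negative log joint. Larger is better. The
#' log-determinant is computed from the eigenvalues of H, clipped below at
#' `1e-8 * max(eigenvalue)` so residual flat (non-identifiable) directions
#' do not send the score to +Inf.
#'
#' @param loglik log-likelihood at the MAP point.
#' @param logprior log-prior at the MAP point.
#' @param H symmetric F x F Hessian from [neg_log_joint_hessian()].
#' @return A list with `total` and the three labeled components
#'   `log_likelihood`, `log_prior`, `log_posterior_volume` (the latter is
#'   `(F/2) log(2 pi) - log|H|/2`).
#' @export
lap_score <- function(loglik, logprior, H) {
  H <- as.matrix(H)
  if (nrow(H) != ncol(H)) stop("H must be square")
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) stop("Hessian has no positive eigenvalues")
  ev <- pmax(ev, 1e-8 * max(ev))
  F_dim <- nrow(H)
  logdet <- sum(log(ev))
  vol <- (F_dim / 2) * log(2 * pi) - 0.5 * logdet
  list(total = loglik + logprior + vol,
       log_likelihood = loglik, log_prior = logprior,
       log_posterior_volume = vol)
}

#' Bayesian information criterion
#'
#' `BIC = -2 (loglik - dim_theta log(n_points) / 2)`; the best model
#' minimizes BIC. The number of data points is the total count of scalar
#' observations, J x T.
#'
#' @param loglik log-likelihood at the MAP point.
#' @param dim_theta number of free parameters (W, S and, for AMM, tau).
#' @param n_points number of scalar data points (J x T).
#' @return Scalar BIC.
#' @export
bic_score <- function(loglik, dim_theta, n_points) {
  if (n_points < 1) stop("n_points must be >= 1")
  -2 * (loglik - 0.5 * dim_theta * log(n_points))
}

#' Akaike information criterion
#'
#' `AIC = -2 (loglik - dim_theta)`; the best model minimizes AIC.
#'
#' @param loglik log-likelihood at the MAP point.
#' @param dim_theta number of free parameters.
#' @return Scalar AIC.
#' @export
aic_score <- function(loglik, dim_theta) {
  -2 * (loglik - dim_theta)
}

.family_order <- c(PPCA = 1L, ICA = 2L, SIM = 3L, AMM = 4L)

.dim_theta <- function(spec, J, T) {
  J * spec$n_sources + spec$n_sources * T +
    if (spec$family == "AMM") J * spec$n_sources else 0L
}

## Enumerate the candidate grid. The f0 = Inf member of the SIM column is
## the pPCA model and is scored once.
.candidate_grid <- function(families, I_range, f0_grid) {
  rows <- list()
  add <- function(fam, I, f0) rows[[length(rows) + 1L]] <<- list(fam, I, f0)
  for (fam in families) {
    for (I in I_range) {
      if (fam %in% c("PPCA", "ICA")) {
        add(fam, I, Inf)
      } else {
        for (f0 in f0_grid) {
          if (fam == "SIM" && is.infinite(f0)) add("PPCA", I, Inf)
          else add(fam, I, f0)
        }
      }
    }
  }
  df <- data.frame(family = vapply(rows, function(r) r[[1]], character(1)),
                   I = vapply(rows, function(r) r[[2]], numeric(1)),
                   f0 = vapply(rows, function(r) r[[3]], numeric(1)),
                   stringsAsFactors = FALSE)
  unique(df)
}

.pick_winner <- function(df, score_col, maximize) {
  ok <- is.finite(df[[score_col]])
  if (!any(ok)) return(NA_integer_)
  sc <- df[[score_col]]
  best <- if (maximize) max(sc[ok]) else min(sc[ok])
  tol <- 1e-6 * max(1, abs(best))
  elig <- which(ok & (if (maximize) sc >= best - tol else sc <= best + tol))
  # ties broken toward parsimony: smaller I, then smaller f0, then family
  ord <- order(df$I[elig], df$f0[elig], .family_order[df$family[elig]])
  elig[ord[1L]]
}

#' Grid-based model selection by LAP, BIC and AIC
#'
#' Fits every candidate (family, number of sources, cutoff) combination
#' with [fit_model()], scores each with LAP, BIC and AIC, and returns all
#' scores together with the per-criterion winning model. Failed fits are
#' recorded and excluded from the winners; they never abort the scan.
#' Ties within a relative tolerance of 1e-6 are broken toward parsimony
#' (smaller I, then smaller f0, then family order PPCA < ICA < SIM < AMM).
#'
#' @param X a `signal_matrix`.
#' @param families character vector drawn from
#'   `c("PPCA", "ICA", "SIM", "AMM")`.
#' @param I_range integer vector of candidate source counts.
#' @param f0_grid numeric vector of candidate cutoffs in Hz (may include
#'   `Inf`; for SIM this member *is* the pPCA model and is scored once).
#' @param opts a `fit_options`.
#' @param keep_fits if `TRUE`, the fitted models are attached.
#' @return A `selection_result` with `candidates` (one data-frame row per
#'   candidate: family, I, f0_hz, loglik, logprior, logposteriorvol, lap,
#'   bic, aic, dim_theta, converged, error) and `winner_lap`,
#'   `winner_bic`, `winner_aic` (each a `model_spec`).
#' @export
select_model <- function(X, families = c("PPCA", "ICA", "SIM", "AMM"),
                         I_range = 1:8,
                         f0_grid = c(1:15, Inf),
                         opts = fit_options(), keep_fits = FALSE) {
  stopifnot(inherits(X, "signal_matrix"))
  families <- match.arg(families, c("PPCA", "ICA", "SIM", "AMM"),
                        several.ok = TRUE)
  if (length(I_range) == 0L || length(f0_grid) == 0L)
    stop("I_range and f0_grid must be non-empty")
  grid <- .candidate_grid(families, I_range, f0_grid)
  J <- nrow(X$values); T <- ncol(X$values)
  n <- nrow(grid)
  out <- data.frame(family = grid$family, I = as.integer(grid$I),
                    f0_hz = grid$f0,
                    loglik = NA_real_, logprior = NA_real_,
                    logposteriorvol = NA_real_, lap = NA_real_,
                    bic = NA_real_, aic = NA_real_,
                    dim_theta = NA_integer_, converged = NA,
                    error = NA_character_, stringsAsFactors = FALSE)
  fits <- if (keep_fits) vector("list", n) else NULL
  for (r in seq_len(n)) {
    res <- tryCatch({
      spec <- model_spec(grid$family[r], grid$I[r], grid$f0[r])
      fit <- fit_model(X, spec, opts)
      Xc <- signal_matrix(X$values - rowMeans(X$values), X$fs)
      kernel <- .kernel_for(spec, fit$phi, T, X$fs)
      H <- neg_log_joint_hessian(Xc, fit$theta, fit$phi, spec, kernel)
      lap <- lap_score(fit$loglik, fit$logprior, H)
      dth <- .dim_theta(spec, J, T)
      list(fit = fit, lap = lap, dth = dth)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error[r] <- conditionMessage(res)
      next
    }
    out$loglik[r] <- res$fit$loglik
    out$logprior[r] <- res$fit$logprior
    out$logposteriorvol[r] <- res$lap$log_posterior_volume
    out$lap[r] <- res$lap$total
    out$bic[r] <- bic_score(res$fit$loglik, res$dth, J * T)
    out$aic[r] <- aic_score(res$fit$loglik, res$dth)
    out$dim_theta[r] <- res$dth
    out$converged[r] <- res$fit$converged
    if (keep_fits) fits[[r]] <- res$fit
  }
  winner_spec <- function(idx) {
    if (is.na(idx)) return(NULL)
    model_spec(out$family[idx], out$I[idx], out$f0_hz[idx])
  }
  structure(list(candidates = out,
                 winner_lap = winner_spec(.pick_winner(out, "lap", TRUE)),
                 winner_bic = winner_spec(.pick_winner(out, "bic", FALSE)),
                 winner_aic = winner_spec(.pick_winner(out, "aic", FALSE)),
                 fits = fits),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>", nrow(x$candidates), "candidates\n")
  for (crit in c("lap", "bic", "aic")) {
    w <- x[[paste0("winner_", crit)]]
    if (is.null(w)) { cat(sprintf("  %s: no valid candidate\n", toupper(crit))); next }
    cat(sprintf("  %s winner: %s, I = %d, f0 = %g Hz\n",
                toupper(crit), w$family, w$n_sources, w$f0))
  }
  invisible(x)
}

#' Write a selection result to disk
#'
#' Writes `<stem>.json` (all candidate scores and the winners) and
#' `<stem>_scores.csv` (the flat candidate score table).
#'
#' @param x a `selection_result`.
#' @param stem output path stem.
#' @return `stem`, invisibly.
#' @export
write_selection_result <- function(x, stem) {
  stopifnot(inherits(x, "selection_result"))
  winners <- lapply(c(lap = "winner_lap", bic = "winner_bic",
                      aic = "winner_aic"),
                    function(f) if (is.null(x[[f]])) NULL else unclass(x[[f]]))
  jsonlite::write_json(list(candidates = x$candidates, winners = winners),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA,
                       na = "null")
  utils::write.csv(x$candidates, paste0(stem, "_scores.csv"),
                   row.names = FALSE)
  invisible(stem)
}
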