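# Conformational dynamics via donor/acceptor cross-correlation.
#
# Anticorrelated donor/acceptor fluctuations report conformational
# exchange; the decay of the cross-correlation with lag carries the
# relaxation rates of the state chain. Correlations are computed on raw
# (unfiltered) intensities because the filter's correlated smoothing would
# distort the lag structure.

#' Donor/acceptor cross-correlation
#'
#' Per molecule, the mean-subtracted normalized cross-correlation
#' `CC(tau) = <dI_D(t) dI_A(t + tau)> / (sd_D * sd_A)` over the analysis
#' window, pooled as the mean across molecules with movie-level SEM.
#'
#' @param traces List of `intensity_trace`; or a `fret_dataset`, in which
#'   case `qc` windows restrict each molecule.
#' @param max_lag Maximum lag in seconds. The analysis window of every
#'   molecule must cover at least `10 * max_lag`.
#' @param qc Optional QC report from [qc_dataset()] (accepted molecules and
#'   windows); only used when `traces` is a `fret_dataset`.
#' @return A `cross_correlation`: list with `lags` (s), `cc` (mean),
#'   `sem` (across movies), `n_molecules`.
#' @export
donor_acceptor_crosscorrelation <- function(traces, max_lag = 2, qc = NULL) {
  windows <- NULL
  if (inherits(traces, "fret_dataset")) {
    ds <- traces
    if (is.null(qc)) qc <- qc_dataset(ds)
    keep <- qc[qc$accepted, , drop = FALSE]
    traces <- lapply(keep$molecule_id, function(id) ds$traces[[id]])
    windows <- lapply(seq_len(nrow(keep)), function(i)
      c(keep$window_start[i], keep$window_end[i]))
  }
  if (!length(traces)) stop("no traces for cross-correlation")
  fr <- traces[[1]]$frame_rate
  nlag <- floor(max_lag * fr)
  lags <- (0:nlag) / fr
  per_mol <- list()
  movie <- numeric(0)
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    idx <- if (!is.null(windows))
      seq.int(windows[[i]][1], windows[[i]][2] - 1L)
    else seq_along(tr$donor)
    d <- tr$donor[idx]; a <- tr$acceptor[idx]
    n <- length(d)
    if (n < 10L * nlag) next   # window too short for this max_lag
    dd <- d - mean(d); da <- a - mean(a)
    den <- sqrt(mean(dd^2) * mean(da^2))
    if (den <= 0) next
    cc <- vapply(0:nlag, function(L)
      mean(dd[seq_len(n - L)] * da[seq_len(n - L) + L]) / den, numeric(1))
    per_mol[[length(per_mol) + 1L]] <- cc
    movie <- c(movie, as.numeric(tr$movie_id)[1])
  }
  if (!length(per_mol))
    stop("analysis windows too short for the requested max_lag")
  mat <- do.call(cbind, per_mol)
  cc_mean <- rowMeans(mat)
  mids <- sort(unique(movie[!is.na(movie)]))
  sem <- if (length(mids) > 1L) {
    mm <- vapply(mids, function(mv)
      rowMeans(mat[, movie == mv, drop = FALSE]), numeric(nrow(mat)))
    apply(mm, 1L, stats::sd) / sqrt(length(mids))
  } else rep(NA_real_, nrow(mat))
  structure(list(lags = lags, cc = cc_mean, sem = sem,
                 n_molecules = ncol(mat)),
            class = "cross_correlation")
}

#' Fit a double-exponential decay to a cross-correlation
#'
#' `|CC(tau)|` is fit to `A1 * exp(-tau/tau1) + A2 * exp(-tau/tau2)` by
#' least squares (deterministic multi-start on log time constants); time
#' constants are reported in ascending order. Near-degenerate fits (one
#' vanishing amplitude or merged time constants) are flagged.
#'
#' @param cc A `cross_correlation`, or a list with `lags` and `cc`.
#' @return An `exp_decay_fit`: list with `A1`, `A2`, `tau1`, `tau2`,
#'   `r_squared`, `degenerate`, `fitted(lags)`.
#' @export
fit_double_exponential <- function(cc) {
  lags <- cc$lags
  y <- abs(cc$cc)
  if (length(lags) < 8L) stop("need at least 8 lag points")
  obj <- function(p) {
    A <- p[1:2]; tau <- 10^p[3:4]
    sum((y - A[1] * exp(-lags / tau[1]) - A[2] * exp(-lags / tau[2]))^2)
  }
  lt <- log10(range(lags[lags > 0]))
  grid <- seq(lt[1] - 0.5, lt[2] + 0.5, length.out = 5L)
  best <- NULL
  a0 <- max(y)
  for (i in seq_along(grid)) for (j in seq_along(grid)) {
    if (grid[i] > grid[j]) next
    p0 <- c(a0 / 2, a0 / 2, grid[i], grid[j])
    ft <- try(stats::optim(p0, obj, method = "L-BFGS-B",
                           lower = c(0, 0, lt[1] - 3, lt[1] - 3),
                           upper = c(2 * a0 + 1e-6, 2 * a0 + 1e-6,
                                     lt[2] + 2, lt[2] + 2),
                           control = list(maxit = 1000, factr = 1e2)),
              silent = TRUE)
    if (inherits(ft, "try-error")) next
    if (is.null(best) || ft$value < best$value) best <- ft
  }
  if (is.null(best)) stop("double-exponential fit failed to converge")
  p <- best$par
  A <- p[1:2]; tau <- 10^p[3:4]
  ord <- order(tau)
  A <- A[ord]; tau <- tau[ord]
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - best$value / ss_tot else NA_real_
  degenerate <- min(A) < 0.02 * max(sum(A), 1e-12) ||
    tau[2] / tau[1] < 1.5
  structure(list(A1 = A[1], A2 = A[2], tau1 = tau[1], tau2 = tau[2],
                 r_squared = r2, degenerate = degenerate,
                 fitted = function(l)
                   A[1] * exp(-l / tau[1]) + A[2] * exp(-l / tau[2])),
            class = "exp_decay_fit")
}

#' Slowest relaxation time of a model under a condition
#'
#' The inverse of the smallest non-zero eigenvalue magnitude of the rate
#' matrix: the generator's slowest relaxation mode, which bounds the decay
#' of the donor/acceptor cross-correlation.
#'
#' @inheritParams rate_matrix
#' @return Relaxation time in seconds.
#' @export
slowest_relaxation_time <- function(model, condition = ligand_condition()) {
  Q <- rate_matrix(model, condition)
  ev <- eigen(Q, only.values = TRUE)$values
  ev <- sort(abs(Re(ev)))
  nz <- ev[ev > 1e-10]
  if (!length(nz)) return(Inf)
  1 / nz[1]
}
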