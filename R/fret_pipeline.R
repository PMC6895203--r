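# FRET computation and nonlinear filtering.
#
# Traces are denoised with a forward/backward predictor filter in the style
# of Chung & Kennedy: at each frame, forward and backward running means of
# span `window` are combined with weights proportional to the inverse
# P-th power of their recent prediction error (comparison span M). The
# large default exponent (P = 15) makes the weights nearly binary, so
# plateaus are averaged without smearing transitions.

#' Filter parameters
#'
#' @param window Predictor span in frames (default 2).
#' @param M Comparison span (frames of prediction error) used for the
#'   weights (default 2).
#' @param P Weighting exponent (default 15).
#' @return A `filter_params` object.
#' @export
filter_params <- function(window = 2L, M = 2L, P = 15) {
  stopifnot(window >= 1, M >= 1, P > 0)
  structure(list(window = as.integer(window), M = as.integer(M), P = P),
            class = "filter_params")
}

# trailing rolling mean of the previous `w` samples (exclusive of t)
lag_mean <- function(x, w) {
  cs <- c(0, cumsum(x))
  n <- length(x)
  t <- seq_len(n)
  lo <- pmax(t - w, 0L)
  cnt <- (t - 1L) - lo
  out <- (cs[t] - cs[lo + 1L]) / cnt
  out[cnt == 0L] <- NA_real_
  out
}

#' Chung-Kennedy-style nonlinear filter
#'
#' @param series Numeric series; length must exceed `2 * (window + M)`.
#' @param params A `filter_params`.
#' @return Filtered series of the same length. A strictly constant series is
#'   returned unchanged; at the edges the single available one-sided
#'   predictor is used.
#' @export
nonlinear_filter <- function(series, params = filter_params()) {
  n <- length(series)
  w <- params$window; M <- params$M; P <- params$P
  if (n <= 2L * (w + M)) stop("series too short for the nonlinear filter")
  fwd <- lag_mean(series, w)                       # mean of x[t-w .. t-1]
  bwd <- rev(lag_mean(rev(series), w))             # mean of x[t+1 .. t+w]
  e_f <- (series - fwd)^2
  e_b <- (series - bwd)^2
  # error sums over the trailing / leading M frames (inclusive of t)
  csf <- c(0, cumsum(ifelse(is.na(e_f), 0, e_f)))
  ncf <- c(0, cumsum(!is.na(e_f)))
  t <- seq_len(n)
  lo <- pmax(t - M, 0L)
  S_f <- csf[t + 1L] - csf[lo + 1L]
  n_f <- ncf[t + 1L] - ncf[lo + 1L]
  csb <- c(0, cumsum(rev(ifelse(is.na(e_b), 0, e_b))))
  ncb <- c(0, cumsum(rev(!is.na(e_b))))
  S_b <- rev(csb[t + 1L] - csb[lo + 1L])
  n_b <- rev(ncb[t + 1L] - ncb[lo + 1L])

  out <- numeric(n)
  have_f <- !is.na(fwd) & n_f > 0
  have_b <- !is.na(bwd) & n_b > 0
  both <- have_f & have_b
  # weight ratio (S_f/S_b)^P computed stably; zero-error cases pinned
  r <- (S_f[both] / n_f[both]) / (S_b[both] / n_b[both])
  wf <- ifelse(is.nan(r), 0.5, 1 / (1 + r^P))
  wf[S_f[both] == 0 & S_b[both] == 0] <- 0.5
  wf[S_f[both] == 0 & S_b[both] > 0] <- 1
  wf[S_b[both] == 0 & S_f[both] > 0] <- 0
  out[both] <- wf * fwd[both] + (1 - wf) * bwd[both]
  out[have_f & !have_b] <- fwd[have_f & !have_b]
  out[!have_f & have_b] <- bwd[!have_f & have_b]
  out[!have_f & !have_b] <- series[!have_f & !have_b]
  # strictly constant input: predictors equal the sample, return it exactly
  out
}

#' Single-molecule FRET efficiency
#'
#' Per-frame crosstalk-corrected efficiency
#' `E = (I_A - alpha * I_D) / (I_D + I_A)` after per-channel background
#' subtraction. Frames whose background-subtracted total intensity is
#' non-positive are masked (`NA`) and counted. By default both channels are
#' denoised with the nonlinear filter before the ratio is formed; the raw
#' efficiency is always returned alongside.
#'
#' @param trace An `intensity_trace`.
#' @param alpha Donor-to-acceptor crosstalk fraction (default 0.1).
#' @param background Per-channel background, scalar or `c(donor, acceptor)`.
#' @param window Optional `c(first, last)` analysis window (frames; last
#'   exclusive), e.g. from [qualify_trace()]. Default: whole trace.
#' @param filter Logical: apply the nonlinear filter (default `TRUE`).
#' @param params A `filter_params`.
#' @return A `fret_trace`: list with `time`, `E` (filtered if requested,
#'   else raw), `E_raw`, `n_masked`, ids, and `filtered` flag.
#' @export
smfret_efficiency <- function(trace, alpha = 0.1, background = 0,
                              window = NULL, filter = TRUE,
                              params = filter_params()) {
  if (length(trace$donor) != length(trace$acceptor))
    stop("malformed trace: unequal channel lengths")
  background <- rep_len(background, 2L)
  if (is.null(window)) window <- c(1L, length(trace$donor) + 1L)
  idx <- seq.int(window[1], window[2] - 1L)
  ID <- trace$donor[idx] - background[1]
  IA <- trace$acceptor[idx] - background[2]
  eff <- function(d, a) {
    tot <- d + a
    e <- (a - alpha * d) / tot
    e[tot <= 0] <- NA_real_
    e
  }
  E_raw <- eff(ID, IA)
  E <- E_raw
  filtered <- FALSE
  if (filter && length(idx) > 2L * (params$window + params$M)) {
    E <- eff(nonlinear_filter(ID, params), nonlinear_filter(IA, params))
    filtered <- TRUE
  }
  structure(list(time = trace$time[idx], E = E, E_raw = E_raw,
                 n_masked = sum(is.na(E_raw)),
                 molecule_id = trace$molecule_id, movie_id = trace$movie_id,
                 condition = trace$condition, filtered = filtered),
            class = "fret_trace")
}

#' Ensemble FRET ratio
#'
#' Per-frame ratio `I_A / (I_D + I_A)` (no crosstalk term, as used for
#' live-cell ensemble recordings). Zero-sum frames are masked.
#'
#' @param trace An `intensity_trace` (typically from
#'   [simulate_ensemble_recording()]).
#' @return Numeric ratio series (NA at masked frames).
#' @export
ensemble_fret <- function(trace) {
  if (length(trace$donor) != length(trace$acceptor))
    stop("malformed trace: unequal channel lengths")
  tot <- trace$donor + trace$acceptor
  r <- trace$acceptor / tot
  r[tot <= 0] <- NA_real_
  r
}

#' Normalized ensemble FRET change per titration step
#'
#' For each protocol step, the plateau ratio is the mean over the final 50%
#' of the step; the FRET change is `baseline - plateau`, where the baseline
#' is the plateau of the zero-concentration step (or the pre-titration
#' level). Changes are normalized to the saturating reference step, which
#' therefore reports 1.0.
#'
#' @param ratio Numeric ratio series from [ensemble_fret()].
#' @param protocol The `titration_protocol` used for the recording.
#' @param frame_rate Acquisition rate of `ratio` in Hz.
#' @return data.frame with `concentration`, `delta_fret` (raw) and
#'   `response` (normalized).
#' @export
delta_fret_response <- function(ratio, protocol, frame_rate = 1) {
  ref_c <- attr(protocol, "reference_concentration")
  if (is.null(ref_c)) stop("protocol lacks a reference step")
  n <- length(ratio)
  plateau <- vapply(seq_len(nrow(protocol)), function(k) {
    half <- (protocol$t_start[k] + protocol$t_end[k]) / 2
    i0 <- floor(half * frame_rate) + 1L
    i1 <- min(n, floor(protocol$t_end[k] * frame_rate + 1e-9))
    if (i1 > n || i0 > i1) stop("protocol step boundaries outside trace")
    mean(ratio[i0:i1], na.rm = TRUE)
  }, numeric(1))
  base_idx <- which(protocol$concentration == 0)
  baseline <- if (length(base_idx)) plateau[base_idx[1]] else
    mean(ratio[seq_len(max(1L, floor(protocol$t_start[1] * frame_rate)))],
         na.rm = TRUE)
  dfret <- baseline - plateau
  ref_idx <- which.min(abs(protocol$concentration - ref_c))
  if (abs(protocol$concentration[ref_idx] - ref_c) >
      1e-12 + 1e-9 * ref_c)
    stop("missing reference step")
  data.frame(concentration = protocol$concentration,
             delta_fret = dfret,
             response = dfret / dfret[ref_idx])
}

#' Compute FRET traces for the accepted molecules of a dataset
#'
#' @param dataset A `fret_dataset`.
#' @param qc QC report from [qc_dataset()]; when `NULL`, QC is run with the
#'   default criteria.
#' @param alpha,background,filter,params Passed to [smfret_efficiency()].
#' @return List of `fret_trace` for the accepted molecules.
#' @export
fret_dataset_traces <- function(dataset, qc = NULL, alpha = 0.1,
                                background = 0, filter = TRUE,
                                params = filter_params()) {
  if (is.null(qc)) qc <- qc_dataset(dataset)
  keep <- qc[qc$accepted, , drop = FALSE]
  lapply(seq_len(nrow(keep)), function(i) {
    tr <- dataset$traces[[keep$molecule_id[i]]]
    smfret_efficiency(tr, alpha = alpha, background = background,
                      window = c(keep$window_start[i], keep$window_end[i]),
                      filter = filter, params = params)
  })
}
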