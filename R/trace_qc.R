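# Trace quality control.
#
# Molecules are retained when they show the canonical single-pair signature:
# exactly one acceptor photobleaching step (with the concomitant donor
# rise), followed by exactly one donor photobleaching step, with a stable
# total intensity for longer than 5 s before the first bleach. Step events
# are located by recursive binary segmentation on the standardized
# mean-difference statistic; small-amplitude changes (conformational
# transitions) are excluded by an amplitude threshold expressed in
# multiples of the channel noise SD.

#' Robust noise SD estimate of a time series
#'
#' Median absolute successive difference, scaled for Gaussian noise.
#' Insensitive to a small number of steps.
#'
#' @param x Numeric series.
#' @return Estimated per-sample noise SD.
#' @export
estimate_noise_sd <- function(x) {
  d <- diff(x)
  stats::median(abs(d)) / (sqrt(2) * 0.6744898)
}

# Best split of series[l..r]: maximises |mean(left) - mean(right)| /
# (sd * sqrt(1/n1 + 1/n2)); ties broken toward the earlier frame.
best_split <- function(cs, l, r, noise_sd, min_seg) {
  n <- r - l + 1L
  if (n < 2L * min_seg) return(NULL)
  ks <- (l + min_seg - 1L):(r - min_seg)
  n1 <- ks - l + 1L
  n2 <- r - ks
  m1 <- (cs[ks + 1L] - cs[l]) / n1
  m2 <- (cs[r + 1L] - cs[ks + 1L]) / n2
  stat <- abs(m1 - m2) / (noise_sd * sqrt(1 / n1 + 1 / n2))
  i <- which.max(stat)          # which.max returns the first (earliest) max
  list(k = ks[i], stat = stat[i], amplitude = m2[i] - m1[i])
}

#' Detect intensity step events
#'
#' Change-points are found by recursive binary segmentation maximising the
#' standardized mean-difference statistic; candidate change-points are then
#' pruned by amplitude (difference of adjacent segment means), iteratively
#' removing the weakest change until all surviving events have amplitude at
#' least `min_amplitude`.
#'
#' @param series Numeric intensity series (length `>= 10`).
#' @param min_amplitude Minimum absolute step amplitude (detector units).
#' @param noise_sd_estimate Per-sample noise SD used to standardize the
#'   split statistic; default from [estimate_noise_sd()].
#' @param stat_threshold Minimum standardized statistic for a split to be
#'   considered a change-point (guards against pure-noise splits).
#' @param min_seg Minimum segment length on each side of a split.
#' @return data.frame of events with columns `frame` (first frame of the new
#'   level), `amplitude` (signed, new minus old level) and `direction`
#'   (`"up"`/`"down"`), ordered by frame. Zero rows if no events.
#' @export
detect_steps <- function(series, min_amplitude,
                         noise_sd_estimate = estimate_noise_sd(series),
                         stat_threshold = 5, min_seg = 4L) {
  n <- length(series)
  if (n < 10L) stop("series too short for step detection (need >= 10 frames)")
  noise_sd <- max(noise_sd_estimate, 1e-12)
  cs <- c(0, cumsum(series))
  cps <- integer(0)
  recurse <- function(l, r) {
    sp <- best_split(cs, l, r, noise_sd, min_seg)
    if (is.null(sp) || sp$stat < stat_threshold) return(invisible())
    cps[[length(cps) + 1L]] <<- sp$k
    recurse(l, sp$k)
    recurse(sp$k + 1L, r)
  }
  recurse(1L, n)
  cps <- sort(cps)
  empty <- data.frame(frame = integer(0), amplitude = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
  if (!length(cps)) return(empty)
  # amplitude pruning on adjacent segment means, weakest-first
  repeat {
    bounds <- c(0L, cps, n)
    means <- vapply(seq_len(length(bounds) - 1L), function(i)
      (cs[bounds[i + 1L] + 1L] - cs[bounds[i] + 1L]) /
        (bounds[i + 1L] - bounds[i]), numeric(1))
    amps <- diff(means)
    if (!length(amps) || all(abs(amps) >= min_amplitude)) break
    drop <- which.min(abs(amps))
    cps <- cps[-drop]
    if (!length(cps)) return(empty)
  }
  data.frame(frame = cps + 1L, amplitude = amps,
             direction = ifelse(amps > 0, "up", "down"),
             stringsAsFactors = FALSE)
}

# Local refinement of a detected downward bleach step: binary segmentation
# cannot place a change-point closer than `min_seg` frames to a
# conformational transition, so a bleach a frame or two after a state jump
# is localized at the jump instead. Anchored at the detected frame, find
# the first sustained (2-frame) excursion below the midpoint of the pre-
# and post-step levels.
refine_down_step <- function(x, frame, halfwidth = 4L) {
  n <- length(x)
  post <- mean(x[min(frame + 3L, n):min(frame + 10L, n)])
  pre <- mean(x[max(frame - 10L, 1L):max(frame - 3L, 1L)])
  if (!is.finite(post) || !is.finite(pre) || pre <= post) return(frame)
  thr <- (pre + post) / 2
  for (k in max(frame - halfwidth, 2L):min(frame + halfwidth, n - 1L))
    if (x[k] < thr && x[k + 1L] < thr) return(k)
  frame
}

#' QC criteria
#'
#' @param min_stable_duration Minimum pre-bleach duration in seconds
#'   (default 5).
#' @param stability_cv_max Maximum coefficient of variation of the
#'   pre-bleach total intensity (default 0.15).
#' @param step_min_amplitude Minimum bleach-step amplitude, in multiples of
#'   the channel noise SD (default 3: large enough to pass over
#'   conformational transitions, small enough to catch an acceptor bleach
#'   from the active state).
#' @param allow_donor_only Accept traces with a single donor bleach and no
#'   acceptor event (dark-acceptor traces); default `FALSE`.
#' @return A `qc_criteria` object.
#' @export
qc_criteria <- function(min_stable_duration = 5, stability_cv_max = 0.15,
                        step_min_amplitude = 3, allow_donor_only = FALSE) {
  stopifnot(min_stable_duration > 0, stability_cv_max > 0,
            step_min_amplitude > 0)
  structure(list(min_stable_duration = min_stable_duration,
                 stability_cv_max = stability_cv_max,
                 step_min_amplitude = step_min_amplitude,
                 allow_donor_only = isTRUE(allow_donor_only)),
            class = "qc_criteria")
}

#' Qualify a trace for analysis
#'
#' Applies the single-molecule selection rule: exactly one acceptor
#' photobleaching step accompanied (within 2 frames) by a donor intensity
#' rise, followed by exactly one donor photobleaching step -- or, when
#' `allow_donor_only` is set and the acceptor channel is dark, a single
#' donor step -- with a stable total intensity (CV below the bound) for at
#' least `min_stable_duration` seconds before the first bleach. The
#' analysis window ends at the first bleach event.
#'
#' @param trace An `intensity_trace`.
#' @param criteria A `qc_criteria`.
#' @return A `qc_result`: list with `accepted`, `reason`
#'   (`"ok"`, `"no-bleach"`, `"multi-step"`, `"signature"`,
#'   `"min_stable_duration"`, `"unstable-intensity"`), `window`
#'   (`c(first, last)` analysed frames, last exclusive of the bleach),
#'   `noise_sd` (per-channel estimates) and the detected `steps`.
#' @export
qualify_trace <- function(trace, criteria = qc_criteria()) {
  if (length(trace$donor) != length(trace$acceptor))
    stop("malformed trace: unequal channel lengths")
  n <- length(trace$donor)
  fr <- trace$frame_rate
  sd_d <- estimate_noise_sd(trace$donor)
  sd_a <- estimate_noise_sd(trace$acceptor)
  steps_d <- detect_steps(trace$donor,
                          min_amplitude = criteria$step_min_amplitude * sd_d,
                          noise_sd_estimate = sd_d)
  steps_a <- detect_steps(trace$acceptor,
                          min_amplitude = criteria$step_min_amplitude * sd_a,
                          noise_sd_estimate = sd_a)
  res <- function(accepted, reason, window = c(NA_integer_, NA_integer_)) {
    structure(list(accepted = accepted, reason = reason, window = window,
                   noise_sd = c(donor = sd_d, acceptor = sd_a),
                   steps = list(donor = steps_d, acceptor = steps_a)),
              class = "qc_result")
  }

  acc_down <- steps_a[steps_a$direction == "down", , drop = FALSE]
  acc_up   <- steps_a[steps_a$direction == "up", , drop = FALSE]
  don_down <- steps_d[steps_d$direction == "down", , drop = FALSE]
  don_up   <- steps_d[steps_d$direction == "up", , drop = FALSE]

  first_bleach <- NA_integer_
  if (nrow(acc_down) == 1L && nrow(acc_up) == 0L) {
    fa <- acc_down$frame[1]
    # the acceptor bleach must show as a donor rise at the same frame
    paired_up <- any(abs(don_up$frame - fa) <= 2L)
    later_down <- don_down[don_down$frame > fa + 2L, , drop = FALSE]
    early_down <- don_down[don_down$frame <= fa + 2L, , drop = FALSE]
    if (!paired_up || nrow(early_down) > 0L)
      return(res(FALSE, "signature"))
    if (nrow(later_down) > 1L || nrow(don_up) > 1L)
      return(res(FALSE, "multi-step"))
    first_bleach <- refine_down_step(trace$acceptor, fa)
  } else if (nrow(acc_down) > 1L) {
    return(res(FALSE, "multi-step"))
  } else if (nrow(acc_down) == 0L) {
    if (criteria$allow_donor_only && nrow(don_down) == 1L &&
        nrow(don_up) == 0L &&
        mean(trace$acceptor[seq_len(min(n, 20L))]) < 3 * sd_a) {
      first_bleach <- refine_down_step(trace$donor, don_down$frame[1])
    } else {
      return(res(FALSE, "no-bleach"))
    }
  } else {
    return(res(FALSE, "signature"))
  }

  if (is.na(first_bleach) || first_bleach < 2L)
    return(res(FALSE, "no-bleach"))
  window <- c(1L, first_bleach)          # [first, last) before the bleach
  n_pre <- first_bleach - 1L
  if (n_pre / fr < criteria$min_stable_duration)
    return(res(FALSE, "min_stable_duration", window))
  total <- trace$donor[seq_len(n_pre)] + trace$acceptor[seq_len(n_pre)]
  cv <- stats::sd(total) / mean(total)
  if (!is.finite(cv) || cv > criteria$stability_cv_max)
    return(res(FALSE, "unstable-intensity", window))
  res(TRUE, "ok", window)
}

#' Run QC over a dataset
#'
#' @param dataset A `fret_dataset`.
#' @param criteria A `qc_criteria`.
#' @return data.frame report: one row per molecule with `molecule_id`,
#'   `movie_id`, `accepted`, `reason`, `window_start`, `window_end`.
#' @export
qc_dataset <- function(dataset, criteria = qc_criteria()) {
  rows <- lapply(dataset$traces, function(tr) {
    q <- qualify_trace(tr, criteria)
    data.frame(molecule_id = tr$molecule_id, movie_id = tr$movie_id,
               accepted = q$accepted, reason = q$reason,
               window_start = q$window[1], window_end = q$window[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
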