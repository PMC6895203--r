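# Synthetic smFRET data generation.
#
# Exact stochastic simulation of the conformational chain, followed by
# camera-style rendering: per-frame time-weighted FRET, inversion of the
# crosstalk-corrected efficiency estimator, single-step photobleaching and
# additive Gaussian detection noise.

#' Photophysics parameters
#'
#' @param total_intensity Sum-channel scale S (arbitrary detector units).
#' @param crosstalk_alpha Donor-to-acceptor bleed-through fraction (the 0.1
#'   term in the efficiency estimator).
#' @param noise_sigma Additive per-channel Gaussian noise SD (detector
#'   units). The default gives a per-channel signal-to-noise ratio of about
#'   6 at 10 Hz.
#' @param donor_bleach_mean,acceptor_bleach_mean Mean single-step
#'   photobleaching lifetimes in seconds (exponential); `Inf` disables
#'   bleaching (used for live-cell ensemble recordings).
#' @param frame_rate Acquisition rate in Hz (10 or 100 for single molecules,
#'   1 for ensemble recordings).
#' @param background Per-channel intensity offset (detector units). The
#'   generator emits background-subtracted intensities by default.
#' @param forster_radius_A Informational metadata (Angstrom); not used in
#'   any computation.
#' @return A `photophysics_params` object.
#' @export
photophysics_params <- function(total_intensity = 1000,
                                crosstalk_alpha = 0.1,
                                noise_sigma = 80,
                                donor_bleach_mean = 30,
                                acceptor_bleach_mean = 20,
                                frame_rate = 10,
                                background = 0,
                                forster_radius_A = 52) {
  stopifnot(total_intensity > 0, crosstalk_alpha >= 0, crosstalk_alpha < 1,
            noise_sigma >= 0, frame_rate > 0,
            donor_bleach_mean > 0, acceptor_bleach_mean > 0)
  structure(list(total_intensity = total_intensity,
                 crosstalk_alpha = crosstalk_alpha,
                 noise_sigma = noise_sigma,
                 donor_bleach_mean = donor_bleach_mean,
                 acceptor_bleach_mean = acceptor_bleach_mean,
                 frame_rate = frame_rate,
                 background = background,
                 forster_radius_A = forster_radius_A),
            class = "photophysics_params")
}

# Deterministic counter-based sub-seed derivation: reproducible and
# independent of simulation order. All arithmetic stays below 2^53 so the
# modulus is exact in doubles; result is in [1, 2^31 - 2].
derive_seed <- function(master, ...) {
  ks <- c(...)
  m <- 2147483647
  s <- master %% m
  mult <- c(7919, 104729, 1299709, 15485863, 32452843)
  for (i in seq_along(ks))
    s <- (s * 48271 %% m + ks[i] * mult[((i - 1) %% 5) + 1]) %% m
  as.integer(s %% (m - 2) + 1)
}

#' Simulate one continuous-time state path
#'
#' Exact (Gillespie) stochastic simulation of the conformational chain under
#' a ligand condition: exponential holding times with competing-rate jump
#' selection. The initial state is drawn from the stationary distribution.
#'
#' @param model An `activation_model`.
#' @param condition A `ligand_condition`.
#' @param duration Path duration in seconds (`> 0`).
#' @param seed Optional integer seed for reproducibility.
#' @return A `state_path`: list with `times` (jump entry times, first is 0),
#'   `states` (integer state indices), `duration`, and the emitting
#'   `fret_levels`.
#' @export
simulate_state_path <- function(model, condition = ligand_condition(),
                                duration, seed = NULL) {
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.null(seed)) set.seed(seed)
  Q <- rate_matrix(model, condition)
  pi <- stationary_occupancy(model, condition)
  n <- nrow(Q)
  state <- sample.int(n, 1L, prob = pi)
  times <- 0
  states <- state
  t <- 0
  repeat {
    out <- Q[state, ]
    out[state] <- 0
    r <- sum(out)
    if (r <= 0) break
    t <- t + stats::rexp(1L, r)
    if (t >= duration) break
    state <- sample.int(n, 1L, prob = out)
    times <- c(times, t)
    states <- c(states, state)
  }
  structure(list(times = times, states = states, duration = duration,
                 fret_levels = model$states$fret_level),
            class = "state_path")
}

# Per-frame time-weighted mean FRET of a piecewise-constant path. Frames
# containing a jump get the camera-integrated (blurred) mean. Exact: the
# integral of E is piecewise linear with knots at jump times.
frame_average_fret <- function(path, frame_rate, n_frames) {
  bounds <- seq(0, by = 1 / frame_rate, length.out = n_frames + 1L)
  E <- path$fret_levels[path$states]
  knots <- c(path$times, path$duration)
  if (bounds[n_frames + 1L] > path$duration + 1e-9)
    stop("path shorter than requested frames")
  cumint <- c(0, cumsum(E * diff(knots)))
  Fb <- stats::approx(knots, cumint, xout = pmin(bounds, path$duration),
                      rule = 2)$y
  diff(Fb) * frame_rate
}

#' Render a state path into donor/acceptor intensities
#'
#' Each frame's time-weighted FRET level `E` is mapped to intensities by
#' inverting the crosstalk-corrected estimator:
#' `I_A = S * (E + alpha) / (1 + alpha)`, `I_D = S - I_A`, so that
#' `(I_A - alpha * I_D) / (I_D + I_A)` returns `E` exactly in the noiseless
#' case. Exponential single-step photobleaching truncates the signal:
#' acceptor bleach converts the molecule to a donor-only emitter (`I_A ->`
#' background, `I_D -> S`); donor bleach sends both channels to background.
#' Additive Gaussian noise is applied last.
#'
#' @param path A `state_path`.
#' @param phys A `photophysics_params`.
#' @param seed Optional integer seed.
#' @param molecule_id,movie_id,condition Identification metadata stored on
#'   the trace.
#' @return An `intensity_trace`: list with `time`, `donor`, `acceptor`,
#'   `frame_rate`, metadata, and ground truth (`truth$donor_bleach_frame`,
#'   `truth$acceptor_bleach_frame` -- first fully bleached frame, NA if none
#'   -- and `truth$fret`).
#' @export
render_trace <- function(path, phys, seed = NULL,
                         molecule_id = NA_integer_, movie_id = NA_integer_,
                         condition = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fr <- phys$frame_rate
  n <- floor(path$duration * fr + 1e-9)
  if (n < 1L) stop("path must cover at least one frame")
  E <- frame_average_fret(path, fr, n)
  S <- phys$total_intensity
  a <- phys$crosstalk_alpha
  IA <- S * (E + a) / (1 + a)
  ID <- S - IA

  t_acc <- if (is.finite(phys$acceptor_bleach_mean))
    stats::rexp(1L, 1 / phys$acceptor_bleach_mean) else Inf
  t_don <- if (is.finite(phys$donor_bleach_mean))
    stats::rexp(1L, 1 / phys$donor_bleach_mean) else Inf
  # first frame fully past the bleach time; bleaching applied at frame
  # granularity so truth metadata matches the truncation exactly
  acc_frame <- if (t_acc < n / fr) floor(t_acc * fr) + 1L else NA_integer_
  don_frame <- if (t_don < n / fr) floor(t_don * fr) + 1L else NA_integer_
  if (!is.na(acc_frame) && !is.na(don_frame) && don_frame <= acc_frame)
    acc_frame <- NA_integer_        # donor died first: no acceptor step
  bg <- phys$background
  if (!is.na(acc_frame)) {
    upto <- if (!is.na(don_frame)) don_frame - 1L else n
    idx <- acc_frame:upto
    IA[idx] <- bg
    ID[idx] <- S + bg
  }
  if (!is.na(don_frame)) {
    idx <- don_frame:n
    IA[idx] <- bg
    ID[idx] <- bg
  }
  if (phys$noise_sigma > 0) {
    IA <- IA + stats::rnorm(n, 0, phys$noise_sigma)
    ID <- ID + stats::rnorm(n, 0, phys$noise_sigma)
  }
  structure(list(time = (seq_len(n) - 0.5) / fr,
                 donor = ID, acceptor = IA, frame_rate = fr,
                 molecule_id = molecule_id, movie_id = movie_id,
                 condition = condition,
                 truth = list(fret = E,
                              acceptor_bleach_frame = acc_frame,
                              donor_bleach_frame = don_frame)),
            class = "intensity_trace")
}

#' Simulate a grouped single-molecule dataset
#'
#' Independent molecules grouped into movies, one or several ligand
#' conditions. Per-molecule seeds are derived deterministically from the
#' master seed with a counter-based scheme, so datasets are reproducible
#' and order-independent.
#'
#' @param model An `activation_model`.
#' @param conditions A `ligand_condition` or list of them.
#' @param n_movies Movies per condition (`>= 1`).
#' @param molecules_per_movie Molecules per movie.
#' @param duration Per-molecule recording length (s).
#' @param phys A `photophysics_params`.
#' @param seed Master integer seed.
#' @return A `fret_dataset`: list with `traces` (list of
#'   `intensity_trace`), `manifest` (data.frame: molecule_id, movie_id,
#'   ligand, concentration), `model_name`, `seed`, and per-condition
#'   ground-truth occupancies.
#' @export
simulate_dataset <- function(model, conditions, n_movies = 5L,
                             molecules_per_movie = 40L, duration = 60,
                             phys = photophysics_params(), seed = 1L) {
  if (n_movies < 1L) stop("n_movies must be >= 1")
  if (inherits(conditions, "ligand_condition")) conditions <- list(conditions)
  traces <- list()
  man <- list()
  truth_occ <- list()
  mol_global <- 0L
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    pi <- stationary_occupancy(model, cond)
    truth_occ[[ci]] <- list(ligand = cond$ligand,
                            concentration = cond$concentration,
                            active_occupancy = sum(pi[model$states$is_active]),
                            occupancy = pi)
    for (mv in seq_len(n_movies)) {
      for (mol in seq_len(molecules_per_movie)) {
        mol_global <- mol_global + 1L
        s_path <- derive_seed(seed, ci, mv, mol, 1)
        s_rend <- derive_seed(seed, ci, mv, mol, 2)
        path <- simulate_state_path(model, cond, duration, seed = s_path)
        tr <- render_trace(path, phys, seed = s_rend,
                           molecule_id = mol_global, movie_id = mv,
                           condition = cond)
        traces[[mol_global]] <- tr
        man[[mol_global]] <- data.frame(
          molecule_id = mol_global, movie_id = mv,
          ligand = cond$ligand, concentration = cond$concentration,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(traces = traces, manifest = do.call(rbind, man),
                 model_name = model$name, seed = seed,
                 frame_rate = phys$frame_rate, truth = truth_occ),
            class = "fret_dataset")
}

#' Titration protocol for ensemble recordings
#'
#' @param concentrations Molar concentration of each step, in order.
#' @param dwell Seconds per step (recycled).
#' @param reference_concentration Saturating normalisation step that must be
#'   present in `concentrations` (default 10 mM glutamate).
#' @return A `titration_protocol` data.frame with columns `concentration`,
#'   `dwell`, `t_start`, `t_end`, plus the reference attribute.
#' @export
titration_protocol <- function(concentrations, dwell = 30,
                               reference_concentration = 1e-2) {
  if (length(concentrations) == 0L) stop("protocol must be non-empty")
  dwell <- rep_len(dwell, length(concentrations))
  if (!any(abs(concentrations - reference_concentration) <=
           1e-12 + 1e-9 * reference_concentration))
    stop("protocol must include the saturating reference step")
  t_end <- cumsum(dwell)
  proto <- data.frame(concentration = concentrations, dwell = dwell,
                      t_start = c(0, t_end[-length(t_end)]), t_end = t_end)
  attr(proto, "reference_concentration") <- reference_concentration
  class(proto) <- c("titration_protocol", "data.frame")
  proto
}

#' Simulate an ensemble (live-cell style) two-channel recording
#'
#' Sums donor and acceptor intensities over `n_receptors` independent
#' receptors, each re-equilibrating to every concentration step with the
#' model's kinetics. Channel noise is applied to the summed intensities.
#'
#' @param model An `activation_model`.
#' @param protocol A `titration_protocol`.
#' @param phys A `photophysics_params`; `total_intensity` is the per-receptor
#'   scale. Bleaching should be disabled (`Inf` lifetimes) for ensemble use.
#' @param n_receptors Number of receptors summed.
#' @param seed Master integer seed.
#' @param ligand Ligand applied in all steps.
#' @return An `intensity_trace` whose `condition` is `NULL` and which carries
#'   the protocol in `truth$protocol`.
#' @export
simulate_ensemble_recording <- function(model, protocol,
                                        phys = photophysics_params(
                                          frame_rate = 1,
                                          donor_bleach_mean = Inf,
                                          acceptor_bleach_mean = Inf),
                                        n_receptors = 2000L, seed = 1L,
                                        ligand = "glutamate") {
  if (nrow(protocol) == 0L) stop("protocol must be non-empty")
  fr <- phys$frame_rate
  total_T <- protocol$t_end[nrow(protocol)]
  n <- floor(total_T * fr + 1e-9)
  Esum <- numeric(n)
  for (r in seq_len(n_receptors)) {
    set.seed(derive_seed(seed, r))
    # piecewise protocol: continue the chain across steps, starting each
    # step from the state reached at the end of the previous one
    Elevels <- model$states$fret_level
    state <- NULL
    times_all <- numeric(0); states_all <- integer(0)
    for (k in seq_len(nrow(protocol))) {
      cond <- ligand_condition(ligand, protocol$concentration[k])
      Q <- rate_matrix(model, cond)
      if (is.null(state)) {
        pi <- stationary_occupancy(model, cond)
        state <- sample.int(length(pi), 1L, prob = pi)
      }
      t <- protocol$t_start[k]
      times_all <- c(times_all, t); states_all <- c(states_all, state)
      repeat {
        out <- Q[state, ]; out[state] <- 0
        rr <- sum(out)
        if (rr <= 0) break
        t <- t + stats::rexp(1L, rr)
        if (t >= protocol$t_end[k]) break
        state <- sample.int(length(out), 1L, prob = out)
        times_all <- c(times_all, t); states_all <- c(states_all, state)
      }
    }
    path <- structure(list(times = times_all, states = states_all,
                           duration = total_T, fret_levels = Elevels),
                      class = "state_path")
    Esum <- Esum + frame_average_fret(path, fr, n)
  }
  S <- phys$total_intensity
  a <- phys$crosstalk_alpha
  IA <- S * (Esum + n_receptors * a) / (1 + a)
  ID <- n_receptors * S - IA
  if (phys$noise_sigma > 0) {
    set.seed(derive_seed(seed, 0, 999))
    IA <- IA + stats::rnorm(n, 0, phys$noise_sigma * sqrt(n_receptors))
    ID <- ID + stats::rnorm(n, 0, phys$noise_sigma * sqrt(n_receptors))
  }
  structure(list(time = (seq_len(n) - 0.5) / fr, donor = ID, acceptor = IA,
                 frame_rate = fr, molecule_id = NA_integer_,
                 movie_id = NA_integer_, condition = NULL,
                 truth = list(protocol = protocol,
                              mean_fret = Esum / n_receptors,
                              acceptor_bleach_frame = NA_integer_,
                              donor_bleach_frame = NA_integer_)),
            class = "intensity_trace")
}
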