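test_that("state paths are exact, reproducible and frozen when rates vanish", {
  m0 <- build_preset("mGluR2/2", overrides = list(k_back = 0))
  p <- simulate_state_path(m0, ligand_condition(), duration = 50, seed = 1)
  expect_length(p$states, 1L)             # no rates -> no jumps
  expect_equal(p$times, 0)

  m <- build_preset("mGluR2/2")
  cond <- ligand_condition("glutamate", 1.87e-5)
  p1 <- simulate_state_path(m, cond, 100, seed = 42)
  p2 <- simulate_state_path(m, cond, 100, seed = 42)
  expect_identical(p1, p2)                # determinism contract
  expect_true(all(diff(p1$times) > 0))    # strictly increasing jump times
  expect_error(simulate_state_path(m, cond, 0), "duration")
})

test_that("dwell fractions agree with the stationary distribution (3 SE)", {
  for (spec in list(list(p = "mGluR2/2", conc = 1.87e-5),
                    list(p = "mGluR7/7", conc = 38.3e-3),
                    list(p = "mGluR2/7", conc = 8.4e-6))) {
    m <- build_preset(spec$p)
    cond <- ligand_condition("glutamate", spec$conc)
    pi <- stationary_occupancy(m, cond)
    Tdur <- 10000
    p <- simulate_state_path(m, cond, Tdur, seed = 7)
    d <- diff(c(p$times, Tdur))
    dwell <- vapply(seq_along(pi), function(s) sum(d[p$states == s]) / Tdur,
                    numeric(1))
    # SE of a time average: var ~= 2 * tau_relax * pi * (1 - pi) / T
    tau <- slowest_relaxation_time(m, cond)
    se <- sqrt(2 * tau * pi * (1 - pi) / Tdur)
    expect_true(all(abs(dwell - pi) <= 3 * se + 1e-9), info = spec$p)
  }
})

test_that("rendering inverts the efficiency estimator exactly", {
  # E = 0.45, S = 1000, alpha = 0.1 -> I_A = I_D = 500
  m0 <- build_preset("mGluR2/2", overrides = list(k_back = 0))
  p <- simulate_state_path(m0, ligand_condition(), 2, seed = 1)
  tr <- render_trace(p, phys_clean())
  expect_equal(tr$acceptor, rep(500, 20))
  expect_equal(tr$donor, rep(500, 20))
  expect_equal((tr$acceptor - 0.1 * tr$donor) / (tr$donor + tr$acceptor),
               rep(0.45, 20), tolerance = 1e-15)

  # E = 0 -> I_A = S * alpha / (1 + alpha), estimator returns 0
  path0 <- structure(list(times = 0, states = 1L, duration = 1,
                          fret_levels = 0), class = "state_path")
  tr0 <- render_trace(path0, phys_clean())
  expect_equal(tr0$acceptor, rep(1000 * 0.1 / 1.1, 10))
  expect_equal((tr0$acceptor - 0.1 * tr0$donor) /
                 (tr0$donor + tr0$acceptor), rep(0, 10), tolerance = 1e-15)
})

test_that("noisy rendering is unbiased (3 SE over 1000 frames)", {
  path <- structure(list(times = 0, states = 1L, duration = 100,
                         fret_levels = 0.45), class = "state_path")
  phys <- photophysics_params(noise_sigma = 80, donor_bleach_mean = Inf,
                              acceptor_bleach_mean = Inf)
  tr <- render_trace(path, phys, seed = 3)
  E <- (tr$acceptor - 0.1 * tr$donor) / (tr$donor + tr$acceptor)
  se <- stats::sd(E) / sqrt(length(E))
  expect_lt(abs(mean(E) - 0.45), 3 * se + 0.005)  # + small ratio-bias slack
})

test_that("bleach metadata matches the rendered truncation exactly", {
  path <- structure(list(times = 0, states = 1L, duration = 60,
                         fret_levels = 0.45), class = "state_path")
  phys <- photophysics_params(noise_sigma = 0, donor_bleach_mean = 40,
                              acceptor_bleach_mean = 15)
  found <- 0L
  for (s in 1:20) {
    tr <- render_trace(path, phys, seed = s)
    fa <- tr$truth$acceptor_bleach_frame
    fd <- tr$truth$donor_bleach_frame
    if (!is.na(fa)) {
      found <- found + 1L
      expect_equal(tr$acceptor[fa], 0)
      expect_equal(tr$donor[fa], 1000)        # donor-only emitter
      expect_gt(tr$acceptor[fa - 1L], 100)
    }
    if (!is.na(fd)) {
      expect_equal(tr$donor[fd], 0)
      expect_equal(tr$acceptor[fd], 0)
    }
  }
  expect_gt(found, 5L)
})

test_that("datasets are grouped, tagged and reproducible", {
  m <- build_preset("mGluR2/2")
  phys <- photophysics_params()
  ds <- simulate_dataset(m, ligand_condition("glutamate", 1e-3),
                         n_movies = 5, molecules_per_movie = 8,
                         duration = 20, phys = phys, seed = 9)
  expect_equal(nrow(ds$manifest), 40L)
  expect_equal(sort(unique(ds$manifest$movie_id)), 1:5)
  expect_equal(unname(table(ds$manifest$movie_id)), rep(8L, 5),
               ignore_attr = TRUE)
  ds2 <- simulate_dataset(m, ligand_condition("glutamate", 1e-3),
                          n_movies = 5, molecules_per_movie = 8,
                          duration = 20, phys = phys, seed = 9)
  expect_identical(lapply(ds$traces, `[[`, "donor"),
                   lapply(ds2$traces, `[[`, "donor"))
})

test_that("frame fraction at low FRET tracks the plateau occupancy", {
  m <- build_preset("mGluR2/2")
  cond <- ligand_condition("glutamate", 1e-3)  # a = 0.9816
  ds <- simulate_dataset(m, cond, n_movies = 2, molecules_per_movie = 15,
                         duration = 60, phys = phys_clean(), seed = 4)
  fr_true <- unlist(lapply(ds$traces, function(tr) tr$truth$fret))
  a_truth <- activation_curve(m, 1e-3)
  expect_lt(abs(mean(fr_true < 0.325) - a_truth), 0.02)
})

test_that("ensemble recordings follow the titration protocol", {
  m <- build_preset("mGluR2/2")
  # single step at 0 -> flat trace at the basal ratio
  proto0 <- titration_protocol(c(0, 1e-2), dwell = 15)
  phys <- photophysics_params(frame_rate = 1, noise_sigma = 0,
                              donor_bleach_mean = Inf,
                              acceptor_bleach_mean = Inf)
  tr <- simulate_ensemble_recording(m, proto0, phys, n_receptors = 50,
                                    seed = 2)
  r <- ensemble_fret(tr)
  # basal step: all receptors resting, ratio = (E + alpha) / (1 + alpha)
  expect_equal(r[1:15], rep((0.45 + 0.1) / 1.1, 15), tolerance = 1e-12)

  # ascending steps -> non-increasing plateau ratios (activation lowers FRET)
  proto <- titration_protocol(c(0, 1e-6, 1e-5, 1e-4, 1e-3, 1e-2),
                              dwell = 20)
  tr2 <- simulate_ensemble_recording(m, proto, phys, n_receptors = 300,
                                     seed = 5)
  dr <- delta_fret_response(ensemble_fret(tr2), proto, frame_rate = 1)
  expect_equal(dr$response[1], 0)
  expect_equal(dr$response[nrow(dr)], 1)
  expect_true(all(diff(dr$response) > -0.05))
  # plateau responses match the activation curve oracle (normalized)
  a <- activation_curve(m, proto$concentration)
  expect_equal(dr$response, a / a[length(a)], tolerance = 0.12)
})
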