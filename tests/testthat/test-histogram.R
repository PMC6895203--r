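test_that("per-trace normalization gives equal mass regardless of length", {
  spec <- histogram_spec()
  # one trace entirely inside one bin
  h1 <- compile_histogram(list(fake_fret_trace(rep(0.451, 100))), spec)
  expect_equal(sum(h1$density), 1, tolerance = 1e-9)
  expect_equal(max(h1$density), 1)
  expect_equal(h1$centers[which.max(h1$density)], 0.45, tolerance = 0.011)

  # a 100-frame and a 10,000-frame trace at different levels -> equal peaks
  h2 <- compile_histogram(list(fake_fret_trace(rep(0.45, 100)),
                               fake_fret_trace(rep(0.20, 10000))), spec)
  masses <- vapply(c(0.20, 0.45), function(mu)
    sum(h2$density[abs(h2$centers - mu) < 0.03]), numeric(1))
  expect_equal(masses[1], masses[2], tolerance = 1e-9)
  expect_equal(sum(h2$density), 1, tolerance = 1e-9)

  expect_error(compile_histogram(list(), spec), "no accepted traces")
})

test_that("movie-level SEM shrinks roughly as 1/sqrt(n_movies)", {
  set.seed(71)
  mk_movie <- function(mv, n_traces = 6)
    lapply(seq_len(n_traces), function(i)
      fake_fret_trace(rnorm(400, 0.45, 0.05), movie = mv))
  # resampling: average the per-bin SEM over independent replicates so the
  # noisy SD estimate does not dominate the scaling comparison
  mean_sem <- function(n_movies, reps = 12) {
    mean(vapply(seq_len(reps), function(r) {
      h <- compile_histogram(do.call(c, lapply(seq_len(n_movies), mk_movie)))
      mean(h$sem[h$density > 0.02])
    }, numeric(1)))
  }
  s4 <- mean_sem(4); s16 <- mean_sem(16)
  expect_true(s4 > 0 && s16 > 0)
  expect_lt(s16 / s4, 1)                   # more movies -> smaller SEM
  expect_equal(s16 / s4, 0.5, tolerance = 0.3)
})

test_that("Gaussian decomposition recovers known generators", {
  set.seed(72)
  # single Gaussian, mu = 0.45, sigma = 0.04, 1e5 samples
  tr <- fake_fret_trace(rnorm(1e5, 0.45, 0.04))
  h <- compile_histogram(list(tr))
  cmp1 <- fit_gaussian_mixture(h, n_components = 1L,
                               center_bounds = rbind(c(0.2, 0.55)))
  expect_lt(abs(cmp1[[1]]$center - 0.45), 0.005)
  expect_lt(abs(cmp1[[1]]$width - 0.04) / 0.04, 0.10)

  # well-separated 70/30 mixture -> area fractions within 0.03
  e <- c(rnorm(7e4, 0.45, 0.04), rnorm(3e4, 0.20, 0.04))
  h2 <- compile_histogram(list(fake_fret_trace(e)))
  cmp2 <- fit_gaussian_mixture(h2, n_components = 2L)
  areas <- vapply(cmp2, `[[`, numeric(1), "area")
  centers <- vapply(cmp2, `[[`, numeric(1), "center")
  expect_lt(abs(areas[which.min(centers)] - 0.3), 0.03)
  expect_lt(abs(centers[which.min(centers)] - 0.20), 0.01)
  expect_lt(abs(centers[which.max(centers)] - 0.45), 0.01)

  # empty / degenerate histogram errors
  h_empty <- h
  h_empty$density <- rep(0, length(h_empty$density))
  expect_error(fit_gaussian_mixture(h_empty), "empty")
})

test_that("occupancy extraction from components", {
  mk <- function(center, width, area)
    structure(list(center = center, width = width, area = area),
              class = "gaussian_component")
  occ <- active_state_occupancy(list(mk(0.2, 0.04, 0.25),
                                     mk(0.45, 0.04, 0.75)))
  expect_equal(as.numeric(occ), 0.25)
  expect_equal(attr(occ, "method"), "area")
  occ1 <- active_state_occupancy(list(mk(0.2, 0.05, 1)))
  expect_equal(as.numeric(occ1), 1)       # all mass low
  # single component halfway between references -> 0.5, flagged shift-based
  occ_mid <- active_state_occupancy(list(mk(0.325, 0.05, 1)))
  expect_equal(as.numeric(occ_mid), 0.5)
  expect_equal(attr(occ_mid, "method"), "shift-based")
  expect_error(active_state_occupancy(list()), "no fitted components")
})

test_that("occupancy is stable to bin width (area and shift modes)", {
  set.seed(73)
  e <- c(rnorm(6e4, 0.45, 0.045), rnorm(4e4, 0.20, 0.045))
  occs <- vapply(c(0.01, 0.02, 0.04), function(bw) {
    h <- compile_histogram(list(fake_fret_trace(e)), histogram_spec(bw))
    as.numeric(active_state_occupancy(fit_gaussian_mixture(h, 2L)))
  }, numeric(1))
  expect_lt(max(occs) - min(occs), 0.01)
  shifts <- vapply(c(0.01, 0.02, 0.04), function(bw) {
    h <- compile_histogram(list(fake_fret_trace(e)), histogram_spec(bw))
    as.numeric(shift_occupancy(h))
  }, numeric(1))
  expect_lt(max(shifts) - min(shifts), 0.01)
})

test_that("occupancy matches the CTMC dwell-fraction oracle at saturation", {
  m7 <- build_preset("mGluR7/7")
  cond <- ligand_condition("glutamate", 0.25)   # saturating
  a_truth <- activation_curve(m7, 0.25)
  ds <- simulate_dataset(m7, cond, n_movies = 4, molecules_per_movie = 35,
                         duration = 90, phys = photophysics_params(
                           donor_bleach_mean = 120,
                           acceptor_bleach_mean = 45), seed = 74)
  qc <- qc_dataset(ds)
  fts <- fret_dataset_traces(ds, qc)
  h <- compile_histogram(fts)
  occ <- active_state_occupancy(fit_gaussian_mixture(h, 2L))
  expect_lt(abs(as.numeric(occ) - a_truth), 0.03)
})
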