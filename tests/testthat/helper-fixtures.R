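# Shared fixture builders. Everything is generated in code at test time.

# noiseless photophysics, no bleaching
phys_clean <- function(frame_rate = 10)
  photophysics_params(noise_sigma = 0, donor_bleach_mean = Inf,
                      acceptor_bleach_mean = Inf, frame_rate = frame_rate)

# a two-state model with a fixed (concentration-independent) active
# occupancy, handy for constructing chains with known rates
fixed_occupancy_model <- function(occ, k_back = 1) {
  build_preset("mGluR2/2",
               overrides = list(k_back = k_back,
                                responses = list(glutamate = list(
                                  constant = occ, basal = NULL,
                                  plateau = NULL, phases = NULL))))
}

# minimal fret_trace for histogram tests
fake_fret_trace <- function(E, movie = 1L, molecule = 1L) {
  structure(list(time = seq_along(E) / 10, E = E, E_raw = E, n_masked = 0L,
                 molecule_id = molecule, movie_id = movie,
                 condition = NULL, filtered = FALSE),
            class = "fret_trace")
}

# intensity trace straight from channel vectors
fake_trace <- function(donor, acceptor, frame_rate = 10, movie = 1L,
                       molecule = 1L) {
  structure(list(time = (seq_along(donor) - 0.5) / frame_rate,
                 donor = donor, acceptor = acceptor,
                 frame_rate = frame_rate, molecule_id = molecule,
                 movie_id = movie, condition = NULL,
                 truth = NULL),
            class = "intensity_trace")
}

# brute-force oracle for the step statistic: argmax over all split points of
# |mean(left) - mean(right)| / (sd * sqrt(1/n1 + 1/n2)); independent of the
# recursive implementation
brute_force_split <- function(x, noise_sd, min_seg = 4L) {
  n <- length(x)
  ks <- min_seg:(n - min_seg)
  stat <- vapply(ks, function(k) {
    m1 <- mean(x[1:k]); m2 <- mean(x[(k + 1):n])
    abs(m1 - m2) / (noise_sd * sqrt(1 / k + 1 / (n - k)))
  }, numeric(1))
  list(k = ks[which.max(stat)], stat = max(stat))
}
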