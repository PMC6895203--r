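test_that("presets encode the published state architecture", {
  m22 <- build_preset("mGluR2/2")
  expect_equal(m22$states$fret_level, c(0.45, 0.20))
  expect_equal(m22$states$is_active, c(FALSE, TRUE))
  expect_equal(m22$n_phases, 1L)

  m27 <- build_preset("mGluR2/7")
  expect_equal(nrow(m27$states), 3L)
  expect_equal(m27$states$fret_level, c(0.45, 0.30, 0.20))
  expect_gt(m27$intermediate_basal, 0)   # basal rotated-open occupancy

  expect_error(build_preset("mGluRX/X"), "unknown preset")
  expect_error(build_preset("mGluR2/2", overrides = list(nonsense = 1)),
               "nonexistent parameter")
})

test_that("stationary occupancy solves global balance", {
  # forward = backward (at EC50) -> (0.5, 0.5)
  m <- build_preset("mGluR2/2")
  cond <- ligand_condition("glutamate", m$responses$glutamate$phases$ec50)
  expect_equal(unname(stationary_occupancy(m, cond)), c(0.5, 0.5),
               tolerance = 1e-12)
  Q <- rate_matrix(m, cond)
  expect_equal(Q[1, 2], Q[2, 1])

  # forward 3 / backward 1 -> (0.25, 0.75)
  m31 <- fixed_occupancy_model(0.75, k_back = 1)
  Q <- rate_matrix(m31, ligand_condition("glutamate", 1))
  expect_equal(unname(Q[1, 2]), 3)
  expect_equal(unname(Q[2, 1]), 1)
  expect_equal(unname(stationary_occupancy(m31, ligand_condition("glutamate", 1))),
               c(0.25, 0.75), tolerance = 1e-12)
})

test_that("stationary occupancy matches an independent eigen-solve oracle", {
  # oracle: left null vector of Q via eigen decomposition
  eigen_stationary <- function(Q) {
    e <- eigen(t(Q))
    v <- Re(e$vectors[, which.min(abs(e$values))])
    v / sum(v)
  }
  m7 <- build_preset("mGluR7/7")
  half <- m7$responses$glutamate$phases$ec50   # half-maximal concentration
  for (cond in list(ligand_condition("glutamate", half),
                    ligand_condition("glutamate", 1),
                    ligand_condition())) {
    pi <- stationary_occupancy(m7, cond)
    expect_equal(sum(pi), 1, tolerance = 1e-12)
    expect_equal(unname(pi), eigen_stationary(rate_matrix(m7, cond)),
                 tolerance = 1e-9)
  }
  # at its half-maximal concentration the active occupancy is half the
  # plateau value
  pi <- stationary_occupancy(m7, ligand_condition("glutamate", half))
  expect_equal(unname(pi["Acc"]), m7$responses$glutamate$plateau / 2,
               tolerance = 1e-12)

  m27 <- build_preset("mGluR2/7")
  for (conc in c(0, 8.4e-6, 1e-2)) {
    cond <- ligand_condition("glutamate", conc)
    pi <- stationary_occupancy(m27, cond)
    expect_equal(unname(pi), eigen_stationary(rate_matrix(m27, cond)),
                 tolerance = 1e-9)
  }
})

test_that("activation curves honour limits, monotonicity and shallowness", {
  concs <- 10^seq(-8, 0, length.out = 40)
  for (p in c("mGluR2/2", "mGluR7/7", "mGluR2/7", "mGluR3/7",
              "mGluR2/2-YADA")) {
    m <- build_preset(p)
    a <- activation_curve(m, c(0, concs))
    expect_true(all(diff(a) >= -1e-12), info = p)  # non-decreasing
    expect_true(all(a >= 0 & a <= 1), info = p)
    basal <- m$responses$glutamate$basal
    expect_equal(a[1], if (is.null(basal)) 0 else basal, ignore_attr = TRUE)
  }
  expect_equal(activation_curve(build_preset("mGluR2/2"), 1), 1,
               tolerance = 2e-5)   # saturation
  # basal: 0 for mGluR2/2; >0 intermediate occupancy for mGluR2/7
  expect_equal(activation_curve(build_preset("mGluR2/2"), 0), 0)
  expect_equal(intermediate_curve(build_preset("mGluR2/7"), 0), 0.25)

  # biphasic heterodimer curve spans more log-units from 10% to 90% of range
  span <- function(m) {
    a <- activation_curve(m, concs)
    a <- (a - min(a)) / (max(a) - min(a))
    diff(log10(concs[c(which(a >= 0.1)[1], which(a >= 0.9)[1])]))
  }
  expect_gt(span(build_preset("mGluR2/7")), span(build_preset("mGluR2/2")))

  expect_error(activation_curve(build_preset("mGluR2/2"), numeric(0)),
               "empty")
  expect_error(activation_curve(build_preset("mGluR2/2"), -1), "finite")
})

test_that("double Boltzmann evaluates correctly at the high-affinity EC50", {
  # 0.8 / (1 + 1) + 0.2 / (1 + 9.9e-3 / 8.4e-6) = 0.4001696
  m27 <- build_preset("mGluR2/7")
  expect_equal(activation_curve(m27, 8.4e-6), 0.4001696, tolerance = 1e-6)
})

test_that("antagonist and NAM conditions act on the right transitions", {
  m27 <- build_preset("mGluR2/7")
  apo <- stationary_occupancy(m27, ligand_condition())
  # LY341495 blocks closure only: basal intermediate unchanged
  ly <- stationary_occupancy(m27, ligand_condition("LY341495", 1e-4))
  expect_equal(ly, apo)
  expect_equal(unname(ly["Roo*"]), 0.25)
  # NAMs block rotation: intermediate driven to zero
  nam <- stationary_occupancy(m27, ligand_condition("NAM-combo", 1e-5))
  expect_equal(unname(nam), c(1, 0, 0))
})

test_that("model serialization round-trips through plain text", {
  m <- build_preset("mGluR2/7")
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$states, m$states)
  expect_equal(m2$k_back, m$k_back)
  expect_equal(m2$responses$glutamate$phases, m$responses$glutamate$phases)
  expect_equal(activation_curve(m2, c(0, 1e-5, 1e-2)),
               activation_curve(m, c(0, 1e-5, 1e-2)))
  unlink(path)
})
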