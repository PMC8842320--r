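test_that("hooking fraction counts crossings of the opposing cation plane", {
  ## hand-built frame: 10 chains per layer; exactly 1 SUB cation above the
  ## SUP cation plane -> h = 1/20 = 5%
  sys <- mini_system(10, TRUE, seed = 0, rotated = FALSE)
  pos <- sys$positions
  ca_sub <- which(sys$species == "CA" & sys$layer == 0L)
  ca_sup <- which(sys$species == "CA" & sys$layer == 1L)
  ## flatten the cation planes, then push one SUB cation through
  pos[ca_sub, 3] <- 1.0
  pos[ca_sup, 3] <- 2.0
  pos[ca_sub[3], 3] <- 2.4
  ## the moved bead raises the SUB plane mean; no SUP cation dips below it
  expect_equal(hooking_fraction(sys, positions = pos), 5)
  ## separated layers: h = 0
  expect_equal(hooking_fraction(sys), 0)
  ## invariance under rigid xy translation of one layer
  pos2 <- pos
  sup_rows <- sys$layer == 1L
  pos2[sup_rows, 1] <- pos2[sup_rows, 1] + 0.3
  expect_equal(hooking_fraction(sys, positions = pos2), 5)
  ## margin dz excludes shallow crossings
  expect_equal(hooking_fraction(sys, positions = pos, dz = 0.5), 0)
})

test_that("interlayer distance is the mean rigid-plane separation", {
  sys <- mini4q()
  d0 <- interlayer_distance(sys)
  ztop <- mean(sys$positions[sys$group == 1L, 3])
  expect_equal(d0, ztop)   # SUB plane at z = 0
  pos <- sys$positions
  pos[sys$group == 1L, 3] <- pos[sys$group == 1L, 3] - 0.25
  expect_equal(interlayer_distance(sys, positions = pos), d0 - 0.25)
})

test_that("pearson_rho matches exact and statistical references", {
  u <- sin(seq(0, 20, length.out = 500))
  h <- -2.5 * u + 7
  expect_equal(pearson_rho(u, h), -1, tolerance = 1e-12)
  ## streaming result equals the two-pass textbook formula
  rng <- ionoslip:::.zw_rng(13)
  x <- vapply(1:400, function(i) rng(), 0)
  y <- vapply(1:400, function(i) rng(), 0)
  expect_equal(pearson_rho(x, y), stats::cor(x, y), tolerance = 1e-12)
  ## independent white noise, n = 1e4: |rho| < 0.05
  xb <- vapply(1:10000, function(i) rng(), 0)
  yb <- vapply(1:10000, function(i) rng(), 0)
  expect_lt(abs(pearson_rho(xb, yb)), 0.05)
  ## undefined when a series is constant
  expect_true(is.na(pearson_rho(x, rep(1, 400))))
  expect_error(pearson_rho(x, y[-1]), "lengths differ")
})

test_that("regime classification separates sawtooth from flat traces", {
  flat <- synthetic_trace("flat", n = 500, travel_nm = 10, s = 2)
  expect_equal(classify_regime(flat), "smooth")
  saw <- synthetic_trace("sawtooth", n = 2000, travel_nm = 10, s_max = 4,
                         period_nm = 2)
  expect_equal(classify_regime(saw), "stick-slip")
  ev <- find_slip_events(saw)
  expect_equal(nrow(ev), 5)   # drops at 2, 4, 6, 8 and 10 nm
  expect_true(all(ev$stress_end < 0.5 * ev$stress_peak))
  ## short window -> unconverged
  shorty <- synthetic_trace("flat", n = 10, travel_nm = 0.5)
  expect_equal(classify_regime(shorty), "unconverged")
  ## stability under stride halving
  saw2 <- saw[seq(1, nrow(saw), by = 2), ]
  expect_equal(classify_regime(saw2), "stick-slip")
})

test_that("critical velocity is bracketed between the regimes", {
  v <- c(1, 2, 3, 6, 8)
  regime <- c("stick-slip", "stick-slip", "stick-slip", "smooth", "smooth")
  vc <- critical_velocity(v, regime)
  expect_equal(vc$v_c, 4.5)
  expect_equal(vc$bracket, c(3, 6))
  expect_error(critical_velocity(c(6, 8), c("smooth", "smooth")),
               "not bracketed")
  ## synthetic labels with a known boundary
  v2 <- seq(0.5, 10, by = 0.5)
  r2 <- ifelse(v2 < 4.3, "stick-slip", "smooth")
  vc2 <- critical_velocity(v2, r2)
  expect_lt(abs(vc2$v_c - 4.25), 0.26)
})

test_that("transient-bond and thermal energies match the printed estimates", {
  ## cation between two adjacent anions (0.41 nm) vs flat layer (0.51 nm)
  e <- transient_bond_energy(0.25, 0.41, 0.51)
  expect_equal(e, 2 * 1.44 * 0.0625 * (1 / 0.41 - 1 / 0.51) * 1e3,
               tolerance = 1e-12)
  expect_equal(e, 86.1, tolerance = 0.01)   # "~ 85 meV"
  expect_equal(transient_bond_energy(0, 0.41, 0.51), 0)
  expect_equal(transient_bond_energy(0.25, 0.47, 0.47), 0)
  ## k_B T at 1000 K ~ 86 meV; 0 at 0 K; 25.85 meV at 300 K
  expect_equal(thermal_energy(1000), 86.17, tolerance = 1e-3)
  expect_equal(thermal_energy(0), 0)
  expect_equal(thermal_energy(300), 25.85, tolerance = 1e-3)
})
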