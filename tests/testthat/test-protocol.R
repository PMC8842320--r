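test_that("steady averages of synthetic traces match closed forms", {
  flat <- synthetic_trace("flat", n = 800, travel_nm = 30, s = 2.5)
  s <- steady_average(flat, discard_nm = 20)
  expect_equal(s$mean_stress, 2.5, tolerance = 1e-12)
  expect_equal(s$rms_stress, 0, tolerance = 1e-12)
  expect_equal(s$regime, "smooth")
  expect_true(is.na(s$rho_Uh))

  saw <- synthetic_trace("sawtooth", n = 20000, travel_nm = 40, s_max = 4,
                         period_nm = 1)
  s2 <- steady_average(saw, discard_nm = 20)
  expect_equal(s2$regime, "stick-slip")
  expect_equal(s2$mean_stress, 2, tolerance = 0.01)          # s_max / 2
  expect_equal(s2$rms_stress, 4 / sqrt(12), tolerance = 0.01)
  ## U anticorrelates with h by construction of the sawtooth fixture
  expect_equal(s2$rho_Uh, -1, tolerance = 1e-9)
})

test_that("the discard rule retains only the steady window", {
  saw <- synthetic_trace("sawtooth", n = 4000, travel_nm = 40, s_max = 4,
                         period_nm = 3)
  s <- steady_average(saw, discard_nm = 20)
  ## retained window starts after max(20 nm, first slip)
  expect_gte(s$window_nm[1], 20)
  s5 <- steady_average(saw, discard_nm = 5)
  ## with a small discard, the window still starts after the first slip
  expect_gte(s5$window_nm[1], 3)
})

test_that("run plan travel maps to the documented duration", {
  ## 100 nm at 5 m/s = 5 nm/ns -> 20 ns of trajectory
  n <- ionoslip:::.nm_to_steps(100, 5, 1e-3)
  expect_equal(n * 1e-3, 20000, tolerance = 1e-9)  # ps
})

test_that("widely separated layers slide freely at zero stress", {
  ## free sliding: huge gap, zero temperature, zero load; the body starts
  ## at the stage velocity so the undamped spring is never excited
  sc <- find_commensurate_supercell(0.82, c(15, 25), 4, 1e-3)
  sys <- assemble_system(sc, charge_on = FALSE, initial_gap = 3.0, seed = 1)
  ff <- default_forcefield()
  st <- init_state(sys, temperature = 0, seed = 1)
  ## relax the chains first so the spring never feels the assembly
  ## transient, then start the body at the stage velocity
  st <- run_md(st, ff, nsteps = 40000, dt = 1e-3, temperature = 0,
               gamma = 2, drive = "none", sample_every = 40000)$state
  ## the whole upper half starts at the stage velocity: no transient
  st$body_vel <- c(20 * zw_units$nmps_per_ms, 0, 0)
  upper <- sys$layer == 1L & sys$group == 2L
  st$velocities[upper, 1] <- 20 * zw_units$nmps_per_ms
  st$forces <- NULL   # recompute with the new velocities
  r <- run_md(st, ff, nsteps = 100000, dt = 1e-3,
              temperature = 0, gamma = 1, v_stage = 20, load = 0,
              drive = "spring", stage0 = st$body_x, sample_every = 200)
  s <- steady_average(r$trace, discard_nm = 0.2)
  expect_lt(abs(s$mean_stress), 0.05)
  expect_equal(s$regime, "smooth")
})

test_that("averages are stable against the output stride", {
  saw <- synthetic_trace("sawtooth", n = 20000, travel_nm = 40, s_max = 4,
                         period_nm = 1)
  s1 <- steady_average(saw, discard_nm = 20)
  saw2 <- saw[seq(1, nrow(saw), by = 2), ]
  s2 <- steady_average(saw2, discard_nm = 20)
  expect_equal(s1$mean_stress, s2$mean_stress, tolerance = 0.01)
  expect_equal(s1$rms_stress, s2$rms_stress, tolerance = 0.01)
})

test_that("configuration files round-trip through YAML", {
  cfg <- default_config()
  f <- tempfile(fileext = ".yml")
  yaml::write_yaml(list(plan = list(temperature = 150, v_stage = 2)), f)
  got <- read_config(f)
  expect_equal(got$plan$temperature, 150)
  expect_equal(got$plan$v_stage, 2)
  expect_equal(got$plan$load, cfg$plan$load)       # default preserved
  expect_equal(got$system$molecule_spacing, 0.82)
  unlink(f)
})
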