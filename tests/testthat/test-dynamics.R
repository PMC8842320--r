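ff <- default_forcefield()

test_that("zero-temperature damped dynamics dissipates energy", {
  sys <- mini_system(2, FALSE, seed = 0)
  st <- init_state(sys, temperature = 300, seed = 4)  # kick it, then damp
  r <- run_md(st, ff, nsteps = 20000, dt = 1e-3, temperature = 0, gamma = 1,
              drive = "none", sample_every = 500)
  e <- r$trace$U + r$trace$ke
  ## total energy non-increasing under pure friction (no noise), up to
  ## integrator shadow noise
  expect_true(all(diff(e) < 0.01))
  expect_lt(e[length(e)], e[1] - 1)
  ## transverse kinetic energy decays towards zero
  expect_lt(r$trace$T_inst[length(r$trace$T_inst)],
            0.05 * max(r$trace$T_inst))
})

test_that("Langevin thermostat reaches its target on the damped DOFs", {
  sys <- mini_system(2, FALSE, seed = 0)
  st <- init_state(sys, temperature = 300, seed = 4)
  ## discard 50 ps, then average 200 ps
  st <- run_md(st, ff, nsteps = 50000, dt = 1e-3, temperature = 300,
               gamma = 1, drive = "none", sample_every = 50000)$state
  r <- run_md(st, ff, nsteps = 200000, dt = 1e-3, temperature = 300,
              gamma = 1, drive = "none", sample_every = 100)
  expect_equal(mean(r$trace$T_inst), 300, tolerance = 0.1)
})

test_that("SUP rigid body follows constant-force kinematics exactly", {
  ## strip the system down to the SUP rigid layer only and push it with a
  ## normal load: velocity Verlet is exact for constant force
  sys <- mini_system(4, FALSE, seed = 0)
  keep <- sys$group == 1L
  sup <- sys
  sup$positions <- sys$positions[keep, , drop = FALSE]
  for (f in c("species", "type", "layer", "group", "charge", "mass",
              "mol_id", "chainpos"))
    sup[[f]] <- sys[[f]][keep]
  sup$bonds <- matrix(integer(0), 0, 2); sup$bond_k <- sup$bond_r0 <- numeric(0)
  sup$angles <- matrix(integer(0), 0, 3); sup$angle_k <- sup$angle_theta0 <- numeric(0)
  st <- init_state(sup, temperature = 0, seed = 1)
  load_mpa <- 10
  nst <- 1000; dt <- 1e-3
  r <- run_md(st, ff, nsteps = nst, dt = dt, temperature = 0, gamma = 0,
              load = load_mpa, drive = "none", sample_every = nst)
  A <- sup$box[[1]] * sup$box[[2]]
  Fz <- -load_mpa / zw_units$mpa_per_evnm3 * A
  M <- sum(sup$mass) * zw_units$amu
  t <- nst * dt
  dz_expect <- 0.5 * Fz / M * t^2
  dz <- mean(r$state$positions[, 3]) - mean(sup$positions[, 3])
  expect_equal(dz, dz_expect, tolerance = 1e-10)
  ## zero net force -> uniform motion
  st2 <- init_state(sup, temperature = 0, seed = 1)
  st2$body_vel <- c(0.1, 0, 0)
  r2 <- run_md(st2, ff, nsteps = 500, dt = dt, temperature = 0, gamma = 0,
               drive = "none", sample_every = 500)
  expect_equal(r2$state$body_x - st2$body_x, 0.1 * 500 * dt, tolerance = 1e-12)
})

test_that("SUB layer beads never move", {
  sys <- mini4q()
  st <- init_state(sys, temperature = 300, seed = 4)
  r <- run_md(st, ff, nsteps = 2000, dt = 1e-3, temperature = 300, gamma = 1,
              v_stage = 5, load = 10, drive = "spring", sample_every = 1000,
              kspace_every = 5)
  frozen <- sys$group == 0L
  expect_identical(r$state$positions[frozen, ], sys$positions[frozen, ])
  expect_true(all(r$state$velocities[frozen, ] == 0))
})

test_that("spring elongation maps to the documented shear stress", {
  ## elongation 1 nm with k = 1 eV/nm^2 over the reference cell area
  A <- 8.32 * 14.41   # 119.9 nm^2
  stress <- 1 * 1 / A * zw_units$mpa_per_evnm3
  expect_equal(stress, 1.336, tolerance = 1e-3)
  ## and the per-metre stiffness quoted for the experiment: 1.34e9 MPa/m
  expect_equal(stress * 1e9 / 1e9, 1.336, tolerance = 1e-3)
})

test_that("runs restart bit-identically from a state snapshot", {
  sys <- mini4q()
  st0 <- init_state(sys, temperature = 300, seed = 9)
  one <- run_md(st0, ff, nsteps = 400, dt = 1e-3, temperature = 300,
                gamma = 1, v_stage = 5, load = 10, drive = "spring",
                stage0 = st0$body_x, sample_every = 100, kspace_every = 5)
  a <- run_md(st0, ff, nsteps = 200, dt = 1e-3, temperature = 300,
              gamma = 1, v_stage = 5, load = 10, drive = "spring",
              stage0 = st0$body_x, sample_every = 100, kspace_every = 5)
  b <- run_md(a$state, ff, nsteps = 200, dt = 1e-3, temperature = 300,
              gamma = 1, v_stage = 5, load = 10, drive = "spring",
              stage0 = a$state$stage, sample_every = 100, kspace_every = 5)
  expect_identical(one$state$positions, b$state$positions)
  expect_identical(one$state$velocities, b$state$velocities)
  expect_identical(one$state$body_vel, b$state$body_vel)
  ## traces agree sample by sample
  expect_identical(one$trace$stress,
                   c(a$trace$stress, b$trace$stress))
})

test_that("x-momentum change equals the integrated external impulse", {
  sys <- mini4n()
  st <- init_state(sys, temperature = 200, seed = 4)
  m_int <- sys$mass * zw_units$amu
  px <- function(s) {
    mob <- sys$group == 2L
    sum(m_int[mob] * s$velocities[mob, 1]) +
      sum(m_int[sys$group == 1L]) * s$body_vel[1]
  }
  p0 <- px(st)
  r <- run_md(st, ff, nsteps = 5000, dt = 1e-3, temperature = 200, gamma = 0,
              v_stage = 5, load = 5, drive = "spring", stage0 = st$body_x,
              sample_every = 5000)
  p1 <- px(r$state)
  imp <- unname(r$state$last_impulse["spring_x"] -
                r$state$last_impulse["frozen_x"])
  ## the accumulator integrates with the rectangle rule, the half-kick
  ## scheme with the trapezoid rule: they differ by dt/2 (F_0 - F_N),
  ## where the substrate reaction force fluctuates by tens of eV/nm
  edge <- 0.5 * 1e-3 * 2 * 40
  expect_equal(p1 - p0, imp, tolerance = edge / max(1, abs(imp)))
})
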