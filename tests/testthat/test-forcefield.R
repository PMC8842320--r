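ff <- default_forcefield()

test_that("harmonic bond energy matches the closed form and its gradient", {
  ## CA-R1 bond stretched to 0.17 nm: E = k/2 (r - r_eq)^2 with k the
  ## literal second derivative (480 N/m = 2995.9 eV/nm^2)
  sys <- mini4q()
  e0 <- bond_energy_forces(sys)$energy
  expect_lt(abs(e0), 1e-8)   # built at equilibrium... except anchor tethers
  k_ev <- 480 * zw_units$evnm2_per_Nm
  expect_equal(0.5 * k_ev * (0.17 - 0.16)^2, 0.1497955, tolerance = 1e-4)
  ## stretch the first CA-R1 bond along z and compare force to gradient
  pos <- sys$positions
  pos[1, 3] <- pos[1, 3] + 0.01
  bf <- bond_energy_forces(sys, positions = pos)
  efun <- function(p) bond_energy_forces(sys, positions = p)$energy
  for (k in 1:3) {
    fn <- numgrad_force(efun, pos, 1, k)
    expect_equal(bf$forces[1, k], fn, tolerance = 1e-6 * max(1, abs(fn)))
  }
  ## Newton's third law for the bond pair
  expect_equal(bf$forces[1, ] + bf$forces[2, ], c(0, 0, 0), tolerance = 1e-9)
})

test_that("angle term is zero at equilibrium and restores towards it", {
  sys <- mini4q()
  e0 <- angle_energy_forces(sys)$energy
  expect_lt(abs(e0), 1e-10)
  ## bend the NP2-NP1-AN kink: move the AN bead of molecule 1
  pos <- sys$positions
  pos[5, 1] <- pos[5, 1] + 0.05
  af <- angle_energy_forces(sys, positions = pos)
  expect_gt(af$energy, 0)
  efun <- function(p) angle_energy_forces(sys, positions = p)$energy
  for (i in c(5, 6, 7)) {
    for (k in 1:3) {
      fn <- numgrad_force(efun, pos, i, k)
      expect_equal(af$forces[i, k], fn, tolerance = 1e-5 * max(1, abs(fn)))
    }
  }
  ## translational invariance: the angle forces sum to zero overall
  ## (each triplet's forces cancel; atoms are shared between triplets)
  expect_equal(colSums(af$forces), c(0, 0, 0), tolerance = 1e-9)
  ## a line-search along the forces lowers the energy
  e1 <- af$energy
  e2 <- angle_energy_forces(sys, positions = pos + 1e-4 * af$forces)$energy
  expect_lt(e2, e1)
})

test_that("shifted Morse vanishes smoothly at the cutoff", {
  m <- morse_energy_force(c(0.999999, 1, 1.2), 0.010, 0.41)
  expect_equal(m$energy[2], 0)
  expect_equal(m$force[2], 0)
  expect_lt(abs(m$energy[1]), 1e-9)
  expect_lt(abs(m$force[1]), 1e-4)
  expect_equal(m$energy[3], 0)
  ## closed form at the minimum: V(r0) = -D0 - M(Rc) - (r0 - Rc) M'(Rc)
  D0 <- 0.010; r0 <- 0.41; al <- 15; rc <- 1
  M <- function(x) D0 * ((1 - exp(-al * (x - r0)))^2 - 1)
  dM <- function(x) 2 * D0 * al * exp(-al * (x - r0)) * (1 - exp(-al * (x - r0)))
  v <- morse_energy_force(r0, D0, r0)
  expect_equal(v$energy, M(r0) - M(rc) - (r0 - rc) * dM(rc), tolerance = 1e-12)
  ## force equals -dV/dr by central difference
  h <- 1e-6
  vp <- morse_energy_force(0.5 + h, D0, r0)$energy
  vm <- morse_energy_force(0.5 - h, D0, r0)$energy
  expect_equal(morse_energy_force(0.5, D0, r0)$force, -(vp - vm) / (2 * h),
               tolerance = 1e-6)
  ## masked pair contributes nothing
  expect_true(all(morse_energy_force(seq(0.2, 1.2, by = 0.1), 0, 0.41)$energy == 0))
})

test_that("isolated charge pair reproduces the bare Coulomb energy", {
  ## +-0.25 e at 0.41 nm: E = -kC q^2 / r = -0.2195 eV
  pos <- rbind(c(0, 0, 0), c(0, 0, 0.41))
  e <- coulomb_direct(pos, c(0.25, -0.25))
  expect_equal(e, -1.4400 * 0.0625 / 0.41, tolerance = 1e-12)
  expect_equal(e, -0.2195, tolerance = 1e-4)
})

test_that("Ewald splitting reproduces the direct periodic lattice sum", {
  pos <- rbind(c(0.3, 0.4, 0.0), c(0.5, 0.4, 0.45),
               c(1.4, 1.1, 0.2), c(1.6, 1.5, 0.6))
  q <- c(0.25, -0.25, 0.25, -0.25)
  sys <- charge_cluster(pos, q, 2.1, 1.9)
  oracle <- direct_coulomb_2d(pos, q, 2.1, 1.9, nmax = 50)
  ew <- ewald_setup(sys, ff)
  er <- coulomb_real_space(sys, ff, ewald = ew)
  ek <- coulomb_reciprocal(sys, ff, ewald = ew)
  expect_lt(abs(er$energy + ek$energy - oracle$e), 1e-4)
  expect_lt(max(abs(er$forces + ek$forces - oracle$f)), 1e-4)
})

test_that("Ewald total is invariant under the splitting parameter", {
  pos <- rbind(c(0.3, 0.4, 0.0), c(0.5, 0.4, 0.45),
               c(1.4, 1.1, 0.2), c(1.6, 1.5, 0.6))
  q <- c(0.25, -0.25, 0.25, -0.25)
  sys <- charge_cluster(pos, q, 2.1, 1.9)
  etotal <- function(acc) {
    f2 <- default_forcefield(ewald_accuracy = acc)
    ew <- ewald_setup(sys, f2)
    coulomb_real_space(sys, f2, ewald = ew)$energy +
      coulomb_reciprocal(sys, f2, ewald = ew)$energy
  }
  ## accuracy from 1e-3 to 1e-6 changes alpha by ~1.3x and the k cutoff a lot
  es <- vapply(c(1e-3, 1e-4, 1e-5, 1e-6), etotal, 0)
  expect_lt(max(es) - min(es), 1e-4)
})

test_that("isolated dipole pair approaches the open-boundary energy in a large box", {
  pos <- rbind(c(0, 0, 0), c(0, 0, 0.41), c(0.9, 0, 0.1), c(0.9, 0, 0.51))
  q <- c(0.25, -0.25, 0.25, -0.25)
  eopen <- coulomb_direct(pos, q)
  for (L in c(6, 12)) {
    sys <- charge_cluster(pos, q, L, L)
    ew <- ewald_setup(sys, ff)
    e <- coulomb_real_space(sys, ff, ewald = ew)$energy +
         coulomb_reciprocal(sys, ff, ewald = ew)$energy
    if (L == 6) e6 <- e else e12 <- e
  }
  expect_lt(abs(e12 - eopen), abs(e6 - eopen) + 1e-9)
  expect_lt(abs(e12 - eopen), 2e-4)
})

test_that("charge-free system has zero electrostatic terms", {
  sys <- mini4n()
  ev <- total_energy_forces(sys, ff)
  expect_equal(unname(ev$breakdown["coul_real"]), 0)
  expect_equal(unname(ev$breakdown["coul_recip"]), 0)
})

test_that("total energy matches the O(N^2) brute-force oracle", {
  sys <- mini4n()   # charge-free: oracle covers bonds, angles, Morse
  ## perturb positions so no term sits at equilibrium
  rng <- ionoslip:::.zw_rng(5)
  pos <- sys$positions +
    0.02 * matrix(vapply(seq_len(3 * nrow(sys$positions)),
                         function(i) rng() - 0.5, 0), ncol = 3)
  ev <- total_energy_forces(sys, ff, positions = pos)
  oracle <- brute_force_energy(sys, ff, positions = pos)
  expect_equal(ev$U, oracle$total, tolerance = 1e-9)
  expect_equal(unname(ev$breakdown["bond"]), oracle$bond, tolerance = 1e-9)
  expect_equal(unname(ev$breakdown["angle"]), oracle$angle, tolerance = 1e-9)
  expect_equal(unname(ev$breakdown["morse"] + ev$breakdown["rigid_rigid"]),
               oracle$morse, tolerance = 1e-9)
})

test_that("every force component equals the gradient of the total energy", {
  sys <- mini4q()
  rng <- ionoslip:::.zw_rng(7)
  pos <- sys$positions +
    0.01 * matrix(vapply(seq_len(3 * nrow(sys$positions)),
                         function(i) rng() - 0.5, 0), ncol = 3)
  ew <- ewald_setup(sys, ff, positions = pos)
  ev <- total_energy_forces(sys, ff, positions = pos, ewald = ew)
  efun <- function(p) total_energy_forces(sys, ff, positions = p, ewald = ew)$U
  idx <- c(1, 5, 7, 30, 45)   # CA, AN, NP2 of molecule 1, and others
  for (i in idx) {
    for (k in 1:3) {
      fn <- numgrad_force(efun, pos, i, k, h = 2e-6)
      expect_equal(ev$forces[i, k], fn,
                   tolerance = 1e-5 * max(1, abs(fn)))
    }
  }
})

test_that("rigid-layer cross pairs are masked to zero", {
  ## moving a SUP rigid bead near a SUB rigid bead leaves U unchanged
  sys <- mini4n()
  i <- which(sys$group == 1L)[1]
  sub_rigid <- which(sys$group == 0L)[1]
  pos <- sys$positions
  ## park the SUP rigid bead at two depths right above a SUB rigid bead
  ## (0.42 and 0.45 nm: deep inside the Morse range); with the SUB-SUP
  ## well masked to zero the energy difference must come exclusively from
  ## same-layer terms, which the independent oracle reproduces
  pos2 <- pos; pos2[i, ] <- pos[sub_rigid, ] + c(0, 0, 0.45)
  pos3 <- pos; pos3[i, ] <- pos[sub_rigid, ] + c(0, 0, 0.42)
  e2 <- total_energy_forces(sys, ff, positions = pos2)$U
  e3 <- total_energy_forces(sys, ff, positions = pos3)$U
  o2 <- brute_force_energy(sys, ff, positions = pos2)$total
  o3 <- brute_force_energy(sys, ff, positions = pos3)$total
  expect_equal(e3 - e2, o3 - o2, tolerance = 1e-9)
})

test_that("net in-plane force vanishes without external drive", {
  sys <- mini14q()
  ev <- total_energy_forces(sys, ff)
  expect_lt(abs(sum(ev$forces[, 1])), 1e-8)
  expect_lt(abs(sum(ev$forces[, 2])), 1e-8)
})
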