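test_that("molecule template obeys its invariants", {
  tpl <- molecule_template(TRUE)
  expect_length(tpl$species, 7)
  expect_equal(sum(tpl$charge), 0)
  expect_equal(tpl$charge[1], 0.25)
  expect_equal(tpl$charge[5], -0.25)
  expect_equal(tpl$mass, c(60, 15, 15, 15, 80, 50, 50))
  expect_equal(nrow(tpl$bonds), 6)
  expect_equal(nrow(tpl$angles), 5)
  expect_equal(tpl$angle_theta0, c(180, 180, 180, 180, 111))
  expect_equal(tpl$bond_r0[6], 0.67)   # the long NP1-NP2 bond
  tpl0 <- molecule_template(FALSE)
  expect_true(all(tpl0$charge == 0))
})

test_that("assembled reference-size system has the right composition", {
  sc <- find_commensurate_supercell(0.82, c(15, 25), 15, 1e-3,
                                    target_dims = c(8.32, 14.41))
  sys <- assemble_system(sc, charge_on = TRUE, seed = 1)
  expect_equal(nrow(sys$positions), 2L * (206L * 7L + 824L))  # 4532
  expect_equal(sum(sys$charge), 0)
  expect_equal(areal_density(sys), 1.72, tolerance = 0.005)
  ## density invariant: 2 / (sqrt(3) a^2)
  expect_equal(areal_density(sys), 2 / (sqrt(3) * 0.82^2), tolerance = 0.005)
})

test_that("mini systems obey counts, charge neutrality and determinism", {
  sys <- mini4q()
  expect_equal(nrow(sys$positions), 88L)        # 2 (4*7 + 16)
  expect_equal(sum(sys$charge), 0)
  expect_equal(sum(sys$group == 0L), 16L)
  expect_equal(sum(sys$group == 1L), 16L)
  ## same seed, bit-identical
  again <- mini_system(4, TRUE, seed = 0)
  expect_identical(again$positions, sys$positions)
  ## charge-free control: identical geometry, all charges zero
  sysn <- mini4n()
  expect_identical(sysn$positions, sys$positions)
  expect_true(all(sysn$charge == 0))
})

test_that("both layers carry the same molecule count and mirror structure", {
  sys <- mini14q()
  expect_equal(sum(sys$layer == 0L & sys$group == 2L),
               sum(sys$layer == 1L & sys$group == 2L))
  ## before dynamics, SUB and SUP bead z-values are mirror images
  zs <- sys$positions[sys$layer == 0L & sys$group == 2L, 3]
  zp <- sys$positions[sys$layer == 1L & sys$group == 2L, 3]
  ztop <- max(sys$positions[sys$group == 1L, 3])
  expect_equal(sort(zs), sort(ztop - zp), tolerance = 1e-9)
})

test_that("assembly rejects overlapping configurations", {
  sys <- mini4q()
  expect_gt(ionoslip:::.min_pair_distance(sys$positions,
                                          sys$box[[1]], sys$box[[2]]), 0.15)
})

test_that("extended-XYZ round trip preserves coordinates", {
  sys <- mini4q()
  f <- tempfile(fileext = ".xyz")
  write_extxyz(sys, f)
  back <- read_extxyz(f)
  expect_equal(back$positions, unname(sys$positions), tolerance = 1e-9)
  expect_equal(back$species, sys$species)
  expect_equal(back$charge, sys$charge, tolerance = 1e-9)
  expect_equal(unname(back$box[1:2]), unname(sys$box), tolerance = 1e-6)
  unlink(f)
})

test_that("LAMMPS data file reports the full topology", {
  sys <- mini4q()
  f <- tempfile(fileext = ".data")
  write_lammps_data(sys, f)
  lines <- readLines(f)
  expect_true(sprintf("%d atoms", nrow(sys$positions)) %in% lines)
  expect_true(sprintf("%d bonds", nrow(sys$bonds)) %in% lines)
  expect_true(sprintf("%d angles", nrow(sys$angles)) %in% lines)
  unlink(f)
})

test_that("trace CSV round trip preserves the data and units metadata", {
  tr <- synthetic_trace("sawtooth", n = 64, travel_nm = 4, s_max = 3,
                        period_nm = 1)
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  expect_true(startsWith(readLines(f, n = 1), "#"))
  back <- read_trace_csv(f)
  expect_equal(back$stress, tr$stress, tolerance = 1e-9)
  expect_equal(attr(back, "v_stage_ms"), attr(tr, "v_stage_ms"))
  unlink(f)
})
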