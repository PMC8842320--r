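test_that("commensuration search recovers the reference rotated supercell", {
  sc <- find_commensurate_supercell(0.82, c(15, 25), 15, 1e-3,
                                    target_dims = c(8.32, 14.41))
  expect_equal(sc$phi, 19.65, tolerance = 1e-3)
  expect_equal(sc$l_x, 8.32, tolerance = 1e-3)
  expect_equal(sc$l_y, 14.41, tolerance = 1e-3)
  expect_equal(sc$n_mol_per_layer, 206L)
  expect_lt(sc$strain, 1e-6)
})

test_that("aligned lattices admit the minimal rectangular cell", {
  sc <- find_commensurate_supercell(0.82, c(0, 5), 2, 1e-3)
  expect_equal(sc$phi, 0)
  expect_equal(sc$l_x, 0.82, tolerance = 1e-9)
  expect_equal(sc$l_y, 0.82 * sqrt(3), tolerance = 1e-9)
})

test_that("search fails explicitly when no commensurate cell fits", {
  expect_error(find_commensurate_supercell(0.82, c(19, 20), 2, 1e-6),
               "no commensurate cell")
})

test_that("returned cells are verified commensurate by brute-force overlap", {
  ## oracle: translating every lattice point by each cell vector must land
  ## on a lattice point of the same rotated lattice
  sc <- find_commensurate_supercell(1.0, c(15, 25), 18, 1e-3)
  a <- 1.0
  th <- sc$phi / 2 * pi / 180
  for (sgn in c(-1, 1)) {
    R <- rbind(c(cos(sgn * th), -sin(sgn * th)),
               c(sin(sgn * th), cos(sgn * th)))
    ## lattice points within a disc
    span <- 30
    ij <- as.matrix(expand.grid(-span:span, -span:span))
    pts <- ij %*% rbind(c(a, 0), c(a / 2, a * sqrt(3) / 2)) %*% t(R)
    ## map a point back to fractional lattice coordinates (columns of B are
    ## the rotated basis vectors)
    B <- R %*% t(rbind(c(a, 0), c(a / 2, a * sqrt(3) / 2)))
    to_frac <- function(p) solve(B, p)
    for (cellvec in list(c(sc$l_x, 0), c(0, sc$l_y))) {
      some <- pts[sample.int(nrow(pts), 50), , drop = FALSE]
      fr <- apply(some, 1, function(p) to_frac(p + cellvec))
      expect_lt(max(abs(fr - round(fr))), 1e-6)
    }
  }
})

test_that("build_layer places rigid beads and anchors with the right counts", {
  sc <- find_commensurate_supercell(0.82, c(15, 25), 15, 1e-3,
                                    target_dims = c(8.32, 14.41))
  lay <- build_layer(sc, "SUB", 0)
  expect_equal(nrow(lay$rigid), 824L)
  expect_equal(nrow(lay$anchors), 206L)
  ## minimal aligned cell: the 4 rigid nodes per anchor ratio
  sc0 <- find_commensurate_supercell(0.82, c(0, 5), 2, 1e-3)
  lay0 <- build_layer(sc0, "SUB", 0)
  expect_equal(nrow(lay0$rigid), 4L * nrow(lay0$anchors))
})

test_that("anchor nearest-neighbour distance equals the molecule spacing", {
  sc <- find_commensurate_supercell(0.82, c(15, 25), 5, 1e-3)
  for (which in c("SUB", "SUP")) {
    lay <- build_layer(sc, which, 0)
    anc <- lay$anchors
    nn <- rep(Inf, nrow(anc))
    for (i in seq_len(nrow(anc))) {
      for (j in seq_len(nrow(anc))[-i]) {
        dx <- anc[i, 1] - anc[j, 1]; dx <- dx - sc$l_x * round(dx / sc$l_x)
        dy <- anc[i, 2] - anc[j, 2]; dy <- dy - sc$l_y * round(dy / sc$l_y)
        nn[i] <- min(nn[i], sqrt(dx^2 + dy^2))
      }
    }
    expect_equal(max(abs(nn - 0.82)), 0, tolerance = 1e-6)
  }
})

test_that("rigid layers are periodic in the supercell", {
  sc <- find_commensurate_supercell(0.82, c(15, 25), 5, 1e-3)
  lay <- build_layer(sc, "SUP", 0)
  pts <- lay$rigid[, 1:2]
  ## translating any bead by a cell vector must land on a bead (mod box)
  key <- function(p) paste(round((p[, 1] %% sc$l_x) * 1e5),
                           round((p[, 2] %% sc$l_y) * 1e5))
  have <- key(pts)
  for (shift in list(c(sc$l_x, 0), c(0, sc$l_y))) {
    moved <- sweep(pts, 2, -shift)
    expect_true(all(key(moved) %in% have))
  }
})
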