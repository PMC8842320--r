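## Shared fixtures and independent oracles for the test suite.
## Fixture seeds are fixed at 0; dynamics seeds are small fixed integers.

## memoised fixtures (assembly is deterministic, this just saves time)
.fixture_cache <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

mini4q <- function() fixture("mini4q", function() mini_system(4, TRUE, seed = 0))
mini4n <- function() fixture("mini4n", function() mini_system(4, FALSE, seed = 0))
mini14q <- function() fixture("mini14q", function() mini_system(14, TRUE, seed = 0))
mini14n <- function() fixture("mini14n", function() mini_system(14, FALSE, seed = 0))

## hand-built bare charge cluster as a zw_system (no bonds, no rigid layers)
charge_cluster <- function(pos, q, lx, ly) {
  n <- nrow(pos)
  s <- list(positions = pos, species = rep("CA", n), type = rep(1L, n),
            layer = rep(0L, n), group = rep(2L, n), charge = q,
            mass = rep(60, n), mol_id = seq_len(n),
            chainpos = rep(0L, n),
            bonds = matrix(integer(0), 0, 2), bond_k = numeric(0),
            bond_r0 = numeric(0),
            angles = matrix(integer(0), 0, 3), angle_k = numeric(0),
            angle_theta0 = numeric(0),
            box = c(lx = lx, ly = ly), n_mol_per_layer = 0L,
            charge_on = TRUE)
  class(s) <- "zw_system"
  s
}

## Direct 2D-periodic Coulomb lattice sum (xy images, open z), Richardson-
## extrapolated in the image radius: energies have a 1/R tail, forces 1/R^2.
direct_coulomb_2d <- function(pos, q, lx, ly, nmax = 60) {
  one <- function(nm) {
    kC <- zw_units$kC
    n <- nrow(pos)
    e <- 0
    f <- matrix(0, n, 3)
    for (ix in -nm:nm) for (iy in -nm:nm) {
      for (i in 1:n) for (j in 1:n) {
        if (ix == 0 && iy == 0 && i == j) next
        d <- pos[i, ] - pos[j, ] + c(ix * lx, iy * ly, 0)
        r <- sqrt(sum(d^2))
        e <- e + 0.5 * kC * q[i] * q[j] / r
        f[i, ] <- f[i, ] + kC * q[i] * q[j] * d / r^3
      }
    }
    list(e = e, f = f)
  }
  a <- one(nmax)
  b <- one(2 * nmax)
  ## both tails behave as c/R for this square image cut
  list(e = b$e + (b$e - a$e),
       f = b$f + (b$f - a$f))
}

## Brute-force O(N^2) total-energy oracle implementing the interaction
## masks directly (no neighbour list): harmonic bonds/angles, shifted
## Morse with the head-bead cross-layer restriction, multi-image xy
## periodicity.  Coulomb excluded (use charge-free fixtures).
brute_force_energy <- function(sys, ff = default_forcefield(),
                               positions = NULL) {
  pos <- if (is.null(positions)) sys$positions else positions
  lx <- sys$box[[1]]; ly <- sys$box[[2]]
  n <- nrow(pos)
  ## bonds
  eb <- 0
  for (b in seq_len(nrow(sys$bonds))) {
    i <- sys$bonds[b, 1]; j <- sys$bonds[b, 2]
    d <- pos[i, ] - pos[j, ]
    d[1] <- d[1] - lx * round(d[1] / lx); d[2] <- d[2] - ly * round(d[2] / ly)
    r <- sqrt(sum(d^2))
    eb <- eb + 0.5 * sys$bond_k[b] * zw_units$evnm2_per_Nm *
          (r - sys$bond_r0[b])^2
  }
  ## angles
  ea <- 0
  for (b in seq_len(nrow(sys$angles))) {
    i <- sys$angles[b, 1]; j <- sys$angles[b, 2]; k <- sys$angles[b, 3]
    d1 <- pos[i, ] - pos[j, ]; d2 <- pos[k, ] - pos[j, ]
    for (dd in 1:2) {
      L <- c(lx, ly)[dd]
      d1[dd] <- d1[dd] - L * round(d1[dd] / L)
      d2[dd] <- d2[dd] - L * round(d2[dd] / L)
    }
    cth <- sum(d1 * d2) / sqrt(sum(d1^2) * sum(d2^2))
    th <- acos(pmin(1, pmax(-1, cth)))
    ea <- ea + 0.5 * sys$angle_k[b] * (th - sys$angle_theta0[b] * pi / 180)^2
  }
  ## pairwise Morse with masks and multi-image periodicity; the
  ## interaction rules are restated here independently of the package's
  ## table builder
  pair_params <- function(si, sj, same_layer) {
    if (!same_layer) {
      heads <- c("CA", "R1", "R2", "R3", "AN")
      if (si %in% heads && sj %in% heads) return(c(0.010, 0.41))
      return(c(0, 0.41))
    }
    sp <- sort(c(si, sj))
    if (sp[1] %in% c("NP1", "NP2") && sp[2] == "RIG") return(c(5.0, 0.41))
    if (si == "NP1" && sj == "NP1") return(c(5.0, 0.82))
    if (si == "NP2" && sj == "NP2") return(c(5.0, 0.82))
    c(0.010, 0.41)
  }
  morse_v <- function(r, D, rr0) {
    M <- function(x) D * ((1 - exp(-ff$morse_alpha * (x - rr0)))^2 - 1)
    dM_rc <- 2 * D * ff$morse_alpha * exp(-ff$morse_alpha * (ff$rc - rr0)) *
             (1 - exp(-ff$morse_alpha * (ff$rc - rr0)))
    M(r) - M(ff$rc) - (r - ff$rc) * dM_rc
  }
  em <- 0
  nix <- floor((ff$rc) / lx + 0.5); niy <- floor((ff$rc) / ly + 0.5)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ## masks
      rig_i <- sys$group[i] != 2L; rig_j <- sys$group[j] != 2L
      if (rig_i && rig_j && sys$layer[i] != sys$layer[j]) next  # SUB-SUP zero
      cross <- sys$layer[i] != sys$layer[j]
      if (cross && (sys$type[i] >= 6 || sys$type[j] >= 6)) next # heads only
      if (sys$mol_id[i] > 0 && sys$mol_id[i] == sys$mol_id[j] &&
          abs(sys$chainpos[i] - sys$chainpos[j]) <= 3) next     # exclusions
      pp <- pair_params(sys$species[i], sys$species[j], !cross)
      D <- pp[1]; rr0 <- pp[2]
      if (D <= 0) next
      d <- pos[i, ] - pos[j, ]
      bx <- d[1] - lx * round(d[1] / lx); by <- d[2] - ly * round(d[2] / ly)
      for (ix in -nix:nix) for (iy in -niy:niy) {
        r <- sqrt((bx + ix * lx)^2 + (by + iy * ly)^2 + d[3]^2)
        if (r < ff$rc) em <- em + morse_v(r, D, rr0)
      }
    }
  }
  ## self-image terms (cells with an edge below the cutoff): each atom
  ## interacts with its own periodic images at fixed lattice separations
  for (i in seq_len(n)) {
    for (ix in -nix:nix) for (iy in -niy:niy) {
      if (!(ix > 0 || (ix == 0 && iy > 0))) next
      r <- sqrt((ix * lx)^2 + (iy * ly)^2)
      if (r >= ff$rc) next
      pp <- pair_params(sys$species[i], sys$species[i], TRUE)
      if (pp[1] > 0) em <- em + morse_v(r, pp[1], pp[2])
    }
  }
  list(total = unname(eb + ea + em), bond = unname(eb), angle = unname(ea),
       morse = unname(em))
}

## central-difference force oracle against any energy functional
numgrad_force <- function(efun, pos, i, k, h = 1e-6) {
  p1 <- pos; p1[i, k] <- p1[i, k] + h
  p2 <- pos; p2[i, k] <- p2[i, k] - h
  -(efun(p1) - efun(p2)) / (2 * h)
}
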