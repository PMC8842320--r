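## System assembly: seven-bead tethered molecules planted on the anchor
## sublattice of two facing rigid layers.

.SPECIES <- c("CA", "R1", "R2", "R3", "AN", "NP1", "NP2", "RIG")

#' Seven-bead molecule template
#'
#' One coarse-grained zwitterionic head group: a cation bead (CA), three
#' neutral residues (R1--R3), an anion bead (AN) and two neutral non-polar
#' beads (NP1, NP2) that anchor the chain to its rigid layer.  Successive
#' beads are connected by harmonic bonds; successive triplets carry harmonic
#' angles, all straight (180 degrees) except the AN--NP1--NP2 angle at the
#' sp3-like kink of 111 degrees.
#'
#' @param charge_on logical; `FALSE` builds the charge-free control with all
#'   charges zero.
#' @param q head-group charge magnitude, e (default 0.25; CA carries `+q`,
#'   AN `-q`).
#' @param k_bond bond stiffness, N m^-1.
#' @param k_angle angle stiffness, eV rad^-2.
#' @return list of class `zw_template` with per-bead `species`, `mass`
#'   (a.m.u.), `charge` (e), and the bond/angle topology with parameters.
#' @export
molecule_template <- function(charge_on = TRUE, q = 0.25,
                              k_bond = 480, k_angle = 10) {
  qq <- if (charge_on) q else 0
  tpl <- list(
    species = c("CA", "R1", "R2", "R3", "AN", "NP1", "NP2"),
    mass    = c(60, 15, 15, 15, 80, 50, 50),
    charge  = c(qq, 0, 0, 0, -qq, 0, 0),
    bonds   = cbind(1:6, 2:7),
    bond_k  = rep(k_bond, 6),
    bond_r0 = c(0.16, 0.16, 0.16, 0.16, 0.16, 0.67),
    angles  = cbind(1:5, 2:6, 3:7),
    angle_k = rep(k_angle, 5),
    angle_theta0 = c(180, 180, 180, 180, 111)
  )
  stopifnot(abs(sum(tpl$charge)) < 1e-12)
  class(tpl) <- "zw_template"
  tpl
}

## Initial single-chain pose pointing along dirz = +1 (SUB) or -1 (SUP):
## NP2 sits above/below its anchor node at the NP-rigid Morse minimum,
## NP1 one long bond further, then the head tilted by (180 - 111) degrees
## off the vertical with azimuth az.
.chain_pose <- function(tpl, anchor, dirz, az, z_np2 = 0.41,
                        tilt = (180 - 111) * pi / 180) {
  d <- c(sin(tilt) * cos(az), sin(tilt) * sin(az), cos(tilt) * dirz)
  np2 <- anchor + c(0, 0, dirz * z_np2)
  np1 <- np2 + c(0, 0, dirz * 0.67)
  an  <- np1 + 0.16 * d
  r3  <- an + 0.16 * d
  r2  <- r3 + 0.16 * d
  r1  <- r2 + 0.16 * d
  ca  <- r1 + 0.16 * d
  rbind(ca, r1, r2, r3, an, np1, np2)
}

.min_image_dist2 <- function(p, q, lx, ly) {
  d <- p - q
  d[1] <- d[1] - lx * round(d[1] / lx)
  d[2] <- d[2] - ly * round(d[2] / ly)
  sum(d^2)
}

#' Assemble the two-layer sliding system
#'
#' Builds the full particle system from a commensurate supercell: frozen SUB
#' rigid layer at z = 0 with upward-pointing molecules on its anchor
#' sublattice, and the mirror-image SUP rigid layer above with
#' downward-pointing molecules, separated so that the two CA planes are
#' `initial_gap` apart.  By default all kink azimuths point the same way
#' (the regularly spaced initial configuration of the model); with
#' `azimuths = "random"` they are drawn per molecule from a seeded RNG,
#' with stochastic repair of any clashing neighbours.
#'
#' @param cell `zw_supercell` from [find_commensurate_supercell()].
#' @param charge_on logical, zwitterionic (`TRUE`) or charge-free control.
#' @param initial_gap initial distance between the opposing CA planes, nm.
#' @param seed integer seed for the kink azimuths (`"random"` mode).
#' @param azimuths `"aligned"` (all kinks along +y; the regular initial
#'   lattice) or `"random"` (disordered start; slow to order at low
#'   temperature).
#' @param template optionally a `zw_template` (default
#'   [molecule_template()] with `charge_on`).
#' @param anchor_k_bond stiffness (N m^-1) of the anchoring tethers: each
#'   NP bead is harmonically bonded to the rigid bead at its anchor node
#'   and to two ring neighbours of that node, with rest lengths equal to
#'   the as-built distances.  The triangulated tethers keep the NP1-NP2
#'   pair planted and near-vertical with limited elastic deformability;
#'   without them the terminal pair could rotate onto the rigid plane at no
#'   bonded-energy cost and the brush would collapse.
#' @return An object of class `zw_system`: positions (N x 3, nm), species,
#'   integer `type`, `layer` (0 = SUB, 1 = SUP), `group` (0 frozen SUB-rigid,
#'   1 rigid-translating SUP-rigid, 2 mobile molecule bead), `charge` (e),
#'   `mass` (a.m.u.), `mol_id`, bond and angle tables, and the periodic box.
#' @examples
#' sc <- find_commensurate_supercell(0.82, c(0, 5), 2, 1e-3)
#' sys <- assemble_system(sc, charge_on = TRUE, seed = 1)
#' sum(sys$charge)  # 0
#' @export
assemble_system <- function(cell, charge_on = TRUE, initial_gap = 0.5,
                            seed = 1, azimuths = c("aligned", "random"),
                            template = NULL,
                            anchor_k_bond = 480) {
  azimuths <- match.arg(azimuths)
  tpl <- if (is.null(template)) molecule_template(charge_on) else template
  sub <- build_layer(cell, "SUB", z_plane = 0)
  ## chain vertical extent above the rigid plane (CA bead height)
  z_ca <- 0.41 + 0.67 + 4 * 0.16 * cos((180 - 111) * pi / 180)
  z_top <- 2 * z_ca + initial_gap
  sup <- build_layer(cell, "SUP", z_plane = z_top)

  nmol <- nrow(sub$anchors)
  if (nrow(sup$anchors) != nmol)
    stop("layer anchor counts differ: ", nmol, " vs ", nrow(sup$anchors))

  rng <- .zw_rng(seed)
  ## min-image squared distances between two small coordinate blocks
  blk_dist2 <- function(p, q, lx, ly) {
    dx <- outer(p[, 1], q[, 1], "-"); dx <- dx - lx * round(dx / lx)
    dy <- outer(p[, 2], q[, 2], "-"); dy <- dy - ly * round(dy / ly)
    dz <- outer(p[, 3], q[, 3], "-")
    min(dx^2 + dy^2 + dz^2)
  }
  ## Inter-molecular clearance for the initial pose: with the Morse
  ## stiffness alpha = 15 nm^-1, contacts below ~0.25 nm start the run
  ## eV-hot, so kink azimuths of clashing molecules (within and across
  ## layers) are resampled stochastically; persistent offenders are
  ## straightened slightly, never enough to breach the cross-layer gap.
  clearance <- 0.25
  tilt0 <- (180 - 111) * pi / 180
  nmol2 <- 2L * nmol
  anc_all <- rbind(sub$anchors, sup$anchors)
  dirz_all <- c(rep(1, nmol), rep(-1, nmol))
  dxm <- outer(anc_all[, 1], anc_all[, 1], "-")
  dxm <- dxm - cell$l_x * round(dxm / cell$l_x)
  dym <- outer(anc_all[, 2], anc_all[, 2], "-")
  dym <- dym - cell$l_y * round(dym / cell$l_y)
  near <- which(dxm^2 + dym^2 < 2.8^2 & upper.tri(dxm), arr.ind = TRUE)
  pairs <- if (nrow(near) > 0) unname(cbind(near[, 1], near[, 2])) else NULL
  az <- if (azimuths == "aligned") rep(pi / 2, nmol2) else
    vapply(seq_len(nmol2), function(i) rng() * 2 * pi, 0)
  tilt <- rep(tilt0, nmol2)
  pose <- lapply(seq_len(nmol2), function(i)
    .chain_pose(tpl, anc_all[i, ], dirz_all[i], az[i], tilt = tilt[i]))
  bad <- integer(0)
  for (sweep in seq_len(if (azimuths == "aligned") 60 else 1500)) {
    bad <- integer(0)
    if (!is.null(pairs)) {
      for (p in seq_len(nrow(pairs))) {
        i <- pairs[p, 1]; j <- pairs[p, 2]
        if (blk_dist2(pose[[i]], pose[[j]],
                      cell$l_x, cell$l_y) < clearance^2)
          bad <- c(bad, if (rng() < 0.5) i else j)
      }
    }
    bad <- unique(bad)
    if (length(bad) == 0) break
    for (i in bad) {
      az[i] <- rng() * 2 * pi
      ## straightening raises the chain tip; cap it so two capped chains
      ## still clear each other across the gap
      if (sweep > 300) tilt[i] <- max(tilt[i] * 0.95, 0.85 * tilt0)
      pose[[i]] <- .chain_pose(tpl, anc_all[i, ], dirz_all[i], az[i],
                               tilt = tilt[i])
    }
  }
  if (length(bad) > 0)
    warning("initial pose retains ", length(bad),
            " contacts below ", clearance, " nm; running-in will relax them")
  sub_mol <- do.call(rbind, pose[seq_len(nmol)])
  sup_mol <- do.call(rbind, pose[nmol + seq_len(nmol)])

  n_rig <- nrow(sub$rigid)
  nb <- nrow(sub_mol)  # nmol * 7
  positions <- rbind(sub_mol, sup_mol, sub$rigid, sup$rigid)
  dimnames(positions) <- NULL
  dmin <- .min_pair_distance(positions, cell$l_x, cell$l_y)
  if (dmin < 0.05)
    stop(sprintf("overlapping beads in assembled system (min distance %.3g nm < 0.05 nm)",
                 dmin))
  species <- c(rep(tpl$species, 2 * nmol), rep("RIG", 2 * n_rig))
  type <- match(species, .SPECIES)
  layer <- c(rep(0L, nb), rep(1L, nb), rep(0L, n_rig), rep(1L, n_rig))
  group <- c(rep(2L, 2 * nb), rep(0L, n_rig), rep(1L, n_rig))
  charge <- c(rep(tpl$charge, 2 * nmol), rep(0, 2 * n_rig))
  mass <- c(rep(tpl$mass, 2 * nmol), rep(50, 2 * n_rig))
  mol_id <- c(rep(seq_len(2 * nmol), each = 7), rep(0L, 2 * n_rig))
  chainpos <- c(rep(0:6, 2 * nmol), rep(-1L, 2 * n_rig))

  off <- 7 * (seq_len(2 * nmol) - 1)
  bonds <- do.call(rbind, lapply(off, function(o) tpl$bonds + o))
  angles <- do.call(rbind, lapply(off, function(o) tpl$angles + o))
  bond_k <- rep(tpl$bond_k, 2 * nmol)
  bond_r0 <- rep(tpl$bond_r0, 2 * nmol)
  angle_k <- rep(tpl$angle_k, 2 * nmol)
  angle_theta0 <- rep(tpl$angle_theta0, 2 * nmol)

  ## Anchoring tethers: each NP bead is bonded to the rigid bead at its
  ## anchor node and to two ring neighbours of that node (~120 deg apart).
  ## The triangulated bonds plant the NP1-NP2 pair at the node and keep it
  ## near-vertical with limited elastic deformability; without them the
  ## terminal pair could rotate onto the rigid plane at no bonded cost and
  ## the brush would collapse.
  rig_off <- 2 * nb   # first rigid bead row
  mi <- function(d, L) d - L * round(d / L)
  anchor_tethers <- function(m) {
    lay_m <- as.integer(m > nmol)
    xy <- if (lay_m == 0) sub$anchors[m, 1:2] else sup$anchors[m - nmol, 1:2]
    rig_xy <- if (lay_m == 0) sub$rigid else sup$rigid
    dxl <- mi(rig_xy[, 1] - xy[1], cell$l_x)
    dyl <- mi(rig_xy[, 2] - xy[2], cell$l_y)
    d2 <- dxl^2 + dyl^2
    node <- which.min(d2)
    if (d2[node] > 1e-10) stop("anchor node has no rigid bead at its position")
    ring <- which(d2 > 1e-10 & d2 < (0.75 * cell$a / 2 * 1.8)^2)
    if (length(ring) < 2) stop("anchor node has fewer than two ring neighbours")
    ang <- atan2(dyl[ring], dxl[ring])
    ring <- ring[order(ang)]
    sel <- ring[c(1L, 1L + round(length(ring) / 3))]
    idx0 <- rig_off + (lay_m == 1) * n_rig
    list(node = idx0 + node, ringsel = idx0 + sel)
  }
  pos_of <- function(i) positions[i, ]
  for (m in seq_len(2 * nmol)) {
    at <- anchor_tethers(m)
    np2 <- 7L * m
    np1 <- np2 - 1L
    for (bead in c(np2, np1)) {
      for (ref in c(at$node, at$ringsel)) {
        dd <- pos_of(bead) - pos_of(ref)
        dd[1] <- mi(dd[1], cell$l_x); dd[2] <- mi(dd[2], cell$l_y)
        bonds <- rbind(bonds, c(ref, bead))
        bond_k <- c(bond_k, anchor_k_bond)
        bond_r0 <- c(bond_r0, sqrt(sum(dd^2)))
      }
    }
  }

  sys <- list(
    positions = positions, species = species, type = type, layer = layer,
    group = group, charge = charge, mass = mass, mol_id = mol_id,
    chainpos = chainpos,
    bonds = bonds, bond_k = bond_k, bond_r0 = bond_r0,
    angles = angles, angle_k = angle_k, angle_theta0 = angle_theta0,
    box = c(lx = cell$l_x, ly = cell$l_y),
    a = cell$a, phi = cell$phi, n_mol_per_layer = nmol,
    charge_on = charge_on, template = tpl, seed = seed
  )
  class(sys) <- "zw_system"
  stopifnot(abs(sum(sys$charge)) < 1e-12)
  sys
}

#' @export
print.zw_system <- function(x, ...) {
  cat(sprintf("zw_system: %d particles (%d molecules/layer, %d rigid beads/layer)\n",
              nrow(x$positions), x$n_mol_per_layer,
              sum(x$group == 0L)))
  cat(sprintf("  box %.4f x %.4f nm, phi = %.3f deg, %s (q = %.2f e)\n",
              x$box[1], x$box[2], x$phi,
              if (x$charge_on) "zwitterionic" else "charge-free",
              max(x$charge)))
  invisible(x)
}

#' @export
summary.zw_system <- function(object, ...) {
  d <- areal_density(object)
  cat(sprintf("Particles: %d; molecules/layer: %d; areal density %.3f nm^-2\n",
              nrow(object$positions), object$n_mol_per_layer, d))
  cat(sprintf("Bonds: %d, angles: %d, net charge %.3g e\n",
              nrow(object$bonds), nrow(object$angles), sum(object$charge)))
  invisible(object)
}

#' Areal molecule density of a system
#'
#' @param sys a `zw_system`.
#' @return molecules per nm^2 per layer.
#' @export
areal_density <- function(sys) {
  sys$n_mol_per_layer / (sys$box[[1]] * sys$box[[2]])
}

## Minimum pairwise distance with xy periodicity (chunked to bound memory).
.min_pair_distance <- function(pos, lx, ly, chunk = 400L) {
  n <- nrow(pos)
  dmin <- Inf
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    rows <- i0:i1
    dx <- outer(pos[rows, 1], pos[, 1], "-"); dx <- dx - lx * round(dx / lx)
    dy <- outer(pos[rows, 2], pos[, 2], "-"); dy <- dy - ly * round(dy / ly)
    dz <- outer(pos[rows, 3], pos[, 3], "-")
    d2 <- dx^2 + dy^2 + dz^2
    d2[cbind(seq_along(rows), rows)] <- Inf   # self
    dmin <- min(dmin, d2)
  }
  sqrt(dmin)
}

## Small deterministic uniform RNG (splitmix64-based) so that system
## assembly does not touch R's global RNG state.
.zw_rng <- function(seed) {
  state <- as.double(seed %% 2147483647L)
  function() {
    ## two rounds of a 31-bit LCG (Park-Miller), returns U(0,1)
    state <<- (16807 * state) %% 2147483647
    state / 2147483647
  }
}
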