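## Commensurate rotated-lattice supercell construction.
##
## Both anchoring layers are triangular lattices of node spacing a/2 whose
## molecule sublattice (1 node in 4) has spacing a.  The layers are rotated
## by -phi/2 (SUB) and +phi/2 (SUP); a rectangular simulation cell must be a
## lattice vector pair of both rotated lattices.  Because the triangular
## point set is mirror-symmetric about a lattice direction, a rectangle
## commensurate with the +phi/2 lattice is automatically commensurate with
## the -phi/2 one, so the search works on a single lattice.

.tri_basis <- function(a) rbind(c(a, 0), c(a / 2, a * sqrt(3) / 2))

.lat_vec <- function(m, n, a) c(m * a + n * a / 2, n * a * sqrt(3) / 2)

#' Find a commensurate rectangular supercell for two rotated triangular lattices
#'
#' Searches integer lattice vectors `u = m a1 + n a2` and `w = p a1 + q a2`
#' of a triangular lattice with spacing `molecule_spacing` such that `u` and
#' `w` are perpendicular within `mismatch_tol`.  Rotating the lattice so that
#' `u` lies along x gives a rectangular periodic cell `|u| x |w|`; the two
#' layers are then rotated by +/- phi/2 with `phi = 2 * angle(u)`.  The
#' smallest qualifying cell (by area) wins; ties are broken by the angle
#' closest to the centre of `angle_window`.
#'
#' @param molecule_spacing triangular lattice constant a of the molecule
#'   sublattice, nm (the rigid-node spacing is a/2).
#' @param angle_window numeric length-2, admissible relative rotation range
#'   phi in degrees, inside `[0, 60)`.  A window touching 0 admits the
#'   aligned (unrotated) solution.
#' @param max_dims maximum allowed cell edge, nm (applies to both edges).
#' @param mismatch_tol maximum relative strain (|cos| of the angle between
#'   `u` and `w`) tolerated when forcing the cell rectangular.
#' @param target_dims optional length-2 `c(l_x, l_y)` in nm: select the
#'   qualifying cell closest to these dimensions instead of the smallest
#'   one.  Several commensurate cells can coexist in one angle window (the
#'   moire construction is not unique), so a reference system quoted by its
#'   cell size is recovered by passing that size here.
#' @return A list of class `zw_supercell`: `phi` (degrees), `l_x`, `l_y`
#'   (nm), `u`, `w` (integer lattice indices), `n_mol_per_layer`,
#'   `strain`, and `a = molecule_spacing`.  The full candidate set is
#'   attached as `attr(, "candidates")`.
#' @examples
#' find_commensurate_supercell(0.82, c(15, 25), 15, 1e-3,
#'                             target_dims = c(8.32, 14.41))  # phi ~ 19.65
#' @export
find_commensurate_supercell <- function(molecule_spacing, angle_window,
                                        max_dims, mismatch_tol = 1e-3,
                                        target_dims = NULL) {
  a <- molecule_spacing
  stopifnot(a > 0, length(angle_window) == 2, mismatch_tol > 0)
  angle_window <- sort(angle_window)
  if (angle_window[1] < 0 || angle_window[2] >= 60)
    stop("angle_window must lie inside [0, 60) degrees")
  centre <- mean(angle_window)

  mmax <- floor(max_dims / a) + 1L
  cands <- list()
  for (m in 0:mmax) {
    for (n in 0:mmax) {
      if (m == 0 && n == 0) next
      u <- .lat_vec(m, n, a)
      lu <- sqrt(sum(u^2))
      if (lu > max_dims + 1e-9) next
      phi <- 2 * atan2(u[2], u[1]) * 180 / pi
      if (phi < angle_window[1] - 1e-9 || phi > angle_window[2] + 1e-9) next
      ## shortest integer vector perpendicular to u within tolerance
      wbest <- NULL
      pmax <- floor(max_dims / (a * sqrt(3) / 2)) + 2L
      for (p in (-pmax):pmax) {
        for (q in (-pmax):pmax) {
          if (p == 0 && q == 0) next
          w <- .lat_vec(p, q, a)
          lw <- sqrt(sum(w^2))
          if (lw > max_dims + 1e-9) next
          if (w[2] < 0) next   # upper half plane only
          cosang <- sum(u * w) / (lu * lw)
          if (abs(cosang) > mismatch_tol) next
          if (is.null(wbest) || lw < wbest$lw - 1e-12) {
            wbest <- list(p = p, q = q, lw = lw, strain = abs(cosang))
          }
        }
      }
      if (is.null(wbest)) next
      area <- lu * wbest$lw
      cands[[length(cands) + 1L]] <- list(
        phi = phi, l_x = lu, l_y = wbest$lw,
        u = c(m, n), w = c(wbest$p, wbest$q),
        strain = wbest$strain,
        n_mol_per_layer = as.integer(round(area / (a^2 * sqrt(3) / 2))),
        a = a)
    }
  }
  if (length(cands) == 0)
    stop("no commensurate cell within max_dims = ", max_dims,
         " nm for the requested angle window")
  if (!is.null(target_dims)) {
    score <- vapply(cands, function(cc)
      (cc$l_x - target_dims[1])^2 + (cc$l_y - target_dims[2])^2, 0)
    best <- cands[[which.min(score)]]
  } else {
    area <- vapply(cands, function(cc) cc$l_x * cc$l_y, 0)
    dang <- vapply(cands, function(cc) abs(cc$phi - centre), 0)
    sel <- which(area <= min(area) + 1e-9)
    best <- cands[[sel[which.min(dang[sel])]]]
  }
  ctab <- data.frame(
    phi = vapply(cands, `[[`, 0, "phi"),
    l_x = vapply(cands, `[[`, 0, "l_x"),
    l_y = vapply(cands, `[[`, 0, "l_y"),
    n_mol_per_layer = vapply(cands, `[[`, 0L, "n_mol_per_layer"),
    strain = vapply(cands, `[[`, 0, "strain"))
  class(best) <- "zw_supercell"
  attr(best, "candidates") <- ctab
  best
}

#' @export
print.zw_supercell <- function(x, ...) {
  cat(sprintf(
    "Commensurate supercell: %.4f x %.4f nm, phi = %.4f deg (strain %.2e)\n",
    x$l_x, x$l_y, x$phi, x$strain))
  cat(sprintf("  lattice a = %.3f nm, %d molecules/layer, u = (%d,%d), w = (%d,%d)\n",
              x$a, x$n_mol_per_layer, x$u[1], x$u[2], x$w[1], x$w[2]))
  invisible(x)
}

## Generate all points of a triangular lattice (spacing s, rotated by
## rot_deg, shifted by offset) wrapped into the box [0,lx) x [0,ly).
.lattice_points <- function(s, rot_deg, lx, ly, offset = c(0, 0)) {
  th <- rot_deg * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  span <- ceiling((lx + ly) / (s * sqrt(3) / 2)) + 3L
  ij <- as.matrix(expand.grid(i = -span:span, j = -span:span))
  pts <- ij %*% .tri_basis(s) %*% t(R)
  pts[, 1] <- pts[, 1] + offset[1]
  pts[, 2] <- pts[, 2] + offset[2]
  wrap <- function(x, L) {
    x <- x - L * floor(x / L)
    x[x > L - 1e-7] <- 0
    x
  }
  px <- wrap(pts[, 1], lx)
  py <- wrap(pts[, 2], ly)
  keep <- !duplicated(paste(round(px * 1e5), round(py * 1e5)))
  parity <- (abs(ij[, 1]) %% 2L == 0L) & (abs(ij[, 2]) %% 2L == 0L)
  list(xy = cbind(px, py)[keep, , drop = FALSE], anchor = parity[keep])
}

#' Build one rigid anchoring layer
#'
#' Places rigid beads on every node of the triangular lattice of spacing
#' a/2, rotated by `-phi/2` (SUB) or `+phi/2` (SUP), wrapped into the
#' supercell, and marks the molecule anchor sublattice (spacing a, one node
#' in four).  The SUP layer is additionally offset along x by half a node
#' spacing (a/4) so that anchor points of the two layers are not in perfect
#' registry at t = 0.
#'
#' @param cell a `zw_supercell` from [find_commensurate_supercell()].
#' @param which `"SUB"` or `"SUP"`.
#' @param z_plane z coordinate of the rigid plane, nm.
#' @return list with `rigid` (n x 3 matrix), `anchors` (m x 3 matrix of the
#'   molecule anchor nodes), `which`, `rotation` (degrees).
#' @examples
#' sc <- find_commensurate_supercell(0.82, c(0, 5), 2, 1e-3)
#' lay <- build_layer(sc, "SUB", 0)
#' nrow(lay$rigid) / nrow(lay$anchors)  # 4
#' @export
build_layer <- function(cell, which = c("SUB", "SUP"), z_plane = 0) {
  which <- match.arg(which)
  rot <- if (which == "SUB") -cell$phi / 2 else cell$phi / 2
  off <- if (which == "SUP") c(cell$a / 4, 0) else c(0, 0)
  lp <- .lattice_points(cell$a / 2, rot, cell$l_x, cell$l_y, offset = off)
  n_nodes_exp <- round(cell$l_x * cell$l_y / ((cell$a / 2)^2 * sqrt(3) / 2))
  if (nrow(lp$xy) != n_nodes_exp) {
    stop(sprintf(
      "incommensurate cell for %s layer: %d nodes generated, %d expected (residual mismatch %.3g)",
      which, nrow(lp$xy), n_nodes_exp,
      abs(nrow(lp$xy) - n_nodes_exp) / n_nodes_exp))
  }
  rigid <- cbind(lp$xy, z_plane)
  anchors <- cbind(lp$xy[lp$anchor, , drop = FALSE], z_plane)
  list(rigid = rigid, anchors = anchors, which = which, rotation = rot,
       z_plane = z_plane)
}
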