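## Deterministic miniature systems and synthetic traces so that every
## module is testable in seconds without a full simulation.

#' Build a miniature two-layer system
#'
#' Finds the smallest commensurate cell holding `n_mol_per_layer` molecules
#' per layer: a rotated (moire) cell when `n_mol_per_layer / 2` is
#' expressible as `m^2 + m n + n^2` (the rotated-rectangle family), or an
#' aligned `p x q` rectangular tiling otherwise, and assembles the system.
#'
#' @param n_mol_per_layer molecules per layer (>= 1).
#' @param charge_on logical, zwitterionic or charge-free.
#' @param seed integer seed for the kink azimuths.
#' @param rotated require the rotated commensurate cell (`NA` = rotated if
#'   available, aligned fallback otherwise).
#' @param a molecule lattice spacing, nm.
#' @return a `zw_system`.
#' @examples
#' sys <- mini_system(4, charge_on = TRUE, seed = 0)
#' nrow(sys$positions)  # 2 * (4*7 + 16) = 88
#' @export
mini_system <- function(n_mol_per_layer, charge_on = TRUE, seed = 0,
                        rotated = NA, a = 0.82) {
  stopifnot(n_mol_per_layer >= 1)
  cell <- NULL
  if (n_mol_per_layer %% 2 == 0 && !isFALSE(rotated)) {
    K <- n_mol_per_layer / 2
    ## rotated family: K = m^2 + m n + n^2 with n >= 1 (phi > 0)
    for (m in 1:32) {
      for (n in 1:32) {
        if (m * m + m * n + n * n == K) {
          phi <- 2 * atan2(n * sqrt(3) / 2, m + n / 2) * 180 / pi
          if (phi < 60) {
            cell <- list(phi = phi, l_x = a * sqrt(K),
                         l_y = a * sqrt(3 * K),
                         u = c(m, n), w = c(-(m + 2 * n), 2 * m + n),
                         strain = 0, n_mol_per_layer = as.integer(2 * K), a = a)
            class(cell) <- "zw_supercell"
          }
          break
        }
      }
      if (!is.null(cell)) break
    }
  }
  if (is.null(cell) && !isTRUE(rotated)) {
    ## aligned p x q tiling of the a x (a sqrt 3) rectangle (2 molecules each)
    if (n_mol_per_layer %% 2 != 0)
      stop("no commensurate mini-cell: need an even molecule count")
    pq <- n_mol_per_layer / 2
    p <- floor(sqrt(pq))
    while (p > 1 && pq %% p != 0) p <- p - 1
    q <- pq / p
    cell <- list(phi = 0, l_x = a * max(p, q) , l_y = a * sqrt(3) * min(p, q),
                 u = c(max(p, q), 0), w = c(-min(p, q), 2 * min(p, q)),
                 strain = 0, n_mol_per_layer = as.integer(n_mol_per_layer),
                 a = a)
    class(cell) <- "zw_supercell"
  }
  if (is.null(cell))
    stop("no commensurate mini-cell for ", n_mol_per_layer,
         " molecules per layer")
  assemble_system(cell, charge_on = charge_on, seed = seed)
}

#' Synthetic friction traces with known statistics
#'
#' Generates `zw_trace` data frames whose mean, RMS and slip-event count
#' are known in closed form, for exercising the analysis functions.
#'
#' Patterns: `flat` (constant stress `s`), `sawtooth` (rises linearly from
#' 0 to `s_max` over `period_nm`, then drops to 0; mean `s_max/2`, RMS
#' `s_max/sqrt(12)`), `noisy` (Gaussian stress around `s`, plus a (U, h)
#' pair constructed with Pearson correlation `rho`).
#'
#' @param pattern `"flat"`, `"sawtooth"` or `"noisy"`.
#' @param n number of samples.
#' @param travel_nm total stage travel, nm.
#' @param s,s_max,period_nm,sd_s pattern parameters (MPa, nm).
#' @param rho target U-h correlation for `"noisy"`.
#' @param seed integer seed.
#' @return a `zw_trace` data frame.
#' @export
synthetic_trace <- function(pattern = c("flat", "sawtooth", "noisy"),
                            n = 1000, travel_nm = 10, s = 1, s_max = 4,
                            period_nm = 1, sd_s = 0.1, rho = -0.8,
                            seed = 0) {
  pattern <- match.arg(pattern)
  x <- seq(0, travel_nm, length.out = n)
  rng <- .zw_rng(seed + 11)
  gauss <- function(k) {
    u1 <- vapply(seq_len(k), function(i) max(rng(), 1e-12), 0)
    u2 <- vapply(seq_len(k), function(i) rng(), 0)
    sqrt(-2 * log(u1)) * cos(2 * pi * u2)
  }
  stress <- switch(pattern,
    flat = rep(s, n),
    sawtooth = s_max * ((x / period_nm) %% 1),
    noisy = s + sd_s * gauss(n))
  U <- rep(0, n); h <- rep(0, n)
  if (pattern == "noisy") {
    g1 <- gauss(n); g2 <- gauss(n)
    U <- g1
    h <- rho * g1 + sqrt(1 - rho^2) * g2
  } else if (pattern == "sawtooth") {
    ## h tracks the stress, U anticorrelates
    h <- stress / s_max * 10
    U <- -h
  }
  tr <- data.frame(time = x / 5e-3, x_stage = x, x_sup = x, stress = stress,
                   U = U, h = h, d = rep(3, n), T_inst = rep(300, n),
                   ke = rep(0, n), vz_sup = rep(0, n), e_recip = rep(0, n),
                   step = seq_len(n))
  attr(tr, "v_stage_ms") <- 5
  attr(tr, "dt_ps") <- 1e-3
  class(tr) <- c("zw_trace", "data.frame")
  tr
}
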