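## Langevin dynamics with anisotropic damping.
##
## Equations of motion: molecule beads follow m dv/dt = F - m gamma v + xi
## with the friction and Gaussian noise applied only along y and z, so that
## no spurious thermostat damping acts along the sliding direction x.  The
## SUB rigid layer is frozen; the SUP rigid layer translates as one body
## under the sum of its bead forces, the normal load (-z) and, when driven,
## a pulling spring along x whose stage advances at constant velocity.

#' Initialise a dynamic state
#'
#' Draws Maxwell-Boltzmann velocities for the molecule beads at the target
#' temperature (all three components; only y and z are thermostatted later,
#' x equilibrates through the interactions) and zero velocity for the rigid
#' layers.
#'
#' @param sys a `zw_system`.
#' @param temperature kelvin.
#' @param seed integer seed (velocities and subsequent Langevin noise).
#' @return object of class `zw_state`.
#' @export
init_state <- function(sys, temperature = 300, seed = 1) {
  n <- nrow(sys$positions)
  v <- matrix(0, n, 3)
  mob <- sys$group == 2L
  if (temperature > 0 && any(mob)) {
    m_int <- sys$mass * zw_units$amu
    sd_v <- sqrt(zw_units$kB * temperature / m_int[mob])
    rng <- .zw_rng(seed + 7919)
    for (k in 1:3) {
      u1 <- vapply(seq_len(sum(mob)), function(i) rng(), 0)
      u2 <- vapply(seq_len(sum(mob)), function(i) rng(), 0)
      v[mob, k] <- sd_v * sqrt(-2 * log(pmax(u1, 1e-12))) * cos(2 * pi * u2)
    }
  }
  sup <- sys$group == 1L
  st <- list(
    sys = sys,
    positions = sys$positions,
    velocities = v,
    body_vel = c(0, 0, 0),
    body_x = if (any(sup)) mean(sys$positions[sup, 1]) else 0,
    time = 0, step = 0,
    forces = NULL, recip_cache = NULL,
    ewald = NULL, u_const = NULL,
    seed = seed
  )
  class(st) <- "zw_state"
  st
}

#' @export
print.zw_state <- function(x, ...) {
  cat(sprintf("zw_state: t = %.4f ps (step %g), %d particles\n",
              x$time, x$step, nrow(x$positions)))
  cat(sprintf("  SUP body at x = %.4f nm, v = (%.3g, %.3g, %.3g) nm/ps\n",
              x$body_x, x$body_vel[1], x$body_vel[2], x$body_vel[3]))
  invisible(x)
}

#' Integrate the equations of motion
#'
#' Velocity-Verlet integration with Langevin friction and noise on the y,z
#' components of the molecule beads.  The SUB layer stays exactly frozen;
#' the SUP layer moves as a rigid body.  Drive modes: `"spring"` attaches
#' the pulling stage (position `stage0 + v_stage * t`) to the SUP body
#' through a spring along x, `"constant_velocity"` prescribes the SUP x
#' velocity (running-in), `"none"` leaves the body free.
#'
#' @param state a `zw_state` from [init_state()] or a previous call.
#' @param ff a `zw_forcefield`.
#' @param nsteps number of timesteps.
#' @param dt timestep, ps (default 1 fs).
#' @param temperature thermostat target, K.
#' @param gamma Langevin damping rate on y,z of molecule beads, ps^-1.
#' @param v_stage stage/driving velocity, m/s.
#' @param k_spring pulling-spring stiffness, eV nm^-2.
#' @param load normal load, MPa (applied to the SUP body along -z).
#' @param drive one of `"spring"`, `"constant_velocity"`, `"none"`.
#' @param stage0 initial stage position, nm (default: current SUP body x).
#' @param sample_every sampling stride, steps.
#' @param kspace_every evaluate the Ewald reciprocal forces every this many
#'   steps (they vary slowly; intermediate steps reuse the cached values).
#' @param skin neighbour-list skin, nm.
#' @param hook_dz hooking-fraction margin, nm (see [hooking_fraction()]).
#' @param seed integer; noise seed (default: the state's seed).
#' @return list with the advanced `state` and the sampled `trace`
#'   (a `zw_trace` data frame).
#' @export
run_md <- function(state, ff = default_forcefield(), nsteps, dt = 1e-3,
                   temperature = 300, gamma = 1, v_stage = 0, k_spring = 1,
                   load = 0, drive = c("spring", "constant_velocity", "none"),
                   stage0 = NULL, sample_every = 100, kspace_every = 1,
                   skin = 0.3, hook_dz = 0, seed = NULL) {
  drive <- match.arg(drive)
  sys <- state$sys
  if (is.null(seed)) seed <- state$seed
  area <- sys$box[[1]] * sys$box[[2]]
  use_coul <- isTRUE(ff$coulomb) && any(sys$charge != 0)
  if (is.null(state$ewald) && use_coul) {
    state$ewald <- ewald_setup(sys, ff, positions = state$positions)
  }
  if (is.null(state$u_const)) {
    r0 <- .zw_eval_cpp(.sys_cpp(sys, state$positions),
                       .ff_tables(sys, .no_coulomb(ff)), TRUE)
    state$u_const <- r0$e_rigid_rigid
  }
  ffp <- .ff_tables(sys, ff, ewald = state$ewald, positions = state$positions)
  dyn <- list(
    velocities = state$velocities,
    mass_int = sys$mass * zw_units$amu,
    dt = dt, nsteps = as.double(nsteps), step0 = as.double(state$step),
    time0 = state$time,
    gamma = gamma, kT = zw_units$kB * temperature,
    seed = as.double(seed),
    sample_every = as.integer(sample_every),
    kspace_every = as.integer(kspace_every),
    skin = skin,
    drive_mode = match(drive, c("spring", "constant_velocity", "none")) - 1L,
    v_stage = v_stage * zw_units$nmps_per_ms,
    k_spring = k_spring,
    stage0 = if (is.null(stage0)) state$body_x else stage0,
    load_fz = -load / zw_units$mpa_per_evnm3 * area,
    u_const = state$u_const,
    hook_dz = hook_dz,
    body_vel = state$body_vel, body_x = state$body_x,
    forces = state$forces, recip_cache = state$recip_cache
  )
  out <- .zw_run_cpp(.sys_cpp(sys, state$positions), ffp, dyn)
  if (out$status != 0)
    warning("non-finite coordinates or energy encountered; ",
            "partial trace returned (", out$nsamp, " samples)")
  tr <- out$trace[seq_len(out$nsamp), , drop = FALSE]
  colnames(tr) <- c("time", "x_stage", "x_sup", "stress", "U", "h", "d",
                    "T_inst", "ke", "vz_sup", "e_recip", "step")
  tr <- as.data.frame(tr)
  attr(tr, "area") <- area
  attr(tr, "v_stage_ms") <- v_stage
  attr(tr, "dt_ps") <- dt
  attr(tr, "k_spring") <- k_spring
  attr(tr, "load_mpa") <- load
  attr(tr, "temperature") <- temperature
  attr(tr, "sample_every") <- sample_every
  class(tr) <- c("zw_trace", "data.frame")

  state$positions <- out$positions
  state$velocities <- out$velocities
  state$body_vel <- as.numeric(out$body_vel)
  state$body_x <- out$body_x
  state$stage <- out$stage_final
  state$time <- out$time
  state$step <- out$step
  state$forces <- out$forces
  state$recip_cache <- if (use_coul) out$recip_cache else NULL
  state$last_impulse <- c(frozen_x = out$imp_frozen_x,
                          spring_x = out$imp_spring_x)
  if (out$status != 0) state$diverged <- TRUE
  list(state = state, trace = tr)
}

#' Advance the dynamics by a single Langevin step
#'
#' Convenience wrapper around [run_md()] with `nsteps = 1` and no drive.
#'
#' @inheritParams run_md
#' @return the advanced `zw_state`.
#' @export
langevin_step <- function(state, ff = default_forcefield(), dt = 1e-3,
                          temperature = 300, gamma = 1, seed = NULL) {
  run_md(state, ff, nsteps = 1, dt = dt, temperature = temperature,
         gamma = gamma, drive = "none", sample_every = 1, seed = seed)$state
}

#' Rigid-body update rule for the SUP layer
#'
#' One velocity-Verlet step of the single translating rigid body: all SUP
#' beads share the body velocity, so the body accelerates with the sum of
#' the member-bead forces (plus drive and load) divided by the total mass.
#' This is the same rule the integrator applies internally.
#'
#' @param body_pos length-3 body position, nm.
#' @param body_vel length-3 body velocity, nm/ps.
#' @param net_force length-3 net force on the body, eV/nm (same force used
#'   for both half kicks, i.e. a constant-force step).
#' @param mass total body mass, internal units (eV ps^2 nm^-2); multiply
#'   a.m.u. by `zw_units$amu`.
#' @param dt timestep, ps.
#' @return list with updated `body_pos` and `body_vel`.
#' @export
rigid_layer_update <- function(body_pos, body_vel, net_force, mass, dt) {
  body_vel <- body_vel + 0.5 * dt * net_force / mass
  body_pos <- body_pos + dt * body_vel
  body_vel <- body_vel + 0.5 * dt * net_force / mass
  list(body_pos = body_pos, body_vel = body_vel)
}

#' Drive and load forces on the SUP body
#'
#' Spring force `k (x_stage - x_SUP)` along x with `x_stage = stage0 +
#' v_stage t`, and the normal load `-L A` along z.  The instantaneous shear
#' stress is the spring force per unit contact area.
#'
#' @param state a `zw_state` (uses its body position and time).
#' @param v_stage stage velocity, m/s.
#' @param k_spring spring stiffness, eV nm^-2.
#' @param load normal load, MPa.
#' @param stage0 stage position at t = 0, nm.
#' @return list with `spring_force` (eV/nm), `load_force` (eV/nm, z),
#'   `shear_stress` (MPa).
#' @export
apply_drive_and_load <- function(state, v_stage, k_spring = 1, load = 0,
                                 stage0 = 0) {
  area <- state$sys$box[[1]] * state$sys$box[[2]]
  x_stage <- stage0 + v_stage * zw_units$nmps_per_ms * state$time
  fs <- k_spring * (x_stage - state$body_x)
  list(spring_force = fs,
       load_force = -load / zw_units$mpa_per_evnm3 * area,
       shear_stress = fs / area * zw_units$mpa_per_evnm3)
}
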