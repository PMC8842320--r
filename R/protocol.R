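## Experiment orchestration: running-in, production sliding, steady-state
## averaging, and load cycles.

#' Default experiment plan
#'
#' @param temperature kelvin.
#' @param load normal load, MPa.
#' @param v_stage stage velocity, m/s.
#' @param runin_nm running-in stage travel before the measuring spring is
#'   attached, nm.
#' @param production_nm production stage travel, nm.
#' @param discard_nm transient discarded before averaging, nm of stage
#'   travel (extended to the first slip event for stick-slip traces).
#' @param dt timestep, ps.
#' @param gamma Langevin damping, ps^-1.
#' @param k_spring pulling-spring stiffness, eV nm^-2.
#' @param sample_every sampling stride, steps.
#' @param kspace_every reciprocal-space refresh stride, steps.
#' @param skin neighbour-list skin, nm.
#' @param hook_dz hooking margin, nm.
#' @param seed integer seed.
#' @return a list of class `zw_plan`.
#' @export
default_plan <- function(temperature = 300, load = 10, v_stage = 5,
                         runin_nm = 10, production_nm = 100,
                         discard_nm = 20, dt = 1e-3, gamma = 1,
                         k_spring = 1, sample_every = 200,
                         kspace_every = 5, skin = 0.3, hook_dz = 0,
                         seed = 1) {
  p <- list(temperature = temperature, load = load, v_stage = v_stage,
            runin_nm = runin_nm, production_nm = production_nm,
            discard_nm = discard_nm, dt = dt, gamma = gamma,
            k_spring = k_spring, sample_every = sample_every,
            kspace_every = kspace_every, skin = skin, hook_dz = hook_dz,
            seed = seed)
  stopifnot(p$discard_nm < p$production_nm)
  class(p) <- "zw_plan"
  p
}

.nm_to_steps <- function(travel_nm, v_stage_ms, dt_ps) {
  v <- v_stage_ms * zw_units$nmps_per_ms          # nm/ps
  as.integer(ceiling(travel_nm / (v * dt_ps)))
}

#' Run one friction experiment
#'
#' Running-in: the SUP layer is driven at constant velocity under the
#' requested load and temperature until the running-in travel is covered.
#' Production: the pulling stage is attached through the spring at the
#' current SUP position and advanced at `v_stage` for the production
#' travel, sampling the friction trace.
#'
#' @param sys a `zw_system`.
#' @param plan a `zw_plan` from [default_plan()].
#' @param ff a `zw_forcefield`.
#' @param state optionally a `zw_state` to continue from (default: fresh
#'   thermalised state).
#' @return list with `trace` (production `zw_trace`) and the final `state`.
#' @export
run_experiment <- function(sys, plan = default_plan(), ff = default_forcefield(),
                           state = NULL) {
  if (is.null(state)) state <- init_state(sys, plan$temperature, plan$seed)
  if (plan$runin_nm > 0) {
    n1 <- .nm_to_steps(plan$runin_nm, plan$v_stage, plan$dt)
    ri <- run_md(state, ff, nsteps = n1, dt = plan$dt,
                 temperature = plan$temperature, gamma = plan$gamma,
                 v_stage = plan$v_stage, load = plan$load,
                 drive = "constant_velocity",
                 sample_every = plan$sample_every,
                 kspace_every = plan$kspace_every, skin = plan$skin,
                 hook_dz = plan$hook_dz)
    state <- ri$state
    if (isTRUE(state$diverged)) stop("dynamics diverged during running-in")
  }
  n2 <- .nm_to_steps(plan$production_nm, plan$v_stage, plan$dt)
  pr <- run_md(state, ff, nsteps = n2, dt = plan$dt,
               temperature = plan$temperature, gamma = plan$gamma,
               v_stage = plan$v_stage, k_spring = plan$k_spring,
               load = plan$load, drive = "spring",
               stage0 = state$body_x,
               sample_every = plan$sample_every,
               kspace_every = plan$kspace_every, skin = plan$skin,
               hook_dz = plan$hook_dz)
  if (isTRUE(pr$state$diverged))
    warning("dynamics diverged during production; partial trace returned")
  tr <- pr$trace
  tr$x_stage <- tr$x_stage - tr$x_stage[1] + (tr$x_stage[2] - tr$x_stage[1])
  attr(tr, "plan") <- plan
  list(trace = tr, state = pr$state)
}

#' Steady-state averages of a friction trace
#'
#' Discards the initial transient -- at least `discard_nm` of stage travel
#' and, for stick-slip traces, at least up to the end of the first slip
#' event -- then reports the mean shear stress with its RMS fluctuation bar
#' (large bars: stick-slip; small bars: smooth sliding), the regime label,
#' the U-h Pearson correlation (stick-slip only; undefined in smooth
#' sliding where h is identically 0), and the mean interlayer distance.
#'
#' @param trace a `zw_trace`.
#' @param discard_nm minimum stage travel discarded, nm.
#' @param ... slip-detection settings passed to [find_slip_events()].
#' @return object of class `zw_summary`.
#' @export
steady_average <- function(trace, discard_nm = 20, ...) {
  x <- trace$x_stage
  x0 <- x[1]
  regime <- classify_regime(trace, ...)
  cut <- x0 + discard_nm
  ev <- find_slip_events(trace, ...)
  if (regime == "stick-slip" && nrow(ev) > 0) {
    cut <- max(cut, ev$x_end[1])
    if (all(ev$x_end <= x0 + discard_nm)) {
      ## need at least one slip inside the retained window
      regime <- if (nrow(ev) >= 2) regime else "unconverged"
    }
  }
  keep <- x >= cut
  if (sum(keep) < 2) {
    keep <- x >= stats::quantile(x, 0.5)
    warning("discard window covers the whole trace; using its second half")
  }
  s <- trace$stress[keep]
  rho <- NA_real_
  if (regime == "stick-slip")
    rho <- pearson_rho(trace$U[keep], trace$h[keep])
  out <- list(
    mean_stress = mean(s),
    rms_stress = stats::sd(s),
    regime = regime,
    rho_Uh = rho,
    mean_d = mean(trace$d[keep]),
    mean_h = mean(trace$h[keep]),
    n_slips = nrow(ev),
    window_nm = c(cut, max(x)) - x0,
    load = attr(trace, "load_mpa"),
    temperature = attr(trace, "temperature"),
    v_stage = attr(trace, "v_stage_ms")
  )
  class(out) <- "zw_summary"
  out
}

#' @export
print.zw_summary <- function(x, ...) {
  cat(sprintf("zw_summary: %s sliding\n", x$regime))
  cat(sprintf("  shear stress %.3f +/- %.3f MPa (RMS bar), %d slip events\n",
              x$mean_stress, x$rms_stress, x$n_slips))
  cat(sprintf("  <d> = %.3f nm, <h> = %.2f %%, rho_Uh = %s\n",
              x$mean_d, x$mean_h,
              if (is.na(x$rho_Uh)) "undefined" else sprintf("%.3f", x$rho_Uh)))
  if (!is.null(x$temperature))
    cat(sprintf("  conditions: T = %g K, L = %g MPa, v = %g m/s\n",
                x$temperature, x$load, x$v_stage))
  invisible(x)
}

#' Friction load cycle
#'
#' Runs consecutive sliding legs at the given sequence of loads (e.g.
#' 0 -> 20 -> 0 MPa), continuing the dynamic state from leg to leg, and
#' summarises each leg.  Loading and unloading visits to the same load are
#' reported separately along with the hysteresis (absolute difference of
#' their mean stresses) and a merged average.
#'
#' @param sys a `zw_system`.
#' @param loads numeric vector of loads, MPa, in cycle order.
#' @param plan base `zw_plan`; its `load` field is overridden per leg.
#' @param ff a `zw_forcefield`.
#' @param state optional starting `zw_state`.
#' @return list with `legs` (list of `zw_summary`), `table` (data.frame of
#'   per-leg means), `hysteresis` (data.frame per revisited load), and the
#'   final `state`.
#' @export
load_cycle <- function(sys, loads = c(0, 5, 10, 15, 20, 15, 10, 5, 0),
                       plan = default_plan(), ff = default_forcefield(),
                       state = NULL) {
  legs <- vector("list", length(loads))
  if (is.null(state)) state <- init_state(sys, plan$temperature, plan$seed)
  for (i in seq_along(loads)) {
    p <- plan
    p$load <- loads[i]
    ## the first leg keeps the plan's running-in; later legs continue and
    ## only need a short re-equilibration, which the discard rule covers
    if (i > 1) p$runin_nm <- min(plan$runin_nm, 0.2)
    ex <- run_experiment(sys, p, ff, state = state)
    state <- ex$state
    legs[[i]] <- steady_average(ex$trace, discard_nm = p$discard_nm)
  }
  tab <- data.frame(
    leg = seq_along(loads), load = loads,
    phase = ifelse(seq_along(loads) <= which.max(loads), "loading", "unloading"),
    mean_stress = vapply(legs, function(s) s$mean_stress, 0),
    rms_stress = vapply(legs, function(s) s$rms_stress, 0),
    mean_d = vapply(legs, function(s) s$mean_d, 0),
    regime = vapply(legs, function(s) s$regime, "")
  )
  hys <- NULL
  for (L in unique(loads)) {
    idx <- which(loads == L)
    if (length(idx) >= 2) {
      m <- tab$mean_stress[idx]
      hys <- rbind(hys, data.frame(
        load = L,
        hysteresis = abs(m[1] - m[length(m)]),
        mean_merged = mean(m),
        rms_max = max(tab$rms_stress[idx])))
    }
  }
  list(legs = legs, table = tab, hysteresis = hys, state = state)
}

#' @export
plot.zw_trace <- function(x, what = c("stress", "h", "U", "d"), ...) {
  what <- match.arg(what)
  ylab <- switch(what, stress = "shear stress (MPa)", h = "hooking h (%)",
                 U = "potential energy U (eV)", d = "interlayer d (nm)")
  graphics::plot(x$x_stage - x$x_stage[1], x[[what]], type = "l",
                 xlab = "stage displacement (nm)", ylab = ylab, ...)
  invisible(x)
}
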