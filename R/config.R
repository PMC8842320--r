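## YAML experiment configuration: one file fully captures an experiment.

#' Default experiment configuration
#'
#' @return nested list with `system` (cell search window, molecule spacing,
#'   charge flag, assembly seed), `forcefield` overrides, and `plan`
#'   (temperature, load, velocity, travel, strides, seed).
#' @export
default_config <- function() {
  list(
    system = list(molecule_spacing = 0.82, angle_window = c(15, 25),
                  max_dims = 15, mismatch_tol = 1e-3,
                  charge_on = TRUE, initial_gap = 0.5, seed = 1),
    forcefield = list(morse_alpha = 15, rc = 1.0, D0_default = 0.010,
                      r0_default = 0.41, D0_anchor = 5.0, r0_np = 0.82,
                      k_bond = 480, k_angle = 10,
                      ewald_accuracy = 1e-4, vacuum_factor = 3),
    plan = list(temperature = 300, load = 10, v_stage = 5,
                runin_nm = 10, production_nm = 100, discard_nm = 20,
                dt = 1e-3, gamma = 1, k_spring = 1,
                sample_every = 200, kspace_every = 5, skin = 0.3,
                hook_dz = 0, seed = 1)
  )
}

#' Read an experiment configuration file (YAML)
#'
#' Missing keys fall back to [default_config()].
#'
#' @param file path to a YAML file.
#' @return configuration list.
#' @export
read_config <- function(file) {
  user <- yaml::read_yaml(file)
  cfg <- default_config()
  for (sec in names(cfg)) {
    if (!is.null(user[[sec]])) {
      for (k in names(user[[sec]])) cfg[[sec]][[k]] <- user[[sec]][[k]]
    }
  }
  cfg
}

#' Build the system described by a configuration
#'
#' @param cfg configuration list from [read_config()]/[default_config()].
#' @return a `zw_system`.
#' @export
system_from_config <- function(cfg) {
  sc <- cfg$system
  cell <- find_commensurate_supercell(sc$molecule_spacing,
                                      unlist(sc$angle_window),
                                      sc$max_dims, sc$mismatch_tol)
  tpl <- molecule_template(charge_on = isTRUE(sc$charge_on),
                           k_bond = cfg$forcefield$k_bond,
                           k_angle = cfg$forcefield$k_angle)
  assemble_system(cell, charge_on = isTRUE(sc$charge_on),
                  initial_gap = sc$initial_gap, seed = sc$seed,
                  template = tpl)
}

#' Build the force field described by a configuration
#'
#' @param cfg configuration list.
#' @return a `zw_forcefield`.
#' @export
forcefield_from_config <- function(cfg) {
  f <- cfg$forcefield
  default_forcefield(morse_alpha = f$morse_alpha, rc = f$rc,
                     D0_default = f$D0_default, r0_default = f$r0_default,
                     D0_anchor = f$D0_anchor, r0_np = f$r0_np,
                     ewald_accuracy = f$ewald_accuracy,
                     vacuum_factor = f$vacuum_factor)
}

#' Build the run plan described by a configuration
#'
#' @param cfg configuration list.
#' @return a `zw_plan`.
#' @export
plan_from_config <- function(cfg) {
  do.call(default_plan, cfg$plan)
}
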