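# Desk-scale sliding experiment: zwitterionic system, 300 K, 10 MPa.
# Any key omitted here falls back to default_config().
system:
  molecule_spacing: 0.82     # nm; rigid-node spacing is half of this
  angle_window: [15, 25]     # degrees, relative rotation window
  max_dims: 4                # nm; smallest rotated cell (14 molecules/layer)
  mismatch_tol: 1.0e-3
  charge_on: true            # false = charge-free control
  initial_gap: 0.5           # nm between the opposing CA planes
  seed: 0
forcefield:
  k_angle: 10                # eV/rad^2
  ewald_accuracy: 1.0e-3     # eV/nm (production setting)
plan:
  temperature: 300           # K
  load: 10                   # MPa
  v_stage: 5                 # m/s
  runin_nm: 1
  production_nm: 4
  discard_nm: 1.2
  sample_every: 200          # steps between trace samples
  kspace_every: 20           # reciprocal-space refresh stride
  skin: 0.1                  # nm neighbour-list skin
  seed: 3
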