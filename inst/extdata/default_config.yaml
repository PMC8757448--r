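# Run configuration for the sorption / adhesion pipeline.
# Keys carry their units as suffixes; unknown top-level keys are rejected.

geometry:
  fluid_volume_uL: 200        # medium volume over the disk
  disk_diameter_mm: 6         # disk (and fluid column) diameter

protein:                      # Langmuir kinetics of the fitted model
  k_a_mL_per_ug_h: 6.2e-4     # adsorption coefficient
  k_d_per_h: 0.2              # desorption coefficient
  c_s_max_ug_per_mm2: 31.5    # maximum surface concentration
  D_mm2_per_h: 0.3            # serum-albumin diffusion coefficient, 37 C

cell:
  gamma: 0.63                 # survival fraction of seeded cells
  c_0_cells_per_cm2: 3500     # seeding density
  c_m_cells_per_cm2: 1.6e+5   # capacity: one 25 um spread cell per square
  k_cm2_per_cells_h: 1.31e-5  # constant adhesion coefficient (uncoupled runs)

transfer:                     # coverage -> adhesion coefficient coupling
  a_cm2_per_cells_h: 1.32e-5  # asymptotic adhesion coefficient
  b_mm2_per_ug: 0.213         # protein sensitivity
  form: exponential

scenarios:                    # pre-incubation conditions, h
  pre_incubation_h: [0, 24, 48]
  culture_h: 6
  initial_fluid_ug_per_mL: 9500

schedules:
  protein_h: [2, 4, 6, 8, 24, 48, 72]
  cell_h: [0.5, 1, 2, 4, 6]

noise:
  kind: multiplicative
  magnitude: 0.05             # CV of replicate scatter
  replicates: 3

output_dir: results
seed: 1
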