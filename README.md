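# sorbcell

Mechanistic modelling of protein adsorption/desorption on a biomaterial
disk and of the cell attachment that follows, for the standard well-plate
configuration used in surface-conditioning studies: a hydroxyapatite disk
under a quiescent 200 uL column of culture medium, incubated with serum
albumin and then seeded with osteoblast-like cells.

The package is for experimentalists and modellers who want to turn
fluid-phase depletion/release time series and attached-cell counts into
kinetic constants — and to know which of those constants the data actually
identify.

## The models

**Protein.** Fluid-phase concentration *c*(*z*, *t*) (ug/mL) obeys 1D
diffusion over the column height with zero flux at the free surface,

∂c/∂t = D ∂²c/∂z²,

coupled at the disk face (*z* = 0) to a Langmuir surface balance for the
areal coverage *c*ₛ (ug/mm²),

dcₛ/dt = kₐ c(0,t) (cₛᵐ − cₛ) − k_d cₛ,

with the diffusive flux at the face equal to dcₛ/dt. The capacity cₛᵐ is
derived from steady-state endpoints, cₛᵐ = cₛᶠ (1 + k_d/(kₐ cᶠ)), and
(kₐ, k_d) are fitted by exhaustive search on a 20 × 20 grid against
adsorption plus desorption series, scored by the relative RMS error in
percent. Sampling events can re-homogenise the column (drawing an aliquot
stirs the well), which matters because column diffusion is slow (h²/D ≈
170 h).

**Cells.** Seeded cells split into a free and an attached compartment;
a fraction γ arrives viable, nothing detaches:

dc_a/dt = k(t) (γc₀ − c_a)(c_m − c_a),  c_a(0) = 0,

with capacity c_m = 1.6 × 10⁵ cells/cm² from a 25 um spread-cell
footprint. In the cumulative exposure K(t) = ∫k dt′ the solution is closed
form and saturates at γc₀.

**Coupling.** Coverage modulates adhesion one way through a saturating
transfer function k(cₛ) = a (1 − e^(−b·cₛ)), so pre-incubating the disk
(0/24/48 h) changes how fast cells attach during the 6 h culture.

Synthetic-data generators run the forward models on the experimental
schedules with replicate noise, so every fitting stage is validated by
parameter recovery without any external data.

## Worked example

```r
library(sorbcell)

p    <- protein_params(k_a = 6.2e-4, k_d = 0.2, c_s_max = 31.5, D = 0.3)
geom <- well_geometry()          # 200 uL over a 6 mm disk

# adsorption: protein-rich medium over a bare disk
ads <- solve_protein_kinetics(p, geom, initial_fluid = 9500, t_end = 72)
ads
#> Protein trajectory: 201 output times over [0, 72] h, 200 depth cells
#>   mean fluid: 9500 -> 5318 ug/mL; surface: 0 -> 29.58 ug/mm^2
#>   mass ledger drift: 1.19e-10%

# desorption into fresh medium, column stirred at each sampling time
des <- solve_protein_kinetics(p, geom, initial_fluid = 0,
                              initial_surface = 29.04, t_end = 80,
                              output_times = c(0, 80),
                              mix_times = c(2, 4, 6, 8, 24, 48, 72))
round(100 * des$mass_fluid[2] / des$mass_surface[1], 1)
#> [1] 20.8        # percent of the coat released by 80 h

# coupled cell attachment after 48 h of pre-incubation
cp  <- cell_params(gamma = 0.63, c_0 = 3500)
tf  <- transfer_function(a = 1.32e-5, b = 0.213)
scn <- scenario(pre_incubation_h = 48, culture_h = 6, protein = p, cell = cp)
round(scenario_mean_cs(scn), 1)
#> [1] 29.3        # mean coverage (ug/mm^2) the cells experience
cells <- coupled_attached_cells(scn, tf, times = c(0.5, 1, 2, 4, 6))
round(cells$attached)
#> [1] 1432 1933 2171 2204 2205   # cells/cm^2; plateau = gamma * c_0
```

The fluid depletion 9500 → 5318 ug/mL corresponds (volume over disk area)
to the ~29.6 ug/mm² that accumulated on the surface; the 80 h release
fraction sits just below the closed-form equilibrium limit of 21.0%; and
by 6 h of culture essentially all 2,205 viable cells are attached.

## Analysis workflow

Numbered drivers under `analysis/` exercise the pipeline end to end and
write tidy CSV/JSON under `results/`:

| script | what it does |
| --- | --- |
| `01_protein_kinetics.R` | forward adsorption/desorption runs, equilibrium check, released fraction |
| `02_fit_protein.R` | synthetic series at the fitted constants → exhaustive (kₐ, k_d) grid fit, error surface |
| `03_cell_adhesion.R` | γ estimation and constant-k fits per pre-incubation condition |
| `04_coupled_model.R` | per-scenario mean coverage, coupled predictions, (a, b) transfer fit |
| `05_recovery.R` | repeated-seed recovery report (PASS/FAIL) for every fitting stage |

Each takes an optional seed argument, e.g.
`Rscript analysis/02_fit_protein.R 1`. Defaults live in
`inst/extdata/default_config.yaml` (unit-suffixed keys, unknown keys
rejected).

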