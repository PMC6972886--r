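# metacage

Desk-scale analysis chain for **electrostatic catalysis of reductive
elimination inside supramolecular nanocages** — the workflow that takes
enhanced-sampling output to a per-source decomposition of the activation
free energy.

Anionic hosts such as the Ga₄L₆¹²⁻ tetrahedron accelerate alkyl–alkyl
reductive elimination from cationic gold(III) complexes. Explaining *why*
requires: free-energy surfaces over two collective variables (the
methyl–methyl carbon distance and the Au–C coordination number
CN = ½ Σᵢ [1−(rᵢ/R₀)⁸]/[1−(rᵢ/R₀)¹⁴]); minimum-energy paths and barriers
on those surfaces; committor-validated transition states; TST rate ratios
exp(ΔΔG‡/RT); and the electrostatic stabilization each environment group
(bulk water, one complexed water, the cage) contributes through its field
projected on the two breaking Au–C bonds:

    ΔG_elec = Σ_{i=1,2} −0.048 (μ_TS^i · E_TS^i − μ_RS^i · E_RS^i)   [kcal/mol]

with bond dipoles μ in Debye and projected fields E in MV/cm.

The package is aimed at molecular-simulation practitioners who have (or
simulate) metadynamics hill files, CV trajectories and per-bond
field/dipole snapshots. Because the original ab initio trajectories are
not reproducible on a desk, a first-class synthetic-data module provides
double-well model potentials, seeded overdamped Langevin dynamics,
well-tempered hill streams at the literature schedule (height 0.005 Ha,
pace 30, dt 0.5 fs), and grouped point-charge environments with
analytically known fields — so every stage of the chain is tested against
ground truth.

Components:

| stage | functions |
|---|---|
| synthetic data | `make_double_well`, `langevin_trajectory`, `run_metadynamics`, `make_charge_environment` |
| collective variables | `methyl_distance`, `coordination_number`, `cv_series` |
| file formats | `read_hills`/`write_hills`, `read_xyz`, `read_fes`/`write_fes`, `read_snapshot_table` |
| FES | `bias_potential`, `reconstruct_fes`, `count_crossings` |
| minimum-energy path | `zero_t_string`, `barrier`, `fes_interpolate` |
| committor | `select_candidates`, `estimate_committor`, `is_transition_state` |
| kinetics | `tst_acceleration`, `dipole_field_energy_constant` |
| electrostatics | `project_field`, `bond_dipole`, `group_fields`, `delta_g_elec`, `decompose` |
| orchestration | `default_config`, `run_barrier_recovery`, `run_demo`, `metacage_cli` |

## Worked example

Decompose the packaged worked-example snapshot table (published fields
and dipoles for the catalyzed reaction), then recover a known barrier
from scratch:

```r
library(metacage)

tab_cat   <- read_snapshot_table(metacage_fixture("table1_catalyzed.csv"))
tab_uncat <- read_snapshot_table(metacage_fixture("table1_uncatalyzed.csv"))
decompose(tab_cat)
#> Electrostatic TS stabilization (kcal/mol):
#>   bulk_water          9.066
#>   complexed_water   -13.623
#>   cage               -1.041
#>   total              -5.597

cmp <- compare_decompositions(decompose(tab_cat), decompose(tab_uncat))
cmp$difference
#> [1] -4.890245
```

The bulk water *destabilizes* the transition state (+9.1 kcal/mol, its
fields misalign with the breaking bonds), the single complexed water is
the dominant stabilizer (−13.6), the cage adds a small direct
stabilization (−1.0); net versus the uncatalyzed reaction the
electrostatics favor the catalyzed transition state by ≈ 4.9 kcal/mol.

Barrier recovery on synthetic ground truth — well-tempered metadynamics
on a 6 kcal/mol double well until the dividing surface is well sampled,
FES reconstruction, 30-image string, committor check at the found TS:

```r
rec <- run_barrier_recovery(6, default_config(), seed = 1)
rec$barrier$dG
#> [1] 6.238371        # true barrier: 6 kcal/mol
rec$barrier$ts_point
#> [1] -0.01452  0.14250  # true saddle: (0, 0)

cr <- estimate_committor(make_double_well(6, 1, 8), rec$barrier$ts_point,
                         basins_from_path(rec$path), friction = 50, seed = 2)
cr$p_product
#> [1] 0.4875      # Wilson 95% CI [0.439, 0.536] — a genuine transition state
```

`run_demo(seed, out_dir)` chains the whole analysis (two pathways, TST
ratio of the recovered barriers, committor validation, worked-example
decomposition) and writes a single JSON summary plus the resolved
configuration, reproducible bit-for-bit from the seed.

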