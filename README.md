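# bioheat3d

Finite-difference simulation of heat transfer through the scalp, skull,
and cerebrospinal-fluid (CSF) layers of the forehead while a cool wet
cloth is held against the skin — the classic tepid-sponge treatment for
fever. The package is for modellers who want a small, fully verified
bioheat solver: it provides a steady-state sparse solver, a
stability-guarded explicit transient solver with a cloth-reset schedule,
closed-form verification oracles, and comparison tooling against published
reference temperature tables.

## The model

Heat transport in living tissue follows the Pennes bioheat equation,
which adds blood perfusion and metabolic heat to ordinary conduction:

```
rho c dT/dt = k (Txx + Tyy + Tzz) + mb cb (TA - T) + Qm + Qe
```

* `k`, `rho`, `c` — per-layer conductivity, density, heat capacity
  (scalp / skull / CSF values ship in `default_materials()`);
* `mb cb (TA - T)` — perfusion exchange with arterial blood at the fever
  temperature `TA` (38, 39.5, or 41 °C in the shipped cases);
* `Qm` — metabolic heat (zero in skull and outer scalp);
* surface boundary `k dT/dx = he (T - Tw)` (Robin) or `T = Tw`
  (Dirichlet) couples the skin to the 7 °C cloth; the deep face is held at
  `TA`; lateral faces are zero-flux.

Both solvers discretise a cuboidal patch (default 8×8×8 mm, spacing
2 mm) with the seven-point stencil. The explicit transient scheme is
stepped strictly below its stability limit
`rho c h^2 / (6 k + h^2 mb cb)` (2.47 s at 2 mm — the skull binds) with
the published 2-minute reading interval treated as an output schedule,
and the cloth re-clamped to 7 °C every 2 minutes.

## Worked example

```r
library(bioheat3d)

cfg <- preset_scenario("case1_38C", surface = "dirichlet")  # 38 C fever, clamped skin
fld <- solve_steady(cfg)
fld
#> temperature_field (case1_38C): range 7.00 .. 38.00 C over 125 nodes
sapply(0:4, function(i) field_at(fld, i, 0, 0))   # centreline, skin -> brain
#> [1]  7.00 14.77 22.53 30.27 38.00
```

The skin sits at the cloth temperature and warms monotonically to the
fever temperature at the brain side; the gradient is steepest in the CSF
(lowest conductivity). Comparing against the published 38 °C steady table:

```r
compare_reference(fld, "table1")
#> comparison vs table1 (steady): 72 entries, max |dT| = 7.08 C, mean = 2.95 C
#>   within 0.50 C: 8 / 72; symmetry-suspect fixture rows: 40
#>   64 entries miss the 0.50 C band; largest at (3,2,-2): model 30.27 vs printed 37.35
```

The large lateral-edge misses are a property of the reference table, not
of the solve: the printed values rise toward the patch edges, which no
solution with zero-flux lateral boundaries can do, and many printed rows
break the problem's own mirror symmetry (`symmetry_audit()` lists them).
See the methods vignette (`vignettes/bioheat-methods.Rmd`) for the full
analysis.

A transient run with 2-minute cloth resets, watching a mid-scalp node:

```r
res <- run_transient(preset_scenario("case1_38C", mode = "transient"))
cooling_curve(res, c(2, 0, 0))
#>   t_s      T_C
#> 1 120 26.30070
#> 2 240 28.69829
#> 3 360 29.84750
```

There is also a thin command-line wrapper (`inst/exec/bioheat3d`) over the
same functions:

```sh
Rscript inst/exec/bioheat3d run --config case1_38C --out results/
Rscript inst/exec/bioheat3d compare --result results/case1_38C_steady_long.csv --fixture table1
Rscript inst/exec/bioheat3d verify --suite slab-convergence
```

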