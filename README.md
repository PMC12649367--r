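# tfusim

Simulation of transcranial focused ultrasound (tFUS) transmission through a
five-layer axisymmetric human head model: coupling gel, skin, outer cortical
bone, trabecular (diploe) bone, inner cortical bone, and brain, separated by
concentric circular-arc interfaces of the regional skull curvature, and
driven by a spherically focused transducer cap.

The package is aimed at computational acousticians and tFUS researchers who
need a self-contained, scriptable model of how skull thickness, curvature,
and drive frequency shape the intracranial field — without a commercial FEM
license or patient imaging.

Two solvers share one material model and one grid:

* a **linear frequency-domain** solver for the inhomogeneous Helmholtz
  equation, with thermoviscous losses as an equivalent fluid
  (`c_c = c (1 + iωδ/c²)^{1/2}`, `ρ_c = ρ (1 + iωδ/c²)^{1/2}`) and
  perfectly matched layers;
* a **nonlinear time-explicit** solver for the conservative first-order
  Westervelt system

  ```
  (1/ρc₀²) ∂p/∂t + ∇·[(1 + βp/ρc₀²) u] = 0
  ρ ∂u/∂t + ∇p = δρ ∇(∇·u),        β = 1 + B/(2A)
  ```

  stepped by classical RK4 under per-class Courant bounds (0.2 soft tissue,
  0.1 bone), with an exponential sponge absorber.

Both realize the same loss contract — plane-wave attenuation
`α = δω²/(2c³)` from the tissue sound diffusivity `δ(f)` — which the test
suite enforces against closed forms. Outputs are the field metrics used in
tFUS planning: sound transmission loss `STL = 20·log₁₀(p_transducer/p_focus)`,
maximum pressure ratio, focal depth, the 5%-of-peak focus zone, and harmonic
spectra at interface probes.

## Worked example

Build a temporal-window scenario (3.5 mm skull, 65 mm radius of curvature),
rasterize it at 0.5 MHz, solve the frequency-domain field, and read off the
focal metrics:

```r
library(tfusim)

decompose_skull(8)
#>      outer trabecular      inner
#>   3.761194   2.000000   2.238806

sc <- region_preset("temporal", 3.5, 65, source_frequency = 0.5e6,
                    brain_depth = 60)
g  <- rasterize(sc, N0 = 1)
g
#> <grid_model> 94 x 173 cells (r x z), dx = 0.5167 mm, f0 = 0.5 MHz
#>   z span [-5.9, 82.9] mm, absorber width 6.20 mm, 72 source cells

sol <- helmholtz_solve(g, source_amplitude = sc$source_pressure)
env <- Mod(sol$pressure)
pr  <- standard_probes(g)
fm  <- focal_metrics(env, g, sc$source_pressure)
fm
#> <focal_metrics> peak ratio 4.339, depth 28.2 mm (11.4 mm intracranial)
#>   focus zone: 59.9 mm axial, 1131.3 mm^2 (threshold 5% of peak)
stl_db(env[pr$i[1], pr$k[1]], fm$peak_pressure)
#> [1] 5.17
```

The peak ratio says the brain-side maximum is 4.3 times the 1 MPa drive
(focusing gain net of skull loss); the focal depth is the axial position of
the on-axis brain maximum measured from the transducer apex — at 0.5 MHz
through the thin temporal window it sits just inside the skull, pulled
proximal of the 65 mm geometric focus by standing-wave structure; the focus
zone is the connected region above 5% of that peak, which at this low
frequency spans essentially the whole modelled brain depth. The STL value
is the dB drop from the transducer-adjacent probe to the brain peak
(negative values mean focusing gain exceeds the losses).

The same scenario runs in the nonlinear time solver via
`westervelt_run(g, synth_pulse(0.5e6, 1e6, n_cycles = 3), probes = pr)`,
and `compare_fd_td(sc)` quantifies what the linear frequency-domain model
misses (its STL deficit and the harmonic content at the focus).
`run_sweep()` / `sweep_report()` orchestrate the parametric studies over
frequency, skull thickness, curvature and source pressure.

See the methods vignette (`vignettes/tfus-methods.Rmd`) for the governing
equations, discretization and verification strategy, including the
documented solver cross-validation mode.

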