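# curvsense

Analysis machinery for quantifying how banana-shaped BAR-domain proteins
(e.g. the F-BAR domain of Pacsin1) **sense** and **induce** lipid-membrane
curvature in coarse-grained simulation snapshots.

A laterally compressed, tensionless bilayer buckles into the Euler
elastica, exposing a continuum of curvatures along one periodic arch. A
single protein diffusing on that surface samples positions and
orientations according to its curvature preference — no pulling, no
restraints. `curvsense` turns bead coordinates from such a setup into
quantitative curvature-sensing results, and complements them with
curvature-induction metrics (circle fits of bent membranes) and an
elastic-theory estimate of how densely the protein must coat a membrane
tube to stabilize it.

## The model in brief

* **Buckle geometry.** With arc length $s$ over one period $L$ and
  elliptic parameter $m$ fixed by the compression ratio
  $\gamma = (L - L_x)/L$ via $L_x/L = 2E[m]/K[m] - 1$:

  $$x(s) = 2\lambda E[\mathrm{am}(s/\lambda, m), m] - s, \qquad
    z(s) = 2\lambda\sqrt{m}(1 - \mathrm{cn}(s/\lambda, m)), \qquad
    \lambda = L/4K[m]$$

  $$\psi(s) = 2\arcsin\{\sqrt m\,\mathrm{sn}(s/\lambda, m)\}, \qquad
    C(s) = \frac{d\psi}{ds} = \frac{\sqrt{2(\cos\psi - (1-2m))}}{\lambda},
    \qquad C(s,\theta) = C(s)\cos^2\theta$$

  where $\theta$ is the in-plane angle between the protein's first
  principal axis and the buckling direction.

* **Mapping.** Each snapshot is aligned to the analytic profile (peak
  centring by circular cross-correlation of the binned membrane height),
  the protein centre of mass is inverted through the monotone $x(s)$ to a
  normalized arc position $s_\mathrm{norm} = s/L$, and $\theta$ is folded
  into $[0^\circ, 90^\circ]$.

* **Statistics.** Boltzmann inversion with a density-of-states correction,
  $F(R) = -\ln[P_\mathrm{obs}(R)/P_\mathrm{geom}(R)]$ in $k_BT$, anchored
  at the flattest populated radius bin, gives the free-energy profile
  along the radius of curvature and the binding free energy
  $\Delta G_\mathrm{bind}$ at any radius.

* **Tube coverage.** $f_\mathrm{tube}(R) = k_c/2R^2$ and
  $\rho = f_\mathrm{tube}(R_\mathrm{bind})/|\Delta G_\mathrm{bind}|$: the
  areal protein density at which binding pays for bending.

Everything the pipeline consumes can also be generated synthetically with
known ground truth (buckled bead sheets, placed banana proteins,
Metropolis ensembles over $(s, \theta)$, cylindrically bent sheets,
flexing conformer ensembles), which is how the package tests itself.

## Worked example

Generate a synthetic curvature-sensing experiment — one protein with a
2 $k_BT$ binding preference for radii between 17 and 33 nm, on a 10%
compressed buckle — then run the sensing pipeline and the tube-coverage
estimate:

```r
library(curvsense)

bp <- buckle_profile(L = 37.8, gamma = 0.1)
bp
#> <buckle_profile>
#>   gamma  = 0.1   (L_x/L = 0.9)
#>   L      = 37.8 nm   L_x = 34.02 nm
#>   m      = 0.098717633   (elliptic parameter, exact)
#>   lambda = 5.86274 nm   peak height = 7.36814 nm
#>   max curvature 2*sqrt(m)/lambda = 0.107183 1/nm (R_min = 9.33 nm)

cfg <- generator_config(seed = 7, n_frames = 5000)   # step well, -2 kBT on 17-33 nm
sim <- run_generate(cfg)                             # Metropolis samples + rendered frames
res <- run_sense(sim$frames, bp, R_bind = 25)        # align -> map -> occupancy -> F(R)

res$landscape
#> <curvature_landscape> 5000 placements in 50 x 45 (s_norm x theta) bins
#>   mode bin: s_norm = 0.890, theta = 37.0 deg (R = 19.2 nm)

round(res$dG_bind, 2)
#> [1] -2.02

required_density(kc = 20, R_bind = 25, dG_bind = round(res$dG_bind, 1))
#> <tube_coverage>
#>   k_c      = 20 kBT    R_bind = 25 nm    dG_bind = -2 kBT
#>   f_tube   = 0.016 kBT/nm^2
#>   rho      = 0.008 proteins/nm^2
#>   area per protein = 125 nm^2
```

Reading the output: the protein's most populated (position, orientation)
bin sits on membrane regions whose local radius of curvature (~19 nm here)
falls inside the imposed preference band; the free-energy profile read at
25 nm recovers the imposed −2 $k_BT$ binding free energy; and at that
preference, elastic theory says about one protein per 125 nm² — a dense
coat — is needed to stabilize a 50-nm-diameter tube against a bending
rigidity of 20 $k_BT$.

`autoplot()` methods exist for the occupancy/curvature landscape, the
free-energy profile and circle fits; `plot_buckle()` draws the analytic
profile. Real trajectories enter through `read_frames()` (GRO, PDB, or a
role-labelled XYZ table) and the same `run_sense()` / `run_bend()` calls.

## Further reading

The methods vignette (`vignettes/curvature-sensing.Rmd`) documents the
model assumptions, every tunable parameter with its default and units,
what the synthetic generators do and do not emulate, the numerical
choices (elliptic-function evaluation, circle-fit refinement, reference
states, degenerate-input handling), and known limitations.
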