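---
title: "Quantifying membrane-curvature sensing on a buckled bilayer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-curvature sensing on a buckled bilayer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(curvsense)
```

## The problem

Banana-shaped BAR-domain proteins (the F-BAR domain of Pacsin1 is the
motivating case) both bend membranes and preferentially bind membranes that
are already bent. A clean way to measure the *sensing* side in simulation is
to let one protein diffuse on a laterally compressed — buckled — bilayer.
The buckle exposes a continuum of curvatures along its arc, so the protein's
equilibrium position and orientation encode its curvature preference,
without any applied force. `curvsense` implements the analysis machinery for
this experiment: the analytic buckle geometry, the mapping from bead
coordinates to a position/orientation on the buckle, the statistics that
turn an ensemble of such placements into a free-energy profile along the
radius of curvature, circle-fit curvature estimation for bent sheets and
for the protein itself, and the elastic-theory tube-coverage estimate.

## The buckled-membrane model

A tensionless, laterally compressed elastic sheet adopts the Euler elastica.
With arc length $s$ along the profile, the parametrization is

$$x(s) = 2\lambda\,E[\mathrm{am}(s/\lambda, m), m] - s,
  \qquad z(s) = 2\lambda\sqrt{m}\,\bigl(1 - \mathrm{cn}(s/\lambda, m)\bigr),$$

where $m$ is the elliptic *parameter* (the square of the elliptic modulus —
all special-function calls in the package use the parameter convention,
matching `pracma` and `scipy.special`), and $\lambda = L/4K[m]$ is the
characteristic length for one buckle period of arc length $L$. The
compression ratio $\gamma = (L - L_x)/L$ fixes $m$ through

$$\frac{L_x}{L} = \frac{2E[m]}{K[m]} - 1 .$$

Two routes to $m$ are provided. `elliptic_parameter_series()` evaluates the
four-term expansion
$m = \gamma - \gamma^2/8 - \gamma^3/32 - 11\gamma^4/1024$, the closed form
usually quoted for weak compression; `elliptic_parameter_exact()` inverts
the complete-elliptic-integral relation by bracketed root finding to a
residual below $10^{-10}$. The exact inversion is the default in
`buckle_profile()` because it removes truncation error; at $\gamma = 0.1$
the two agree to about $10^{-7}$, and the test suite checks both routes
against an independent bisection oracle.

The tangent angle and the curvature fields follow in closed form:

$$\psi(s) = 2\arcsin\{\sqrt{m}\,\mathrm{sn}(s/\lambda, m)\},\qquad
  C(s) = \frac{d\psi}{ds}
       = \frac{\sqrt{2(\cos\psi - (1 - 2m))}}{\lambda},$$

and a protein whose long axis makes an in-plane angle $\theta$ with the
buckling direction feels, by Euler's curvature theorem with principal
curvatures $c_1 = C(s)$ and $c_2 = 0$,

$$C(s, \theta) = C(s)\cos^2\theta .$$

```{r buckle}
bp <- buckle_profile(L = 37.8, gamma = 0.1)
bp
```

```{r buckle-plot, fig.height = 2.5}
plot_buckle(bp)
```

The only numerical ingredient beyond `pracma`'s complete elliptic integrals
and Jacobi functions is the Jacobi epsilon function
$\varepsilon(u) = \int_0^u \mathrm{dn}^2(w, m)\,dw$, which gives the
incomplete $E$ term of $x(s)$. It is reduced to a quarter period by the
symmetries $\varepsilon(u + 2K) = \varepsilon(u) + 2E$ and
$\varepsilon(2K - u) = 2E - \varepsilon(u)$ and then integrated with
48-node Gauss–Legendre quadrature; the integrand is entire, so the result
is accurate to close to machine precision, and the test suite verifies
$x(L) = L_x$, arc-length closure, and $d\psi/ds = C(s)$ by central
differences at the $10^{-6}$ level.

### Choice of the period `L`

The buckle period is set by the simulation box, not by the theory, and it
is deliberately an explicit argument everywhere. The generator default
`L = 37.8` nm (so $L_x \approx 34$ nm at $\gamma = 0.1$) is an assumption
chosen to be of the order of a coarse-grained buckled-bilayer box; every
curvature in the package scales linearly with this choice, so analyses of
real data must pass the true box dimensions.

## Mapping snapshots onto the buckle

`map_trajectory()` reduces each snapshot to a placement
$(s_\mathrm{norm}, \theta)$:

1. **Alignment** (`align_to_profile()`). The membrane's mean head-bead
   height per $x$-bin (bin width $L_x/50$, 3-bin circular moving average)
   is matched against the analytic profile by circular cross-correlation
   over whole-bin shifts, with parabolic sub-bin refinement, and the frame
   is translated so the buckle crest sits at $x = L_x/2$. Correlating the
   whole binned profile rather than taking the argmax of the bin means
   matters: the two leaflets project onto the $x$ axis with unequal bead
   densities near the crest (the convex leaflet is stretched, the concave
   one compressed), which dents the mean-height curve exactly at the peak
   and makes a bare mode estimate ambiguous. The correlation uses the full
   arch shape and is insensitive to this artefact.
2. **Arc position** (`protein_arclength()`). The protein-backbone centre
   of mass (unweighted mean — coarse-grained backbone beads are nearly
   uniform in mass, and requiring no topology keeps the analysis
   reproducible from coordinates alone) is unwrapped through the periodic
   boundaries bead-by-bead along the chain, which stays correct even when
   the protein spans more than half the box. The monotone map $x(s)$ — its
   derivative is $\cos\psi = 1 - 2m\,\mathrm{sn}^2 > 0$ for $m < 1/2$ — is
   inverted by interpolation on a precomputed 4097-point table.
3. **Orientation** (`protein_orientation()`). The first principal axis of
   the backbone bead cloud is computed in 3D, projected onto the $x$–$y$
   plane, and the angle to the buckling direction is folded into
   $[0^\circ, 90^\circ]$: a principal axis is sign-free, and the curvature
   response depends only on $\cos^2\theta$. On a gently buckled membrane
   the difference between projecting a 3D axis and computing the axis
   in-plane is well under a degree.

Per-frame failures are logged and skipped; if more than 20% of frames fail,
the mapping aborts rather than returning a quietly decimated ensemble.

## From placements to a free-energy profile

`occupancy_map()` histograms placements over
$(s_\mathrm{norm}, \theta) \in [0,1) \times [0^\circ, 90^\circ]$ (default
$50 \times 45$ bins) next to the analytic $R(s,\theta)$ evaluated at the
bin centres — the two companion panels of the analysis.

`free_energy_profile()` performs the Boltzmann inversion

$$F(R) = -\ln\frac{P_\mathrm{obs}(R)}{P_\mathrm{geom}(R)} \quad [k_BT],$$

over log-spaced radius bins (default 24 bins from 10 to 200 nm plus an
overflow bin that also collects the infinite-radius sentinel returned for
curvatures below $10^{-6}\,\mathrm{nm}^{-1}$, e.g. at $\theta \to 90^\circ$).

The **density-of-states correction** $P_\mathrm{geom}$ — the distribution
of $R(s,\theta)$ under the uniform measure on the surface, evaluated on a
$2000 \times 900$ grid — is the load-bearing statistical decision in this
module. The raw histogram of $R$ conflates the protein's preference with
the amount of surface exhibiting each curvature; dividing by the geometric
measure makes a non-interacting ensemble exactly flat. That null is the
master test of the module and runs in the suite with $10^5$ uniform
samples. Because it is a genuine modelling choice rather than a theorem
about what any particular study did, the raw inversion remains available
via `correct_dos = FALSE`.

The profile is anchored at zero in its flattest (largest-$R$) populated
bin, the operational stand-in for a flat membrane; free-energy
*differences* between populated bins are independent of this choice, which
the tests assert. Empty bins are reported as `NA`, never as zero.

One identifiability caveat follows from this anchoring. The overflow bin
aggregates everything flatter than the last finite edge (200 nm by
default). If the true binding energy is still slightly favourable there —
as for a wide harmonic well in curvature, which only reaches zero exactly
at $C = 0$ — the "flat" reference absorbs that residual attraction and the
whole profile shifts shallow by the bin-averaged amount (about
$+0.2\,k_BT$ for a $2\,k_BT$ harmonic well at 25 nm with the default
edges). A binding model that is exactly zero outside a finite curvature
band, like the step well, has no such bias. This is a property of the
reference definition, not of the inversion; pushing the last finite edge
outward trades this bias for counting noise in an ever-thinner reference
bin.
`binding_free_energy()` reads the profile at a chosen radius by linear
interpolation in $\log R$ between populated bin centres.

## Circle fitting and shape metrics

`fit_circle()` initializes with the algebraic Kåsa solution of the linear
normal equations — deterministic and exact on any three non-collinear
points — and then refines by damped Gauss–Newton on the true radial
residuals. The refinement is not cosmetic: on a 30° arc with 0.3 nm bead
noise the algebraic radius is biased low by about 8%, while the geometric
fit is unbiased to within its 2% statistical spread (the package's
Monte-Carlo tests quantify both). Fits whose radius exceeds $10^4$ nm are
reported as a flat sentinel.

`membrane_radius_series()` estimates, per frame, the midsurface circle of
the whole bilayer, splits the head beads into leaflets by their radial
distance to it, fits the innermost (concave-side) leaflet, and flags
pathologies instead of returning silently wrong numbers: `flat` when a
straight line explains the beads as well as the circle, `degenerate` when
the fitted circle curls tighter than the patch it spans (the failure mode
of very short, noisy arcs, where the fit locks onto the bilayer thickness),
and `high_residual` when the radial scatter exceeds a threshold.

`rmsd()` (optional Kabsch superposition), `rmsf()` (five iterations of
mean-structure superposition) and `protein_curvature()` provide the
ensemble metrics used to validate coarse-grained elastic networks against
atomistic references. For the protein's side-view radius of curvature the
backbone is projected onto the plane of its long axis and whichever
transverse principal axis carries the larger quadratic (bow) signal; fixing
the plane to the first and third principal axes instead fails on flat,
arc-like bead chains, whose thinnest axis is the featureless out-of-plane
direction.

## The synthetic generators

Every input the pipeline consumes can be generated with known ground truth
(`generator_config()` + `make_buckled_sheet()`, `place_protein()`,
`sample_boltzmann_trajectory()`, `make_bent_sheet()`,
`make_conformer_ensemble()`), and every generator is a pure function of its
configuration and seed.

Defaults emulate a coarse-grained buckled-bilayer study at 10% lateral
compression: $\gamma = 0.1$, one period $L = 37.8$ nm, sheet depth 15 nm,
0.8 nm head-bead spacing, leaflets offset $\pm 2$ nm along the local
normal, 0.3 nm isotropic positional noise (the scale of thermal head-bead
roughness), and a protein arc of radius 25 nm, chord 15 nm, 21 beads. What
is *not* emulated, deliberately: lipid chemistry (head-bead geometry is all
that any downstream operation consumes), membrane shape response to the
protein, protein internal flexibility during placement sampling, and
thermal undulations of the buckle beyond isotropic bead noise. Passing
tests on these generators therefore demonstrate the correctness of the
analysis chain, not the realism of any force field.

Two conventions make the ground truth exact rather than approximate.
First, the protein arc is translated so that its *centre of mass* projects
onto the target arc position — the centre of mass is what the mapper
measures, and its standoff above the surface would otherwise bias the
recovered position by up to 0.02 in $s_\mathrm{norm}$ on the steep flanks.
Second, the arc's long axis is laid down so that its $x$–$y$ *projection*
makes the requested angle with the buckling direction, again matching the
measured quantity exactly even on slopes.

`sample_boltzmann_trajectory()` runs Metropolis Monte-Carlo in
$(s, \theta)$ with uniform base measure, Gaussian proposals
($\Delta s = 0.02L$, $\Delta\theta = 5^\circ$, auto-tuned towards 30–50%
acceptance if the rate leaves $[0.1, 0.9]$), periodic wrapping in $s$,
reflection at the $\theta$ boundaries, and 10× thinning. Two binding
models are built in, both parametrized by a well depth in $k_BT$ relative
to a flat membrane: a `step` well on a radius window (default 17–33 nm, a
broad band around a 25 nm preference), and a `harmonic` well
$U = w\,((C - C_0)/C_0)^2 - w$ with a unique preferred curvature
$C_0 = 1/R_\mathrm{pref}$. The step model is the package default for
generating study-condition ensembles; the harmonic model is what the
recovery tests impose when they need the occupancy mode to sit *on* the
preferred-curvature contour, because a step well is deliberately agnostic
about where within its window the protein sits.

## Test problem sizes and statistical design

The suite's statistical checks use sizes chosen so that each assertion has
clear power: $10^5$ samples for the uniform-ensemble null (all populated
radius bins within three counting errors of zero) and for the
Boltzmann-chain mode checks; 15 000 rendered and mapped frames per imposed
well depth (1, 2 and 4 $k_BT$) for the end-to-end recovery of the binding
free energy at 25 nm within $\pm 0.3\,k_BT$; 50 seeds per radius for the
bent-sheet recoveries at 2%; $10^4$ frames for the RMSF closed form at 5%.
The occupancy mode of a sampled histogram is read after a $3\times3$
boxcar smooth — along the preferred-curvature contour the expected
occupancy is exactly flat, so the unsmoothed argmax is a draw among tied
bins dominated by multinomial noise.

One statistical caveat is worth stating: for shallow wells
($\sim 1\,k_BT$) the occupancy ridge is flat to within a few percent over
a broad band of bins, so the *location* of the mode along (and slightly
off) the contour is intrinsically noisy even at $10^5$ samples; the
free-energy profile, which aggregates over the contour, is the robust
summary statistic.

## Tube coverage

With the bending rigidity $k_c$ (about $20\,k_BT$ for fluid bilayers) the
elastic cost per area of a tube of radius $R$ is
$f_\mathrm{tube} = k_c / 2R^2$, and the protein surface density needed to
pay for it out of the curvature-dependent binding free energy is
$\rho = f_\mathrm{tube}(R_\mathrm{bind}) / |\Delta G_\mathrm{bind}|$.
Everything stays in $k_BT$ units end to end, so temperature never enters
as a hidden parameter.

```{r tube}
required_density(kc = 20, R_bind = 25, dG_bind = -2)
```

## Known limitations

- The analytic profile is the zero-temperature elastica; thermally
  fluctuating buckle shapes are not modelled, and alignment quality
  degrades if real membranes deviate strongly from it.
- The Helfrich estimate carries no tension or spontaneous-curvature terms
  and no protein–protein interactions; it is an order-of-magnitude
  coverage estimate.
- Binary trajectory formats (XTC/TRR/DCD) are out of scope; convert to
  GRO/PDB/XYZ first.
- Error bars on free-energy profiles are counting errors only; no
  autocorrelation correction is applied to externally supplied
  trajectories.
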