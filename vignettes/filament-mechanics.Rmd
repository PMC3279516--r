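---
title: "Models and methods: simulating and analysing Ig-helix filament elasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and analysing Ig-helix filament elasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoelastica)
```

## Scope

`myoelastica` models the mechanics of modular filaments built from
immunoglobulin-like (Ig) domains and α-helical linkers — the architecture
of the C-terminal myomesin My9–My13 tail-to-tail dimer — and implements
the analysis procedures used on single-molecule force spectroscopy data
from such filaments. This vignette documents the models, the tunable
parameters, the numerical choices, and the limits of what the synthetic
data can show.

## The mechanical model

### Worm-like chain

All unfolded polypeptide is described by the Marko–Siggia interpolation
of the worm-like chain,

$$F(x) = \frac{k_BT}{p}\left[\frac{x}{L} +
\frac{1}{4\,(1-x/L)^2} - \frac14\right],$$

with persistence length $p = 0.5$ nm (the value used for unfolded
polypeptide in AFM contour calibration; it is *fixed*, never a free fit
parameter) and $k_BT = 4.114$ pN·nm at the 298 K default. The inverse
$x(F)$ is obtained by safeguarded Newton iteration to a relative
tolerance below $10^{-8}$; `wlc_force()` and `wlc_extension()` round-trip
to better than $10^{-6}$ nm.

### Serial chain and folded-element compliance

Elements in series share the force and add extensions. By default every
*folded* element is itself represented as a short worm-like chain whose
contour equals its folded extent (`folded_compliance = "wlc"`), so the
whole tether is a single effective WLC whose contour length jumps by
exactly the element's `contour_gain` when it unfolds. This choice is
deliberate: the two standard analyses — fixed-persistence WLC segment
fitting and the contour-length transformation — both presuppose that the
tether behaves as one WLC. If folded extents were inextensible rods, the
single-WLC inversion $L = x/\varphi(F)$ would acquire a force-dependent
term $C/\varphi(F)$ that smears each contour-length peak by several
nanometres and destroys the 6 nm substructure that the analysis is meant
to resolve. A rigid-rod mode (`folded_compliance = "rigid"`) is kept for
comparison, with an affine fitting variant (`fit_wlc_segments(offset =
TRUE)`) that absorbs the rod contribution.

`contour_gain` is a *direct* generator parameter — the net ΔL the
analysis should recover — rather than a quantity derived from residue
counts, because folded end-to-end distances are not knowable to the
precision that would require. The consistency formula is still provided:
`expected_ig_contour_gain(n, d)` $= n \times 0.365\,\mathrm{nm} - d$, and
the canonical Ig defaults (92 residues, folded extent 3.88 nm) satisfy it
exactly for ΔL = 29.7 nm.

### Two-state helical linkers

Helix unfolding/refolding is fast compared with pulling, so linkers are
treated as equilibrium two-state elements. At constant force the
unfolded occupancy is

$$p_u(F) = \frac{1}{1 + \exp\!\left(-(F - F_{1/2})\,\Delta L_{\mathrm{eff}}/k_BT\right)},
\qquad \Delta L_{\mathrm{eff}} = \Delta L\,\varphi(F_{1/2}),$$

which is 0.5 at the midpoint force $F_{1/2}$ and essentially zero at
rest. During a simulated pull the helix states are *not* drawn from this
constant-force law: a helix in series with a cantilever changes the
force by flipping, so the correct conditional at fixed stage position
weighs the **total elastic energy** (cantilever deflection + chain
stretching) of the folded and unfolded branches, plus a folding free
energy $\Delta G_0 = \Delta L\,[F_{1/2}\varphi_{1/2} -
e(\varphi_{1/2})]$ calibrated so that the constant-force midpoint stays
at $F_{1/2}$ (here $e(\varphi)$ is the WLC stretching energy per unit
contour). Sampling instead from $p_u$ at the instantaneous force
flip-flops unphysically: unfolding drops the force, which immediately
drives refolding. Both branch energies are evaluated exactly at every
step with the same Newton solver used for the force balance.

One randomly chosen helix re-equilibrates per sample step (a random-scan
Gibbs update). Updating all linkers simultaneously from the lagged force
allows collective refolding coincidences that spike the force by over
100 pN mid-plateau; asynchronous single-element updates bound the
fluctuations at the single-helix scale (~5–10 pN), which is also what
asynchronous molecular transitions look like in reality. An optional
kinetic mode (`helix_mode = "kinetic"`) turns the same conditional into
a telegraph process with a symmetric attempt frequency.

### Bell–Evans Ig unfolding

Folded Ig domains unfold irreversibly (on the timescale of one trace)
with force-dependent rate $k(F) = k_0 \exp(F\,\Delta x/k_BT)$, applied
per step as probability $1 - \exp(-k(F)\,\mathrm{d}t)$ — exact for a
constant rate within a step. The defaults $k_0 = 10^{-4}\,s^{-1}$,
$\Delta x = 0.3$ nm are typical Ig-domain values; no kinetic parameters
are published for these particular domains, so they are free
configuration, always recorded in the trace metadata. The mean
unfolding force grows logarithmically with pulling speed, which the test
suite verifies over 200–5000 nm/s.

### Protocol and noise

The stage advances by `speed / sampling_rate` per step (20 kHz default,
matching the recording rate of the experiments), the cantilever is a
Hookean spring (6 pN/nm default), and the quasi-static force balance
$z = F/k_c + x_{\mathrm{mol}}(F)$ is solved to a residual below
$10^{-6}$ pN at every sample. Gaussian force noise (sd 3 pN default) is
added *after* the mechanics, so state transitions are noise-free and
detection robustness is a property of the analysis, not of the
generator. Identical seeds give bit-identical traces; multi-pull runs
derive per-pull sub-seeds deterministically.

## The canonical architecture

Per protomer: five Ig domains (My9…My13; 92 residues, folded extent
3.88 nm, ΔL 29.7 nm) alternating with four helical linkers (15/22/22/15
residues — two roughly four-turn and two roughly six-turn helices — ΔL
6 nm, midpoint 30 pN), dimerised tail-to-tail. The central My13 pair is
the dimerisation interface and is kept as a non-unfoldable rigid body,
so the dimer presents eight unfoldable Ig domains plus that central
body — nine rigid bodies in all. Exact linker boundaries are only known
graphically, so every count is overridable.

A separate configuration, `straightened_reference_architecture()`,
reproduces the published straightened-filament decomposition: ten
straightened modules of 29 Å (290 Å) plus 150 linker residues at the
3.8 Å Cα spacing (570 Å), i.e. 860 Å ≈ 2.5 × 340 Å. Only the class
totals are published; the per-linker split (15/22/23/15 per protomer) is
a declared configuration, not a derivation. Note the two distinct
unfolded-spacing constants: 3.8 Å/residue (Cα–Cα, length model) and
0.365 nm/residue (AFM contour calibration). They are kept as separate
named constants and never interchanged.

## Trace analysis

* **Event detection** (`detect_events()`): a drop of ≥ 10 pN within 1 ms
  while the stage advances, grouped into runs, one event per run at the
  force maximum. Events with peak force below 50 pN are discarded by
  default because reversible helix flicker inside the ~30 pN plateau
  also produces fast drops; Ig unfolding peaks sit far above it. The
  experiments publish no detection threshold, so these are declared
  defaults, all configurable.
* **Segment fitting** (`fit_wlc_segments()`): per rising segment, the
  single-parameter fit $x = L\,\varphi(F)$ at fixed persistence, linear
  least squares refined against force residuals (the noise lives in the
  force channel). Only samples above 40 pN enter, keeping the plateau
  out. ΔL is the increment between consecutive fitted contours. Two Ig
  domains occasionally unfold within the same millisecond; that is one
  observable drop of ≈ 2ΔL, which downstream means exclude by a
  1.5×median cut.
* **Contour-length transformation** (`contour_length_transform()`):
  $L = x/\varphi(F)$ per sample, for samples above a 5 pN force floor
  (below it the inversion amplifies noise; the floor is a declared
  default). On single-WLC input the output is constant to $10^{-6}$ nm.
* **Peak spacing** (`fit_peak_spacing()`): histogram (0.75 nm bins),
  one Gaussian per local maximum above 10% prominence — mirroring visual
  peak counting — then a sum-of-Gaussians least-squares fit; the spacing
  is the mean of successive component means.
* **Plateau detection** (`detect_plateau()`): median force per 0.5 nm
  extension bin, rolling-median smoothing over 5.5 nm (the scale of the
  plateau's two-state substructure), then the longest interval of span
  ≥ 10 nm with fitted |slope| ≤ 0.3 pN/nm whose smoothed endpoints stay
  within 2.5 pN of the interval mean — the endpoint criterion rejects
  the steep borders and the slowly rising toe of a long WLC, which can
  pass a bare slope test. The reported force is the median over raw
  samples in the interval. A sufficiently long WLC (toe slope below the
  tolerance) can still masquerade as a plateau; the force floor of
  10 pN and the declared tolerances bound, but do not eliminate, this.
* **Hysteresis** (`hysteresis()`): signed area between stretch and relax
  curves interpolated onto a common extension grid (trapezoidal rule).

## Problem sizes and reproducibility

The packaged analyses use the following sizes, chosen to give standard
errors comfortably inside the tolerances being checked: 50 fast pulls
(1 µm/s, ~400 ΔL increments) for the mean contour-length increment; 20
slow pulls (10 nm/s, 0–55 nm stage) for the plateau substructure and
peak spacing; 20 stretch–relax cycles for the plateau force and
hysteresis; the test suite runs scaled-down versions of the same
analyses (15/6/8). `scripts/acceptance.R` recomputes everything from a
single command-line seed.

## What the synthetic data do and do not show

The generator emulates: constant-velocity pulls of a serial Ig/helix
chain, near-equilibrium helix flicker and its force plateau with
substructure, sequential stochastic Ig unfolding, cantilever compliance,
sampling rate, and white force noise. It does **not** emulate cantilever
dynamics (resonance, damping, 1/f noise), baseline drift, surface and
multi-tether artefacts, refolding of Ig domains, or force-clamp
protocols. Passing the generator/analyzer closure tests therefore shows
that the analysis recovers the parameters of *this* forward model under
realistic noise — not that it is robust to every instrumental artefact
of real recordings.

## Geometry of composite filament models

Domain centroids are unweighted means of Cα positions (mass-weighted
all-atom centroids are available behind `weighting = "mass"`); the
published "centers of gravity" do not state a weighting, and the Cα
centroid is reproducible without element masses. Distance spectra pool
all pairs a fixed number of positions apart along the filament order,
intra- and inter-molecular alike; the dimerisation pair can be treated
as two domains (ten labels) or merged into one rigid body (nine bodies)
via `domain_centroids(merge = …)`.

Tilt/twist uses a fixed, documented convention: each domain's frame
comes from its Cα inertia tensor, the long axis (largest spatial extent)
sign-fixed N→C; **tilt** is the angle between long axes and **twist** is
the swing–twist component of the inter-domain rotation about the first
domain's long axis. The literature convention these angles are usually
quoted in is not fully specified, so numeric agreement with published
per-pair values is not promised; the package's own convention is exact
on constructions (a copy rotated about its long axis by θ returns twist
θ, tilt 0, and the synthetic superhelix round-trips its input twist to
within 0.1°). p(r) is the unnormalised histogram of all unordered Cα
pair distances (2 Å bins by default, left-closed), with
$R_g$ = root-mean-square distance from the centroid and
$D_{max}$ = largest pair distance.

Superposition is classical Kabsch (SVD) on Cα atoms matched by author
residue number through a shared domain label, with collinear point sets
rejected; the tests cross-check it against an independent reference
implementation. Composite models are assembled by fixing one fragment,
superposing each next fragment through the shared domain, and merging
(earlier copies of a domain win).

The deposited fragment coordinates of the real filament cannot be
shipped with the package, so the packaged validation of the full
geometry pipeline runs on `synthetic_filament_standin()`: a ten-module
regular superhelix whose rise (38.059 Å), radius (21.070 Å) and
per-module rotation (259.385°, equivalently −100.6°) were solved so that
its order-1/3/4 centroid distances are exactly the filament's published
50/116/153 Å distance windows, with $D_{max} \approx 360$ Å emerging.
It is labelled synthetic throughout: it reproduces the distance
spectrum, not the deposited coordinates, and its per-module rotation is
a geometric solution, not the filament's 26–27° twist (a regular helix
cannot produce those windows at a 26° twist; the real filament is not a
regular helix — its centre is a zigzag).

## Known limitations

* The quasi-static force balance ignores cantilever and chain inertia;
  at 20 kHz and the speeds used here that is standard, but resonance
  effects near real cantilever frequencies are out of scope.
* Helix state updates are one per sample step; the effective attempt
  rate is the sampling rate divided by the number of linkers. Much
  faster true rates would only narrow the flicker further.
* The event log records every Ig transition; helix toggles are counted
  always but logged individually only on request (`log_helix = TRUE`),
  because a linker near its midpoint toggles on the order of $10^3$
  times per slow pull.
* `detect_plateau()` tolerances are tuned for plateaus of the ~30 pN,
  ≥10 nm kind; very long WLC toes below ~0.3 pN/nm slope remain a
  theoretical false-positive source.
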