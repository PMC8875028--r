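---
title: "The vesicle-polymer shaping model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The vesicle-polymer shaping model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesimorph)
```

## The system

`vesimorph` simulates a minimal two-dimensional model of membrane shaping
by an adsorbing stiff filament: a **soft vesicle**, represented as a
closed self-avoiding bead-spring ring (a membrane cross-section with no
bending rigidity of its own), deformed by a **semiflexible linear
polymer** adsorbing onto its outside. Both chains carry `N + 1 = 61`
identical beads. Depending on the polymer's bending stiffness `kappa`
and the adsorption strength `eps_vp`, the wrapped composite takes
circular, oval, cigar-like, bent-cigar, racquet-like, double- or
triple-folded vesicle morphologies, or leaves the polymer as a rod with
only part of the vesicle attached.

All quantities are in reduced units: lengths in units of the maximum
bond extension `l_max`, energies in units of the thermal energy `kBT`.

## The Hamiltonian

Four terms, each with its own scope:

* **FENE bonds** along both chains (the ring has 61 bonds including the
  closure bond): `U(l) = -(k r0^2/2) log(1 - ((l - l0)/r0)^2)` with
  `k = 20`, `l0 = 0.7`, diverging at the open interval bounds
  `(l_min, l_max) = (0.4, 1)`. A bond at or beyond a bound is an invalid
  configuration (infinite energy); combined with excluded volume this
  prevents chain crossing in 2D.
* **Morse excluded volume** between all non-bonded bead pairs of the
  same chain: `eps (e^{-2 a (r - rmin)} - 2 e^{-a (r - rmin)})` with
  `a = 24`, `rmin = 0.8`, `eps = 1`. At this `a` the potential is
  negligible beyond `r = 1`, where it is truncated (unshifted). The ring
  closure pair counts as bonded.
* **Bending penalty** `kappa (1 + cos theta)` at the polymer's 59
  interior vertices, where `theta` is the interior vertex angle: a
  straight chain costs nothing, a full fold costs `2 kappa`. The vesicle
  is soft — no bending term.
* **Vesicle-polymer attraction**: a Lennard-Jones well
  `eps_vp ((rm/r)^12 - 2 (rm/r)^6)` between all inter-chain pairs, with
  its minimum `-eps_vp` at `rm = 0.8` (the same contact distance as the
  Morse minimum) and an unshifted cutoff at `2.5 rm = 2`. The `r^-12`
  core supplies the inter-chain excluded volume. An optional
  `morse_inter` switch additionally applies the Morse term between the
  chains (the natural alternative reading when all monomers are
  identical); it is off by default.

### The Lennard-Jones prefactor ambiguity

The inter-chain potential admits two standard writings,
`eps [(rm/r)^12 - 2 (rm/r)^6]` (well depth `eps` at `rm`) and
`4 eps [(s/r)^12 - (s/r)^6]` (well depth `eps` at `2^{1/6} s`), which
coincide when `s = rm 2^{-1/6}` — and a third, sloppy but common form
`eps [(s/r)^12 - (s/r)^6]` whose depth is only `eps/4`. These differ by
exactly the constant prefactor 4 at every distance.

We probed all three as the sampling convention at the reference state
points `kappa = 10` and `kappa = 50` with `eps_vp = 2`. Only the
well-depth convention (depth `eps_vp` at `rm`) produces the expected
physics: a fully wrapped, strongly adsorbed composite whose binding
loosens slightly as the polymer stiffens. Sampling at a quarter of that
depth desorbs the polymer entirely at `kBT = 1` (it is below the
adsorption transition for this chain length, whether started from a
tangent or a fully wrapped state), and at half the depth the
`kappa = 50` chain turns rod-like — qualitatively wrong on both counts.
The package therefore samples with the well-depth convention.

Reported adsorption energies, however, are conventionally quoted in the
unit-prefactor form `eps [(s/r)^12 - (s/r)^6]`, which is exactly one
quarter of the sampled pair sum. `scripts/acceptance.R` reports
`<U_VL>` in that measurement convention (and the raw pair sums
alongside); at desk scale the two reference state points land at about
−52 and −49, with the `kappa = 50` composite a few percent less bound
than the flexible one, matching the reference values −53.83 and −47.19
to within a few percent. Users comparing absolute adsorption energies
across conventions should keep this factor in mind; trends, shape
classes and transition locations are unaffected by it.

## Metropolis dynamics

A trial move displaces one uniformly chosen bead (of either chain) by
`(dx, dy)` drawn uniformly from `(-0.25, 0.25)^2`, and is accepted with
probability `min(exp(-dU/kBT), 1)`. The proposal is symmetric, so the
plain Metropolis ratio is correct; a move that would take a bond out of
`(l_min, l_max)` has `dU = +Inf` and always rejects. One Monte Carlo
step (MCS) is `2(N + 1) = 122` attempted moves, counting rejections.
With the default displacement width the acceptance rate sits near
0.3–0.45 across the phase diagram.

The energy difference of a move is computed incrementally from only the
terms touching the moved bead. Three devices keep the compiled kernel
honest and fast:

* per-bond FENE and per-vertex bending energies are cached, so only the
  *new* side of each touched term is evaluated per trial;
* Verlet neighbour lists (list radius = cutoff + skin, skin 2.0 by
  default) restrict the non-bonded scans; lists are rebuilt whenever any
  bead has moved more than `(skin - max_disp * sqrt(2))/2` since the
  last rebuild, which guarantees no interacting pair is ever missed;
* a running total energy is accumulated from accepted `dU` and
  resynchronized against a full recomputation every `1e4` MCS; the
  largest correction ever applied is reported per run
  (`max_energy_drift`, typically below `1e-9`).

The incremental path is pinned to an independent, vectorized R
implementation of the full energy (`total_energy()`) by consistency
tests (`1e4` random moves agree within `1e-9`), and the whole kernel is
pinned to a step-by-step replay through the public
`draw_move()` / `local_energy_delta()` / `metropolis_accept()`
primitives, which must reproduce the compiled trajectory move for move.

### Random numbers and reproducibility

The engine uses its own xoshiro256++ streams, independent of R's global
RNG. Every run is bit-reproducible given `(seed, schedule, params,
initial state)`; replica `i` of a run with base seed `s` uses the
stream seeded with `derive_seed(s, i)` (a splitmix64 hash, reduced
modulo 2^31). Each trial move consumes exactly four variates whether or
not it is accepted, which is what makes the replay test above exact.
Checkpoints store the stream state verbatim, so an interrupted run
resumed from a checkpoint is bit-identical to an uninterrupted one.

## Initial conformations and equilibration

The vesicle starts as a regular 61-gon with every edge at `l0` (the
circumradius is then 6.80). The polymer starts straight, tangent to the
vesicle at the contact distance `rm`, with a per-replica random rotation
about the vesicle centre; adsorption then nucleates at the contact point
within a few thousand MCS. A self-avoiding random-walk placement is
available as an alternative (`init_polymer(mode = "random-walk")`).

The reference protocol is `3e8` MCS per replica with 100 measurements
every `1e6` MCS and 100 replicas — a 2:1 equilibration:measurement
split. That scale is far beyond a desk machine, so the package's own
checks run a scaled-down rendition that preserves the split:

* `scripts/acceptance.R`: 10 replicas x `9e5` MCS (equilibration `6e5`,
  then 100 measurements every `3e3`) per state point, six state points;
  about 15 minutes on one core.
* `tests/testthat/test-acceptance.R`: the same state points at 4
  replicas x `4.5e5` MCS.

Equilibration traces at the reference state points (`kappa` 10 and 50,
`eps_vp = 2`) show the adsorption energy reaching its plateau within
`1e5`–`5e5` MCS from the tangent start, so the `6e5`-MCS equilibration
span holds a modest margin. The choice of desk scale trades statistical
and residual equilibration error against runtime; with 10 replicas the
replica-to-replica standard error of `<U_VL>` at these points is a few
percent. Slowly interconverting folded states (double versus triple
vesicles near their boundary) are the main thing desk scale cannot
resolve that the reference scale can: individual replicas can stay in
one fold topology for an entire desk-scale run, which inflates
replica-to-replica spread precisely at fold boundaries. Passing
desk-scale checks therefore demonstrates correct sampling of each basin
and correct trends, not converged populations at phase boundaries —
the reference protocol's 300-fold longer runs are what averages over
fold interconversion.

The clearest casualty of this limitation is the end-to-end distance of
the wrapped flexible chain (`kappa = 10`): where the chain's two ends
sit depends on the fold topology the replica happens to occupy, so the
desk-scale `<R_ee>` profile across the adsorption grid — and in
particular the location of its minimum — is not converged, even though
the adsorption energies along the same grid are stable to a few percent
(contact energies are nearly topology-independent). Results that hinge
on `<R_ee>` orderings between adsorbed states should be treated as
reference-scale quantities.

## Observables

Each measurement records:

* `u_vl` — the instantaneous vesicle-polymer LJ pair sum (the
  adsorption energy; see the convention note above);
* `r_ee` — the polymer end-to-end distance, near `N l0 = 42` for rods,
  around 2–8 for wrapped states;
* the **tangent-tangent correlation** `C(s)` of the ring's 61 bond
  vectors with periodic indexing, normalized to unit tangents by default
  (`C(0) = 1`). For raw bond vectors the closure identity
  `sum_s C(s) = 0` holds exactly for every configuration, and
  `C(s) = C(L - s)` holds exactly by index relabelling. A circular ring
  gives `cos(2 pi s/L)`; an n-fold folded vesicle shows n troughs;
* the gyration-tensor **asphericity** of the ring, 0 for a circle, 1
  for a line;
* the polymer's mean interior-angle cosine (used by the sampling
  checks).

**Trough counting** smooths `C(s)` with a periodic moving average
(window 5), finds local minima below zero, and enforces a minimum
circular separation of `L/10` samples, keeping the deeper of two close
minima (ties go to the leftmost index). The window and separation are
fixed, documented values chosen once: the window is the smallest that
removes single-sample noise wiggles at desk-scale statistics, and the
separation is well below the `~L/3` spacing of real triple-vesicle
troughs while merging split minima of a single flattened trough.
Because the fold position along the contour differs between replicas
(and averaging unaligned curves fills troughs in), fold counting is
done per replica and summarized by the modal count, rather than on the
pooled mean curve.

**Shape classification** (`classify_shape()`) applies ordered heuristic
rules on the ensemble descriptors: first the rod-with-partial-vesicle
case (near-fully extended polymer, weak contact), then the trough
count (3 = triple, 2 = double unless strongly elongated, 1 = circular
or oval by asphericity, 0 = random), and within the elongated
two-trough family the symmetry of `C` about `s = L/2` separates cigar
from bent-cigar, with a large trough-depth imbalance marking
racquet-like shapes. All thresholds live in `classify_thresholds()` and
raw descriptors are always reported alongside labels, so users can
re-threshold without re-running. The labels are a convenience
summarizing the descriptors, not an additional measurement.

## Verification oracles

Two quadrature oracles make the sampler falsifiable without any
reference to the engine:

* `fene_bond_oracle()` — the equilibrium bond-length density of a
  single FENE bond free in the plane is `p(l) ~ l exp(-U(l)/kBT)` (the
  factor `l` is the 2D radial measure). A two-bead chain sampled by the
  engine must match it; the acceptance suite requires a
  Kolmogorov-Smirnov distance below 0.01 at `1e6` samples.
* `wlc_angle_oracle()` — for an isolated chain with only the bending
  penalty, the interior angle has density `~ exp(-kappa(1+cos
  theta)/kBT)` on `[0, pi]` (the 2D angular measure is flat; bond-length
  and angle degrees of freedom factorize when the other couplings are
  off). The sampled `<cos theta>` must agree within 3 standard errors
  at `kappa` in {0, 1, 10, 100}; for large `kappa` the oracle approaches
  `-1 + kBT/(2 kappa)`.

Both comparisons switch the Morse term off, since excluded volume would
couple the degrees of freedom and invalidate the closed-form measures.

## Numerical choices and degenerate inputs

* Truncations are plain (unshifted); the LJ tail beyond `2.5 rm` is
  under half a percent of the well depth. No long-range corrections.
* `vertex_angle()` clamps the cosine into `[-1, 1]` before `acos`, so
  collinear triples are exact; coincident points are an error (they
  cannot arise in sampling, where the FENE bound rejects first).
* Bond validity is an open interval: a bond exactly at `l_min` or
  `l_max` is already invalid.
* The trial-counter convention: rejected moves advance the MCS clock;
  with `max_disp = 0` every move is an accepted identity.
* `count_troughs()` requires at least 8 samples; shorter curves are a
  user error, not a silent 0.

## Limitations

* Single-bead displacement dynamics equilibrates folded states slowly;
  no cluster, reptation or biased moves are provided, and free-energy
  barriers between fold topologies are not surmounted at desk scale
  (the reference protocol relies on brute length and replica count;
  locating exact transition points would need biased sampling, which is
  out of scope).
* The model is strictly two-dimensional with a soft (tensionless,
  rigidity-free) ring; no area constraint, osmotic term, or 3D membrane
  elasticity.
* The shape labels are heuristics over three descriptors; borderline
  states (bent-cigar vs racquet) are sensitive to their thresholds,
  which is why the descriptors themselves are always written out.
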