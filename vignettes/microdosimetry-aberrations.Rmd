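---
title: "Modeling nucleus microdosimetry and chromosome aberrations for high-energy ion beams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nucleus microdosimetry and chromosome aberrations for high-energy ion beams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microca)
```

## The problem

Cells exposed to high-energy ions (space radiation, ion-beam therapy,
ground-based radiobiology beams) receive energy through two channels: ion
tracks that traverse the nucleus directly, and delta electrons ejected by
tracks passing through neighboring cells, which can travel micrometers to
millimeters.  `microca` simulates both channels for a spherical nucleus,
scores the resulting nanometric dose against a 3D interphase chromatin
model, induces simple and complex DNA double-strand breaks (DSBs), follows
24 h of repair with distance-dependent misrepair, and classifies the
resulting chromosome exchanges.  The package separates every result into
*direct* (nucleus-crossing tracks, with their own delta electrons) and
*indirect* (delta electrons of tracks that miss the nucleus)
contributions.

The pipeline covers six reference mono-energetic beams from protons at
1000 MeV (LET 0.22 keV/µm) to iron at 1000 MeV/n (149.2 keV/µm), and
arbitrary poly-energetic fluence spectra such as those produced by beam
transport through tissue.

## Geometry and the track surrogate

The nucleus is a sphere of radius $R_T = 4$ µm centered in a cubic box of
side $L = 10$ µm with periodic boundary conditions (PBC), which emulate an
infinite uniform irradiation field: an electron leaving one face re-enters
on the opposite one, so the delta-electron bath of distant tracks is
represented by the wrapped electrons of the box's own chords.  The box
side is a free choice; because PBC make the chord density uniform, its
influence is weak (the nucleus diameter plus a 1 µm margin on each side).
For a dose $D$ and LET $L$, the fluence is the standard conversion
$\Phi = D / (0.1602\,L)$ (µm$^{-2}$, with LET in keV/µm), the number of
chords through the box is Poisson with mean $\Phi L^2$, and the expected
number of nucleus traversals is $\Phi \pi R_T^2$ — 1426 per Gy for the
0.22 keV/µm proton beam down to 2 for the iron beam.

Full event-by-event track structure is out of scope; in its place each
chord carries a parametric surrogate:

* a fraction `f_local` of the LET is deposited as discrete core events
  along the chord (exponential energies, mean `w0` = 60 eV);
* the remainder is emitted as delta electrons with a knock-on spectrum
  $dN/dT \propto 1/T^2$ between `T_cut` and the kinematic maximum
  $T_{max} = 2 m_e c^2 (\gamma^2 - 1)$, where $\gamma$ uses 931.5 MeV per
  nucleon uniformly;
* electrons perform a condensed random walk: per step they lose a fixed
  fraction (`step_frac` = 0.25) of their energy along the corresponding
  decrement of the residual range $R(E) = a E^p$ (defaults
  $a = 0.043$ µm keV$^{-p}$, $p = 1.67$), then scatter isotropically.

Within each step, 40% of the energy loss (`cluster_frac`) is deposited as
discrete *cluster* events with a $1/T^2$ spectrum on 100–2000 eV, and the
rest is spread continuously along the step path.  The cluster channel is
the surrogate's stand-in for energy-loss straggling (spurs and blobs):
without it, a fast electron deposits a nearly uniform few eV per 20 nm
voxel and can never exceed the 500 eV complexity threshold except at its
track end, which starves the indirect contribution of complex breaks and,
downstream, of exchanges.  The split is drawn so that each step's energy
is conserved exactly.

`f_local` and `T_cut` are the surrogate's calibration knobs.  They were
fixed once (`scripts/calibrate_surrogate.R`) so that the indirect share of
nucleus energy deposition falls in the 18–22% band across the six
reference beams: `f_local = 0.35`, `T_cut = 1500` eV.  With these values
the 1000 MeV/n beams sit near the top of the band (~21–22%) and the
250–325 MeV/n beams near 18–19%, reproducing the increase of the indirect
share with ion energy that follows from the larger $T_{max}$.

What the surrogate does *not* model: radial dose structure of the track
core, radiolysis chemistry, explicit secondary-electron cascades, nuclear
fragmentation along the chord, or magnetic fields.  Its per-track energy
deposition statistics are calibrated at the micrometer scale, not derived
from cross sections, so absolute LQ coefficients of exchange dose
responses should be read as model outputs of this surrogate, not as
reproductions of full track-structure codes.

## Chromatin, DSB induction and the 500 eV rule

Interphase chromatin is modeled as 46 fibers (human diploid karyotype,
22 autosome pairs plus XX; lengths from the reference assembly, packaged
as `inst/extdata/genome_human.csv`), each a fixed-step random walk
confined to the sphere with radial reflection at the boundary.  The step
is one voxel (20 nm) and the resolution is 250 segments per Mbp (~4 kbp
per segment, ~31 mm total fiber), which gives a chromatin occupancy of
roughly 4% of nucleus voxels — enough that voxel-level damage-chromatin
coincidence is selective, while staying tractable.  Fibers have no
excluded volume and no territories; the genomic bookkeeping (fiber,
segment) only needs to identify the chromosome and an approximate locus.

Energy is scored in 20 nm voxels (sparse storage; only occupied voxels are
kept).  A voxel is *eligible* when it holds deposited energy and at least
one chromatin segment.  The number of DSBs per eligible voxel is Poisson
with mean $k E_{voxel}$; breaks in voxels above 500 eV are *complex*,
otherwise *simple*.  Because the total break count is exactly linear in
$k$, `calibrate_k()` is a one-shot estimate: it measures the mean eligible
energy per history for the reference low-LET beam at 1 Gy and sets
$k = 35 / \bar S$, so the model yields ~35 DSB per cell per Gy.  The
yield is LET-independent by construction (eligible energy tracks total
nucleus energy), which the test suite verifies within a few percent.

Because regenerating the full random walk each history would dominate the
runtime, runs cycle over a small pool of independently generated chromatin
configurations (default 4).  The pool is a variance-reduction device: break
loci remain stochastic through the Poisson draws and track randomness;
per-history regeneration is available by supplying a larger pool.

## Repair and misrepair

Breaks rejoin with first-order kinetics over 24 h in 1 s steps: simple
breaks with time constant 1.7 h, complex breaks with 23.7 h.  On each
attempt a complex break misrejoins with probability
$w_{mis} (1 - e^{-S_i})$, where
$S_i = \sum_{j} \exp(-d_{ij}^2 / 2\sigma_{int}^2)$ sums over the other
complex breaks with open ends; the partner is drawn proportionally to the
same Gaussian kernel and one open end of each partner is joined.  Simple
breaks never misrejoin.  The implementation is event-driven: attempt times
are drawn from the geometric distribution of the per-step hazard, which is
exactly equivalent to stepping and makes the results independent of the
step size (verified for dt in 0.5–2 s).  An isolated complex break
therefore survives to 24 h with probability $e^{-24/23.7} = 0.363$, and a
simple break to 1.7 h with probability $e^{-1}$ — both closed-form oracles
in the test suite.

The kernel's form and constants are surrogate choices: the functional form
of distance-dependent misrepair is not part of the package's inputs, only
the qualitative statement that misrepair probability increases as complex
breaks get closer.  `sigma_int = 0.8` µm and `w_mis = 0.85` were
calibrated once so that (a) the mid-LET simple-exchange yield at 1 Gy is
of order 0.1–0.2 per cell and (b) the indirect contribution's share of
simple exchanges at 1 Gy is ~16% for the lowest-LET beam and ~6% for the
highest, with a near-zero indirect share of complex exchanges — the
structure the decomposition is designed to expose.

Exchanges are classified from the connected components of the misrepair
edges: 2 breaks on 2 distinct chromosomes form a simple exchange
(dicentrics and translocations), more than 2 breaks on 2 or more
chromosomes a complex exchange; components confined to a single chromosome
(ring/inversion analogs) are tallied separately and excluded from both
classes.  Homologous copies count as distinct chromosomes.

## Dose-response statistics

For each contribution the mean exchange counts over histories at the seven
dose points (0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 1 Gy — a
seven-point design spanning 0.05–1 Gy) are fitted with the linear-quadratic
model $y(D) = \alpha D + \beta D^2$ by parametric bootstrap: each of 2000
draws perturbs the means by their standard errors and refits by weighted
least squares (weights $1/SE^2$, zero intercept).  The draws give
$\mu_\alpha, \sigma_\alpha, \mu_\beta, \sigma_\beta$ and, on a 101-point
dose grid, a 95% *prediction* band formed from the pointwise percentiles
of the predicted yields plus a residual noise term resampled from the
interpolated per-dose SEs (a prediction band, not a confidence band on the
mean curve — the wider of the two readings, labeled as such).  Negative
fitted yields are not clipped.

Two dose responses are compared with three statistics integrated over
0–1 Gy (trapezoidal rule on the grid): the containment probabilities
$m_{i \to j}$ and $m_{j \to i}$ (fraction of contribution $i$'s predictive
draws inside $j$'s 95% prediction interval; both the band and the draws
use the same predictive distribution, so $m_{i \to i} \approx 0.95$ by
construction), and $m_{KS}$, the two-sample Kolmogorov–Smirnov statistic
between the predictive yield distributions.  Values of $m_{i \to j}$ near
1 and $m_{KS}$ near 0 mean statistically indistinguishable responses; the
containment measures are deliberately asymmetric.

## Synthetic poly-energetic spectra

The Geant4/phantom transport that produces tissue-filtered fluence spectra
is out of scope; `load_fluence_spectrum()` reads such spectra from
delimited text, and `synth_fluence_spectrum()` emulates their reported
structure: the surviving primary peak one to two orders of magnitude above
a broad log-normal bump of secondary H and He, plus low-energy heavy
fragments.  Heavy fragments are given charges up to max(8, Z of the
primary) because target fragmentation of tissue nuclei (C, N, O) produces
fragments heavier than a light primary — this is what makes a transported
proton beam acquire a high-LET component.  LET values for arbitrary ions
fall back to a $Z^2/\beta^2$ scaling of the packaged proton LET unless the
user supplies a table; tabulated LET for exotic low-energy fragments is
itself uncertain, so the fallback is deliberately simple.

## Numerical choices and degenerate inputs

* Voxel indices are `floor((x + R_T)/voxel)` per axis, half-open, with
  boundary events assigned to the higher-index voxel.
* Fused simulation discards out-of-nucleus deposits analytically
  (segment-sphere clipping) and prunes electrons whose residual range
  cannot reach the sphere; the event-recording mode used by
  `sample_irradiation(..., keep_events = TRUE)` and
  `transport_electron()` keeps everything and conserves each electron's
  energy exactly.
* Voxel deposits are aggregated in sorted key order, so runs are
  reproducible: identical configuration and seed give identical outputs.
* Degenerate inputs error early: non-positive LET or voxel size, empty
  spectra, `T_cut` above a component's kinematic maximum, fewer than three
  distinct dose points, all-equal doses (singular design), fewer than two
  histories (no standard error).

## Problem sizes

The packaged defaults aim at desk-scale studies: the test suite and the
acceptance script use 150–500 histories per beam for microdosimetry and
DSB quantities, 1000–3000 histories per contribution for 1 Gy exchange
shares, and 250–400 histories per dose point for dose-response fits.
These sizes keep the Monte Carlo standard errors comfortably inside the
tolerances being tested; production-scale runs (10⁴ histories per dose
point) are a matter of patience, not of code changes.

## Known limitations

* The surrogate's complex-break fraction at low LET (~22%) is higher than
  full track-structure codes produce, and its absolute complex-exchange
  yield for the lowest-LET beams is correspondingly high; the decomposition
  shares and the LET trends are the calibrated quantities.
* Simple-exchange dose responses of the two highest-LET beams do not bend
  downward (fitted $\mu_\beta$ stays near zero or positive): with a
  sub-micrometer misrepair range, breaks from different high-LET tracks (several
  µm apart at ≤1 Gy) essentially never interact, so the yield is linear in
  the track count.  A negative quadratic term requires inter-track
  competition at micrometer distances — a longer-ranged kernel or break
  mobility during repair, both of which would trade away the calibrated
  low-LET yields and the static-break model.  See the discussion in the
  repository notes; the corresponding trend check is expected to fail and
  documents this limitation.
* Per-track indirect energies are inflated for high-LET beams: the 10 µm
  periodic box folds the many distant physical tracks of an infinite field
  onto the few indirect chord identities present in the box, so one
  "indirect track" accumulates what thousands of distant tracks would
  deposit individually.  All energy *sums* (dose fractions, spectra
  totals, break counts) are unaffected; only the per-track decomposition
  of `f_ind` at high LET should be read with this in mind.  The effect
  shrinks with a larger box at proportional cost.
* Chromatin has no territories, loops or excluded volume; inter-changes
  between any fibers are equally available at equal distance.
* The isotropic-incidence option assigns each chord a finite length equal
  to the box side, so categorization of grazing tracks differs slightly
  from an infinite-line treatment.
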