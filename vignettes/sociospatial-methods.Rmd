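---
title: "Socio-spatial analysis of co-housed primate groups: models and methods"
author: "SocioSpace authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Socio-spatial analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

SocioSpace analyzes simultaneous 3D position recordings of small groups of
co-housed primates (the motivating system: four macaques in a 270 x 150 x
200 cm enclosure, tracked at 15 Hz over 3-hour sessions). From such data it

1. builds normalized spatial-occupancy maps and quantifies how an
   individual's occupancy changes between social contexts (all four animals
   present vs. one removed);
2. decodes individual identity from instantaneous position with pairwise
   classifiers, testing whether spatial footprints persist within and
   across sessions and contexts;
3. characterizes affiliation through interpersonal-distance distributions,
   data-driven proximity thresholds, affiliative strength/weakness, and the
   durations of close-proximity bouts; and
4. explains the shape of interpersonal-distance distributions with a
   mechanistic two-agent random walk carrying a single social parameter,
   the stay-together probability.

Because raw tracking data of the motivating study are not redistributed
with the package, a synthetic trajectory generator reproduces the
statistical structure those analyses consume. All package analyses are
validated on generated data with known ground truth.

## Coordinate conventions and data model

Positions live in a box with x along the 270 cm wall, y along the 150 cm
wall, z vertical, origin at a floor corner; units are centimeters and
seconds throughout. A `TrajectorySet` holds one session: a shared,
strictly regular time base and one n x 3 position matrix per individual,
with an all-NA row marking an occluded (missing) sample. The on-disk
format is a long/tidy CSV (`session_id, tick, time_s, individual_id, x_cm,
y_cm, z_cm`; empty coordinate cells = missing), so rosters of any size need
no schema change, and `writeSession()`/`readSession()` round-trip
bit-exactly.

## The synthetic trajectory generator

The generator's goal is stationary, individual-specific, wall-attached
occupancy plus controllable pairwise attraction -- not realistic macaque
kinematics (speeds and gaits are out of scope). Each individual follows a
discrete-time mean-reverting (AR(1)) walk,

$$x_{t+1} = \mu_t + \phi\,(x_t - \mu_t) + \varepsilon_t,\qquad
  \varepsilon_t \sim N(0, \sigma^2_\varepsilon),$$

with relaxation time 2 s ($\phi = e^{-1/(2\,\mathrm{rate})}$) and the
innovation SD chosen so the stationary SD equals the footprint's
`spreadCm`. The attractor $\mu_t$ alternates between the footprint center
and its projection onto the nearest wall at perch height (90 cm), driven by
a two-state Markov chain whose stationary wall fraction is `wallAffinity`
and whose mean full cycle is about one minute -- emulating perch use.
Positions are reflected at the cage walls.

Social attraction follows the same rule as the mechanistic model below:
whenever a pair's distance is below `closeThreshCm` (default 50 cm), a
single Bernoulli draw with the pair's `pStay` freezes *both* members for
the next tick; an individual in two staying pairs is frozen once.
Occlusions are independent per-sample drops at `missingRate` (default
0.05; the original tracking system's loss rate is unreported, and
independent drops are the simplest model -- bursty occlusions can be
emulated by post-processing if needed).

Sessions are seeded explicitly; `generateStudy()` derives per-session seeds
as `baseSeed + session index`, so a whole study is reproducible from one
integer.

What the generator does *not* emulate: autocorrelated occlusion bursts,
diurnal nonstationarity, locomotor dynamics, and more-than-pairwise social
structure. Tests passing on generated data therefore certify the analysis
machinery (estimators, nulls, bookkeeping), not claims about real animals.

## Occupancy maps and the context-change index

An occupancy map discretizes the horizontal plane into 16 bins along the
150 cm axis x 29 bins along the 270 cm axis (cells of about 9.3 cm) and
records the fraction of tracked time per cell. Two conventions are worth
stating:

* the map is a floor-plan (z marginalized); a wall projection would be an
  alternative reading of a 16 x 29 grid, and the grid shape is an argument
  if other discretizations are wanted;
* the denominator is the number of *non-missing* samples, so occlusion does
  not deflate the map; with complete tracking this equals session duration.

The context-change index between two maps of the same individual is the
mean over the 464 cells of the absolute difference,
$D = \frac{1}{464}\sum_{ij} |A_{ij} - B_{ij}|$ -- the L1 difference
normalized by cell count. $D$ is symmetric, non-negative, and zero exactly
for identical maps. `contextChangeTable()` enumerates $D$ for every
unordered pair of quadruple sessions (the within-context baseline) and for
every quadruple x triplet session pair per removal condition.

### The resampled t scheme and its caveat

Because conditions contribute unequal numbers of session pairs, inference
follows a resampling scheme: each of 200 repeats draws 100 values per group
*with replacement* and computes a Welch two-sample t test; the inference
quantity is the average p over repeats. Drawing with replacement is forced
by groups that can hold fewer than 100 values, and Welch is used because
the group variances have no reason to be equal.

The caveat: resampling 100 values from groups of, say, 171 and 50 session
pairs inflates the effective n of each t test relative to the number of
genuinely independent session pairs, so the averaged p is anti-conservative
in absolute terms. The package implements the scheme as specified and
treats it as a *relative* index across conditions. A user wanting a
calibrated alternative can run `stats::t.test()` directly on the raw
baseline and condition D values (sessions pairs as samples). Under the
simulation conditions used in the acceptance analyses (groups of 171 and
50 values from a common distribution), the scheme's false-positive rate at
mean p < 0.05 stays within a few percent.

## Identity decoding

Each classifier is a binary RBF-kernel support vector machine (`e1071`,
cost C = 1) on single-sample (x, y, z) features, one classifier per pair
of individuals. Choices the underlying study leaves open, fixed here:

* **Standardization.** Features are z-scored with training-set statistics
  (toggleable). An RBF kernel is scale-sensitive; without this the 270 cm
  axis dominates the kernel distance.
* **Kernel bandwidth.** gamma = 1/3 (1/n_features on standardized data).
* **Subsampling.** Sessions are capped at 5000 samples per class before
  training (uniform subsample, configurable). Kernel SVM training grows
  superlinearly with n while accuracy at the footprint separations involved
  saturates far below the cap; the demo scale (9000 samples/session) is
  below it anyway.
* **Missing data.** Dropped per individual before classification; the
  classifier consumes position samples, not time-aligned pairs.

Three protocols mirror the study design. Within-session: 10 random,
non-contiguous 90/10 sample-level splits. Cross-session: train on one full
session, score each test session separately. Cross-context: the same,
restricted to triplet sessions still containing both pair members.

Significance uses shuffled-label nulls with
p = (1 + #{null >= observed}) / (1 + #shuffles), which cannot return zero.
Within-session nulls must refit the classifier per shuffle (one random
90/10 split per shuffle rather than all 10, and a tighter 1500-per-class
cap: shuffled data is inseparable, which is the SVM's worst case for
training cost, while the null's location at chance is insensitive to n).
Cross-session nulls need no refit: predictions are fixed, so labels are
permuted against them.

A chance-level subtlety surfaced by validation: trajectory samples are
autocorrelated (2 s relaxation; minute-scale wall-state dwells), so two
individuals with *identical* footprint specifications still differ by
finite-sample chance in their realized occupancy over short sessions, and
a within-session classifier can learn that realized difference. The
chance-level checks therefore use footprints without the wall state and
hour-long sessions, under which the exchangeability premise holds; this is
a property of any within-session decoder on autocorrelated data, not an
artifact of this implementation.

## Proxemics

`distanceSeries()` gives the 3D Euclidean distance at every tick where both
individuals are tracked, keeping original tick indices. Distance
distributions are histogrammed at 1 cm and smoothed with a fixed 5 cm
Gaussian kernel (renormalized at the range boundaries so mass is
conserved); the smoothing bandwidth matters only through the threshold
finder and is exposed as an argument.

Affiliation thresholds are read off the smoothed density: the **close**
threshold is the first local minimum after the first (close-proximity)
mode, the **far** threshold the first local minimum after the main
right-side mode; modes are local maxima at or above 5% of the global
maximum, which suppresses smoothing ripples. A unimodal density yields a
flagged result with no close threshold; tri-modal densities (an avoidance
peak on the right) report all modes. On the motivating study's own
recordings this procedure gave 73 cm and 185 cm; those values are available
as presets, including the alternative 80 cm close cutoff that the study
used as the upper end of its cumulative-sum range (the two are reported
inconsistently there; 73 cm is the stated definition and is the default).
Note that the 5 cm smoothing slightly shifts valley locations: the
estimator's target is the valley of the *smoothed* density, which is what
the package's recovery checks compare against (in closed form for Gaussian
mixtures).

Affiliative strength (weakness) is the total time below the close threshold
(above the far threshold), accumulated per partner and summed -- an
individual simultaneously close to two partners accrues time twice, once
per pair, matching the per-pair definition.

Close-proximity chunks are maximal runs of consecutive ticks below 50 cm (a
threshold deliberately distinct from the 73 cm affiliation cutoff; both are
arguments). A single qualifying sample is a one-sample chunk. An occlusion
gap inside a run *breaks* it by default -- the conservative reading, since
nothing is known about the pair during the gap -- with an optional
`bridgeGapTicks` to tolerate short gaps. Chunk durations are compared
across pairs on 20 logarithmically spaced bins between one sample and the
longest observed chunk, with two-sample Kolmogorov-Smirnov tests per
duration interval. Durations are discrete (multiples of 1/15 s), so KS
p-values are conservative under heavy ties; the package's calibration
check asserts the rejection rate does not exceed its nominal level.

## The constrained random walk with a stay-together rule

The mechanistic model runs two agents on a 240 x 140 step lattice,
restricted to the band of points within 40 units of the nearest boundary
(the frame region -- mirroring perch use along the walls; the alternative
reading of "vicinity of the wall" as a half-plane is not supported by the
enclosure's geometry). Per sample each agent draws a continuous uniform
direction and an integer step length uniform on {1, ..., 40}; the
displacement is rounded to the nearest lattice point (continuous angle +
rounding reproduces isotropy better than 4- or 8-connectivity). Proposals
leaving the band are re-drawn, up to 100 attempts, after which the agent
stays put. Initial positions are independent uniform over the band.

The social rule: once the agents' distance is below 10 units, a *single*
Bernoulli draw per sample freezes both agents jointly with probability
`pStay` ("staying in close proximity" is a property of the pair; a
per-agent reading would let one agent walk away from a frozen partner,
which contradicts the rule's purpose). The first sample is excluded (there
is no previous distance). With `pStay = 0` the model reduces exactly to
the free constrained walk. The simulation core is implemented in C++
(Rcpp) using R's RNG, so results are bit-reproducible from the config seed
and a 10^4-sample run takes milliseconds.

### Fitting the stay probability

`fitPStay()` grid-searches `pStay` over 0.10 to 0.90 in steps of 0.05 (17
candidates, per-candidate derived seeds), scoring each candidate by the
Pearson correlation between the empirical and simulated binned distance
densities and returning the argmax (ties toward the smaller value).
Empirical distances in centimeters are first rescaled to lattice units by
the ratio of the long sides (240/270).

Two numerical choices make the fit usable. First, densities are binned at
2 lattice units, which keeps the region below the 10-unit proximity
threshold -- the only region where candidates differ materially -- resolved
into several bins. Second, each candidate's density is averaged over 4
independent simulations (each at the configured 10^4 samples): a single
10^4-sample density carries enough Monte-Carlo noise in its broad
right side to swamp the close-region signal that discriminates neighboring
candidates, and averaging restores self-recovery of a known `pStay` to
within one grid step. The empirical side of the package's recovery checks
uses a 10^5-sample simulation, standing in for session-scale empirical
data (a 3-hour session at 15 Hz provides ~1.6 x 10^5 samples per pair).

## Problem sizes and seeds in the validation suite

The test and acceptance analyses run at the package's demo scale, chosen
once: 10-minute sessions at 15 Hz (9000 samples) for decoding regimes,
hour-long sessions for chance-level premises, 10^5 samples for density
recovery, the model's native 10^4 samples and 17-candidate grid for the
walk, 200 x 100 resampling for the context test, and 20 replicate fits for
stay-probability recovery. Every stochastic step is driven by an explicit
seed; the acceptance script threads a single command-line seed through all
of them.

## Known limitations

* The resampled context test is anti-conservative in absolute terms (see
  above); treat mean p as a relative index across conditions.
* Within-session decoding accuracy on autocorrelated data mixes stable
  footprint signal with realized-path idiosyncrasy; cross-session decoding
  is the cleaner test of footprint persistence.
* The threshold finder assumes a well-formed smoothed density; thresholds
  on multi-group data should be found on the *average* distribution, as in
  the motivating study.
* The walk model is planar, two-agent, and ignores the vertical dimension
  by construction.
* The generator's stay-together rule freezes positions exactly; real
  proximity bouts involve correlated slow movement, so generated
  close-proximity distance spikes are sharper than real ones.
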