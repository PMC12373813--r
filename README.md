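# SocioSpace

Socio-spatial behavior analysis for small groups of co-housed primates
tracked in 3D. The motivating system is a group of four macaques sharing a
270 x 150 x 200 cm enclosure, each animal's position recorded at 15 Hz over
3-hour sessions. From simultaneous position time series the package asks,
and answers quantitatively: do individuals keep personal spatial
footprints? Does an animal's occupancy shift when a particular group
member is absent? Which pairs affiliate, for how long at a time, and can
the shape of their interpersonal-distance distribution be explained by a
single social parameter added to a random walk?

## What it computes

* **Occupancy and social context.** Normalized 16 x 29 occupancy maps
  (fraction of tracked time per ~9.3 cm floor-plan cell) and the
  context-change index between two maps of the same individual,
  `D = mean(|NC_n - NC_m|)` over the 464 cells. Baseline D values (between
  all-four-present sessions) are compared with condition D values (between
  quadruple and one-removed triplet sessions) by a resampled Welch-t
  scheme: 200 repeats of 100 draws per group with replacement, inference on
  the mean p. Per-session median positions with Friedman and Wilcoxon
  signed-rank comparisons across individuals complete the occupancy
  picture.
* **Identity decoding.** Pairwise RBF-kernel SVMs (C = 1) on single-sample
  (x, y, z) features, under three protocols: 10 random 90/10 within-session
  splits, train-on-one-session / test-on-others, and quadruple-to-triplet
  generalization, each with shuffled-label nulls,
  `p = (1 + #{null >= obs}) / (1 + #shuffles)`.
* **Proxemics.** Interpersonal distance series; mean-distance matrices
  with sessions as samples; binned and kernel-smoothed distance
  distributions; data-driven affiliation thresholds (close = first local
  minimum after the close-proximity mode, far = first local minimum after
  the main right-side mode; 73/185 cm presets); affiliative strength and
  weakness (time below/above threshold summed over partners); and
  close-proximity chunks — maximal runs of consecutive samples below 50 cm
  — with log-binned duration histograms and Kolmogorov-Smirnov
  comparisons.
* **Mechanistic model.** A two-agent random walk on a 240 x 140 lattice
  confined to a 40-unit wall band, uniform directions and integer step
  lengths in [1, 40], with a stay-together rule: below 10 units of
  separation, both agents freeze for the next sample with probability
  P(StayTogether). A grid search (0.10 to 0.90 in 0.05 steps) fits that
  probability to an empirical distance density by Pearson correlation of
  binned densities.
* **Synthetic data.** A generator producing sessions with
  individual-specific stationary footprints (mean-reverting walks with
  wall/perch attachment), pairwise stay-together attraction, occlusion
  gaps, and quadruple/triplet rosters — so every stage is testable with
  known ground truth.

A full study replica (generate → validate → context → decode → proxemics →
walk fit) runs via `runStudy(studyConfig(...))`, writing per-stage CSV/JSON
artifacts and a consolidated report; `inst/scripts/sociospace.R` wraps it
for the shell.

## Worked example

```r
library(SocioSpace)

setup <- defaultStudySetup()    # 4 individuals, separable footprints,
                                # one affiliated pair (m1-m2, pStay 0.6)
ts <- generateSession(setup$geometry, setup$footprints, setup$social,
                      sessionSpec(setup$roster, durationS = 600, seed = 42))
ts
#> TrajectorySet 'S00042': 4 individuals (m1, m2, m3, m4), 9000 ticks @ 15 Hz (10.0 min)
#>   missing fraction: m1=0.050, m2=0.046, m3=0.048, m4=0.050

withinSessionCV(ts, c("m1", "m3"), nShuffles = 20, seed = 1)
#> DecodingResult [within_cv] m1 vs m3: mean accuracy 1.000 over 10 folds, null mean 0.487, p = 0.04762

proximityChunks(distanceSeries(ts, "m1", "m2"), thresholdCm = 50)
#> ChunkSet m1-m2: 14 chunks below 50 cm, longest 1.3 s

emp <- simulatePair(walkConfig(pStay = 0.6, seed = 7L, nSamples = 100000L))
fitPStay(emp@distance, walkConfig(seed = 8L), rescale = 1)$best
#> [1] 0.55
```

Reading the output: the two individuals' footprints are fully separable
within a session (accuracy 1.0 against a shuffled-label null at 0.487);
the m1–m2 pair with stay probability 0.6 accumulates 14 short
close-proximity bouts in 10 minutes; and fitting the walk model to a
distance density simulated at P(StayTogether) = 0.6 recovers 0.55, one
grid step from the truth.

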