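---
title: "Measuring temporal visual salience from multi-observer gaze"
author: "Glimpse package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring temporal visual salience from multi-observer gaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(Glimpse)
```

## The problem

Spatial salience asks *where* in an image attention lands; temporal
salience asks *when* a time-varying stimulus — a video — grabs attention.
Glimpse quantifies the latter with a single per-frame score built from raw
eye-tracking data of several observers, with no training and no analysis
of the video content itself. The premise is behavioral: when something
genuinely attention-grabbing happens, different observers look at the same
place at the same time, so their gaze points aggregate in space and time;
during uneventful passages gaze disperses.

## The score

Let $g(o, t) = (x, y)$ be the normalized gaze position of observer
$o \in \{1, \dots, N\}$ at frame $t \in \{1, \dots, T\}$. Positions are
divided by the frame width $W$ and height $H$, so on-screen gaze lies in
the unit square and one spatial scale works across videos of any
resolution. For each frame, all gaze points of all observers within the
temporal window $[t - \theta_t,\, t + \theta_t]$ are pooled into an
anonymous bag $P_t$ of $n$ points, and the score is the fraction of point
pairs that lie closer than the spatial scale $\theta_s$:

$$ s(t) \;=\; \frac{2}{n(n-1)} \sum_{i < j} \mathbb{1}\!\left[\, d_{ij} < \theta_s \,\right] \;\in\; [0, 1], $$

with $d_{ij}$ the Euclidean distance between points $i$ and $j$ of the
bag. This is a windowed, threshold-normalized relative of Ripley's $K$
statistic from spatial point-pattern analysis: it measures aggregation
without any explicit clustering, and because the bag is unordered it is
invariant to permuting observers or samples.

### Parameters

* `thetaS` (default **0.1**, dimensionless): the distance under which two
  gaze points count as "looking at the same thing", roughly a tenth of
  the frame diagonal scale. Larger values inflate all scores (the
  indicator is monotone in the threshold — this holds pointwise and
  exactly); smaller values sharpen peak/valley discrimination.
* `thetaT` (default **5** frames): the half-width of the pooling window,
  so scores pool $2\theta_t + 1$ frames (0.44 s at 25 fps). Wider windows
  smooth the score profile; `thetaT = 0` scores each frame in isolation.

### Numerical and boundary conventions

* **Pair enumeration.** The normalization $2/(n(n-1))$ counts unordered
  pairs, which keeps $s(t)$ inside $[0, 1]$; the inequality is strict
  ($d_{ij} < \theta_s$).
* **Video boundaries.** Windows are clipped to $[1, T]$, so every frame
  gets a score; boundary frames simply pool fewer points.
* **Degenerate windows.** A window with fewer than two points carries no
  pair evidence and scores 0 (one aggregate warning); this also avoids
  the $n(n-1)$ division by zero. Missing samples (blinks, tracking loss)
  are dropped before pooling, never interpolated.
* **Off-screen gaze.** Samples outside the unit square after
  normalization are retained by default — disperse off-screen gaze is
  itself evidence of inconsistency — but counted, reported and removable
  (`filterOffScreen()`).
* **Anisotropy.** Dividing $x$ by $W$ and $y$ by $H$ makes the Euclidean
  metric anisotropic on non-square frames; this is accepted deliberately
  for resolution independence.
* **Eye selection.** The reader ingests exactly one position stream per
  observer; fusing binocular recordings is up to the user upstream.

Raw tracker streams sample far above the frame rate (e.g. 500 Hz against
25 fps), so `aggregateToFrames()` averages each observer's valid samples
over each frame's half-open interval $[(t-1)/f,\, t/f)$; frames are
1-based.

## Scoring from spatial salience maps

Where no gaze data exist, a temporal signal can be attempted from a
sequence of spatial salience maps $S(x, y; t)$. Four heuristics are
provided, each targeting a different failure mode of map sequences:

* **MutualInfo** (`scoreMutualInfo`): the average mutual information
  between the map at $t$ and each neighbor in the temporal window. The
  printed form of this window average spans the $2\theta_t + 1$ window
  terms over a divisor of $2\theta_t$; the package excludes the $k = 0$
  self-term, whose contribution (the map's own entropy) is independent of
  temporal consistency, which makes the divisor equal the term count.
  The estimator is a joint histogram after linear quantization of the
  whole sequence into `nBins = 64` levels over its global range (the
  estimator is otherwise an open choice; bins are configurable). Units
  are bits, range $[0, \log_2 \texttt{nBins}]$.
* **MaxValue** (`scoreMaxValue`): the global map maximum, rescaled by the
  declared value scale so 8-bit and float maps are comparable.
* **Spread** (`scoreSpread`): mass concentration around the salience
  centroid. The centroid is the intensity-weighted pixel mean; the map is
  then weighted by a Gaussian kernel centered there with
  $\sigma = W \theta_s / 2$, and the weighted mass is divided by the
  total mass. The kernel peaks at 1 (not unit mass) so a perfectly
  concentrated map scores exactly 1, and it is evaluated over the whole
  map — the conventional odd window side $\ell = 2\lceil 2\sigma \rceil + 1$
  is kept as metadata only. The ratio form makes the score invariant to
  positive rescaling of the map. Zero-mass maps score 0 with a warning.
* **Points** (`scorePoints`): "gaze hypotheses" from map structure. Each
  map is thresholded (Otsu by default — parameter-free; or a fixed
  fraction of the maximum), the centroids of the 8-connected components
  are taken as surrogate gaze points in normalized coordinates (the
  $\theta_s = 0.1$ threshold is defined in normalized units, so
  centroids must be normalized too), and the pair-consistency score is
  applied to the windowed bag of centroids exactly as for real gaze.

## Comparing salience signals

`compareSignals()` bundles the measures used to relate two temporal
signals $s_1, s_2$ of equal length:

* length-normalized Euclidean distance
  $d = \sqrt{\tfrac{1}{T}\sum_t (s_1(t) - s_2(t))^2}$;
* mean Jaccard index $\mathrm{IoU} = \tfrac{1}{T}\sum_t \min(s_1, s_2) /
  \max(s_1, s_2)$ for nonnegative signals, where a $0/0$ frame counts as
  perfect agreement (both signals assert "no salience" identically);
* soft precision/recall against a binary reference $r$:
  $I = \sum_t \min(s, r)$, precision $= I / \sum_t s$, recall
  $= I / \sum_t r$, each undefined (NA) when its denominator vanishes;
* Spearman's $\rho$ and Kendall's $\tau$ (the tie-corrected $\tau_b$, the
  common statistical practice), undefined for constant signals.

Binary references are built from change-point frames with
`binaryReferenceFromChangepoints()`; "temporally close" defaults to
$\theta_t$ frames, configurable. External signals on other scales can be
min–max normalized to $[0, 1]$ before comparison (`normalize = TRUE`).

## How many observers are enough?

`convergenceCurve()` resamples observer subsets: for each $k = 1..N$ it
draws $p(k) = \min(p_{\max}, \binom{N}{k})$ distinct $k$-subsets
($p_{\max} = 400$ by default), recomputes the score from each subset
alone, and reports the mean and standard error of the distance
$d(s_k, s_N)$ to the all-observer score. Below the cap all subsets are
enumerated, avoiding sampling noise; above it distinct subsets are drawn
uniformly (combinations, not ordered draws), reproducibly under a seed.
The curve vanishes exactly at $k = N$ and decreases quickly: few
observers already approximate the full panel. A related qualitative
effect is that small panels *overestimate* salience — with temporally
persistent gaze, a larger share of window pairs come from the same
observer and are therefore close — so the full-panel score is the
conservative lower bound.

## The synthetic scenario generator

`Scenario()` + `generateGaze()` / `generateSalienceMaps()` provide data
with known attention structure so every pipeline stage is testable
without an external eye-tracking dataset. Per observer and frame, gaze
follows a scripted attractor trajectory with isotropic Gaussian jitter
(`clusterSd`) while the observer is attending, and is uniform on the unit
square otherwise; the attending state is a two-state Markov chain that
re-draws Bernoulli(`alpha(t)`) with probability `switchProb` per frame —
the persistence produces the temporal autocorrelation real scan paths
show, which is exactly what drives the few-observer overestimation above.
Matching maps render a Gaussian blob (sd `blobSd` pixels, peak
`alpha(t)`) at the attractor plus zero-clipped Gaussian noise.

Default conditions, chosen once as a realistic desk-scale panel: $N =
20$ observers, $T = 200$ frames (8 s at 25 fps), a slowly circling
attractor, an event-structured attended fraction (0.15 background, 0.85
over the middle third — a clip with one salient event; a constant
fraction would make correlation-based validation meaningless), gaze
cluster spread 0.03 (a third of $\theta_s$), 64×64 maps with blob sd 4 px
and noise sd 0.02, switch probability 0.05, gaze clipped to the screen.
Generation is deterministic given the seed, byte for byte.

The generator emulates the *consistency structure* the score relies on —
not saccade dynamics, tracker noise spectra, fixation durations, or
center bias. Tests passing on synthetic data therefore validate the
algorithmic contracts and the statistical tendencies (uniform-gaze floor,
subset convergence, overestimation, smoothing), not photorealistic gaze
behavior.

A useful analytic anchor: for fully inattentive (uniform) gaze the
expected score is the probability that two uniform points in the unit
square lie closer than $\theta_s$,
$$ p(\theta_s) = \pi\theta_s^2 - \tfrac{8}{3}\theta_s^3 + \tfrac{1}{2}\theta_s^4 \approx 0.0288 \text{ at } \theta_s = 0.1, $$
implemented in `uniformPairProbability()` (valid for $\theta_s \le 1$;
the $(1, \sqrt 2]$ regime has a different closed form and is out of
scope). Because consecutive scores share window points, Monte-Carlo
standard errors for the mean score are computed over disjoint
window-length blocks, not per frame.

## Worked example

```{r example}
sc <- Scenario(seed = 11)          # 20 observers, 200 frames, one event
gaze <- generateGaze(sc)
s <- temporalSalience(gaze)        # thetaS = 0.1, thetaT = 5
mean(scores(s)[67:133])            # inside the attended segment
mean(scores(s)[c(1:66, 134:200)])  # outside: near the uniform floor
uniformPairProbability(0.1)

maps <- generateSalienceMaps(sc)
sm <- suppressWarnings(scorePoints(maps))
compareSignals(s, sm)
```

```{r convergence}
res <- convergenceCurve(generateGaze(Scenario(N = 8, T = 80, seed = 5)),
                        pmax = 400, seed = 1)
as.data.frame(res)
```

Problem sizes throughout the examples and the test suite (panels of 5–20
observers, 20–200 frames, 16–64 px maps) are desk-scale choices: they are
large enough to separate the statistical tendencies from noise at fixed
seeds while keeping any run interactive.

## Known limitations

* The two scales need light domain tuning: smooth with larger
  $\theta_t$, emphasize peaks with smaller $\theta_s$; a content-adaptive
  $\theta_s$ (e.g. tied to attended object size) is out of scope.
* The score is undefined ($= 0$ by convention) where gaze is absent; it
  cannot distinguish "nobody attended" from "no data".
* Fixation/saccade structure is ignored by design: points are used raw.
* The map scorers are heuristics; on real model-generated maps their
  agreement with gaze-based scores is modest and map-model dependent.
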