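---
title: "Estimating density of group-living animals from camera traps: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating density of group-living animals from camera traps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupdens)
```

## The problem

Estimating the density of unmarked animals that live in large, cohesive
social groups — savanna primates are the motivating case — is hard with
conventional tools: individuals cannot be told apart, groups overlap in
range, and habituation for direct counts is often impossible or unethical.
`groupdens` implements the two camera-trap estimators that have emerged for
unmarked populations, plus the simulation machinery needed to validate them
by parameter recovery:

* **CTDS** (camera trap distance sampling): point-transect distance sampling
  applied to camera frames discretized into *snapshot moments*.
* **REM** (random encounter model): density from the rate of first contacts
  between moving animals and static cameras under an ideal-gas model.

## The CTDS model

Each camera $k$ monitors a sector of radius $w$ (after truncation) and
effective angle $\theta$. Operating time $T_k$ is *trigger-adjusted*: the
camera is dead for a recovery period after each multi-photo burst, so
$T_k = \mathrm{span} - n_\mathrm{triggers} \times \mathrm{recovery}$.
Effort in snapshot moments is

$$e_k = \frac{\theta\, T_k}{2\pi t},$$

with $t$ the snapshot interval. Here $t = 0.5$ s by default because the
measured spacing of photos within a burst (0.49 s) makes each frame stand
for half a second of monitoring; frames, not an abstract lattice, are the
snapshot moments, and $t$ enters only through $e_k$.

Density is

$$\hat D = \frac{\sum_k n_k}{\pi (w^2 - w_\mathrm{left}^2)\,
  \hat P \sum_k e_k} \Big/ \hat a,$$

where $n_k$ counts individual tags whose band midpoint falls in the
truncation annulus, $\hat P$ is the average detection probability inside
the annulus from the fitted detection function, and $\hat a$ is the
activity level (availability correction: animals asleep or hidden cannot
be photographed, so the raw estimate refers to the active fraction of the
day and is divided by $\hat a$). The annulus area $\pi(w^2 -
w_\mathrm{left}^2)$ replaces $\pi w^2$ under left truncation; at the 1.5–2 m
left-truncation distances typical of these surveys the difference is below
1%.

### Detection functions on binned data

Distances are tagged in bands (0.5 m to 10 m, 1 m to 25 m), so the fit
maximizes the **multinomial interval likelihood** with bin probabilities
proportional to $\int_\mathrm{bin} r\,g(r)\,dr$ — the point-transect
geometry in which availability grows linearly with distance. A midpoint
approximation would be coarse in the 1 m outer bands, which is why the
interval likelihood is the default. The candidate set is fixed: half-normal
with 0–1 Hermite adjustment terms, uniform with 1–2 cosine terms,
hazard-rate with 0–2 cosine terms. Fitted $g$ is standardized to $g(0)=1$
and clipped to $[0,1]$; non-monotone fits raise a flag rather than a hard
constraint. The optimizer is Brent (one parameter) or Nelder–Mead with a
multistart log-grid on the scale parameter; bin integrals use composite
Simpson (33 nodes per bin, 513 for the $\hat P$ integral, accurate to
about $10^{-5}$ relative).

Bursts of the same individuals violate independence, so model selection
uses **QAIC**: $\hat c = \max(1, \chi^2/\mathrm{df})$ from the
most-parameterized candidate's observed-vs-expected bin counts, then
$-2\ell/\hat c + 2(K+1)$, ties broken by fewer parameters then family
order. Right truncation follows the detection-probability rule: shrink $w$
one band at a time until $g(w) \ge 0.15$.

The **effective detection angle** is fitted as a half-normal falloff over
the absolute angles (band-midpoint fraction of the half field-of-view times
the nominal half-angle $h$), assuming uniform availability across the
viewshed, and converted as $\theta = 2\sqrt{2\sigma_a^2(1 -
e^{-h^2/2\sigma_a^2})}$, capped at $2h$. The half-normal family is fixed
for angles; the source analyses do not state that angles went through the
same family-selection procedure as distances, so we do not pretend they
did.

### Activity

The activity level $a$ is estimated from the clock times of *group
contacts* (a new contact requires at least one animal-free frame since the
last occupied frame) as $1/(2\pi \max \hat f)$, where $\hat f$ is a von
Mises kernel density of event times on the circle. The kernel concentration
comes from the standard trigonometric-moment plug-in rule multiplied by an
adjustment of 1.5 — the usual choice when the target is the level rather
than the shape; both the adjustment and the bootstrap size are configurable
because the source analyses name the method but not its tuning. The
estimator assumes animals are all active at the daily peak; the simulator's
activity curves are peak-normalized so that the generator's analytic level
is exactly the quantity the estimator targets. Uncertainty is a
nonparametric bootstrap over events with the kernel concentration held at
the point-estimate value.

### Variance

Uncertainty in $\hat D$ comes from a nonparametric bootstrap resampling
*camera locations* with replacement (1000 draws by default): each resample
refits the detection function with the selected family held fixed,
recomputes the encounter rate and the activity level, and recomputes
$\hat D$; the CI is the 2.5/97.5 percentile interval. Re-selecting the
model family per resample is off by default. The effective angle is held at
its full-data value (its SE is an order of magnitude below the encounter
rate's contribution). Resamples with zero observations are recorded as
zero density, not dropped — with patchily distributed groups these are real
outcomes and discarding them would understate the variance.

## The REM model

$$D = \frac{y/t \cdot \pi}{v\, r\,(2+\theta)},$$

with trapping rate $y/t$ in contacts per camera-day (trigger-adjusted
effort, matched to CTDS), day range $v$ in km/day, effective detection
radius $r$ (km) and effective angle $\theta$ (radians) fitted by distance
sampling *on the contact positions* (not the CTDS fit). Day range is
`speed_active * moving_proportion * active_seconds_per_day`; the
relationship between speed while active, activity level and day range is
under-determined in the source material, so `moving_proportion` is an
explicit input rather than an inferred quantity.

**Contacts.** Identities are unknown, so contacts are bookkept from
per-frame counts of individuals within the 25 m gate: a frame-over-frame
increase of $m$ adds $m$ contacts, departures decrement, an animal-free
frame resets the in-view set, and the gate applies at the first qualifying
frame. An optional `gap_reset_s` also resets after a long frameless
silence: when in-zone detection is near-certain, a live camera facing a
present animal would have triggered, so silence implies the viewshed
emptied. This inference is *invalid* with weak detection and is therefore
off by default; recovery tests with certain detection enable it.

**Speed.** Straight-line speed between consecutive GPS fixes, averaged over
segments above a 0.05 m/s activity threshold (the source is silent on the
classification; the threshold is configurable). `rarefy_track` thins a
track to coarser fix schedules: straight-line path length is non-increasing
under rarefaction (triangle inequality), which is the mechanism behind the
fix-interval sensitivity of REM densities — coarser fixes, shorter apparent
day range, higher density.

**Variance.** Component CVs combine by the delta method,
$\mathrm{CV}(D)^2 = \mathrm{CV}(y/t)^2 + \mathrm{CV}(v)^2 +
\mathrm{CV}(r)^2 + (\mathrm{SE}(\theta)/(2+\theta))^2 +
\mathrm{CV}(a)^2$, and the CI is lognormal with that CV (the source does
not name its CI construction for REM; lognormal is the standard choice for
a positive quantity with multiplicative error).

## The simulator: what it emulates and what it does not

`simulate_movement` runs group centroids as correlated random walks at 1 s
resolution on a torus (no edge effects, so ideal-gas assumptions hold
exactly and estimator error is isolated); members scatter around the
centroid with bivariate-normal spread refreshed each second; activity is a
per-second Bernoulli matched to the marginal daily curve (no bout
autocorrelation — sufficient for activity-level recovery, not for bout
statistics). `simulate_detections` implements the trigger mechanics:
per-second trigger draws, six-frame bursts at 0.49 s spacing, recovery dead
time after the burst's nominal coverage, re-triggering at the exact end of
recovery while occupancy persists, and a spurious-trigger rate (default
5e-4/s, about 43 blank triggers per camera-day — vegetation and heat
trigger real PIR cameras constantly, and these blanks are what delimit
contacts in the photo stream). Tags are binned exactly as an analyst would
bin them.

Defaults are a stated world: groups of a few dozen animals (sizes drawn to
sum exactly to `density * area`), 30 m within-group spread, 0.22 m/s travel
while active (which gives a ~4.9 km day range at a 0.26 activity level —
the regime of a large terrestrial primate), a two-mode diurnal activity
curve (`activity_curve_diurnal()`), a 4 km torus.

Two deliberate simplifications matter for interpreting green tests:

* **Refresh-each-step scatter** makes individual member paths jittery at
  1 s resolution; GPS speed tests therefore use solitary (spread 0) tracks
  or hourly fixes, where the jitter is negligible.
* **Detection enters twice in the default mechanics** (trigger draw and
  per-frame tag draw), as real cameras' sensor and image-tagging processes
  both lose animals. The observed distance distribution is then *not* the
  fitted single-$g$ family. Recovery tests that validate the detection
  *fitting* use `g_trigger = 1` (ideal motion sensor), which makes the
  tagged distances exactly $r\,g(r)$ distributed.

### A mechanics bias worth knowing about

CTDS assumes (near-)continuous monitoring. With slow-recovery mechanics
(10.35 s dead time per trigger) and *sparse* visits, frames cover only
$\approx 2.94/13.29 \approx 22\%$ of occupied time, while the
trigger-adjusted deduction removes generic operating time — mostly empty
time — so the snapshot estimator undercounts by roughly the coverage
fraction. The published trigger-adjustment heuristic is exact only when
occupancy is continuous. Our CTDS recovery test therefore uses
continuous-monitoring cameras (recovery 0, frames tiling at $t$); the
slow-recovery bias can be reproduced with the defaults and is a real
caveat for field deployments of snapshot methods on species that pass
cameras briefly.

## Parameter-recovery results established by the test suite

The acceptance tests (not this document) compute: REM mean recovery within
5% of a known density with ~95% CI coverage over 100 replicate surveys;
CTDS mean recovery within 10% under a known half-normal curve at 1500
camera-days; the half-normal $P$/EDR closed forms to four significant
figures; the von Mises activity-level closed form within 2%; DPL
monotonicity under rarefaction; and strictly larger CTDS bootstrap CV for
clustered than solitary truth at equal density. Published-table
reconstructions (speed-rescaled densities, DPL percent changes, the
survey-area-1 density from printed parameters) are asserted at 1–1.5%.

One reconstruction is deliberately looser: survey area 2's printed summary
parameters (encounter rate 0.00019, $\hat P$ 0.11, activity 0.33) are
two-significant-figure values whose rounding envelope spans several
percent; the package asserts the reconstruction within that envelope (5%)
rather than the 1.5% achievable for area 1.

## Numerical and degenerate-input choices

* Detection fits require at least `n_params + 1` non-empty bins; fewer is
  an error, not a silent fallback. Bootstrap resamples that cannot support
  a refit reuse the full-data $\hat P$.
* `c_hat` is floored at 1; non-positive degrees of freedom are an error.
* The activity kernel concentration is capped at $10^5$ and Bessel
  functions are exponentially scaled, so tightly clustered events degrade
  gracefully (with a warning) instead of overflowing.
* All stochastic operations take explicit integer seeds; identical seeds
  give byte-identical output.
* Effort floored at zero (with a warning) when recovery deduction exceeds
  the deployment span.

## Known limitations

* The simulator does not model sit-and-wait foraging bouts, landscape
  covariates, fences, or sleeping-site fidelity; heterogeneity enters only
  through group clustering.
* Contact bookkeeping by counts cannot distinguish a departure plus an
  arrival between frames; with the strict empty-frame rule this merges
  consecutive contacts when no blank intervenes (a few percent undercount
  in sparse solitary worlds), which is why `gap_reset_s` exists.
* Covariate detection functions and spatially explicit density surfaces
  are out of scope.
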