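---
title: "Methods: ERA-based complexity analysis of phased LFP recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ERA-based complexity analysis of phased LFP recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eralfp)
```

## The problem and the model

Chronic multi-electrode recordings of local field potentials (LFPs) are
long (a 5-minute phase at 3000 Hz is 900,000 samples per channel) and, in
phased experiments such as euthanasia studies, change character sharply
between phases: a strong, structured baseline decays toward a flat,
low-amplitude signal. `eralfp` treats each phase as the impulse response
of an unobserved linear system

$$x_{k+1} = A x_k + B u_k, \qquad y_k = C x_k,$$

with a unit impulse at $k = 0$ and $x_0 = 0$, so that
$y_k = C A^{k-1} B$ for $k \ge 1$ and $y_0 = 0$. The Eigensystem
Realization Algorithm (ERA) identifies a reduced triple
$(A_r, B_r, C_r)$ from the singular value decomposition of the
block-Hankel matrix of the samples. Two quantities summarise a phase:

* **NS (Number of Stacks)** — the number of block rows $s$ of the Hankel
  matrix needed for a satisfactory reconstruction. Richer dynamics need
  more time-shifted copies of the signal, so NS acts as a complexity
  proxy that can be tracked across phases and compared between groups.
* **RelErr** — the joint relative Frobenius error
  $\lVert Y - \hat Y\rVert_F / \lVert Y \rVert_F$ over all channels of a
  phase. One value per phase; per-channel MSE and Pearson correlation
  give channel-level detail.

The model is deliberately linear and autonomous: external stimuli are not
modelled (the input enters only as the impulse convention), and all
temporal structure must be explained by the modes of $A_r$.

## Pipeline stages and their parameters

`run_pipeline()` executes the stages in a fixed order; each is exported
on its own.

1. **Denoising** — `smooth_moving_average()`, a centred moving average.
   Default window 5 samples (odd; at 3000 Hz this is 1.7 ms, well below
   any LFP band of interest). At the edges the window shrinks
   symmetrically to the largest centred odd window that fits, so the
   first and last samples pass through unchanged; this keeps the filter
   a range contraction and length-preserving.
2. **Change-point downsampling** — `detect_change_points()` approximates
   each channel by a continuous piecewise-linear function whose knots are
   observed samples, targeting the penalized cost
   $\mathrm{RSS} + \lambda \cdot \#\{\text{interior knots}\}$. The
   segmenter splits top-down, best-first: the worst-fitting segment is
   split at the sample with maximum absolute deviation from its chord
   (earliest sample on ties) while the segment's chord RSS exceeds the
   penalty $\lambda$. We deliberately do *not* gate each split on an
   immediate decrease of the penalized cost: on a multi-knot signal a
   single split can transiently increase the RSS even though the
   completed recursion drives it to zero, and the deviation from any
   chord of a piecewise-linear signal always peaks at a true knot, so
   the "split while misfit exceeds one knot's cost" rule recovers exact
   knots, keeps the knot count monotone in $\lambda$, and is
   deterministic. $\lambda$ has units of squared signal amplitude; a
   useful default is of the order of the per-sample noise variance times
   the shortest trend length one cares about (the pipeline default is 1;
   the tests use 0.5 on unit-RMS surrogates).
3. **Interpolation** — `interpolate_to_uniform()` joins each channel's
   knots by straight lines and samples all channels on one shared uniform
   grid. Default 3000 points per 5-minute phase (a 10 Hz coarse rate);
   on piecewise-linear inputs the composition of stages 2–3 is exact to
   numerical precision at every grid point.
4. **Realization** — `build_hankel_pair()` + `era_realize()`. The $k=0$
   sample of a phase is a structural zero and never enters the Hankel
   matrix; the first data sample is $y_1$. Each Hankel block is one
   $q \times 1$ measurement vector, so the input dimension of the
   realization is $p = 1$; full $q \times p$ Markov-parameter arrays are
   also accepted for system-identification studies with matrix impulse
   responses. The truncation rank defaults to the numerical rank of $H$
   at a relative tolerance of $10^{-10}$, capped at `r_max = 20`; the
   rank used is recorded in every report.
5. **NS selection** — `select_ns()` evaluates the AIC
   $N \ln(\mathrm{RSS}/N + 10^{-300}) + 2p_{\mathrm{free}}$, with
   $p_{\mathrm{free}} = r^2 + rp + qr$ (the free entries of the reduced
   triple), over the coarse grid $\mathrm{NS} = 2^k$, $k = 1..13$
   (clipped to the validity interval $[1, m-2]$), refines around the
   minimiser by step-halving down to unit steps, and applies three nested
   strategies: accept the AIC minimiser if its RelErr is at most
   `rel_err_accept` (default 0.25 — a quantitative stand-in for visual
   inspection of the reconstruction); otherwise try NS* ± 10; otherwise
   expand outward in steps of 10 (at most 50 extra evaluations) and take
   the RelErr minimiser. AIC ties break to the smallest NS (parsimony),
   and reconstructions that are exact to machine precision
   ($\mathrm{RSS} \le 10^{-24}\lVert Y\rVert^2$) are all scored at the
   RSS = 0 floor so that their ordering is not decided by the logarithm
   of numerical noise. Candidates whose identified dynamics are unstable
   enough to overflow the state-norm guard score infinite AIC and are
   skipped rather than returned as non-finite reconstructions.
6. **Spectra** — `windowed_power_spectrum()`: 30-s sliding windows
   (default hop 15 s, i.e. 50% overlap), mean removal, rectangular
   window, one-sided periodogram normalised so the per-window power sums
   to the mean-removed signal energy; dB values are
   $10\log_{10}(P + 10^{-12})$, the floor keeping silent windows finite.
7. **Phases and group statistics** — `partition_phases()` cuts
   consecutive 300-s segments (a trailing remainder shorter than half a
   phase is dropped, a longer one kept and flagged `partial`).
   `compare_groups()` runs a two-sided Mann-Whitney U test (midranks;
   exact by full enumeration of group assignments for combined
   $n \le 20$, which remains exact under ties; tie-corrected normal
   approximation above) and Welch's $t$ with Welch–Satterthwaite degrees
   of freedom. `phase_difference_test()` compares groups on per-subject
   $|\mathrm{NS}(a) - \mathrm{NS}(b)|$ drops. Two-sided p-values
   throughout; no multiple-testing correction is applied by default.
   Degenerate tests (constant data) are reported as `NA` with a note,
   never as a number.

## The synthetic generator

`generate_synthetic_lfp()` emulates the study design the package targets:
4 channels at 3000 Hz, seven 5-minute phases (baseline + six exposure
phases). Each phase is state-space-filtered white noise from a stable
random system whose order follows `true_order_schedule` (complexity decay
= decreasing order), plus a random piecewise-linear trend; the sum is
RMS-normalised per channel and scaled by `amplitude_schedule`, then
corrupted with i.i.d. Gaussian measurement noise. Scaling the trend
inside the phase envelope (rather than adding it outside) is a deliberate
choice: the whole LFP decays during exposure, and it makes two properties
exact — per-phase RMS strictly follows a decreasing amplitude schedule,
and a zero-amplitude phase is exactly the measurement-noise floor. All
randomness flows from one integer seed; the per-phase ground-truth
systems are drawn in their own seeded stream and are recoverable via
`phase_systems()` without regenerating the signal.

What the generator does *not* emulate: biophysical neural dynamics,
spikes, line noise, artifacts, or the strongly non-stationary
within-phase envelopes of real euthanasia recordings. One consequence is
worth stating plainly: within a phase the surrogate is (apart from its
trend) stationary filtered noise, and a stationary noisy series remains
rough after change-point compression, so its ERA reconstruction error is
dominated by that roughness rather than by the generative order — the
selected NS then reflects fitting difficulty, not complexity. The
NS-decay property is therefore tested as *parameter recovery*: on the
noise-free impulse responses of the per-phase ground-truth systems, the
selected NS equals the smallest stack count whose Hankel matrix carries
the full system rank ($\lceil n/q \rceil$ for an order-$n$ system on $q$
channels), and its per-phase median across seeds is non-increasing
whenever the order schedule decreases. Passing tests demonstrate that
the estimator recovers generative complexity when the model class
contains the truth; they do not demonstrate that real LFP phases are
impulse responses of linear systems.

## Numerical conventions

* SVD signs are fixed by making the largest-magnitude entry of each left
  singular vector non-negative, so realizations are bit-reproducible.
* Reconstruction uses iterated state propagation, never explicit matrix
  powers; a state-norm ceiling (default $10^{12}$ times the scale of
  $B_r$) converts divergence into a classed error with a diagnostic.
* Ties: earliest sample wins in the segmenter's split; smallest NS wins
  in AIC ties; channel order follows first appearance in the data.
* The sampling rate is always taken from the data (file metadata or time
  stamps), never hard-coded.
* Recordings round-trip through plain text (`# rate_hz=` metadata line,
  17 significant digits) and bit-exactly through RDS; reports and
  realizations serialise to JSON at full precision.

## Problem sizes used by the tests

The suite exercises the study's arithmetic at full scale where it is
cheap (a 900,000-sample phase count) and scales the stochastic studies to
desk size: recovery ensembles of 20 systems up to order 8, NS-decay
schedules of 5–6 phases on 10 seeds, group-power studies of 200
replicates at 5 subjects per group, and pipeline fixtures of 2 channels ×
8–10 s at 100 Hz with 120–200 coarse grid points. These sizes are the
package's chosen trade-off between statistical resolution and a test
suite that runs in well under a minute; all of them are parameters, and
nothing in the implementation depends on them.

## Known limitations

* The impulse-response reading of an ongoing recording is the method's
  central idealisation; signals dominated by stationary stochastic
  activity are reconstructed poorly at any NS (this is visible in the
  `distant`-strategy RelErr values on synthetic subjects, e.g. in the
  README example).
* The AIC parameter count charges the full reduced triple; if NS should
  be penalised directly, the convention is isolated in one place
  (`select_ns()`'s evaluator) for replacement.
* The Mann-Whitney enumeration is exponential in the group sizes and is
  gated to combined $n \le 20$; beyond that the tie-corrected normal
  approximation (without continuity correction) is used.
* No artifact rejection, line-noise filtering, seasonality, or
  input-driven (non-impulse) identification is provided.
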