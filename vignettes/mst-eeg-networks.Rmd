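---
title: "Phase-lag spanning-tree networks and ex-Gaussian reaction times: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-lag spanning-tree networks and ex-Gaussian reaction times: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstnet)
```

This vignette is the package's own account of its methods: the models it
implements, the assumptions they rest on, the tunable parameters and their
defaults, what the synthetic generators do and do not emulate, and the
numerical and design choices made where the method leaves room.

## 1. The pipeline

For each subject the chain is: broadband 0.5–45 Hz zero-phase filtering →
common average reference → segmentation into 4096-sample epochs (≈ 8 s at
500 Hz) → selection of artifact-free epochs → per-band filtering into
delta (0.5–4), theta (4–8), lower alpha (8–10), upper alpha (10–12), beta
(13–30) and low gamma (30–48 Hz) → per-epoch phase-lag-index (PLI)
matrices over all electrode pairs → per-epoch spanning tree of strongest
connections → tree metrics → arithmetic averaging of all per-epoch results
within subject and band. A behavioural branch fits the ex-Gaussian model to
each subject's reaction times, and a statistics layer relates the two.

### Phase lag index

Phases come from the analytic signal (FFT Hilbert transform); for channels
$x, y$ the PLI is $|\langle \mathrm{sign}\,\Delta\phi(t)\rangle|$ with
$\Delta\phi$ wrapped to $(-\pi,\pi]$. Two conventions matter and are fixed
here:

* `sign(0)` contributes 0, so identical signals give PLI exactly 0 —
  zero-lag (common-source / volume-conduction) synchronization is
  deliberately discounted.
* Wrapping precedes the sign, so the statistic reflects lead/lag direction
  rather than unwrapped phase drift.

`pli_matrix()` evaluates the equivalent cross-term
$\mathrm{sign}\,\mathrm{Im}(z_x \bar z_y)$ on the analytic signals, which
avoids per-pair trigonometry; a property test asserts exact equality with
the definitional `pli_pair()`. No epoch-edge trimming is applied after the
Hilbert transform: epochs are 4096 samples, long relative to edge effects
(a configurable trim was judged unnecessary and is not exposed). PLI is
computed per epoch and then averaged — never on concatenated epochs.

### Spanning tree and metrics

Kruskal's algorithm orders all pairwise PLI weights and connects the
strongest edges that do not close a loop, yielding the unique 19-node,
18-edge tree of strongest connections (ties broken lexicographically by
electrode label pair, so trees are bit-reproducible across platforms; exact
ties are measure-zero for continuous weights). The maximum-weight tree on
$w$ is identical to the minimum-weight tree on $1 - w$, which the tests
verify against an independent graph library.

Metrics, for $N$ nodes and $m = N - 1$ edges:

* leaf number $L \in [2, m]$, leaf fraction $L_f = L/m$;
* diameter $d$ in hops, with the identity $d \le m - L + 2$; a normalized
  $d/m$ is emitted alongside for cross-study comparison;
* betweenness centrality normalized by $(N-1)(N-2)/2$, forced by the
  requirement that the hub of a star attains exactly 1 and leaves 0; on a
  tree the pair path is unique, so BC is computed from the component sizes
  left by deleting a node;
* `bc_global` is the mean over **all** N nodes, leaves included (whether
  leaves should be excluded is unspecified in the literature this follows;
  inclusion is the documented choice);
* degree correlation $R$ is Newman's edge-endpoint assortativity (Pearson
  correlation of endpoint degrees over both edge orientations), the usual
  reading of a verbally cited "degree correlation"; a star gives exactly
  $-1$; zero endpoint-degree variance returns `NA` rather than a value;
* regional BC is the arithmetic mean of node BC over the anterior
  (Fp1, Fp2, F7, F8, F3, F4, Fz) and posterior (T5, T6, P3, P4, Pz, O1, O2)
  sets; the central row (C3, C4, Cz) belongs to neither, keeping regional
  nodes unambiguously frontal or non-frontal and the two sets equal-sized.

### Preprocessing choices

The filter is a Hamming-window FIR, applied with its symmetric-kernel delay
compensated, i.e. exactly zero-phase. The half-amplitude cutoffs sit half a
transition width *outside* the stated band edges (transition default
`min(1, edge distance)` Hz), so the passband proper keeps ≈ unit gain and
the response is ≥ 20 dB down one transition width beyond each edge; kernel
length ≈ 3.3 / (normalized transition width). Filtering the continuous
recording and then epoching equals epoching then filtering on all samples
more than half a kernel from the epoch edges (tested); the pipeline filters
first, which avoids edge transients inside epochs.

The common average reference excludes Fp1/Fp2 and A1/A2 (EMG contamination)
from the reference and drops A1/A2 from the output, taking 21 recorded
channels to the 19 analysed ones; Fp1/Fp2 stay in the output. A separate
50 Hz notch is unnecessary after the 0.5–45 Hz bandpass and is omitted.

Epoch selection is an automated, clearly-labelled stand-in for expert
visual artifact rejection (whose criteria are not reproducible
mechanically): an epoch is inadmissible if any channel exceeds
`amp_limit` (default 100, the conventional ±100 µV rule) or its mean
channel variance is a > 4 SD outlier among epochs; the `k = 30` admissible
epochs with the lowest peak amplitude are kept, with a loud error — never
silent padding — when fewer than `k` qualify.

### Ex-Gaussian model

The density of Normal($\mu,\sigma$) ⊛ Exponential($\tau$) is evaluated in
log space (`pnorm(..., log.p = TRUE)` plus the exponential term), stable
for $\tau \ll \sigma$ and $\tau \gg \sigma$; a quadrature oracle checks it
to $10^{-8}$. Fitting is maximum likelihood (box-constrained quasi-Newton,
$\sigma, \tau \ge 10^{-3}$ ms) from moment-based starts, with two
additional deterministic starts (exponential share halved/doubled) because
skewed small-sample likelihoods can be multimodal; the best log-likelihood
wins, a derivative-free polish recovers the occasional quasi-Newton
linesearch abort, and non-convergence is reported explicitly. No outlier
trimming is applied before fitting — the long tail is the object of
interest — though a `trim` window is exposed, off by default. For an
exactly symmetric sample the fit collapses to the Gaussian MLE with
$\hat\tau$ at its bound (tested); note that a finite sample with positive
skew can legitimately yield a small nonzero $\hat\tau$.

### Statistics layer

Group comparisons are ANCOVAs realized as OLS with a group indicator and
the covariates age, education and premorbid IQ; with one two-level factor
and covariates always retained, Type I/II/III sums of squares coincide for
the group term. $F$ is the residual-sum-of-squares increase from dropping
the group term; $\eta_p^2 = SS_g/(SS_g + SS_e)$; df $(1, n - p - 1)$ from
the actually usable (listwise-complete) $n$. Network metrics are
$\ln(x + 10^{-24})$-transformed before modelling (the offset keeps exact
zeros finite and is far below measurement precision); the sign-valued
degree correlation $R$ cannot be log-transformed and is modelled on its raw
scale — a documented deviation from a blanket log rule. Bonferroni control
is applied over the metric-by-band family actually tested, with the family
size recorded in the report; correlations use the fixed p < 0.01 rule.
Missing clinical covariates (controls have no illness variables) are
structurally missing and excluded listwise from the specific model only.
The one-sample Kolmogorov–Smirnov normality screen uses the sample mean and
SD as reference parameters, with the Lilliefors caveat (conservative
p-values) documented rather than corrected, matching common practice for
this screen.

## 2. The synthetic world

No recordings or trial-level behavioural data are publicly deposited for
studies of this design, so the package states a synthetic world once and
tests against it.

**Coupled EEG.** The planted tree is rooted at node 1; the root channel is
band-limited Gaussian noise, and each child is
$s\cdot\mathrm{rotate}(\text{parent}, \theta) + \sqrt{1-s^2}\cdot
\text{private}$, where $s$ is the edge strength, the rotation is a constant
phase lag applied to the analytic signal, and *private* is an independent
band-limited source; channels are scaled to 10 µV SD and independent 2 µV
band-limited sensor noise is added (defaults). This realizes exactly the
generative assumption PLI is built for: adjacent channels share a source at
a consistent nonzero lag, while siblings share their parent's component at
zero relative lag, which PLI discounts like volume conduction. The default
lag is $\pi/2$ — the most sign-identifiable lag, which additionally parks
even-hop indirect pairs at the PLI-blind lag $\pi$; lags that are multiples
of $\pi$ are rejected as unidentifiable. Defaults mirror the stated
recording world: 500 Hz, 75 × 4096-sample epochs recorded, 30 selected.

What a green recovery test establishes, and what it does not: star
topologies are recovered exactly and their hub identified in ≥ 95% of
seeds at low noise, and star-like versus balanced cohorts separate cleanly
in the pipeline report; but odd-hop leakage (a 3-hop pair sits at lag
$3\pi/2$) means *chain-like* topologies at high edge strength are not
always recovered edge-exactly. The generator is a coupling-ground-truth
device, not a biophysical EEG model: no 1/f spectrum, no volume-conduction
mixing matrix, no non-stationarity.

**Reaction times.** Sessions draw Normal + Exponential with the published
group parameter triples as defaults (patients μ 990.44, σ 78.31, τ 673.93
ms; controls 765.19, 90.81, 455.23 ms), with session lengths from each
group's processed-stimuli distribution (≈ 55 ± 13 vs 74 ± 7, floored at 30
trials — per-subject trial counts are not published, so the floor is a
stated choice).

**Cohort tables.** Cross-correlations between network metrics and (μ, τ)
are imposed by a Gaussian copula (eigendecomposition of the target
correlation matrix, which must be positive semidefinite), giving exact
Pearson targets under the Gaussian margins; the correlated block is left
un-truncated, so extreme tails can produce nonphysical negatives — accepted
for exactness of the correlation targets and documented. Independent
clinical covariates are floored at 0. The default preset carries the
reported patient-group structure (r(BC posterior gamma, τ) = 0.72, etc.);
the *metric* means/SDs have no published table and were chosen once as
plausible 19-node tree values with the reported group directions (patients:
higher BC_max, leaf fraction and posterior BC, lower diameter).

**Planted group topologies.** The pipeline's patient-like group couples as
a star anchored posteriorly and the control-like group as a balanced tree
anchored anteriorly: each topology's highest-BC nodes are placed (in random
order) on the anchor region's electrodes, the regional contrast the method
is meant to detect. A naive unanchored star would actually *lower* mean
posterior BC (its non-hub posterior electrodes are all zero-BC leaves),
which is why the anchoring is part of the stated world.

## 3. Numerical notes

* FFT convolutions pad to 2-3-5-smooth lengths; R's default padding to
  $n + m - 1$ can hit a large prime factor and degrade the FFT badly.
* The EDF writer stores integer physical ranges so its 8-character ASCII
  header fields cannot overflow; round-trip error is bounded by the 16-bit
  quantization step. The ASCII writer uses `%.17g`, so matrices round-trip
  exactly.
* Kruskal tie-breaking, the copula eigendecomposition, and all generators
  under fixed seeds make every pipeline output bit-reproducible.
* Degenerate inputs fail loudly and early: all-zero channels (undefined
  phase), disconnected zero-weight graphs, non-PSD correlation targets,
  zero-variance samples, fewer admissible epochs than requested.

## 4. Known limitations

* The artifact-selection thresholds cannot reproduce expert visual
  selection; they are a stand-in and labelled as such.
* PLI localizes only cortical-surface interactions and the 19-electrode
  montage limits spatial precision; nothing here is a source-space method.
* Group-level clinical values from patient data cannot be reproduced
  (recordings are not deposited); the package's claims are structural
  identities, oracle equivalences, and recovery on the stated synthetic
  world.
* Weighted PLI, imaginary coherence, tree hierarchy/kappa/eccentricity
  metrics, ICA artifact correction and source localization are out of
  scope.
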