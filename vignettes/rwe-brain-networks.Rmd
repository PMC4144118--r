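---
title: "Wavelet-entropy brain networks from resting-state EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-entropy brain networks from resting-state EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Neurodegeneration reorganizes the brain's functional networks before it is
clinically obvious.  One way to quantify that reorganization from
resting-state EEG is to (i) measure, for every ordered pair of electrodes,
how similar their oscillatory content is, (ii) binarize those similarities
into a directed graph with a *fixed* number of edges per participant, and
(iii) summarise the graph with small-world and hub statistics that can be
compared across diagnostic groups.  `rwenet` implements that pipeline end to
end, together with a synthetic EEG generator that makes every stage testable
without access to clinical recordings.

## The synchronization measure

Each 20-s epoch of each electrode is cut into non-overlapping 128-ms windows
(64 samples at 500 Hz).  A periodized discrete wavelet cascade splits every
window into the five classical rhythms; with six levels at 500 Hz the
retained detail levels carry gamma (31.25–62.5 Hz, 8 coefficients), beta
(15.6–31.25 Hz, 4), alpha (7.8–15.6 Hz, 2) and theta (3.9–7.8 Hz, 1), and the
final approximation carries delta (0–3.9 Hz, 1).  The two finest detail
levels (62.5–125 and 125–250 Hz) lie above the gamma band and are computed
but discarded.  Band energies are sums of squared coefficients,
$E_j = \sum_k |C_k|^2$, and their normalization
$p_j = E_j / \sum_j E_j$ turns each electrode-window into a probability
distribution over rhythms.

The synchronization of an ordered electrode pair $(p, q)$ is the Relative
Wavelet Entropy, the Kullback–Leibler divergence

$$\mathrm{RWE}(p \,\|\, q) \;=\; \sum_{j=1}^{5} p_j \ln\frac{p_j}{q_j},$$

with $0\ln(0/\cdot) \equiv 0$ and $q_j$ floored at `eps` ($10^{-12}$ by
default, flooring events are counted).  RWE is nonnegative, zero only for
identical distributions, directional, and **smaller for more synchronized
pairs**.  Per-window $57\times57$ matrices are averaged entrywise over all
windows of all epochs — the mean of per-window divergences, not the
divergence of mean distributions, so transient co-fluctuations are not
averaged away.

## Graphs and their characteristics

The aggregated matrix is thresholded adaptively so that every participant's
graph has exactly $K$ edges, placed at the $K$ smallest off-diagonal RWE
values, for $K \in \{500, 600, 700, 800\}$ at $N = 57$.  Densities are
reported with the $100K/N^2$ convention (15.39–24.62 %) to match the
published arithmetic of the design this package reproduces; the standard
$K/(N(N-1))$ value is attached alongside.  Ties at the cutoff break by
(value, row, column), so graphs are bit-reproducible and nested across $K$.

Global characteristics: the characteristic path length $L$ is the mean
directed shortest-path length over reachable ordered pairs (unreachable
pairs are excluded and counted — fixed-density directed graphs are often
weakly disconnected, and infinite distances would otherwise destroy the
mean).  The clustering coefficient $C_i$ of a node uses the union of in- and
out-neighbours, counting directed edges among them over $n_i(n_i-1)$
possible ones.  Both are referenced against the analytic random-graph
expectations $L_{rand} = \ln N / \ln k$ and $C_{rand} = k/N$ with mean degree
$k = K/N$, giving $\lambda = L/L_{rand}$, $\gamma = C/C_{rand}$, and the
small-world coefficient $\sigma = \gamma / \lambda$; $\sigma > 1$ indicates
small-world organization.  The printed forms of those reference formulas are
typographically ambiguous in parts of the literature; we use the standard
Watts–Strogatz-era approximations above, which also make $C_{rand}$ coincide
with the $N^2$ density convention.

Nodal characteristics: directed betweenness centrality $B_i$ (fractional
shortest-path counting), normalized by the network mean so the normalized
values $b_i$ average exactly 1.  Nodes with $b_i \ge 1.5$ (inclusive) are
functional hubs.  The anterior hub ratio (AHR) is the summed $b_i$ over a
left-anterior list (F3, FC1, AF3, F1, FC3) divided by that over a
right-anterior list (F2, F4, Fz, AFz, FCz, FC2, FC4); the midline electrodes
are kept in the denominator list deliberately, for fidelity to the reference
analysis that defined the ratio.

## Choices the data could not make for us

**Wavelet family.**  "Fifth-order biorthogonal" names more than one standard
filter pair.  The default is the common spline-biorthogonal 5/5 pair
(`bior5.5`); `rbio5.5` and the orthogonal `db5` are available via
`wavelet_family`.  A biorthogonal analysis bank is *not* energy-preserving
(we measure a ~9 % Parseval deviation for `bior5.5` on white noise), so
exact energy conservation across levels — which holds to machine precision
for `db5` — should not be expected of the default.  Perfect reconstruction
holds for every supported family.  Relative band energies remain
well-defined either way, and RWE compares them consistently across
electrodes.

**Boundary handling.**  Per-window transforms use circular (periodized)
convolution.  This is the only boundary mode in which every level halves the
coefficient count exactly, which the canonical 8/4/2/1/1 counts per 64-sample
window require, while keeping perfect reconstruction.  Symmetric extension
would inflate the per-level counts (37 instead of 32 at the first level for
a 12-tap filter).

**Frequency resolution at 128 ms.**  A 128-ms window holds less than one
cycle of a mid-theta oscillation and barely more than one cycle of alpha.
Tone experiments show delta, beta and gamma concentrate ≥ 80 % of retained
energy in their own band, while theta and alpha smear into their neighbours
(dominant-band recovery still holds for the orthogonal family).  This is a
resolution limit of the windowing itself, not of the implementation; RWE is
unaffected as a *comparison* because the leakage is identical across
electrodes.

**Epoch selection.**  Randomized selection is implemented as uniform
sampling of non-overlapping 20-s windows *without* replacement: overlapping
or repeated epochs would double-count data in the RWE average.  Selection is
reproducible bit-exactly from the seed.

**Filtering.**  Third-order Butterworth high-pass (1 Hz) and 50-Hz notch,
applied forward–backward (zero phase), after per-channel demeaning.
Zero-phase application avoids the group delay that would misalign windows
across channels.  Artifact handling (ICA, visual inspection) is expected to
have happened upstream; `select_epochs(exclude = ...)` lets users mask bad
segments out of the sampling.

**Degenerate windows.**  A window with zero retained energy has no
distribution; such windows are excluded from the aggregate with a warning
rather than imputed uniformly, which would bias RWE toward zero.

## The synthetic generator

`generate_recording()` builds each channel as a weighted mixture of
unit-variance band-limited Gaussian processes (synthesized spectrally:
complex Gaussian amplitudes on the Fourier bins inside each rhythm band),
plus white measurement noise:

* channels in the same cluster share the cluster's five band processes with
  fraction $\rho' = \rho\,e^{-\text{severity}}$, so within-cluster pairs
  have matched band-energy fluctuations and low RWE;
* clusters differ in their mean band weights (posterior alpha dominance,
  frontal slow-wave dominance), the second ingredient separating
  between-cluster pairs;
* designated hub channels (Fz, Cz, Pz by default) mix a global process
  shared by all clusters, making them cross-cluster shortcuts — the planted
  graphs are therefore clustered *and* short-pathed, i.e. small-world;
* the severity dial weakens coupling multiplicatively, so severity 0 *is*
  the healthy model, and cognitive scores decrease linearly in severity
  (MMSE-like: $28 - 2.85s$, SD 2.3; MoCA-like: $26 - 4.3s$, SD 3.0,
  truncated to 0–30) with spreads resembling typical screening data.

Defaults: 57 channels at 500 Hz for 220 s, $\rho = 0.8$, five spatially
contiguous anterior-to-posterior clusters (594 within-cluster ordered pairs,
so the lowest density $K=500$ is dominated by planted structure), amplitude
20 µV, noise 2 µV.  What the generator does **not** emulate: volume
conduction, 1/f spectral shape beyond the band weights, non-stationarity,
artifacts, or any genuine neurophysiology.  Tests that pass on this
generator demonstrate that the *pipeline* recovers planted structure — they
say nothing about clinical effect sizes in real recordings.

## Problem sizes used by the test suite

The shipped tests run the full pipeline at desk scale: cohort checks use 10
epochs of 20 s per subject (rather than the 75 a full study would use), 20
subjects per arm for the two-arm recovery check and 30 subjects for the
score-correlation check.  Unit tests use 6–12-channel montages with two
planted clusters.  Graph-metric implementations are verified exhaustively
against brute-force oracles on all directed graphs with up to 4 nodes and on
random graphs with up to 12.

## Known limitations

* Re-referencing to linked mastoids is assumed to have happened upstream
  (reference channels are typically dropped before export); the package does
  not re-reference.
* Group comparisons implement per-density one-way ANOVAs with Tukey HSD and
  a pooled two-way layout; no repeated-measures/sphericity machinery and no
  multivariate test.
* The EDF reader supports the plain EDF subset this pipeline needs (uniform
  sampling rate across signals, no annotations).
* Betweenness normalization is undefined on graphs with no transit paths
  (e.g. complete graphs); the hub table errors in that case and the fit
  records NA for hub-derived quantities at that density.
* `sigma` inherits the exclusion of unreachable pairs from $L$: at the
  lowest density the graph can be strongly modular and $L$ is then a
  within-component quantity; the unreachable-pair count is reported so users
  can judge.
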