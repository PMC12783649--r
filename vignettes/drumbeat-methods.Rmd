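---
title: "Methods: time-resolved probabilistic graphs over residue contacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved probabilistic graphs over residue contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drumbeat)
```

This vignette documents the models implemented by `drumbeat`, the
assumptions behind them, the tunable parameters and their defaults, and
the design choices made where the methodology is genuinely open.

## 1. Contact fingerprints

The unit of analysis is a binary *contact fingerprint*: entry
$(f, i) = 1$ iff contact $i$ is formed at frame $f$. Contacts arrive as
per-frame interaction records (frame, type, two atom tokens
`CHAIN:RESNAME:RESID:ATOM`); geometric contact detection itself (distance
and angle criteria) is upstream and out of scope. By default all
interaction types between one residue pair collapse into a single
column, because the graph's nodes are residue pairs; `collapse_types =
FALSE` keeps typed columns. Endpoints are ordered canonically by
(chain, resid), so `(a,b)` and `(b,a)` records share one column.
Water-bridged records between two protein residues are treated as
ordinary pair contacts; only non-protein partners are excluded
upstream.

## 2. Feature selection

Two filters reduce the full contact set $C^{all}$ to the significant
set $C$:

* **Neighbor exclusion** removes intra-chain contacts with
  $|resid_a - resid_b| \le$ `min_separation`. "Neighboring" is not
  precisely defined in the underlying methodology; the default 1
  (exclude $i, i\pm1$) is the minimal reading, and the parameter is
  exposed.
* **MI filter**: within each trajectory, a contact is kept iff its
  maximum plug-in pairwise MI with any other contact exceeds
  `mi_filter_bits` (default 0.01 bits). The estimator is the plain
  plug-in (no bias correction): the fixed 0.01-bit threshold is defined
  against that estimator. Constant columns are always dropped.

Per-trajectory kept sets are combined by **intersection** (default) or
union. Intersection is chosen as the default because per-trajectory
retention is typically much larger than the final cross-trajectory set,
consistent with a reduction step; union (with zero-filled absent
columns) is available since the combination rule is a genuine open
choice.

## 3. Universal dataset

Two aggregation modes build the row set for graph learning:
concatenation of all frames, or *transition-enriched sampling*:
`n_per_traj` frames drawn uniformly with replacement from a region of
`region_frames` (default 5,000, interpreted as a total width, i.e.
$\pm 2500$) centered at each trajectory's transition point, clipped at
the trajectory bounds. Sampling uses one seeded stream per trajectory
(seed + trajectory index), so per-trajectory draws are reproducible
regardless of ensemble order. A budget guard warns above roughly 1,000
contacts or 15,000 rows, the practical tractability limit for structure
search on this kind of data.

The transition point comes from a 1-D proxy trace (for GPCRs, the
TM3–TM6 interhelical distance, whose drop marks deactivation). The
locator is a deterministic least-squares single change point: the split
minimizing total two-segment squared deviation of the (optionally
moving-averaged) trace, returning the first frame of the second
segment. This is one defensible instantiation of "the drop in the
proxy"; an externally supplied transition frame overrides it. The
moving average is centered with shrinking windows at the edges. A
constant trace yields a distinct no-transition value (`NA`), never a
fabricated index.

## 4. The universal graph

A directed acyclic graph $G = (C, \mathcal{E})$ factorizes the joint
contact distribution as $P(C) = \prod_i p(c_i \mid pa_i)$. Structure is
learned by greedy hill climbing over add/delete/reverse moves on the
decomposable **BIC/MDL score**: maximized multinomial log-likelihood of
each binary child given its parent configurations minus
$(\log n)/2$ free parameters ($2^k$ for $k$ binary parents). BIC was
chosen because it is standard, decomposable, and exactly checkable by
exhaustive enumeration on small systems; the reference implementation
the methodology builds on does not publish its score. Search starts
from the empty graph plus seeded random restarts (`restarts`, default
2) and is deterministic given the seed; equal-score moves resolve by
the fixed lexicographic scan order over (child, parent). `max_parents`
defaults to 3, bounding the $2^k$ configuration table.

Edge *strength* is defined as the plug-in pairwise MI (bits) of the
edge's endpoints over the full universal dataset — the same units as
the time-resolved layer, making the static weighted degree
$D_i = \sum_{\text{incident}} \text{strength}$ directly comparable to
its time-resolved analog. A node's neighborhood $\Gamma_i$ is parents
$\cup$ children (moral co-parents excluded), matching the community
sums below.

A caveat stated once: greedy score-based search recovers structures
whose dependencies are marginally visible. Parity-type mechanisms
(a child depending on the XOR of two parents, each marginally
uninformative) are invisible to any single-edge greedy move; the
package's recovery guarantees are stated for faithful, strong
dependencies.

## 5. Time-resolved rescoring (TRACs)

Along one trajectory, the dependency on each graph edge is re-measured
by sliding-window MI,
$$\mathrm{MI}_t(i,j\,|\,\delta) = H(X_{i,t-\delta:t+\delta}) +
H(X_{j,t-\delta:t+\delta}) - H(X_{i,j,t-\delta:t+\delta}),$$
and the TRAC trace of node $i$ is the time-resolved weighted degree
$$D_i(t) = \sum_{j \in \Gamma_i} \mathrm{MI}_t(i,j\,|\,\delta).$$

Conventions and choices:

* The window grid 150–1050 is read as **full** window widths $2\delta$;
  a window of size $s$ at time $t$ spans $[t - s/2,\ t + s/2]$. The
  halving convention is documented and configurable via
  `window_grid()`.
* The window is optimized (MI maximized over all feasible grid sizes)
  independently per edge and per evaluation time — the most literal
  reading; exact ties resolve toward the **largest** feasible window,
  guarding against the small-sample inflation of plug-in MI.
* Evaluation times run on a stride (default 10 frames, a pure
  performance knob); values at shared times are stride-invariant, and
  times where no grid window fits are reported missing, never zero.
* $D_i(t)$ is exactly additive over the stored per-edge traces, each
  edge term is $\le 1$ bit for binary streams, so $D_i(t) \le
  |\Gamma_i|$.

## 6. Signals: ranking, selection, ordering

A node's *amplitude* in a trajectory is $\max_t D_i(t)$. Ranking sorts
by the number of trajectories with amplitude above the threshold
(default 1.0 bit; a data-driven "one standard deviation of all trace
values" alternative is available), then mean amplitude, then label.
Key TRACs must (1) exceed the threshold, (2) do so in every trajectory,
and (3) show at most `max_peaks` (default 2; the criterion is an
explicit "one or two peaks" reading) peaks per trajectory — the
signature of macro-state transitions rather than microstate noise.
Peaks are local maxima above threshold separated by at least twice the
largest grid window (so one transition is not double-counted); plateaus
report their center.

Temporal order uses **first** peak times: community $a$ precedes $b$
iff $a$'s first peak is strictly earlier in every trajectory where both
peak; equal times or one discordant trajectory give "unordered".
Preceding communities are the *enablers*, the others the *effectors*;
*connector* contacts are adjacent (direction ignored) to both hubs.

## 7. Conformational states

PCA of the fingerprint columns of a selected subnetwork (typically
enabler + effector + connectors) is computed by SVD on column-centered
but **unscaled** data — unit-variance scaling of 0/1 columns inflates
rare contacts. Component signs are fixed (largest-magnitude loading
positive) for determinism. State assignment adds a seeded k-means
partition of the score space, with labels renumbered by first
occurrence so state 1 temporally precedes state 2; the cluster count
(default 3: before the enabler event, between events, after the
effector event) is user-set. The clustering step exists to make state
delineation testable; visual inspection of the score space remains the
primary use.

## 8. Evolutionary scoring

Per alignment column, residue frequencies $P$ (gaps dropped,
renormalized; columns over 50% gaps flagged low-confidence) and a
similarity matrix $S$ form the density matrix
$$\rho = \frac{P^{1/2} S P^{1/2}}{\mathrm{tr}(P^{1/2} S P^{1/2})},$$
whose Von Neumann entropy $S_i = -\sum \lambda\, \log_{20} \lambda$
(eigenvalues $\lambda$ of $\rho$; base 20 so the maximum over 20 amino
acids is exactly 1) gives the conservation score $C_i = 1 - S_i$. The
symmetric $P^{1/2} S P^{1/2}$ form is chosen over $P\,S$ because it
guarantees a real non-negative spectrum; the construction in the
underlying literature is not published in full. $S$ is derived from
BLOSUM50 by min-max mapping to $[0,1]$ and rescaling to a unit
diagonal — raw log-odds entries are not usable as similarities.

Position classification over a residue subset: *fully conserved* = one
residue type in every sequence of every class; *perfectly specific*
for class $k$ = one residue type in all $k$ sequences, absent at that
position in all other classes; gaps disqualify by default. The
specificity ratio $\rho = \log_2 |S|/|C|$ is negative when purifying
selection dominates, with $\pm\infty$/NaN sentinels for empty sets.
(The literature reuses $\rho$ for both the density matrix and this
ratio; context disambiguates.)

## 9. The synthetic generator

`generate_ensemble()` emulates the statistical structure the method
assumes, not MD physics: each planted community follows a latent
two-state signal switching at its role's time (enabler $t_e = 3000$,
effector $t_f = 5000$ by default, each jittered $\pm 200$ frames per
trajectory — transitions recur at different times while communities
stay fixed); members copy the latent state with probability `coupling`
(default 0.95) and otherwise flip to a fair coin. Background contacts
are independent two-state Markov chains (flip rate 0.02 per frame,
giving the slow autocorrelation real contact streams show, a harder
null for windowed MI than i.i.d. noise). A proxy trace steps from 12 to
4 (distance-like units, noise SD 0.5) at the effector switch, so
change-point detection and enriched sampling are exercised exactly as
in the real workflow. The default ensemble is 12 trajectories × 8,000
frames × 40 contacts with two size-5 communities.

What passing tests on this generator do *not* show: robustness to
non-stationary baselines, correlated background communities, frame
counts or contact densities of real MD data, or contact-detection
noise. The generator's defaults are the package's reference study
conditions and are not adjusted per test.

`generate_msa()` plants fully conserved and class-specific columns in
a toy alignment with tunable background diversity; classification
round-trips these sets exactly.

## 10. Numerical conventions and degenerate inputs

* All MI is plug-in, log base 2, $0 \log 0 \equiv 0$, clamped at 0
  against rounding; the 2×2 kernel canonicalizes table orientation so
  $\mathrm{MI}(x,y)$ and $\mathrm{MI}(y,x)$ are bitwise identical.
* A symmetric window holds $2\delta + 1$ frames (odd), so "balanced"
  streams reach 1 bit only up to a one-frame imbalance
  ($\approx 10^{-5}$ at $\delta = 75$).
* Entropy eigenvalues below $10^{-12}$ are treated as zero; density
  matrices are validated to trace 1 within $10^{-8}$.
* Constant contact columns: rejected (or optionally dropped) by
  structure learning, dropped with reason "constant" by the MI filter,
  MI 0 everywhere.
* Family-score configuration tables are capped by `max_parents`;
  exceeding it is an error, not silent truncation.
* Test problem sizes are scaled-down but structurally faithful: the
  flagship end-to-end property runs 10 master seeds of the default
  12 × 8,000 × 40 ensemble; structure-recovery checks use 3-node
  exhaustive enumeration (25 DAGs, 50 seeds) and 8-node planted
  graphs ($n = 10^4$, 20 seeds).

## 11. Known limitations

* Greedy BIC search gives no global-optimality guarantee beyond the
  enumerable cases; learned edge sets on real data will differ from
  other implementations edge by edge even on identical input.
* The change-point locator assumes a single transition; multi-modal
  proxies need externally supplied transition frames.
* Windowed MI has a small-sample positive bias; no analytic bias
  correction is applied, and the thresholds (0.01-bit filter, 1-bit
  peaks) are defined against the uncorrected estimator. The
  largest-window tie rule and the data-driven threshold
  (`ensemble_std_threshold()`) are the provided mitigations.
* Only binary features are supported; continuous features would need
  discretization upstream.
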