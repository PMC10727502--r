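---
title: "Mapping allosteric communication with elastic network transfer entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping allosteric communication with elastic network transfer entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allosTE)
```

## The model

allosTE treats a protein as an elastic network of C-alpha nodes and asks
two questions: *which residues drive the collective dynamics* (information
sources), and *in what order does a conformational change propagate*
(leaders and followers).

### Gaussian network model and transfer entropy

The Gaussian network model (GNM) connects every pair of residues within a
cutoff distance (default 10 Å) by a spring of unit force constant. The
contact topology is encoded in the Kirchhoff (Laplacian) matrix
$\Gamma$; residue fluctuations are isotropic 1-D Gaussian variables whose
stationary covariance is the pseudoinverse $\Gamma^{+}$. Everything is
expressed in reduced units ($k_BT = \gamma = $ spring constant $= 1$), so
the time delay $\tau$ is dimensionless. Restricting to a subset $s$ of
slow modes (eigenpairs $\lambda_k, u_k$), the lagged covariance is

$$c_{ij}(\tau) = \sum_{k \in s} \lambda_k^{-1}\, u_{ki} u_{kj}\,
  e^{-\lambda_k \tau},$$

which is exactly the lag covariance of the overdamped (Ornstein-Uhlenbeck)
Langevin dynamics on the same network. Because the fluctuations are
Gaussian, the transfer entropy from residue $i$ to residue $j$ at delay
$\tau$ has a closed form in the log-determinants of the covariance blocks
of $(\Delta R_i(0), \Delta R_j(0), \Delta R_j(\tau))$:

$$T_{i \to j}(\tau) = S\!\left(\Delta R_j(\tau) \mid \Delta R_j(0)\right)
  - S\!\left(\Delta R_j(\tau) \mid \Delta R_i(0), \Delta R_j(0)\right),$$

the reduction in uncertainty of $j$'s future given $i$'s present, beyond
what $j$'s own present already explains. This is the conditional mutual
information $I(\Delta R_j(\tau); \Delta R_i(0) \mid \Delta R_j(0)) \ge 0$.
The net transfer $\Delta T_{i \to j} = T_{i \to j} - T_{j \to i}$ is
antisymmetric; residues with predominantly positive rows are entropy
*sources*, those with negative rows are *sinks*.

**A note on the conditioning set.** Some presentations of GNM transfer
entropy write the first conditional entropy as conditioning on the
*source's* present value, $S(\Delta R_j(\tau) \mid \Delta R_i(0))$. That
variant equals $I(\Delta R_j(\tau); \Delta R_j(0) \mid \Delta R_i(0))$,
which diverges as $\tau \to 0$ (a variable shares infinite information
with itself), so a delay chosen by maximizing total transfer entropy
degenerates to the smallest delay considered. Because the delay-selection
rule below requires an interior maximum, the package defaults to the
Schreiber convention above (`conditioning = "target"`); the other variant
remains available (`conditioning = "source"`) as a sensitivity check at a
fixed, user-supplied $\tau$.

Pairs whose covariance blocks are singular at working precision — which
happens when a truncated mode subset makes two residues perfectly
collinear — are flagged, zeroed and counted, rather than propagated as
numerical noise.

### Delay selection

Too small a $\tau$ reveals only contacts between sequence neighbours; too
large a $\tau$ erases all correlation. The package scans a logarithmic
grid (60 points spanning $[0.01/\lambda_{\max},\ 20/\lambda_{\min}]$ of
the chosen subset) for $\tau_{\mathrm{opt}}$, the delay maximizing the
total transfer entropy $\sum_{i \ne j} T_{i \to j}(\tau)$, and runs the
analyses at $3\,\tau_{\mathrm{opt}}$, where the collectivity of the net
transfer is typically maximal. Both the total TE and the total positive
net TE curves are returned so the choice can be inspected. The delay is
selected per mode subset.

### Collectivity and the TECol score

A residue that sends a large amount of entropy to a single neighbour is
less interesting, as an allosteric source, than one that broadcasts to
the whole fold. For each source residue $i$ the positive net transfers
$\Delta T_{ij}$ are squared and normalized into a distribution over
targets $j$ ($\alpha_i \sum_j (\Delta T_{ij})^2 = 1$); the exponential of
its entropy, scaled by $1/N$, is the collectivity

$$K_i = \frac{1}{N} \exp\!\Big(-\sum_j \alpha_i (\Delta T_{ij})^2
  \log \alpha_i (\Delta T_{ij})^2\Big) \in [1/N,\, 1],$$

reaching $1/N$ for a single-target row and 1 for a perfectly uniform one.
The **TECol score** of residue $i$ is its cumulative positive net
transfer $\sum_j \max(\Delta T_{ij}, 0)$ multiplied by $K_i$. Analyses
are run for three slow-mode subsets — modes 1–10, 2–10 and 3–10 — because
removing the one or two most collective modes exposes latent sources
otherwise hidden under global motions.

### Allosteric peaks and co-localization statistics

Peaks of the per-residue TECol profile are local maxima (per chain,
plateaus report their leftmost residue) kept when their score exceeds the
profile mean *and* their topographic prominence exceeds the mean
prominence of all local maxima; ties at the mean prominence are kept so
an isolated single bump counts. Agreement between peaks and a reference
residue set (functional residues, ligand-binding residues, ...) is
counted at cutoffs of 0 Å (exact), 4 Å and 7 Å between C-alpha atoms, and
assessed against a null of peak sets drawn uniformly *from the modeled
residues* without replacement:

$$Z = \frac{X - \mu}{\sigma},$$

with $\mu, \sigma$ estimated from the null draws (default 100 000) and a
one-tailed normal $p$; the empirical tail probability is reported
alongside since exact-match counts are discrete and small. Drawing from
modeled residues only matters: unresolved parts of a structure must not
dilute the null.

### ANM-LD transition simulation

To order events in time the package simulates the transition between two
conformers. Each cycle: (1) superpose the target onto the current
conformer; (2) build the anisotropic network model (ANM) Hessian at a 13
Å cutoff and take the lowest `mode_pool` (default 50) non-zero modes; (3)
pick the mode with the largest overlap with the coordinate difference
vector and step along it with deformation factor DF = 0.4 Å (the C-alpha
RMSD of the step), signed to reduce the difference; (4) relax. The step
amplitude is capped at the least-squares projection of the remaining
difference on the mode, so the fixed DF cannot overshoot near
convergence. Iteration stops after `max_cycles` (default 50) or when the
RMSD to the target stops improving by `rmsd_tol` over `patience` cycles.

The relaxation backend is deliberately coarse-grained, at the same
C-alpha resolution as the rest of the package: harmonic pseudo-bonds
between consecutive residues at their cycle-start lengths, a soft
excluded-volume term below 4 Å (native pairs already closer than that are
exempt, so an undeformed structure is a fixed point of the relaxation),
and a weak positional tether to the pre-deformation conformer; 500
steepest-descent steps are followed by 100 overdamped Langevin steps. The
nominal 310 K temperature maps to reduced units through a single scale
factor (`temp_scale`, default $10^{-6}$ Å$^2$/K) chosen so the thermal
RMS displacement along the softest restrained directions (~0.08 Å) stays
an order of magnitude below DF — at C-alpha resolution only the
noise-to-restoring-force ratio is meaningful. The backend is pluggable:
any function with the same signature can replace `relax()` if an external
engine is preferred. Published transition studies with all-atom
relaxation quote convergence near 2 Å for a large membrane protein; with
this coarse backend such figures should be read as bounds, not exact
values.

### Time-delayed cross-correlations and directionality

Over a window of trajectory frames, residue fluctuations are
displacements from the window-mean conformer, and

$$C_{ij}(\tau) = \frac{\langle \Delta R_i(t)\cdot \Delta R_j(t+\tau)\rangle}
 {\sqrt{\langle \Delta R_i(t)^2\rangle\,\langle \Delta R_j(t+\tau)^2\rangle}}$$

with averages over all frames for which both $t$ and $t + \tau$ fall in
the window (no padding or wraparound; the two normalizing variances use
their own valid frame ranges, exactly as the estimator is written).
$\tau = 0$ gives the familiar symmetric DCCM with unit diagonal. For
$\tau > 0$, residue $i$ *leads* $j$ when $C_{ij}(\tau) > C_{ji}(\tau)$
and the larger of the two reaches `min_corr` (default 0.4). The delay is
chosen as the smallest $\tau$ at which the residue-averaged
autocorrelation $C_{ii}(\tau)$ crosses zero (falling back to a third of
the window if it never crosses); for a ~50-cycle transition of a large
two-lobed protein this lands around 16 cycles in a 48-cycle window, which
are also the defaults of the correlation pipeline.

## What the synthetic systems emulate — and what they do not

`make_two_domain_toy()` builds two compact self-avoiding chains (bead
spacing 3.8 Å, minimum pair distance 3.4 Å, the C-alpha geometry of real
proteins) joined by a slightly zigzagged extended linker (a perfectly
straight linker would have zero-energy bending modes in the ANM). The
generator guarantees by construction — with internal retries — that the
contact graph is connected at the 10 Å GNM cutoff and that the ANM at 13
Å has exactly six zero modes. `radius_factor` loosens one domain's
packing radius *and* self-avoidance distance, producing a domain with
systematically lower contact density; on such systems the tightly packed
domain is consistently the net entropy source at the selected delay, a
deterministic property of the structure used by the recovery tests.
`make_conformer_pair()` rotates domain 2 rigidly about the linker
(emulating an open/closed pair), `simulate_gnm_langevin()` samples the
exact stationary OU process of the GNM, and `make_lagged_trajectory()`
plants a known leader/follower relationship.

These toys reproduce the *statistical structure* the methods rely on —
connectivity contrast, rigid-body domain motion, Gaussian fluctuations
with a known covariance, a known lag — but not protein secondary
structure, side-chain packing, or any particular fold. Passing tests
demonstrate that the estimators recover planted ground truth under the
model's own assumptions; they do not validate the elastic-network
approximation itself against experiment.

## Numerical choices

* **Eigensolvers.** Dense symmetric `eigen()` throughout; structures to
  a few thousand residues decompose in seconds, which covers the intended
  use. Zero modes are identified by a relative threshold
  ($\lambda < 10^{-9} \lambda_{\max}$ for GNM, $10^{-8}$ for the ANM);
  a disconnected network is an error naming the components, never a
  silent analysis of one component.
* **Exact OU sampling.** The Langevin oracle integrates the process in
  the eigenbasis, where each mode is an exact AR(1) with coefficient
  $e^{-\lambda \Delta t}$ started from its stationary distribution, so
  sampled covariances are unbiased at any step size; Euler stepping of
  the same SDE would carry an $O(\Delta t)$ covariance bias that the
  5%-level oracle comparisons would conflate with implementation error.
* **Singular pairs.** TE entries with covariance determinants below
  $10^{-10}$ of their scale are zeroed and counted (see above); values
  within $-10^{-8}$ of zero are floored to 0.
* **Randomization.** Null draws are uniform without replacement over
  modeled residues; $\mu$ and $\sigma$ come from the draws, and results
  carry the seed, iteration count and both normal and empirical tails.
* **Degenerate inputs.** Coincident nodes warn and count as contacts;
  constant profiles yield no peaks; zero-variance residues in a DCCM warn
  and give zero rows; a transition already at its target converges in
  zero cycles; RMSD growth over three consecutive cycles aborts with
  diagnostics.

## Problem sizes used by the test-suite and acceptance script

The oracle comparison uses an 8-node system with a $10^6$-step
trajectory; invariant suites run on 66-residue two-domain toys; the
transition and directionality recoveries use a 20° closure and a
16-frame planted lag in a 48-frame window. These sizes make every
statistical tolerance in the tests comfortably attainable while the whole
suite completes in about a minute.

## Known limitations

* The GNM is isotropic and 1-D per residue; transfer entropy here
  captures amplitude, not direction, of local motions.
* Delay selection assumes the total-TE curve has an interior maximum,
  which holds under the default conditioning but not under the
  source-conditioned variant.
* The coarse relaxation backend preserves chain geometry and local
  packing but has no physical energy scale; convergence RMSDs are not
  comparable to all-atom values.
* Randomization nulls ignore chain topology and peak spacing; if peaks
  cluster for structural reasons the null is slightly liberal.
* Reference residue sets resolved by ligand contacts depend on the
  chosen heavy-atom cutoff (default 4.5 Å); curated lists can be supplied
  instead and take precedence.

## A worked toy example

```{r example, eval = FALSE}
toy <- make_two_domain_toy(30, 6, seed = 2, radius_factor = c(1, 1.6))
fit <- gnm_te(toy$coords)          # GNM at 10 A, modes 1-10, tau = 3 tau_opt
print(fit)
peaks <- detect_peaks(fit$tecol)
rt <- randomization_test(peaks, toy$linker, toy$coords,
                         cutoff = 4, n_iter = 10000, seed = 1)
print(rt)

pair <- make_conformer_pair(toy, angle = 20)
tr <- run_transition(pair$open, pair$closed, anmld_config(seed = 5))
plot(tr)
```
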