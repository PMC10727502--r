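# allosTE

Allosteric communication in proteins, mapped from C-alpha coordinates
with elastic network models.

Large proteins such as the CFTR chloride channel are controlled by
long-range communication: ATP binding at the nucleotide-binding domains
changes gating at a pore tens of Ångström away, and drugs potentiate the
channel from peripheral sites. `allosTE` implements a complete,
self-contained pipeline for dissecting such communication from structure
alone:

* **GNM transfer entropy.** A Gaussian network model (Kirchhoff matrix
  at a 10 Å cutoff, unit springs) defines Gaussian residue fluctuations;
  the transfer entropy between every ordered residue pair at time delay
  τ is evaluated in closed form from log-determinants of lagged
  covariances restricted to slow-mode subsets (modes 1–10, 2–10, 3–10).
  Net transfer ΔT(i→j) = T(i→j) − T(j→i) separates entropy *sources*
  from *sinks*; the delay is chosen as 3× the delay maximizing total
  transfer entropy.
* **TECol scores and allosteric peaks.** Each residue's cumulative
  positive net transfer is weighted by its *collectivity* K ∈ [1/N, 1]
  (how broadly it broadcasts); peaks of the resulting TECol profile with
  above-average score and prominence are the predicted allosteric
  sources. Their co-localization with reference residue sets is scored
  with Z = (X − μ)/σ against 100 000 random peak sets drawn from the
  modeled residues.
* **ANM-LD transition simulation.** The transition between two
  conformers is evolved by iteratively deforming along the
  best-overlapping anisotropic-network mode (13 Å cutoff, 0.4 Å step)
  and relaxing with a coarse-grained C-alpha backend.
* **Time-delayed cross-correlations.** Windowed DCCMs at delay τ give
  leader/follower calls: residue i leads j when C_ij(τ) > C_ji(τ), which
  orders the sequence of allosteric transduction along a trajectory.
* **Synthetic ground truth.** Generators for two-domain elastic toys,
  conformer pairs, exact Ornstein–Uhlenbeck fluctuation trajectories and
  planted-lag trajectories let every stage be validated end-to-end with
  no external files.

## A worked example

```r
library(allosTE)

toy <- make_two_domain_toy(30, 6, seed = 2, radius_factor = c(1, 1.6))
fit <- gnm_te(toy$coords)   # GNM at 10 A, modes 1-10, tau = 3 x tau_opt
print(fit)
#> GNM transfer entropy fit
#>   66 residues, modes 1-10, tau = 2.079 (3 x tau_opt = 0.6929), conditioning = target
#>   top TECol residues: 18 (0.332), 2 (0.318), 1 (0.306), 17 (0.288), 3 (0.261)
```

The toy's second domain is loosely packed (`radius_factor = c(1, 1.6)`),
so the tightly connected first domain (residues 1–30) acts as the net
entropy source — exactly where the top TECol residues land. Peak
detection and a randomization test against the planted linker:

```r
peaks <- detect_peaks(fit$tecol)
print(peaks)
#> Allosteric peaks: 6 of 18 local maxima (score > 0.0623 and prominence > 0.0576 )
#>   index      score prominence
#> 1    14 0.15829378 0.14333659
#> 2    18 0.33199159 0.32238436
#> ...

randomization_test(peaks, toy$linker, toy$coords, cutoff = 4,
                   n_iter = 10000, seed = 1)
#> Co-localization randomization test (cutoff 4 A, 10000 sets of 6 peaks)
#>   null: mu = 1.591, sigma = 1.610
#>   observed X = 3 -> Z = 0.87, p(normal) = 0.191, p(empirical) = 0.345
```

Three of the six linker residues lie within 4 Å of a peak versus 1.59
expected by chance (Z = 0.87) — a positive but, on a 66-residue toy, not
yet significant enrichment; on real structures the same statistic is
computed against curated functional residue sets. Finally, the
open→closed transition of the same toy:

```r
pair <- make_conformer_pair(toy, angle = 20)
tr <- run_transition(pair$open, pair$closed, anmld_config(seed = 5))
print(tr)
#> ANM-LD trajectory: 26 cycles, RMSD 1.95 -> 0.59 A (converged)
plot(tr)                       # RMSD-to-target per cycle
res <- run_correlation_pipeline(list(tau = 8), tr)  # DCCM + leader calls
```

For real structures, `read_structure()` accepts PDB and mmCIF files,
`ligand_contact_residues()` derives binding-site sets (e.g. `"ATP"` at
4.5 Å), and the config-driven `run_te_pipeline()`,
`run_anmld_pipeline()` and `run_correlation_pipeline()` chain the whole
analysis and write CSV/JSON/PDB artifacts. A thin command-line wrapper
lives at `inst/cli/alloste.R`.

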