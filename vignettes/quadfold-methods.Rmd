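---
title: "quadfold: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{quadfold: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(quadfold)
```

This vignette explains the science implemented in `quadfold`: the
collective variables, the metadynamics and bias-exchange machinery, the
free-energy-landscape and basin analysis, the per-intermediate statistics,
and the synthetic-data generators used to validate all of it. It also
records the numerical choices and the decisions taken where the underlying
methodology leaves them open.

Units everywhere: lengths in nm, times in ns, energies in kJ/mol,
`kB = 0.0083145` kJ/mol/K, default temperature 300 K.

## 1. The problem and the modelling strategy

A G-quadruplex folds far too slowly for unbiased all-atom simulation, and
its folding couples three things: formation of native (Hoogsteen)
hydrogen bonds, binding of channel cations, and syn/anti reorientation of
the glycosidic bonds. The analysis stack mirrors the established two-part
strategy for such systems:

1. **Sampling**: bias-exchange metadynamics over a small set of collective
   variables reconstructs a free-energy landscape whose basins are the
   (meta)stable states.
2. **Characterisation**: ensembles of each intermediate are summarised by
   hydrogen-bond probability maps, per-nucleotide ion-binding
   probabilities, syn/anti classification, clustering, and pathway graphs
   over unfolding trajectories.

`quadfold` implements both parts but deliberately replaces the MD engine
with overdamped Langevin dynamics on analytic landscapes, and replaces
real trajectories with synthetic ensembles in which every statistic of
interest is *planted*. Validation is therefore parameter recovery: the
pipeline must read back what the generator wrote in.

## 2. Collective variables

* **Q, fraction of native contacts** (`compute_q`). The native contact
  list is built once from the reference structure: all pairs of selected
  heavy atoms (defaults `O6`, `N7`, `N2`, the guanine Hoogsteen-face
  atoms) on nucleotides separated by `|i - j| >= 2`, with native distance
  below 0.45 nm. The separation rule excludes trivially bonded
  neighbours. In sharp mode a contact is formed when
  `d < lambda * d_native` with `lambda = 1.2`; smooth mode uses the
  rational switching function below. Q is stored as a fraction in
  `[0, 1]`; bias widths quoted on a contact-count scale (such as the
  conventional `2.5/130`, where 130 is a total contact count) convert by
  dividing by the count. The package makes no claim about reproducing any
  particular published contact count — the contact definition is
  parameterised and documented instead.
* **dRMSD** (`compute_drmsd`) over the `C4*` backbone points:
  `sqrt(mean_(i<j) (d_ij - d_ij_ref)^2)`. Built from internal distances
  only, hence rigid-motion invariant (tested to 1e-9 nm). Also the metric
  of the leader clustering.
* **N_ion** (`compute_ion_coordination`): cation–O6 pairs within
  `r0 = 0.35` nm (sharp) or the sum of switching values (smooth).
* **Rg** (`compute_rg`): mass-uniform RMS distance of the backbone points
  from their centroid.

The smooth variants use `s(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m)` with
`n = 6, m = 10`; the removable singularity at `r = r0` takes its limit
value `n/m = 0.6`, with a first-order expansion applied in a 1e-6 band
and a log-space tail form for exponents large enough to overflow. As
`n, m` grow at fixed ratio the smooth value converges to the sharp
indicator for distances bounded away from `r0` — the property tests
exercise exactly that statement, with a 5% exclusion band.

The glycosidic torsion is measured on O4′–C1′–N9–C8 with the standard
signed dihedral convention (cross-checked against an independent
implementation) and reported in `[-180, 180)` degrees, so the syn window
`(-90, 90]` and its complement tile the circle without ambiguity.

## 3. Metadynamics, exchange, and the toy dynamics

The bias is the standard (non-well-tempered) sum of Gaussians; the free
energy estimate is `F(s) = -V_G(s, t_final)`, shifted to minimum zero.
Dynamics is overdamped Langevin,
`x' = x + (dt/gamma) F + sqrt(2 kB T dt / gamma) xi`, with `gamma = 1`
kJ/mol ns/nm² and `dt = 1e-4` ns by default; with no inertia, the
"conformations and velocities" swapped at an exchange reduce to the
coordinates.

Defaults that the methodology leaves open, and why these values:

* **Gaussian height 0.1–0.2 kJ/mol** (`run_metad` uses 0.1, the BEMD toy
  0.2): small hills keep the ripple of the recovered profile well below
  the 5 kJ/mol barriers of the toy landscapes.
* **Deposition stride `tau_g = 0.05` ns.** At the toy diffusivity
  `D = kB T / gamma ≈ 2.5` nm²/ns the well relaxation time is a few
  hundredths of a ns; depositing much faster than that overfills the well
  before the walker re-equilibrates and inflates the error, so the stride
  is set at the relaxation scale. (Much faster deposition, e.g. one hill
  per ps, was measurably worse on the double-well benchmark.)
* **Exchange attempts every 0.01 ns between a uniformly chosen replica
  pair.** Neighbour schemes and random pairing give the same diagnostics;
  the log records the pair of every attempt so the analysis is
  scheme-agnostic.
* **Temperature 300 K** throughout.

Two engine-internal choices worth knowing:

* **Grid-cached bias.** The per-step bias force uses a dense 1D grid
  (2001 points over the landscape range) holding the accumulated value and
  its analytic derivative, updated at each deposit and read by linear
  interpolation — the standard trick that makes cost independent of the
  kernel count. The kernel list itself is the authoritative record: the
  free-energy readout (`bias_to_free_energy`, `metad_fel_average`) sums
  kernels exactly.
* **Stopping rule and averaged readout** (`run_metad`). Every 20 ns
  window the growth of the bias over `[-1.3, 1.3]` is compared with a
  uniform rise; when the relative RMS deviation stays below 0.2 for two
  consecutive windows the landscape is considered filled, after which
  deposition continues for a 300 ns averaging window. The reported
  profile is the time average of the instantaneous estimate over the last
  half of the run (`metad_fel_average`), which removes most of the
  hill-scale ripple; barrier heights are read at the *known* barrier and
  minima positions (`fel_barrier_height`) rather than by minimising over
  windows, which would bias the estimate upward by the ripple amplitude.

The exchange criterion is implemented exactly as
`min(1, exp[(V_a(x_a) + V_b(x_b) - V_a(x_b) - V_b(x_a)) / kB T])`, where
`V_a(x_b)` means replica a's bias at its own CV evaluated on b's
coordinates. Empty biases give acceptance exactly 1; a planted bias
difference of `-kB T` reproduces acceptance `e^{-1}` to binomial
accuracy.

## 4. Free-energy landscapes and basins

Landscapes are estimated **only from neutral replicas** by Boltzmann
inversion of the histogram, `F = -kB T ln(n / n_max)`; no reweighting of
biased replicas is attempted, which avoids otherwise-arbitrary choices.
Decisions left open by that procedure:

* default 40 bins per axis over the observed range padded 5% for the
  generic estimator; the BEMD toy workflow uses 16 bins so that a
  60 ns run yields solidly populated bins;
* the first 20% of samples are discarded as equilibration;
* bins with fewer than `min_count` samples are masked (1 by default; the
  basin workflow uses 20, because nearly-empty bins at the rim of the
  sampled region carry `±kBT`-scale noise that fabricates shallow minima);
* basins: steepest descent on the 4-neighbour (2D) or 2-neighbour (1D)
  grid graph, followed by persistence merging — two minima merge when
  their separating saddle lies less than `min_barrier` (default `1 kB T`)
  above the shallower minimum. Plateau ties break toward the smaller bin
  index, and basins are numbered by ascending minimum free energy. The
  merge threshold must stay below the smallest real barrier of interest
  (5 kJ/mol ≈ 2 kT on the toy landscapes) and above the histogram noise;
  `1 kB T` satisfies both with margin.

Convergence diagnostics mirror accepted practice: RMS difference between
surfaces from independent replicas or run halves (after aligning minima
over the common support), per-replica cumulative accepted-exchange counts
with a linear fit (steady exchange gives R² near 1), and CV-range
coverage with a traversal count (alternations between the lowest and
highest decile of the range).

## 5. Ensemble statistics

* **Leader clustering**: one pass over frames; each frame joins the
  *first* representative within the threshold (0.3 nm; 0.45 nm for
  unfolding runs, where stages are further apart) or founds a new
  cluster. The order dependence is inherent to the algorithm and is
  documented rather than hidden; the test suite pins the implementation
  against an independent brute-force reference, including representatives
  and populations.
* **Hydrogen bonds**: nucleotide-level probability that any donor–
  acceptor pair satisfies the criterion. In the reduced representation
  the criterion is distance-only (≤ 0.35 nm); when hydrogens are present
  a donor–H–acceptor angle ≥ 135° is also required. Pairs are annotated
  native/non-native against the reference structure's map.
* **Ion binding**: per-nucleotide probability of a cation within 0.35 nm
  of the O6 (the same `r0` as the N_ion CV, deliberately shared), and the
  mean number of bound ions per frame with each ion counted once.
* **Syn/anti**: per-sample windows as above; a nucleotide is called
  `syn` or `anti` when that state's occupancy is ≥ 0.8 *and* fewer than
  2 transitions occur, otherwise `fluctuating`. Mean dwell times are
  mean run lengths times the sampling interval — a slight overestimate
  when runs are censored at the trace ends, negligible once a trace
  contains tens of transitions.
* **Pathway graphs**: consecutive distinct stage labels become directed
  edges (runs collapse), counts aggregate over trajectories, and each
  distinct route is reported with its multiplicity.

## 6. What the generators emulate — and what they do not

`make_toy_quadruplex` builds a parallel four-repeat, three-layer
quadruplex at the pseudo-atom level (7–10 points per nucleotide), with O6
atoms ringing a channel that holds two cations, one donor (`N2`) and one
acceptor (`N7`) per guanine placed so that exactly the
adjacent-in-tetrad pairs satisfy the hydrogen-bond criterion, and a fixed
mixed syn/anti pattern realised through the actual C8 positions. O6 is
deliberately *not* a default hydrogen-bond acceptor: it is reserved for
ion coordination so that planted bond probabilities and planted ion
occupancies cannot contaminate each other.

`make_intermediate_ensemble` realises planted statistics geometrically,
not as labels: an in-contact bond places the acceptor 0.28–0.33 nm from
the donor, an out-of-contact one at 0.5–0.8 nm, straddling the 0.35 nm
criterion with margin. Placement directions are validated so that the
whole placement segment stays at least 0.36 nm from every *other* donor
atom — candidate directions are tried in order (native direction, radial
outward from the channel axis, ±z) and the generator raises an
"infeasible constraints" error naming the pair if none is clear, or if an
acceptor atom is claimed by two pairs. Cation sites sit 0.25 nm radially
outward of their O6, which puts an occupying ion within the cutoff of
exactly one nucleotide; unoccupied ions are parked several nm away.
Glycosidic telegraph dynamics are discretised at the frame stride with
per-frame switching probability `1 - exp(-stride/dwell)`; with the
default 0.5 ns stride and 10 ns dwell, discretisation inflates the
recovered dwell by only ~2.5%.

The default study conditions (`default_ensemble_spec`): four native bonds
at probability 0.9, two non-native at 0.3, cation occupancies 1.0 and 0.5
(mean bound count 1.5), two nucleotides with 10 ns symmetric dwell, 2000
frames at 0.5 ns, 0.02 nm coordinate noise. These sizes give 99% binomial
confidence intervals of about ±0.02 on the probabilities and roughly 100
torsion transitions per dynamic nucleotide.

What passing on these ensembles does **not** show: the generators have no
force field, no solvent, no realistic DNA mechanics, and no coupling
between hydrogen bonds, ions and torsions beyond what is planted
independently. Recovery tests validate the *analysis operations*, not any
claim about real quadruplex ensembles; conversely, analysis code that
passes here can still be defeated by real-data pathologies (atom-naming
variants, broken chains, partial occupancy) that the readers handle only
via the role map.

`make_unfolding_set` plants stage sequences (native → intermediate(s) →
unfolded) as uniformly scaled copies of the native structure: scaling by
`c` multiplies all internal distances by `c`, so consecutive stages sit
at a chosen backbone dRMSD (1.0 nm, far above the 0.45 nm clustering
threshold) while intra-stage noise stays at 0.01 nm. This makes
stage-label recovery by leader clustering exact by construction, which is
precisely what a pathway-counting test needs.

## 7. Sampling-test design and problem sizes

Two statistical checks need care with correlated samples:

* **Boltzmann sanity.** The unbiased sampler is tested on the 5 kJ/mol
  double well with `dt = 2e-4` ns and `gamma = 0.2` (Euler bias
  `k dt/gamma = 0.04`, i.e. ~2% in the well variance, well below the test
  resolution). The Kramers estimate of the well-hopping rate at these
  settings (~3/ns) sets the thinning: keeping every 1000th step makes
  consecutive kept samples nearly independent. The 1e5-step run then
  yields 100 effective samples, compared against ten equal-probability
  bins from the analytic Boltzmann CDF by a chi-square test at
  alpha = 0.01. Equal-probability binning keeps every expected count at
  10, where the chi-square approximation is solid.
* **Exchange acceptance.** 1e4 attempts at a planted bias difference of
  exactly `-kB T`, compared to `e^{-1}` within 3 binomial standard
  deviations.

Problem sizes used by the test suite and the acceptance script — chosen
so each check has comfortable statistical resolution while the whole
suite runs in well under a minute of compute: metadynamics barrier
recovery averaged over 3 seeds (a few hundred ns each, ~2 s total); BEMD
toy with 2 biased + 2 neutral replicas for 60 ns (~12,000 neutral
samples); ensembles of 2000 frames; 10 unfolding trajectories with the
8/1/1 route split; leader-clustering equivalence on 100 frames at
thresholds 0.1/0.3/0.5 nm.

## 8. Known limitations

* The engine integrates only the bundled analytic landscapes (the
  landscape reaches C++ by id); a user-supplied R potential would need
  either a new id or an R-level integrator loop.
* 1D bias grids assume the biased CV stays within the landscape's stated
  range; outside it the bias force is zero and the value is clamped.
* `estimate_fel` supports one or two axes — the dimensionality a
  histogram estimator can realistically fill.
* The PDB reader resolves atoms through a name→role map and ignores
  everything else; it is not a general-purpose structure parser, and
  trajectories must share a topology across models.
* Dwell-time estimates use uncensored run-length means; for traces with
  very few transitions they are biased low (the fluctuation rule keeps
  such traces out of the dwell statistics in practice).
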