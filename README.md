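# quadfold

Bias-exchange metadynamics and ensemble analysis for G-quadruplex folding,
in R.

G-quadruplexes are four-stranded DNA/RNA structures built from stacked
G-tetrads that coordinate monovalent cations in a central channel. Their
folding is slow (milliseconds and beyond), proceeds through intermediates
such as G-triplexes, and is coupled to cation binding and to syn/anti
reorientations of the glycosidic bonds — far outside the reach of plain
all-atom MD. The computational strategy this package implements studies
that problem with (i) bias-exchange metadynamics (BEMD) to reconstruct the
free-energy landscape over a few collective variables, and (ii) ensemble
statistics of the intermediate states (hydrogen-bond maps, ion-binding
profiles, syn/anti dynamics, unfolding-pathway graphs).

`quadfold` provides that full analysis stack as reusable, tested R code,
exercised on analytic toy landscapes and synthetic conformational ensembles
with planted statistical structure, so every stage is validated by
parameter recovery rather than by irreproducible microsecond simulations.
It is aimed at computational biophysicists who want the machinery —
the CVs, the metadynamics bookkeeping, the exchange criterion, the
landscape/basin analysis, the per-intermediate statistics — without a
molecular-dynamics engine attached.

## The methods in brief

**Collective variables** (units: nm, ns, kJ/mol):

- `Q` — fraction of native contacts among the guanines: a contact
  `(i, j)` counts as formed when `d_ij < 1.2 d_ij^native`;
- `dRMSD` — distance RMSD of the `C4*` backbone,
  `sqrt(mean_(i<j) (d_ij - d_ij^ref)^2)`, rigid-motion invariant;
- `N_ion` — number of cation–O6 contacts within `r0 = 0.35` nm;
- `Rg` — radius of gyration of the backbone.

**Metadynamics.** The history-dependent bias is a sum of deposited
Gaussians, `V_G(s, t) = Σ_k w exp(-(s - s_k)² / 2σ²)` over kernels with
deposit time `≤ t`; after the bias flattens, `F(s) = -V_G(s, t)` estimates
the free energy. Replicas biased on different CVs exchange coordinates
under the Metropolis-like criterion

    p_accept = min(1, exp[(V_a(x_a) + V_b(x_b) - V_a(x_b) - V_b(x_a)) / kBT])

with the paper-standard widths retained as defaults (σ_Q = 2.5/130 on the
fraction scale, σ_dRMSD = 0.02 nm, σ_Nion = 0.5, σ_Rg = 0.2 nm). Neutral
(bias-free) replicas sample the corrected ensemble; their 2D histogram
yields the free-energy landscape `F = -kBT ln(n/n_max)`, whose basins are
found by steepest descent plus persistence merging.

**Ensemble statistics.** Leader clustering (one pass, first representative
within a 0.3 nm dRMSD threshold wins; 0.45 nm for high-temperature
unfolding runs); hydrogen-bond probability maps (donor–acceptor distance
≤ 0.35 nm); per-nucleotide ion-binding probabilities and mean bound-ion
counts; syn/anti classification of the glycosidic torsion measured on
O4′–C1′–N9–C8 (syn for χ ∈ (-90°, 90°]), with two-state dwell-time
estimation; and directed pathway graphs with per-route multiplicities.

**Synthetic data.** `make_toy_quadruplex()` builds a reduced pseudo-atom
quadruplex (4 repeats × 3 tetrad layers, channel ions);
`make_intermediate_ensemble()` plants Bernoulli hydrogen bonds, cation-site
occupancies and telegraph syn/anti dynamics with stated dwell times;
`make_unfolding_set()` plants stage sequences with known multiplicities.

## Worked example

```r
library(quadfold)

native  <- make_toy_quadruplex()
contacts <- build_native_contacts(native)
evaluate_cv_vector(native, native, contacts)
#> CV vector: Q = 1.000, dRMSD = 0.0000 nm, N_ion = 16.00, Rg = 0.9897 nm

# a 2000-frame ensemble with planted statistics, and their recovery
spec <- default_ensemble_spec(native, seed = 1, n_frames = 2000)
ens  <- make_intermediate_ensemble(spec, native)
hbond_map(ens, native = native)$probability[1, 4]   # planted 0.9
#> [1] 0.8905
ion_binding_profile(ens)
#> g4_ion_profile: mean bound ions 1.50; per-nucleotide P in [0.00, 1.00]
subset(glycosidic_summary(ens), classification == "fluctuating")
#>   resno classification n_transitions occupancy_syn dwell_syn_ns dwell_anti_ns
#> 3     3    fluctuating            87        0.4625    10.511364      12.21591
#> 6     6    fluctuating            90        0.4185     9.097826      12.92222

# metadynamics on a 5 kJ/mol double well: barrier recovery
land <- make_analytic_landscape("double_well", list(h = 5))
run  <- run_metad(land, seed = 1)
fel  <- metad_fel_average(run$bias, seq(-1.5, 1.5, length.out = 301))
fel_barrier_height(fel)
#> [1] 5.157733
```

The two fluctuating nucleotides are exactly the ones planted with 10 ns
two-state glycosidic dynamics (the others keep their native syn/anti
call); the mean bound-ion count 1.50 reproduces the planted site
occupancies 1.0 + 0.5; and the recovered barrier is within a few percent
of the analytic 5 kJ/mol.

End-to-end runs are available through `run_workflow("full-synthetic")`
(or any of `bemd-toy`, `fel`, `cluster`, `analyze-ensemble`,
`unfold-pathways`, `make-fixtures`) and, from a shell, through the wrapper
`inst/scripts/quadfold-cli.R`. Each run writes CSV/JSON/PDB/DOT artifacts
plus a manifest with checksums; identical configs and seeds give
byte-identical outputs.

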