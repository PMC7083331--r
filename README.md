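# emtkinetics

Multi-state Markov kinetics of the epithelial-to-mesenchymal transition
(EMT), for systems biologists studying cell-state plasticity.

Population time courses of the three observable EMT macrostates —
epithelial (E), partial EMT (P), mesenchymal (M) — are poorly described by
a three-state Markov chain: macrostate dwell times are non-exponential.
`emtkinetics` models EMT as an absorbing continuous-time Markov chain over
*hidden microstates*, with Arrhenius energy-barrier rates
`k = k0 * exp(-δE)` (energies in units of kBT, rates in 1/day) and a fixed
total barrier ΔE divided across steps. It provides:

- **Rate/topology construction** — chain, parallel-path, layered and
  stabilized-intermediate topologies with even barrier splitting
  (`energy_config`, `topology_spec`, `step_rates`, `split_paths`,
  `split_layers`, `calibrate_k0`);
- **Analytic kinetics** — closed-form occupancies and first-arrival-time
  (FAT) densities: Erlang for the uniform chain
  (MFAT = (N_int+1)/k), hypoexponential for parallel paths
  (MFAT = (1+ΣN_i)/k_A) and layers (MFAT = (N_ly+1/N_L1)/k), stabilized
  chains with mean dwelling time exactly 1/k2
  (`erlang_occupancy`, `fat_mfat_chain`, `parallel_kinetics`,
  `layered_kinetics`, `stabilized_occupancy`, `mfat_surface`,
  `compare_topologies`), all evaluated through numerically stable
  incomplete-gamma / log-space routes;
- **A reversible-chain solver** (uniformized matrix exponential,
  `reversible_occupancy`);
- **Exact stochastic simulation** — a Gillespie simulator over the same
  topologies (`build_transition_system`, `simulate_cells`,
  `summarize_ensemble`);
- **Hidden-microstate fitting** — grid search over (N_E, N_P) microstate
  counts with per-cell rate optimization scored by pooled RMSE on the
  percent scale (`fit_irreversible`, `fit_reversible`, `rmse_score`);
- **Synthetic data** — a generator emulating an induction experiment with
  multinomial sampling noise (`generator_spec`, `generate_timecourse`);
- **Sweep drivers** — reproducible tabular experiments with manifests
  (`run_chain_mfat`, `run_branch_sweeps`, `run_stabilized`; thin CLI at
  `inst/cli/emt-experiments.R`).

The headline structural result: for a fixed total barrier, the MFAT
`(N_int+1) exp(ΔE/(N_int+1)) / k0` is minimized near `N_int + 1 = ΔE`,
so intermediate states *accelerate* EMT up to an optimal count; parallel
paths help at low barriers and hurt at high ones (layers mirror this); a
stabilized intermediate traps cells for a mean time `1/k2`.

## Worked example

```r
library(emtkinetics)

# Calibrate the attempt rate so a 9-intermediate chain reproduces the
# fitted step rate 3.4261/day at a total barrier of 10 kBT
k0 <- calibrate_k0(10)            # 9.313105
ra <- step_rates(energy_config(10, k0), topology_spec("chain", N_int = 9))
ra$step_rates[1]                  # 3.4261 (1/day)
fat_mfat_chain(3.4261, 9)$mfat    # 2.918771 days to complete EMT

# Optimal chain length for this barrier
mfat_surface(10, 0:30)$argmin
#   delta_E N_int_min mfat_min
# 1      10         9 2.918771

# Recover hidden microstate counts from a synthetic time course
tc  <- generate_timecourse(generator_spec(seed = 1))  # 1e4 cells, days 0-8
fit_irreversible(tc)
# hidden-microstate irreversible fit
#   N_E = 5, N_P = 5
#   rates (1/day): k = 3.43176
#   RMSE = 0.1864 percent
```

The fitted `(N_E = 5, N_P = 5)` and `k ≈ 3.43/day` recover the
generator's truth: five hidden epithelial and five partial-EMT
microstates with a common step rate of 3.4261/day, the regime in which
the model reproduces observed EMT population kinetics. The MFAT of
2.92 days matches the simulated single-cell ensembles (few cells
mesenchymal by day 2, most by day 4).

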