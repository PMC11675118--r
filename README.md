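# dllmc

Cooperative-motion Monte Carlo for a dense two-dimensional dimer–solvent
liquid with immobile obstacles, on a fully occupied triangular lattice.

## The problem

In crowded two-dimensional fluids — colloidal monolayers, membranes,
cytoplasm-like media — transport is shaped by three ingredients at once:
the high density (no molecule can move without its neighbors moving),
the mixture of species of different size and shape, and quenched
obstacles.  `dllmc` implements the *dynamic lattice liquid* (DLL) model
for exactly this setting: solvent monomers, rigid dimers and immobile
obstacles fill every site of a periodic triangular lattice, and motion
occurs only through closed cooperative displacement loops, so the
continuity equation holds by construction and the dynamics exhibits the
correlated, heterogeneous character of real dense liquids.  The package
is for simulation studies of anomalous diffusion, dynamic heterogeneity
and caging in such crowded media.

## The model in brief

Each Monte Carlo step: every non-obstacle site draws a uniform random
direction toward one of its 6 neighbors; the cycles (length ≥ 3) of the
resulting successor map are candidate cooperative loops; loops are
rejected if they would break a rigid dimer bond (mers must stay nearest
neighbors) or carry a molecule through a moving dimer bond; all accepted
loops then execute simultaneously, each molecule replacing its successor.
Mutual exchanges (2-cycles) never execute.  Concentrations follow
c = n/L² (obstacles) and d = 2m/L² (sites covered by dimer mers).

Observables: mean square displacement ⟨Δr²(t)⟩ (unwrapped coordinates;
dimers tracked by their center of mass), anomalous exponent α from
MSD ~ t^α (walk dimension d_w = 2/α), short- and long-time diffusion
coefficients from the 2D Einstein relation ⟨Δr²⟩ = 4Dt with a
0.9 < α ≤ 1.1 validity gate, the non-Gaussian parameter
α₂(t) = ⟨Δr⁴⟩/(2⟨Δr²⟩²) − 1, the dimer end-to-end autocorrelation
⟨cos φ⟩(t), the solvent position autocorrelation ρ(t) (wrapped-site
identity), trapped-molecule fractions, cooperative-loop statistics, and
a site-percolation threshold estimator for obstacle matrices (union-find
wrapping criterion).

## Worked example

```r
library(dllmc)

st <- initialize_system(L = 32, c = 0.12, d = 0.5, seed = 7)
st
#> dll_state: L = 32  t = 0
#>   obstacles n = 123 (c = 0.1201), dimers m = 256 (d = 0.5000), solvent = 389

tr <- run_trajectory(st, n_steps = 5000)
m  <- msd(tr, "solvent")
tail(m, 3)
#>    time species statistic     value n_ensemble
#> 63 3981 solvent       msd  76.46787        389
#> 64 4467 solvent       msd  90.38817        389
#> 65 5000 solvent       msd 103.32905        389

fit_diffusion_coefficient(m, window = c(1, 100))
#> diffusion_fit: alpha = 0.9029 (d_w = 2.215, R2 = 0.9949), window [1, 100]
#>   D = 0.0059804 (gated valid)

stats <- loop_statistics(tr)
stats$mobile_fraction   # fraction of sites moving per step: 0.0204
stats$mean_length_found # mean cooperative-loop length: 3.38

estimate_threshold(c(32, 64), seq(0.44, 0.56, 0.01), 200, seed = 7)
#> percolation_result: p_c = 0.4853 +/- 0.0022 (sizes: L=32: 0.4800, L=64: 0.4906)
```

Reading the numbers: at 12% obstacles and 50% dimer coverage the solvent
MSD grows near-linearly (α ≈ 0.90 over the short-time window, already
showing the crowding-induced slowdown), the short-time diffusion
coefficient is D_SH ≈ 6.0×10⁻³ lattice²/step, about 2% of all sites move
in a typical step, and most cooperative loops are the minimal triangles.
The percolation estimate approaches the triangular-lattice site
threshold 1/2 from below as L grows (the wrapping-probability crossing
carries a small finite-size bias).

Experiment orchestration (concentration sweeps, ensembles over obstacle
matrices, manifests, tidy CSV outputs) goes through a strict YAML config:

```r
write_config_template("run.yaml")
run_experiment(load_config("run.yaml"))
```

A thin command-line wrapper with the same functionality ships in
`inst/cli/dllmc.R` (subcommands `init`, `run`, `percolation`,
`fixtures`).

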