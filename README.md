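# lpshells

Lone-pair decomposition of ion hydration shells from molecular-dynamics
trajectories.

## The problem

Halide ions (Cl⁻, I⁻, …) in water have diffuse first hydration shells:
literature first-shell coordination numbers scatter from ~4 to ~10 because a
purely radial cutoff on the ion–oxygen distance cannot distinguish waters
that actually hydrogen-bond to the ion from waters that merely pass nearby.
`lpshells` implements an interaction-based decomposition that starts from
the anion's four lone pairs — carried in the trajectory as pseudo-atom
sites, e.g. maximally localized Wannier-function centers from ab initio MD.
It is written for people analyzing such trajectories (and for method
development against its built-in synthetic generator, which provides
ground-truth-labeled data).

## The descriptor at the core

Each (lone pair, hydrogen) contact of an ion–water pair is scored by the
angle-weighted lone-pair–hydrogen distance

    eta = r_LP-H * sec(alpha/2) * sec(beta/2)

where `alpha` measures how far the hydrogen sits off the lone-pair axis
(angle at the ion) and `beta` how far the O–H bond points off the lone pair
(angle at the hydrogen). A perfectly linear hydrogen bond has
`alpha = beta = 0` and `eta = r_LP-H`; weaker, bent, or distant contacts
have larger eta. The ion–water descriptor `eta_ij` is the minimum over the
eight contacts. Because eta correlates linearly with the ion–water
interaction energy (the package fits and applies that calibration), a
cutoff on eta splits the conventional first shell into:

* a **tight** shell — waters with `eta < eta_cut`, tetrahedrally anchored
  on the four lone pairs, regardless of their distance;
* a **loose** shell — the remaining waters inside the first-minimum radius
  `r_cut`;
* **bulk** — everything else. Waters inside `r_cut` with both hydrogens
  pointing away from the ion are additionally flagged *misoriented*.

On top of the classification the package computes ion–O / ion–H radial
distribution functions and coordination numbers, spatial distribution
functions in the instantaneous lone-pair frame (Gaussian cube output),
eta distributions with automatic cutoff selection, committed exchange
events between shells (with the 0.1 ps transient filter) and normalized
mean residence times by the direct method,
`NMRT = t_sim / N_ex^shell`.

## Worked example

```r
library(lpshells)

params <- synth_preset("chloride", n_frames = 1000, seed = 42)
traj   <- generate_trajectory(params)
traj
#> lp_trajectory: 1000 frames, dt = 0.005 ps, span = 4.995 ps, box = 14 Ang, 30 waters

rc <- eta_rank_cutoff(eta_table(traj))
sprintf("eta cutoff from rank-distribution intersection: %.2f Ang", rc$eta_cut)
#> "eta cutoff from rank-distribution intersection: 2.03 Ang"

labels <- classify_shells(traj, shell_cutoffs(r_cut = 4.0, eta_cut = rc$eta_cut))
cn_distribution(labels, "tight")
#>   n     p
#> 1 0 0.000
#> 2 1 0.023
#> 3 2 0.207
#> 4 3 0.273
#> 5 4 0.496
#> 6 5 0.001

coordination_number(traj, 4.0)
#> [1] 8.7

exchange_analysis(labels, threshold = 0.1)$summary
#> Exchange summary (direct method)
#>   events: T-L = 1, L-B = 43, T-B = 0, T-L-B = 26
#>   t_sim = 4.995 ps; N_ex tight = 27, loose = 70
#>   NMRT tight = 0.185 ps, loose = 0.071 ps
#>   MRT  tight = 0.600 ps, loose = 0.386 ps (n-bar 3.25 / 5.41)
```

Reading: although ~8.7 waters sit inside the conventional 4.0 Å shell, the
eta classification finds the tight shell peaked at exactly 4 waters — the
tetrahedral structure hidden in the radial picture. The loose shell
exchanges with bulk several times per picosecond (NMRT 0.07 ps) while tight
waters persist roughly 2.6× longer per unit occupancy, and nearly all
tight→bulk exchanges route through the loose shell (`T-L-B` events,
`T-B = 0`). `run_full_analysis()` chains all stages and writes curves,
cube files, label tables and a JSON report into a run directory.

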