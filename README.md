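# ipwalk

Testing the mean-path-length **invariance property** (IP) for random walks
entering a virtual circular medium from an open environment.

## The problem

Transport theory predicts that the mean total path length of random walkers
crossing a bounded 2D domain is fixed by geometry alone,

```
⟨L⟩_IP = π S / P        (disk of radius R:  π R / 2)
```

independent of the walkers' step statistics — provided they enter with a
Lambertian (cosine) angular profile and the population is in statistical
equilibrium, i.e. the trajectory density inside the domain is constant. The
ballistic limit is the Cauchy/Dirac mean-chord theorem. Whether *animals
foraging in an open, unconfined environment* satisfy this invariance is a
question for movement ecology: equilibrium is not guaranteed in an open
system, and the answer turns out to hinge on the step-length distribution —
exponential (Lambert–Beer) steps preserve the IP, heavy-tailed steps break
it.

ipwalk implements the complete analysis pipeline for that test, for movement
ecologists with digitized trajectory data and for anyone studying random-walk
transport in 2D:

* **trajectory tables** — tidy I/O (`read_trajectories()`,
  `write_trajectories()`) for plain-text paths (`traj_id`, `point_idx`,
  `x_mm`, `y_mm`), rigid placement on a source circle (`translate_rotate()`);
* **exact geometry** — closed-form clipping of polylines against disks
  (`segment_disk_overlap()`), splitting into boundary-to-boundary **entry
  events** with re-entries counted anew (`clip_to_entry_events()`),
  equal-area annuli (`equal_area_annuli()`);
* **the experiment** — ⟨L⟩ per entry event versus π R / 2 across a grid of
  inner radii R and source gaps d, in replay mode on recorded paths
  (`mean_path_length()`, `ip_sweep()`) or with synthetic walkers in a fused
  Monte Carlo kernel that handles millions of walkers per cell
  (`simulate_ip()`);
* **diagnostics** — radial trajectory-density profiles in equal-area annuli
  (`density_profile()`, `simulate_density()`), Lambertian entrance-angle
  checks (`entrance_angle_profile()`), and mean-free-path estimation from 1D
  projections of the paths (`steps_from_turns()`, `estimate_mfp()`);
* **synthetic walkers** — `generate_ensemble()` produces isotropic random
  walks with exponential, Pareto (Lévy-like) or constant step lengths,
  standing in for recorded animal paths wherever real data cannot be shipped.

Results are tibbles with `autoplot()`, `tidy()` and `glance()` methods.

## Worked example

Exponential walkers with a 50 mm mean free path, launched isotropically from
a source circle of radius R_e = 200 mm, clipped against inner disks whose gap
d = R_e − R always exceeds one mean free path:

```r
library(ipwalk)

mpl <- simulate_ip(
  R_mm = c(25, 50, 75, 100, 125), R_e_mm = 200,
  model = step_model("exponential", 50),
  n_walkers = 1e4, seed = 1
)
mpl
#> # A tibble: 5 × 9
#>    R_mm  d_mm mean_L_mm se_L_mm ip_mm ratio n_entries n_placements valid
#>   <dbl> <dbl>     <dbl>   <dbl> <dbl> <dbl>     <dbl>        <int> <lgl>
#> 1   125    75     194.    1.38  196.  0.987     16834        10000 TRUE
#> 2   100   100     156.    1.11  157.  0.996     13339        10000 TRUE
#> 3    75   125     118.    0.864 118.  0.999      9922        10000 TRUE
#> 4    50   150      78.2   0.605  78.5 0.995      6595        10000 TRUE
#> 5    25   175      39.2   0.324  39.3 0.997      3285        10000 TRUE

glance(mpl)
#> # A tibble: 1 × 4
#>   n_cells n_valid max_abs_ratio_dev total_entries
#>     <int>   <int>             <dbl>         <dbl>
#> 1       5       5            0.0131         49975
```

Each row is one virtual medium: `mean_L_mm` is the Monte Carlo mean path
length per entry event inside the disk of radius `R_mm`, `se_L_mm` its
standard error (clustered by walker), `ip_mm` the invariance prediction
π R / 2, and `ratio` their quotient. At this quick size (10⁴ walkers per
cell) every ratio is within a few Monte Carlo standard errors of 1 — the IP
holds for exponential steps even in an open system; the sub-percent agreement
is resolved at full fidelity (below). Swap in
`step_model("pareto", 50, pareto_mu = 2.5)` and the ratios fall several
standard errors short of 1 at radii beyond the mean free path: heavy-tailed
walkers break the invariance.

`autoplot(mpl)` draws ratio versus R with 3-SE bars;
`simulate_density(R_e_mm = 200, n_walkers = 1e4, seed = 1)` profiles the
walker density whose constancy underwrites the IP. The methods vignette
(`vignettes/invariance-property.Rmd`) walks through the model, the estimator
design, and every numerical choice.

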