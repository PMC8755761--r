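# shipquant

Quantification toolkit for quench-based receptor-internalization (SHIP:
specific hybridization internalization probe) assays, with a ground-truth
forward simulator.

## The problem

In the SHIP assay a ligand (e.g. an anti-IgM surrogate antigen engaging
the B-cell receptor) carries a fluorophore-labelled ssDNA probe; adding
the complementary quencher oligo abolishes, within seconds, the
fluorescence of probe still exposed on the cell surface. What survives is
the internalized pool. Quantifying the assay means: turning per-cell
fluorescence into internalization kinetics, measuring how well the
internalized signal colocalizes with endosomal markers, detecting and
sizing the vesicles that carry it, tracking them in live imaging, and
testing effects at the replicate level. Published analyses of this assay
were assembled from FlowJo, Fiji plugins and spreadsheets; `shipquant`
implements that quantification layer as one tested, reproducible R
package — for microscopists and cytometrists who want the numbers without
the tool chain.

Because assay microscopy data are rarely deposited, the package ships a
forward simulator (`simulate_flow_timecourse()`, `simulate_cell_image()`,
`simulate_timelapse()`) that generates flow tables, two-channel cell
images and timelapses from known kinetics, quenching, optics and noise —
with full ground truth attached — so every estimator is validated by
recovery, not by eye.

## The statistics at the core

Per timepoint, with group means `F` (background `F_bg`):

* quench readout:
  `% surface = 100 − (F_Q − F_bg) / (F_noQ − F_bg) × 100`
* time-zero readout (surface stains, on-ice control defines 100 %):
  `% surface = (F_x − F_bg) / (F_0 − F_bg) × 100`

Colocalization is thresholded Mander's `tM1`/`tM2` with Costes automatic
thresholds and a 90° rotation null; vesicle sizing is a Gaussian fit to a
line profile with apparent diameter `FWHM = 2√(2 ln 2)·σ`; tracking is
mutual-nearest-neighbour linking with diffusion from the MSD slope
(`MSD(τ) = 4Dτ`); significance is a paired t-test on replicate means.

## Worked example

Simulate the default flow timecourse (5000 cells/group, quench efficiency
0.98) and recover the internalization curve:

```r
library(shipquant)
sim   <- simulate_flow_timecourse(n_cells = 5000, seed = 1)
curve <- summarize_flow_table(sim$table)
curve
#>   replicate timepoint_min percent_surface percent_internalized n_cells flag
#> 1         1             0           97.98                2.018   10000   ok
#> 2         1             5           89.08               10.921   10000   ok
#> 3         1            15           65.95               34.051   10000   ok
#> 4         1            30           42.51               57.494   10000   ok
#> 5         1            45           28.04               71.965   10000   ok
```

The simulated truth for the same run (`sim$truth$per_timepoint`) puts the
internalized signal share at 9.1 % (5 min), 33.0 % (15 min), 56.3 %
(30 min), 71.1 % (45 min): the quench statistic lands within 2 points of
truth everywhere. The ~+1.8-point gap at 5 min is the expected residue of
a 98 %-efficient quencher (2 % of the surface pool is read as
internalized), not estimator error.

One simulated quenched cell, colocalization against the vesicle-marker
channel (45 % of vesicles truly marker-positive):

```r
cellsim <- simulate_cell_image(quenched = TRUE, coloc_fraction = 0.45,
                               seed = 2026)
mask <- cell_disc_mask(cell_geometry(), acquisition_grid())
coloc_pipeline(cellsim$stack, cell_masks = mask)
#>   cell_id   tM1   tM2  T1  T2 null_tM1 null_tM2
#> 1       1 0.513 0.545 105 104    0.246    0.174
```

`tM1` is the fraction of antigen signal in marker-positive pixels (here
0.51 for a true fraction of 0.45 in this single cell; the mean over 30
cells lands on the truth), and the rotation null (0.25) is the
chance-overlap floor for the same intensities.

There is also a thin CLI:

```sh
inst/cli/ship-quant simulate flow --seed 1 --out out/
inst/cli/ship-quant flow --table out/flow_cells.csv --mode quench --out out/curve.csv
inst/cli/ship-quant run-demo --seed 1 --out demo/
```

Identical config + seed reproduce bit-identical CSVs.

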