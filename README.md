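# qdmi3d — 3D quantitative DNA methylation imaging

Demethylating drugs (DNA methyltransferase inhibitors such as 5-azacytidine
and zebularine) strip 5-methylcytosine (MeC) from the genome with spatial
structure: loss starts at the nuclear periphery and in DAPI-dim euchromatin
and spreads inward with dose. `qdmi3d` quantifies this process cell by cell
from two-channel 3D confocal stacks (anti-MeC immunofluorescence + DAPI),
for people studying epigenetic drug response and chromatin reorganization at
single-cell resolution.

Per nucleus, the pipeline measures:

* **MeC load** — mean in-nucleus MeC intensity *I*<sub>MeC</sub>, normalized
  to the untreated control population.
* **MeC/DAPI codistribution** — the joint 2D intensity histogram, scored
  against the condition's pooled reference by Kullback–Leibler divergence
  *D*(nucleus ∥ reference) = Σ *p* ln(*p*/*q*) and bucketed into the
  similarity categories similar [0, 0.5), likely similar [0.5, 2),
  unlikely similar [2, 4.5), dissimilar [4.5, ∞).
* **LIM/LID topology** — low-intensity MeC / low-intensity DAPI voxel sites
  (intensities strictly inside (t<sub>bcg</sub>, t<sub>Q</sub>)), profiled
  over anisotropic erosion shells (1.32 × 1.3 × 0.25 µm per iteration →
  (11, 11, 1) voxels at the 0.116 × 0.116 × 0.2305 µm voxel size). The
  statistic LIM<sub>0.5</sub> is the cumulative site fraction at
  *V*/*V*<sub>tot</sub> = 0.5 — the fraction of sites in the peripheral half
  of the nuclear volume.

Population statistics include pairwise two-sample Kolmogorov–Smirnov tests
with Bonferroni correction (β = α/n) and Pearson correlation of normalized
*I*<sub>MeC</sub> against MethyLight percent-of-methylated-reference (PMR)
values for repeat classes (Alu, Sat2, Satα); a Huh-7 / 5-azacytidine PMR
dose-response table ships as a fixture. A calibrated synthetic two-channel
nucleus generator with voxel-level ground truth makes the whole pipeline
testable end to end without external data.

## Worked example

Simulate a three-dose series (5 nuclei per dose), run the full pipeline —
segmentation, codistribution phenotyping, shell topology, dose statistics —
and correlate the packaged MethyLight table:

```r
library(qdmi3d)

run <- run_pipeline(doses = c(0, 0.5, 1), n_nuclei_per_dose = 5L,
                    spec = field_spec(seed = 42L),
                    config = pipeline_config(), seed = 42L)
print(run$table[, c("dose", "n_nuclei", "norm_mean_mec", "pooled_similar",
                    "lim_half_fraction", "lid_half_fraction")], digits = 3)
#>   dose n_nuclei norm_mean_mec pooled_similar lim_half_fraction lid_half_fraction
#> 1  0.0        5         1.000              1             0.811             0.818
#> 2  0.5        5         0.867              1             0.634             0.794
#> 3  1.0        5         0.617              1             0.194             0.793

correlate_imaging_vs_pmr(methylight_table())
#>   class n     r r_rounded
#> 1   alu 6 0.959      0.96
#> 2  sat2 6 0.897      0.90
#> 3  sata 6 0.853      0.85
```

Reading the dose table: the untreated row is the normalization anchor
(`norm_mean_mec` exactly 1); mean MeC load falls with dose while every
population stays homogeneous (`pooled_similar` = 1, i.e. no cell crosses the
KL ≥ 4.5 dissimilarity boundary — drug response is uniform across cells).
`lim_half_fraction` starts at 0.81 — in untreated nuclei about 80% of
low-MeC sites sit in the peripheral half of the nuclear volume — and falls
toward the 0.5 diagonal and below as hypomethylation spreads into the
interior. The DAPI analogue (`lid_half_fraction`) drops early and then
plateaus: chromatin reorganization saturates at low dose. The correlation
table gives Pearson R between normalized imaging MeC and normalized PMR per
repeat class over the control-through-10 µM rows, at full precision and
rounded half-up to the 2-decimal report convention.

`run$ks` holds the pairwise KS matrix: with α = 0.05 over the dose levels,
the untreated and top-dose populations differ significantly at β = α/n.

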