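# dlossr

Per-atom quantification of site-specific radiation damage in macromolecular
crystallography dose series.

## The problem

When successive diffraction datasets are collected from the same protein
crystal, absorbed X-ray dose (measured in MGy) causes localized, reproducible
chemical changes — disulfide cleavage, glutamate/aspartate decarboxylation —
long before global diffraction decay sets in. These events appear as negative
peaks in *F*obs(*n*) − *F*obs(1) difference density maps: Fourier syntheses
whose coefficients are the amplitude differences between dataset *n* and the
first dataset, phased with the fixed first-dataset calculated phases
φcalc(1).

`dlossr` turns those maps into an objective per-atom metric and a set of
comparative statistics:

- **D_loss(atom, n)** — the maximum density-loss value (negated minimum of
  the difference map) over all grid points within a vicinity radius
  (default 1.5 Å, periodic minimum-image) of the atom. Large positive
  values flag atoms losing electron density with dose.
- **Cα normalization** — `(D_loss − mean_Cα) / mean_Cα`, expressing loss
  relative to the radiation-insensitive Cα backbone set at the same dose.
- **Atom-type ranking** — for each atom type *A* (e.g. all Glu OE1
  oxygens) the mean raw D_loss is ranked per dataset (rank 0 = most
  damaged); across datasets the products of per-dataset ranks
  *R*(A,2) × … × *R*(A,n) are ranked again, giving a scale-free ordering
  that can be compared between independent damage series.
- **Damage signatures** — the distribution of Cα-normalized D_loss over
  all heavy atoms of a residue type, compared between residue pairs
  (Tyr–Phe, Asp–Asn, Leu–Ile, …) with the two-sample Kolmogorov–Smirnov
  statistic and visualized with Gaussian kernel density estimates.
- **Structural context** — hydrogen bonds from Tyr OH to Glu/Asp
  carboxylate oxygens (< 4 Å), Shrake–Rupley solvent accessibility (with
  optional removal of the carboxylate CO2 moieties), distance to
  disulfide bonds, the packing-density-normalized *Bdamage* B-factor
  metric, and a two-sample Hotelling T² comparison of hydrogen-bonded
  versus non-bonded Tyr subsets.

Everything runs end-to-end on synthetic damage series with known injected
damage: `make_toy_structure()` builds an idealized P1 model containing
every residue type the analysis needs (including engineered Tyr–Glu
hydrogen bonds and disulfides), and `make_damage_series()` simulates dose
series by occupancy loss and/or rigid aromatic-ring displacement, with
calibrated amplitude noise and full ground truth.

## Worked example

Simulate a decarboxylation series (both Glu carboxylate oxygens lose 30%
occupancy per dose step, 2% amplitude noise), run the analysis, and rank
the side-chain oxygens:

```r
library(dlossr)
s   <- make_toy_structure(2, seed = 1)
sc  <- damage_scenario(
         target_spec = data.frame(resname = "GLU", atom = c("OE1", "OE2"),
                                  loss_per_dose = 0.3),
         noise_sigma = 0.02, seed = 1)
sim <- make_damage_series(s, sc)
tab <- run_series(sim$series)          # D_loss per atom per dose
rk  <- rank_atom_types(tab, oxygen_rank_keys())
rk[order(rk$rank_overall),
   c("resname", "atom", "mean_ds2", "rank_ds2", "rank_product", "rank_overall")]
```

```
  resname atom mean_ds2 rank_ds2 rank_product rank_overall
2     GLU  OE2  0.16302        0            0            0
1     GLU  OE1  0.15889        1            1            1
7     SER   OG  0.01045        2            8            2
4     ASP  OD2  0.00943        3           27            3
9     TYR   OH  0.00730        4           64            4
...
```

The injected damage dominates: the two Glu carboxylate oxygens take
overall ranks 0 and 1 with mean D_loss an order of magnitude above every
control oxygen, whose ordering among themselves is noise. The strongest
single-atom signals sit on the damaged carboxylate group:

```r
head(tab[order(-tab$dloss_sigma),
         c("resname", "atom", "dataset", "dose_MGy", "dloss_sigma")])
#>     resname atom dataset dose_MGy dloss_sigma
#> 300     GLU   CD     ds4        8        46.1
#> 301     GLU  OE1     ds4        8        46.1
```

(the CD carbon ties with its bonded oxygens because their 1.5 Å vicinity
spheres cover the same negative peak). A signature comparison confirms
that the targeted Glu is distinguishable from its amide control while the
untouched Tyr–Phe pair is not:

```r
compare_residue_pairs(tab, pairs = list(c("TYR","PHE"), c("GLU","GLN")))
#>   res_a res_b dataset statistic  p_value n_a n_b
#>     TYR   PHE     ds4     0.278 0.307    36  16
#>     GLU   GLN     ds4     0.750 0.000915 12  12
```

A thin command-line wrapper is installed at `inst/exec/dloss-pipeline`
(subcommands `simulate`, `dloss`, `rank`, `signatures`, `context`, `all`).

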