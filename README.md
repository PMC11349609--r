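# specdelim

Integrative species delimitation for multi-locus sequence data and linear
morphometrics, built for the kind of question that recurs in small-mammal
systematics: a nominal species spans several allopatric populations — do the
molecular distances, tree structure, haplotype sharing and skull
measurements support splitting it?

The package implements, as tested reusable functions, the analysis chain
such studies run:

* **K2P distances.** Pairwise Kimura two-parameter distances with pairwise
  deletion of non-ACGT sites, for all substitutions
  (d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)) or transversions only
  (d = −½ ln(1 − 2Q), the 12S rRNA convention), plus clade-level
  mean/min/max summaries.
* **Divergence dating.** A linear pairwise clock t = d / r (default
  r = 2.1 % per My, the dasyurid cytochrome-b calibration) and the 12S
  transversion regression t = (d% − 0.0584)/0.0854.
* **Tree-based delimitation.** Neighbor-joining from any distance matrix,
  outgroup rooting on the separating bipartition edge, reciprocal-monophyly
  checks, the intra/inter distance ratio, leave-one-out probability of
  correct identification with a normal-approximation CI, and Rosenberg's
  probability of monophyly under random coalescence
  (R(i,j) = [C(i,2) R(i−1,j) + C(j,2) R(i,j−1)] / C(i+j,2); both the
  reciprocal and single-clade variants).
* **Haplotype networks.** Global masking of columns with gaps/unknowns,
  haplotype collapsing with per-population frequencies, and an
  epsilon-relaxed minimum-spanning network (epsilon = 0 is the union of all
  MSTs, so tied alternative connections appear as reticulations) with an
  optional step limit.
* **Morphometrics.** The standard craniodental pipeline: 20 % variable /
  15 % individual missingness filters, |r| > 0.90 correlation pruning,
  chained-equations predictive-mean-matching imputation, a
  Bartlett-gated ANOVA + Tukey / Kruskal–Wallis univariate procedure,
  correlation PCA, UPGMA clustering, Mosimann log-shape ratios
  (shape = log(x / geometric mean)), geometric-mean size ANOVA, and
  leave-one-out k-NN classification.
* **Synthetic data.** Seeded generators for alignments evolved under a K2P
  process on a species tree (expected pairwise distance = rate × divergence
  time) and for morphometric tables with multiplicative group size factors,
  so every stage is exercisable without external data.

## Worked example

The `analysis/` directory holds numbered drivers that run the whole study
on a synthetic two-clade, four-population system (deep split 3.9 My,
shallow splits 1.0 My, 2.1 %/My, 2 kb):

```sh
Rscript analysis/01_simulate.R        # writes results/fixtures/
Rscript analysis/02_distances_dating.R
Rscript analysis/03_delimitation.R
Rscript analysis/04_network.R
Rscript analysis/05_morphometrics.R
```

Stage 2 prints

```
between-clade mean K2P: 8.47% -> 4.03 My at 2.1%/My
                 quantity  time_my
1       mean (8.09/8.23%) 3.885714
2       range low (6.05%) 2.880952
3     range high (10.74%) 5.114286
4 12S transversion 0.165% 1.248244
```

— the simulated clades land near the generating 8.2 % / 3.9 My, and the
clock applied to published clade-level distances of 8.09–8.23 % (range
6.05–10.74 %) gives ~3.9 My (2.88–5.11). Stage 3 reports the delimitation
table:

```
  group_a group_b mono_reciprocal intra_inter prob_correct         p_ab
1    west    east            TRUE   0.1709185            1 1.073336e-10
2      WA      NT            TRUE   0.3532091            1 1.036001e-05
```

(reciprocally monophyletic clades, within-clade diversity ~17 % of the
between-clade distance, every individual identifiable, and random
coalescence firmly rejected), while a label-shuffled control gives
`mono_reciprocal = FALSE, p_ab = NA`. Stage 5 prints

```
pruned: BL_clone1
PC1 raw: 75.9%; PC1 shape: 25.6%
size ANOVA p = 2.54e-08
k-NN (k = 7): raw 79.3%, size-corrected 51.7%
```

— only the built-in clone variable is pruned, PC1 of the raw data is a size
axis, the small-bodied group separates on geometric-mean size, and
classification accuracy drops once isometric size is removed, exactly the
qualitative pattern such datasets show.

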