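# kdacselect

Zn-dependent lysine deacetylases (KDACs, also called HDACs; EC 3.5.1.98)
remove the acetyl group from acetyllysine (K<sup>ac</sup>) in proteins and
peptides. Which substrates an individual KDAC prefers is encoded less in
bulk binding affinity than in a handful of short-range interactions between
enzyme surface residues and the substrate residues flanking the
acetyllysine (the −2…+2 register, with K<sup>ac</sup> at 0). `kdacselect`
is an R package for mapping those selectivity surfaces. It is aimed at
structural bioinformaticians and enzymologists who have (or simulate) MD
trajectories of enzyme–acetylpeptide complexes alongside peptide-panel
activity data.

## What it computes

**Interaction fingerprints from trajectories** (multi-model PDB, one MODEL
per frame). Per frame, enzyme residue, and substrate position the package
detects:

- *total contact*: any atom of the enzyme residue within ≤ 0.30 nm of any
  atom of the substrate residue;
- *ionic interaction*: a cationic-group hydrogen (Arg guanidinium, Lys
  ammonium, protonated His) within ≤ 0.25 nm of a carboxylate oxygen;
- *hydrogen bonds* (side chain–side chain, and enzyme side chain to
  substrate backbone): donor–acceptor heavy atoms ≤ 0.35 nm apart with
  H–D–A angle ≤ 30°.

Per-frame occurrences are converted to percent time, averaged over
replicate simulations, and truncated to integer percent (lower limit 1%).
Two exclusion rules apply: interactions observed only while the complex is
*not* in a catalytically relevant conformation (Zn²⁺-to-acetyl-carbonyl
distance exceeding 0.32 nm) are discarded, as are low-frequency
interactions averaging < 1% across the peptides chemically capable of
forming them.

**Cluster selectivity statistics.** Panel peptides sharing one or two
residues at the +1 or +2 position form substrate clusters. Stage 1 tests
each (cluster × enzyme residue × interaction type) with a pooled two-sample
t-test of interaction frequency, Bonferroni-corrected over the whole family
(significance p ≤ 0.01). Stage 2 tests stage-1 survivors for an activity
difference with a two-sided Mann–Whitney U (exact for small groups;
p ≤ 0.05), a ranked test that limits the influence of the other substrate
position. Frame-level co-occurrence of two interactions is tested with a
log-space two-sided Fisher's exact test (finite p down to arbitrarily
extreme associations), and interaction–activity relationships with
Pearson's r.

**Activity panels and kinetics.** Endpoint specific activities (s⁻¹) are
normalized to a reference peptide (FRK<sup>ac</sup>WR ≡ 1), compared
pairwise with Bonferroni-corrected pooled t-tests, and validated against
sequence predicates with Fisher's exact test (below-detection peptides
count as not deacetylated). Timecourses yield initial rates; v₀ = k_cat·E·[S]/(K_M + [S])
is fit by weighted nonlinear least squares to give K_M, k_cat and
k_cat/K_M (M⁻¹s⁻¹) with standard errors.

**Synthetic data.** Seeded generators produce toy trajectories with planted
two-state (Markov) interaction episodes and catalytic-pose excursions,
activity panels with planted multiplicative cluster effects, and
Michaelis–Menten timecourses — so every stage of the pipeline is testable
offline with known ground truth.

## Worked example

Validate the aromatic-+1 preference of KDAC6 on the packaged 30-peptide
panel (Fisher's exact test of Y/W/F at +1 vs detectable activity):

```r
library(kdacselect)

t2 <- read_activity_table(
  system.file("extdata", "table2_kdac6.csv", package = "kdacselect"),
  enzyme = "KDAC6", detection_limit = 0.0013)
aromatic_plus1 <- function(p) residue_at(p, 1) %in% c("Y", "W", "F")
res <- residue_presence_fisher(t2, aromatic_plus1)
res$table
#>          detectable
#> predicate yes no
#>       yes  10  0
#>       no   10 10
round(res$p_value, 3)
#> [1] 0.011
```

All ten panel peptides with an aromatic residue at +1 were deacetylated,
half of the rest were not; the association is significant at p = 0.011.

Fit Michaelis–Menten kinetics to a simulated noisy timecourse at the
reference peptide's constants (K_M = 28 µM, k_cat = 0.23 s⁻¹, 100 nM
enzyme, 5% noise):

```r
tc  <- generate_timecourses(K_M = 28, k_cat = 0.23, enzyme_conc = 100,
                            noise_sd = 0.05, seed = 1)
fit <- fit_michaelis_menten(initial_rates(tc), enzyme_conc = 100)
fit
#> <kdac_kinetic_fit> K_M = 25.4 +/- 2 uM, k_cat = 0.218 +/- 0.0098 1/s, kcat/KM = 8.57e+03 1/(M s)
```

The fit recovers the planted parameters within error; the catalytic
efficiency ~8.6 × 10³ M⁻¹s⁻¹ is the headline number for comparing
substrates. For the full trajectory-to-report path see `run_pipeline()`
and the methods vignette (`vignettes/selectivity-mapping.Rmd`).

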