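---
title: "Mapping KDAC substrate selectivity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping KDAC substrate selectivity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Zn-dependent lysine deacetylases (KDACs) act on acetyllysine in a sequence
context, and individual family members prefer different flanking residues
at the positions immediately after the acetyllysine (+1, +2). The
mechanistic question is *which* enzyme residues produce those preferences.
`kdacselect` answers it by combining two data streams: per-frame geometric
interaction fingerprints from MD trajectories of enzyme–acetylpeptide
complexes, and deacetylation activities of the corresponding peptide
panel. An interaction "drives selectivity" when (i) a cluster of peptides
sharing a residue at one position interacts significantly more (or less)
with a particular enzyme residue than the rest of the panel, and (ii) the
same cluster shows significantly different activity.

# Interaction model

Within each frame, four interaction types are detected between an enzyme
residue and a substrate position:

| type | definition | cutoff |
|---|---|---|
| contact | min any-atom/any-atom distance | ≤ 0.30 nm |
| ionic | cationic-group H to carboxylate O | ≤ 0.25 nm |
| H-bond (side chain) | donor–acceptor heavy atoms, either donation direction | ≤ 0.35 nm, H–D–A ≤ 30° |
| H-bond (to backbone) | enzyme side chain vs substrate backbone C=O / N–H | same |

All cutoffs sit in `interaction_criteria()` and are configurable; the
defaults are the conventional MD-analysis values. Boundary comparisons are
inclusive (`<=`). Two interpretation choices were genuinely open and are
resolved as follows, both configurable:

* **H-bond angle convention.** "Appropriate bond angle" is implemented as
  the hydrogen–donor–acceptor angle ≤ 30°, the convention of the standard
  GROMACS analysis tooling. Other toolchains use donor–H–acceptor angles
  near linearity; if you need that convention, the angle test is the only
  code that would change.
* **The catalytic reference atom.** Catalytic relevance is defined by the
  distance from the Zn²⁺ ion to the *acetyl carbonyl oxygen* of the
  acetyllysine (≤ 0.32 nm, with the boundary counting as catalytic,
  compared on squared distances so the boundary is exact in floating
  point). The oxygen rather than the carbon is used because the oxygen is
  the Zn-coordinating atom in the accepted deacetylation mechanism. The
  atom name is a parameter of `load_trajectory()`.

Charge-group membership follows standard protonation at assay pH:
Arg/Lys cationic, Asp/Glu anionic, His neutral unless
`his_protonated = TRUE`. Panel peptides are N-acetylated and C-amidated,
so termini are uncharged and play no role in the ionic detector.

# From frames to frequency tables

Percent time is computed per replicate over **all** frames (catalytic or
not), averaged across replicates (five by default), then truncated toward
zero to an integer percent. Truncation realizes the 1% reporting floor:
keys flooring to 0 are dropped. Catalytic relevance enters only through an
all-or-nothing exclusion — an interaction observed exclusively in
non-catalytic frames in *every* replicate is excluded — rather than
through re-normalization of the denominator, because the procedure being
reproduced describes exclusion, not conditional frequencies.

The low-frequency filter removes keys averaging < 1% across the peptides
*capable* of the interaction (a charged +2 residue for a +2 ionic key, a
polar side chain for an H-bond key, and so on); incapable peptides stay
out of the denominator, so a single capable peptide at 5% keeps its key.
Filter order was an open question; the order used is: catalytic exclusion,
truncation, low-frequency filter, with the filter averaging the
*pre-truncation* replicate means. The filter must see sub-1% values —
otherwise a panel of ten capable peptides at 0.5% each would have nothing
left to exclude — which forces the pre-truncation choice.

# Statistics

* **Stage 1 (interaction).** For every substrate cluster (peptides sharing
  one or two residues of the `{A, E, R, W, Y}` alphabet at +1 or +2) and
  every retained (enzyme residue, interaction type) at that position: a
  pooled-variance two-sided t-test of member vs non-member frequencies.
  Pooled rather than Welch, consistent with the equal-variance assumption
  used for the activity t-tests. Peptides lacking the key count as 0%.
  Bonferroni correction uses the family of *all* tests run in the
  invocation — clusters × residues × types — since no other family
  definition is canonical; the family size is reported alongside the
  results. Significance: adjusted p ≤ 0.01. Degenerate inputs are handled
  explicitly: zero pooled variance with equal means gives p = 1, with
  unequal means p collapses to the machine floor.
* **Stage 2 (activity).** Mann–Whitney U, exact via the null U
  distribution when the smaller group has ≤ 8 observations and no ties,
  otherwise normal approximation with tie and continuity correction;
  significance p ≤ 0.05. A rank test is used so that the other substrate
  position's effect cannot dominate through magnitudes. Direction
  (enhanced/inhibited) comes from the median difference.
* **Co-occurrence.** Two-sided Fisher's exact test on the 2×2 frame-count
  table, summing hypergeometric log-probabilities ≤ the observed table's
  (the same convention as `fisher.test`, to which it is cross-checked in
  the test suite). Log-space evaluation keeps `log10_p` finite at
  arbitrarily extreme associations (trajectory-scale tables can reach
  p ~ 10⁻¹³¹ and beyond); the threshold default is 10⁻¹⁰.
* **Correlations.** Pearson's r with the two-sided t-distribution p
  (n − 2 df), threshold 0.01, with least-squares slope/intercept reported.

On the activity side, normalization divides by the reference peptide's
mean (FRK^ac^WR by default) with ratio error propagation; a peptide
reporting *at* the panel's detection limit counts as detectable (the limit
is defined as the smallest *reliable* activity), and below-limit peptides
are censored — excluded from normalization and correlations, "not
deacetylated" in Fisher validations.

# Kinetics

Initial rates are unforced least-squares slopes of product vs time per
concentration (≥ 3 timepoints). A warning fires if a timecourse flattens
(significant negative quadratic curvature improving AIC by > 10),
indicating substrate depletion. The Michaelis–Menten fit
v₀ = k_cat·E·[S]/(K_M + [S]) uses Levenberg–Marquardt least squares
initialized at K_M = median [S], k_cat = max v₀/E. Because endpoint-style
assay error scales with the rate, the default weighting is relative
(1/v₀²); with it, ±1.96·SE intervals achieve near-nominal coverage, which
the acceptance suite verifies over 500 simulated fits at 5% noise. When
the K_M gradient is numerically degenerate (all [S] ≫ K_M) the fit falls
back to direct optimization on log parameters, whose near-singular
curvature yields the huge standard errors that trigger the `reliable =
FALSE` flag (also raised when K_M leaves the sampled range by more than
5× or its relative SE exceeds 0.5). Catalytic efficiency converts units
explicitly: K_M in µM and k_cat in s⁻¹ give k_cat/(K_M·10⁻⁶) M⁻¹s⁻¹. The
assay description we follow contains an internal unit inconsistency
(substrate concentrations quoted in nM where the fitted K_M values are
tens to hundreds of µM); the synthetic kinetics generator sides with the
µM scale and spans 0.1×–10× K_M as a ten-point dilution series, the usual
design for plate-based steady-state kinetics.

# What the synthetic generator does and does not emulate

`generate_trajectory()` builds a deliberately schematic complex: substrate
positions threaded 1.5 nm apart past a fixed Zn site, enzyme anchors on a
grid, and one mobile probe group per planted interaction whose distance
(and, for H-bonds, angle) geometry satisfies the corresponding detector in
"on" frames and fails it in "off" frames. Occurrence follows a two-state
Markov chain rather than i.i.d. draws so frame-to-frame autocorrelation is
present, as in real trajectories; recovery tolerances therefore use the
effective sample size n·(1−ρ)/(1+ρ) with ρ = 1 − p_on − p_off. The
catalytic pose follows its own chain (90% stationary catalytic fraction by
default, matching a productively-bound complex). Physically coupled
detections are reproduced faithfully — a salt bridge is simultaneously a
contact and a side-chain hydrogen bond, and planted H-bond geometry keeps
the pair in contact — so tests assert on the planted channel, not on
exclusive detection.

What this validates: the geometric detectors, the frequency/exclusion
arithmetic, and the statistical machinery, against exact ground truth.
What it does not validate: force-field realism, solvent effects,
conformational heterogeneity of real side chains, or correlated motions
between interactions — passing tests say nothing about whether a *real*
trajectory's interactions are correctly sampled, only that whatever is in
the coordinates is correctly measured and summarized. Published
trajectory-scale numbers (occupancy fractions, co-occurrence p-values,
interaction–activity r²) require the original ensembles and are therefore
checked as statistical *properties* at synthetic scale instead.

# Problem sizes in the test suite

The acceptance suite runs the detector-vs-oracle comparison on 1000 random
frames, planted-frequency recovery at full study scale (5 replicates ×
2500 frames), family-wise-error control over 200 null panels of 16
peptides, Michaelis–Menten coverage over 500 noisy fits, and pipeline
determinism on a reduced bundle; unit tests use smaller instances of the
same constructions. These sizes were chosen to give the statistical
assertions comfortable margins (3σ bands, binomial slack on coverage and
FWER) while keeping the suite quick to run routinely.

# Known limitations

* Hydrogen placement is taken from the input topology; trajectories
  without explicit hydrogens cannot use the ionic or H-bond detectors.
* Donor/acceptor dictionaries cover the 20 standard residues plus
  acetyllysine with standard PDB v3 atom names; exotic protonation states
  beyond the His flag need a code extension.
* The Bonferroni family is the whole invocation; re-running with a subset
  of clusters changes adjusted p-values, as it must.
* The linear interaction–activity correlation is a deliberate
  oversimplification, useful for ranking residues rather than as a
  quantitative activity model.
* Multi-model PDB is the only trajectory format; convert compressed MD
  formats externally.
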