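---
title: "Detecting condition-specific binding site motif variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting condition-specific binding site motif variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A transcription factor (TF) binds a family of similar sites across a genome.
At many motif positions, different promoters carry different nucleotides —
binding site motif variants (BSMVs). Two mechanisms can make such variants
matter for regulation. Under a pure affinity model, one variant is simply a
stronger site, and the regulatory difference between variants is a matter of
degree that keeps the same sign in every condition. Under a cofactor
(allosteric) model, the variant changes the conformation of the bound TF and
its interactions with condition-specific cofactors, so the regulatory
difference between variants can change sign across conditions — at the
extreme, the relative expression ranking of the variants' target genes is
completely reversed between environments. This package detects variant
positions with condition-dependent effects from genome-wide expression and
binding-site annotation data, and then asks which of them bear the signature
of the cofactor model.

## Inputs and gene selection

Three tables drive the analysis: a normalized gene-by-condition expression
matrix (log-like scale; the platform is irrelevant because everything
downstream is rank-based), a table of annotated binding sites (TF, target
gene, site sequence, posterior probability), and a condition metadata table
assigning each condition to an experiment-type class (sporulation, MMS
exposure, desiccation, ...). GO annotations and aligned motif columns are
optional extras for the characterization stages.

Sites are split by posterior probability: **primary** sites at posterior ≥
0.7 and **secondary** sites strictly between 0.2 and 0.7; anything at or
below 0.2 is kept in the table but marked discard so that counts remain
auditable. The main analysis restricts to target genes with a **single
primary binding site**, counted genome-wide across all annotated TFs — a
proxy for simple regulatory control that makes the variant at the one site
the dominant regulatory input. The boundary case posterior = 0.7 is
classified primary, and 0.2 exactly is discarded (the secondary class is the
open interval). A `scope = "same_tf"` switch preserves the alternative
reading in which only the focal TF's sites are counted.

For one TF and one 1-based motif position, the eligible genes are
partitioned by the nucleotide their site carries at that position. A
position is testable when at least two nucleotide groups have at least two
genes each; smaller groups are reported but excluded from the statistic
(an alternative would be to let singleton groups contribute between-group
distances — we exclude them so that every group contributes both within- and
between-group information symmetrically).

## The VDRE statistic

Each gene's expression vector is replaced by its ranks across conditions
(ties averaged), which removes gene-specific baselines and measurement
scale: any strictly monotone transformation of one gene's measurements
leaves its rank profile unchanged. The distance between two genes is the
Euclidean distance between their rank profiles — the variant distance of
ranked experiments (VDRE).

For a testable position, with $D_W$ the set of pairwise distances between
genes sharing a nucleotide (over all groups simultaneously, $N$ pairs) and
$D_B$ the distances between genes in different groups ($M$ pairs), the
functionality score is

$$F \;=\; \frac{1}{N}\sum D_W \;-\; \frac{1}{M}\sum D_B .$$

Functional positions drive $F$ negative: genes sharing a variant behave more
alike across conditions than genes with different variants. Significance
comes from permuting the gene-to-group assignment (group sizes fixed; 1000
permutations by default) with the one-sided, bias-avoiding estimator
$p = (1 + \#\{F_{perm} \le F_{obs}\})/(1 + n)$, which can never be exactly
zero. Across a scan of all TF × position pairs, q-values are estimated with
the Storey procedure using a fixed $\lambda = 0.5$:
$\hat\pi_0 = \min(1, \#\{p > \lambda\}/(m(1-\lambda)))$ and
$q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j$. The fixed-$\lambda$
variant is the simplest published estimator and is exposed as a tunable
parameter; no spline smoothing is applied.

With a set of discoveries in hand, the expected number of true positives is
`n_discoveries * (1 - FDR)` — e.g. 17 discoveries at FDR 0.3 are expected to
contain about 12 true effects.

## Condition specificity

A functional BSMV should not perturb conditions at random: whatever cofactor
mediates the difference is present in some classes of experiments and absent
in others. For each pair of variants at a significant position, conditions
are ordered by the standardized difference in the groups' mean expression,
$(\bar{x}_a(c) - \bar{x}_b(c))/s_{pooled}(c)$, where $s_{pooled}$ pools the
two target sets' values within condition $c$. We divide by the pooled
standard deviation rather than the variance so that the sorted statistic is
unitless and comparable across conditions; a `normalize = "var"` switch
preserves the literal alternative. Ties are broken by condition id so the
ordering is deterministic; a condition with zero pooled spread gets
statistic 0 with a warning.

Given experiment ranks $1..E$ along that ordering and the experiment-type
labels, the clustering score is

$$S \;=\; C_Q - C_W,$$

where $C_W$ is the mean $|rank_i - rank_j|$ over the $A$ same-type pairs and
$C_Q$ the mean over the $B$ different-type pairs
($A \cdot C_W + B \cdot C_Q$ always equals the total pairwise rank
distance, a conservation law the tests exploit). Larger $S$ means
experiments of a type bunch together along the variant-driven ordering.
Significance is right-tailed, from permuting the type labels over conditions
(10,000 permutations by default) with the ordering held fixed.

Two further tests separate the cofactor signature from affinity scaling:

* **Rank reversal** — the Spearman correlation between the two groups'
  per-condition mean rank vectors; a significant reversal is a negative
  correlation with one-sided p < 0.05. The statistic choice (the analysis
  needs only "a significant inversion") is recorded in the output.
* **Slope signs** — along the variant-driven ordering, a least-squares line
  through each group's mean rank; the pair passes when the slopes have
  opposite signs and both are individually significant (two-sided t-test on
  the regression coefficient at 0.05). At least three conditions are
  required for the slope test to be defined.

A pair "passes both" when the reversal is significant and the slopes
oppose — affinity-only variants (same-sign effects of different magnitude)
fail the reversal test by construction.

## Enrichment and confounding screens

**GO enrichment.** For each nucleotide group and each process annotated on
at least one eligible gene, the observed count of annotated genes in the
group is compared to a null built by shuffling the gene-to-group assignment
(10,000 shuffles; enrichment-only, one-sided). Shuffling assignments rather
than annotation labels is marginally equivalent and keeps each gene's
annotation structure intact. The gene universe is the focal position's
eligible targets. Raw p-values are reported without multiple-testing
correction, matching how such screens are normally read as secondary
evidence; q-values from the main scan remain the error-control instrument.

**Secondary-site co-occurrence.** An apparent BSMV effect could instead be
driven by a lower-quality site of another TF co-occurring with one variant.
For every (nucleotide group, other TF with a secondary site among the
targets), a 2×2 table of group membership × site presence is tested with
Fisher's exact test (two-sided, probability ordering, α = 0.01); any flag at
a position marks it as potentially confounded. "Coincident" means annotated
to the same target gene — no distance window is imposed because annotation
coordinates are not part of the input contract.

## Motif conservation statistics

Position information content uses the Schneider formulation with a
non-uniform genomic background: $R = H(bg) - H(pos)$ in bits, with
$0 \log 0 = 0$ and no small-sample correction. The default background is the
yeast composition $f_A = 0.307$, $f_C = f_G = 0.188$, $f_T = 0.316$. These
published frequencies sum to 0.999; the constructor renormalizes them, which
is what makes a fully conserved position carry 1.96 bits (the unnormalized
entropy would round to 1.95). Under this form the conserved-position maximum
equals the background entropy regardless of which base is conserved; a
relative-entropy form would instead give different maxima for A/T versus C/G
and is deliberately not used. Negative $R$ is reported, not clamped — the
classifier only needs the cut at 1 bit, at or below which a position is
"highly variable".

Alignment-column diversity (per site class: proportion of invariant columns
with a Wilson 95% score interval, $z = 1.959964$, and the mean number of
distinct nucleotides per column) is computed on user-supplied columns;
evolutionary rate estimation itself (phylogenies, site-rate models) is out
of scope, and externally computed rates can be summarized alongside.

## The synthetic-data generator

Every statistic is validated against simulations with planted truth.
Expression is generated as

```
expression(g, c) = baseline(g) + condition_effect(c)
                 + interaction(nucleotide(g), experiment_type(c))
                 + Gaussian(0, noise_sd)
```

Baselines are drawn once per gene and shared across conditions, so the
within-gene ranking removes them exactly — the same argument that motivates
ranking in the first place. Gaussian noise is a config choice, not a claim
about microarray error structure: rank statistics are valid under any noise
family, only power changes.

Defaults describe a deliberately small but realistic study: 24 conditions in
4 experiment-type classes, 3 nucleotide groups of 5 target genes per focal
position, baseline sd 2, condition-effect sd 1, noise sd 1, planted
interaction magnitude 3 (a strong, clearly resolvable effect three times the
noise), 10% secondary-site sprinkling, motif lengths 6–16 bp with one
variable position per TF and consensus bases elsewhere. Each TF's
interaction targets its own (rotated) pair of experiment types so that
different regulons respond to different conditions, as with real
condition-specific regulators. The `reversal` regime plants mirror-image
effects in two groups (rank correlation −1 between their effect vectors);
`affinity_scaling` plants same-sign effects of different magnitude — the
contrast the reversal test must separate. Posteriors are drawn in [0.7, 1)
for planted primary sites and (0.2, 0.7) for secondary ones.
`plant_cooccurrence()` adds confounder-TF secondary sites to one nucleotide
group at a chosen rate as the positive control for the Fisher screen.

One master seed drives everything, with per-component sub-seeds derived by
hashing the seed with a component label, so adding one component does not
perturb the streams of the others and every result is bit-reproducible.

What the simulations do not emulate: sequence-level sampling of whole sites
from PWMs (only the focal position varies), array hybridization artifacts,
correlated noise between genes, combinatorial regulation by multiple
primary inputs, and GO annotation realism beyond flat labels. Passing tests
therefore demonstrate the statistics' calibration and power under the
stated generative model, not performance on any particular real dataset.

## Numerical and testing choices

* Permutation p-values use the $+1/(n+1)$ convention everywhere; exact
  enumeration oracles in the test suite check the Monte-Carlo estimates
  within three standard errors on problems small enough to enumerate
  (≤ 8 genes, ≤ 6 conditions, 2×2 tables with total ≤ 20).
* Null calibration uses 200 simulated null positions per statistic with 500
  permutations each, and checks the rejection rate at the nominal level
  against the exact binomial 99% interval; the Fisher screen is expected to
  sit below its nominal α because the test is discrete and conservative.
* Truth recovery runs 100 replicates of the bundled reversal scenario and
  requires the planted position to clear every stage (VDRE p < 0.05,
  clustering p < 0.05, negative reversal correlation, opposite slopes,
  planted GO process at p < 0.001) in at least 95 of them. These problem
  sizes keep the whole suite under a couple of minutes while leaving the
  statistical checks well-powered.
* Pipeline outputs are TSVs with floats at 6 significant digits, so
  re-running a configuration is byte-identical; a JSON manifest records the
  seed, derived stage seeds, parameters, input digests and row counts.

## Known limitations

Only one motif position is considered at a time; positions interact in real
sites, and promoters with several primary inputs are excluded by the default
filter (an `any_primary` mode relaxes this without modeling the
combinatorics). The experiment-type labels are an input — the package does
not curate them from metadata. The reversal and slope tests are
interpretations of a qualitative signature; their thresholds (0.05 per
component) are conventional, not derived. And with permutation nulls of
1000–10,000 draws, the smallest attainable p-values are bounded by
$1/(n+1)$, which matters when screening many positions at strict FDR
levels.
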