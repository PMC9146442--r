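---
title: "Methods: comparing gut-microbiome cohorts with gutcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing gut-microbiome cohorts with gutcohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutcohort)
```

## The analysis problem

A cross-sectional microbiome cohort study produces two linked tables: a
samples × taxa count matrix from 16S amplicon sequencing, and a per-sample
clinical table (anthropometry, body composition, diet, activity, fasting
blood chemistry). The questions are comparative — does the case cohort's
taxonomic composition and diversity differ from a reference cohort, which
taxa drive the difference, which clinical variables do taxa track, and how
does the *interaction structure* among taxa (cooccurrence) differ between
cohorts. `gutcohort` implements that full chain as composable functions
over one central container, the `abundance_table`.

All analyses start from counts. Collapsing to a rank sums reads of taxa
sharing a name at that rank; taxa unassigned at the rank are discarded
there but remain available at higher ranks where they are assigned.
Relative abundances are recomputed (renormalized) after any discarding —
the alternative, carrying the original denominators, makes rows that no
longer sum to one and breaks every downstream compositional computation.

## Diversity

Alpha diversity is computed per sample: Shannon entropy (natural log by
default; the base is a visible parameter and recorded on every output,
since log2 conventions are also common), Gini–Simpson `1 - sum(p^2)` (the
dominance `sum(p^2)` is attached as an attribute rather than silently
replacing it), and Chao1 in its classic form `S_obs + F1^2/(2 F2)` with the
`S_obs + F1(F1-1)/2` fallback when no doubletons exist; the bias-corrected
variant is behind a flag. Chao1 requires integer counts — singletons are
undefined on normalized data — and the function refuses anything else.

Beta diversity uses Bray–Curtis dissimilarity,
`d(u,v) = 1 - 2 sum(min(u,v)) / (sum(u) + sum(v))`, delegated to
`vegan::vegdist`. PCoA is classical scaling: Gower double-centering of
`-d^2/2` and an eigendecomposition. Bray–Curtis matrices are generally
non-Euclidean, so negative eigenvalues appear; they are reported but
excluded both from the coordinates and from the proportion-explained
denominator, which keeps the reported proportions interpretable as shares
of representable variance.

ANOSIM ranks all `n(n-1)/2` dissimilarities once (average ranks on ties)
and contrasts mean between-group and within-group ranks:
`R = (rbar_B - rbar_W) / (M/2)`. Inference is one-sided (large `R`). When
the number of distinct label arrangements is at most 10,000 the null set is
enumerated exhaustively and the p-value is exact; otherwise `B` random
permutations (default 999, configurable — the reference analyses report
significance without stating their permutation count) give
`p = (1 + #{R_perm >= R_obs}) / (B + 1)`, the standard convention that
counts the observed labeling and cannot produce p = 0.

## Compositional comparison

Per-taxon screens are two-sided Wilcoxon rank-sum tests on relative
abundances, with the classical switch: exact enumeration when both groups
have at most 10 tie-free observations, otherwise the normal approximation
with tie correction and 0.5 continuity correction (this is also exactly
`stats::wilcox.test`'s behavior, which backs the implementation).

Because relative abundances sum to one, a real change in one taxon
mechanically perturbs every other proportion. ANCOM sidesteps this by
testing *ratios*: for every taxon pair the per-sample additive log-ratio
`log((c_i + 1)/(c_j + 1))` is compared between groups; each taxon's
`m - 1` pair p-values are BH-adjusted at 0.05 and its `W` counts the
rejections; `W >= ceiling(0.7 (m-1))` flags the taxon. The pseudocount of 1
is the standard zero-handling choice; the per-taxon BH family at 0.05 and
the 0.7 threshold follow the method's common defaults, since the analyses
this package reimplements cite ANCOM without settings. `W` is invariant to
per-sample scaling of counts (log-ratio cancellation, up to the
pseudocount), which is the property that makes it compositional.

## Taxa–clinical associations

The association grid computes Spearman correlations between every taxon's
relative abundance and every listed clinical variable. P-values come from a
permutation test that shuffles the clinical variable (5,000 shuffles by
default) while holding the taxa fixed; for n ≤ 7 the full n! permutation
set is enumerated instead. One BH family spans the entire grid, matching an
"overall FDR" interpretation rather than per-variable control. Missing
metadata is handled by pairwise-complete deletion per cell; cells with
fewer than 10 complete pairs are flagged and excluded from the BH family
rather than contributing unstable estimates.

Partial Spearman correlations (confounder adjustment for age, sex, BMI)
rank-transform all variables, project the ranks of `x` and `y` onto the
covariate ranks plus intercept, and correlate the residuals; the p-value
uses the t approximation on `n - k - 2` degrees of freedom. The analytic
approximation was chosen over permutation here because residual-based
permutation schemes for partial rank correlations are not uniquely defined
and the t form is the one standard implementations report; a permutation
variant can be layered on by the user via `permutation_pvalue` on the
residuals.

Canonical correlation between a taxa block and a clinical-variable block
standardizes both blocks and solves the classical eigenproblem
(`stats::cancor`). Component significance uses Wilks'
`Lambda_k = prod_{i>=k} (1 - r_i^2)` with Bartlett's chi-square
`-(n - 1 - (p+q+1)/2) log(Lambda_k)` on `(p-k+1)(q-k+1)` degrees of
freedom. Block membership is configuration, not code: the default pipeline
groups metabolic variables (FPG, TG, HDL-C, LDL-C, ALT) and lifestyle
variables separately.

## Cooccurrence networks

Presence is `count > 0` after the 0.1 % rare-genus filter — the underlying
studies never define presence, so the detection threshold is an explicit
parameter. For each unordered genus pair with presence counts `a`, `b` and
copresence `k` among `N` samples, the Jaccard index is `k/(a+b-k)` and the
null model is hypergeometric: placing the two presence sets at random makes
`k ~ Hypergeometric(N, a, b)`. Both tails are inclusive —
`P(X >= k)` for copresence, `P(X <= k)` for exclusion — which is
conservative and matches exhaustive enumeration exactly. The Bonferroni
family is all pairs × both tails (a per-tail family is behind a flag);
edges with adjusted p ≤ 0.05 are kept, signed by the winning tail, with
display strength J for copresence and 1−J for exclusion.

The network statistic is the average local clustering coefficient, with
degree-<2 nodes contributing 0 and edge signs ignored. Its null is the
uniform G(n, m) random graph on the same node and edge counts (10,000
graphs by default); degree-preserving rewiring is available behind a flag
because the two nulls genuinely differ for skewed degree sequences, and
"random networks" alone does not pin the choice down. Intra-phylum
cooccurrence is contrasted between cohorts by a rank-sum test on the two
sets of intra-phylum pairwise Jaccard indices (comparing significant-edge
counts instead is a coarser alternative we did not adopt).

## The synthetic study conditions

Cohort data of this kind are rarely depositable, so the generator is a
first-class module: it produces cohorts with exactly the statistical
structure the analyses assume, plus a serialized truth object, so every
stage can be scored for recovery and error control without downloads.

`default_spec()` encodes the target design: 164 "obese" samples with
phylum means 47.1 / 34.4 / 14.0 / 2.4 / 1.0 % (Firmicutes, Bacteroidetes,
Proteobacteria, Actinobacteria, Fusobacteria) and 45 "nonobese" samples
with 46.0 / 46.0 / 2.7 / 5.2 / 0.8 %; both vectors are renormalized to sum
to one (the printed obese values total 98.9 %). Seventy genera are spread
over the phyla (40/14/8/5/3) with per-phylum weights drawn once from a
symmetric Dirichlet under a fixed catalogue seed; a few anchor genera carry
real names (Bifidobacterium, Bacteroides, Blautia, ...) and the rest are
explicitly artificial `Phylum_gNN` placeholders — the real genus-level
composition beyond a handful of named genera is not publicly available.

Per sample: depth ~ log-normal (median 20,000 reads, sdlog 0.4, a typical
MiSeq range); genus proportions ~ Dirichlet with concentration 50 around
the cohort template (θ ≈ 0.02 overdispersion, in the range of
Dirichlet-multinomial fits to real gut data); presence/absence overlays the
proportions by thresholding latent Gaussians, with per-genus presence
probability `min(0.98, plogis(4.37 + 1.49 log10(mean)))` — abundant genera
are nearly always present, rare ones increasingly zero-inflated. Planted
copresence pairs set the latent correlation (0.8 by default) of the two
genera's Gaussians, so the pair attains that tetrachoric correlation;
infeasible correlation matrices are repaired by nearest-positive-definite
projection with a warning. The Dirichlet template is pre-divided by the
presence probabilities so that the *observed* (masked, renormalized)
composition matches the stated phylum means rather than drifting low for
heavily zero-inflated phyla. Counts are multinomial at the drawn depth, so
each sample's total equals its depth exactly.

Clinical variables are drawn through a Gaussian copula from the cohort's
marginals — normal for mean ± SD variables, log-normal matched to
median/Q3 for the skewed activity variables, Bernoulli for sex (0.59 male)
and acanthosis (0.80). A planted taxon–variable Spearman correlation ρ ties
the variable's latent to the normal scores of the genus's relative
abundance at latent correlation `2 sin(πρ/6)` (the exact bivariate-normal
inversion); the default plants Bifidobacterium ~ HDL-C at 0.4. Height, fat
mass and weight are generated so that the derived BMI/FMI/FFMI/HOMA-IR
columns are self-consistent.

What the generator does **not** emulate: inter-variable clinical
correlation structure (variables are independent apart from planted taxon
links), taxonomic misassignment, phylogenetic signal, longitudinal
structure, or genus-level compositional correlations beyond what the
Dirichlet and the planted pairs induce. Passing the recovery and
error-rate tests therefore demonstrates that the *statistics* behave as
designed under their own assumptions — not that real cohorts satisfy those
assumptions.

## Numerical choices and degenerate inputs

- Permutation p-values use `(1 + count)/(B + 1)`; exhaustive enumerations
  divide by the arrangement count with the observed arrangement included.
  Comparisons against the observed statistic use a 1e-12 slack so exact
  ties in floating point count as exceedances.
- Distance ranking uses average ranks on ties throughout.
- The rare filter keeps taxa *at* the threshold (strictly-less excluded);
  it is idempotent because renormalization after filtering only raises the
  surviving taxa's means.
- `to_relative` refuses all-zero samples by name; `build_network` at
  threshold 0 skips the filter entirely so pure presence/absence tables
  with empty samples remain analyzable.
- Wilks' chain flags any canonical correlation of 1 as degenerate
  (Λ = 0, p reported as 0) instead of taking `log(0)`.
- A sample whose latent presences are all below threshold keeps its most
  abundant genus, so no all-zero samples are generated.
- HOMA-IR converts glucose from mg/dL to mmol/L with the clinical constant
  18.0; the formula itself fixes only the mmol/L form.

## Problem sizes in the test suite

The validation suite runs the full generator at the design sizes (164 and
45 samples, 70 genera). Error-rate and recovery checks use 20–50 seeds per
property: Bonferroni edge FWER and association-grid FDR on 50 null
cohorts, planted-pair recovery on 20 cohorts, ANCOM's planted 8× taxon on
50 paired 50+50 cohorts of 10 taxa, and the planted canonical correlation
of 0.64 on 50 draws at n = 164. Permutation counts in simulation-heavy
tests (300–2,000) are smaller than the interactive defaults (5,000); they
bound the attainable p-values and hence make those checks conservative
rather than lenient. Exhaustive oracles cover every hypergeometric
configuration with N ≤ 10, all 4+4 ANOSIM partitions, all 7! Spearman
shuffles, and Wilcoxon arrangement counts up to C(20,10).

## Known limitations

- ANCOM is implemented in its original W-counting form; covariate-adjusted
  or bias-corrected variants (ANCOM-BC, ALDEx2-style CLR models) are out of
  scope.
- UniFrac and any phylogeny-aware beta diversity are out of scope (no tree
  handling); Bray–Curtis carries the beta-diversity results.
- The hypergeometric edge test conditions on presence margins and ignores
  abundance information beyond detection; SparCC/SPIEC-EASI-style
  compositional correlation networks are a different (out-of-scope) tool.
- Cells of the association grid are tested marginally; the BH family
  treats them as exchangeable hypotheses and offers no hierarchical
  (per-taxon) control.
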