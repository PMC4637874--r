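---
title: "Detecting molecular convergence: models and methods"
author: "phyloconverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting molecular convergence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Lineages that independently adapt to the same environment — the classic
case being cetaceans, pinnipeds and sirenians returning to the sea — may
acquire similar phenotypes, and possibly similar molecular changes. This
package implements a complete screen for such molecular convergence in
protein-coding genes, combining three complementary signals:

1. **Likelihood convergence (ΔSSLS).** For each gene, the sitewise
   log-likelihood support (SSLS) of every alignment column is computed
   under the accepted species topology H~0~ and under alternative
   topologies H~A~ that force the focal lineages into a single
   (erroneous) monophyletic clade. The per-site difference
   ΔSSLS = lnL(H~A~) − lnL(H~0~), averaged over sites, indexes how much a
   gene's sequence "pulls" the focal lineages together: genes fitting a
   convergence topology better score positive.
2. **Parallel / unique / backward substitutions.** Marginal ancestral
   reconstruction identifies sites where all focal lineages independently
   derived the same amino acid (parallel), where that residue is absent
   from every background taxon and ancestral node (unique), and where it
   matches a distant reference clade (backward).
3. **Selection regimes.** Codon models measure whether focal lineages
   evolve rapidly (branch model), under positive selection (branch-site
   model A per lineage), with sitewise selection (M7/M8), and with
   clade-divergent site classes (Clade Model C vs M1a). A locus-wise
   regression of sitewise ΔSSLS on sitewise dN/dS, stratified by Clade
   Model C category, asks whether convergence support is driven by
   positive selection.

A gene is a **candidate adaptation gene** when it is both rapidly evolving
(Δω > 0, LRT p ≤ α) and a likelihood-convergence gene (mean ΔSSLS > 0,
empirical P ≤ α) — the intersection rule reported by `run_study()`.

# Likelihood engine

All stages share one pruning engine. A substitution process is a mixture
of classes, each with a weight, a rate multiplier, root frequencies, and a
map from tree edges to rate-matrix eigendecompositions; this covers
Gamma-rate mixtures of the empirical amino-acid models (JTT, WAG, and the
equal-rates Poisson model) and every codon model variant, including
branch-heterogeneous ones. Per-column conditional likelihoods are computed
over unique site patterns with periodic rescaling, so long or highly
gapped alignments do not underflow; gaps and ambiguity codes are missing
data and are marginalized, never treated as a 21st state.

Branch lengths are optimized by depth-first smoothing: each edge is
optimized by safeguarded Newton ascent (analytic first and second
derivatives from the eigendecomposition) against its freshly maintained
flanking partial vectors, falling back to Brent's method when curvature is
unusable. The Gamma shape α alternates with branch sweeps via Brent on a
log scale. Optimization is monotone in lnL and stops when a sweep improves
lnL by less than 10⁻⁶ (default; the scan stages use 10⁻⁴, which changes
gene-mean ΔSSLS by far less than the simulation-null resolution). Bounds:
branch lengths in [10⁻⁶, 20], α in [0.02, 100]. Equilibrium frequencies
default to the published model values; the `+F` empirical option is
available and the choice is recorded in the fit (`frequencies` field),
since the original tooling leaves this choice open.

Rooted trees are used throughout because ancestral reconstruction needs a
root. Under reversible models the likelihood depends only on the sum of
the two root-child branch lengths; their split is not identifiable and no
result depends on it.

# Convergence scan

For three focal lineages, the alternative-topology generator prunes the
lineages, then combines each of the 3 internal resolutions of the focal
clade with each of the 3 backbone attachment branches where a lineage was
originally attached, giving 9 distinct H~A~ topologies (2 lineages give
2). Regrafted stems (0.1) and focal-clade internal branches (0.05) are
starting values only — every topology is re-fitted per gene, including α,
because sharing parameters between H~0~ and H~A~ would bias ΔSSLS toward
the topology whose parameters were reused. User-supplied Newick topologies
override the generated set when provided.

Significance comes from a parametric null: template genes (fitted under
H~0~) are re-simulated R times with their fitted trees, models and
lengths; each replicate's gene-mean ΔSSLS per hypothesis builds the null
sample. The empirical cdf uses plotting positions i/R at the order
statistics with linear interpolation, and P = 1 − cdf(observed) is clamped
to [1/(R+1), 1], so an observation beyond all null values is reported at
the resolution limit rather than as zero. The null is built from
**gene-level mean** ΔSSLS by default — the statistic actually tested; a
site-level pool is available (`site_level = TRUE`) since published
descriptions of this protocol are ambiguous between the two.

Gene calls aggregate over hypotheses: `"any"` (supported under at least
one hypothesis — the inclusive convention), `"all"` (every hypothesis),
or `"mean"` (averaged ΔSSLS and averaged P; this package's own definition,
chosen so the mean aggregation needs no second null simulation).

# Ancestral reconstruction and substitution classes

Marginal (empirical Bayes) reconstruction computes, for every internal
node and site, the posterior over the 20 states from the product of the
partials above and below the node, mixed over Gamma categories. MAP ties
are broken alphabetically and flagged; MAP posteriors below 0.5 mark a
call as low-confidence (the threshold is this package's choice — the
original analyses validated such sites manually).

For each focal group, the **ancestral reference** is the MAP state at the
parent of the group's MRCA — the ancestor shared with its terrestrial
sister. At a site, the group's **derived state** is the single state
carried by all its non-missing leaves; internally heterogeneous groups are
skipped and counted. Then:

* **parallel** — all groups share one derived state, and it differs from
  every group's ancestral reference. "Strict parallel" additionally has
  identical ancestral states across groups (otherwise the change is
  convergent in the narrow sense); the `unique` flag requires absence
  from all background leaves and from the groups' sister reconstructions.
* **unique** — the shared derived state is absent from every background
  leaf and every group's ancestral node.
* **backward** — a parallel/unique call whose derived state is also the
  prevailing state (≥ 50% of non-missing taxa, configurable) in a distant
  reference alignment such as non-mammal vertebrates.

Gaps are never evidence: a group needs at least one non-missing leaf, and
a gapped background leaf cannot veto uniqueness.

# Codon models

All codon machinery is built on the 61 sense codons of the standard code
with F3×4 frequencies (position-specific nucleotide frequencies, stops
excluded and renormalized; zero frequencies get a 10⁻⁶ pseudocount).
Rates follow the usual codon-model rules: single-nucleotide changes only,
a factor κ for transitions and ω for nonsynonymous changes, target-codon
frequency π~j~. Matrices are scaled so one unit of branch length is one
expected substitution per codon site, with one shared scale factor across
site classes (the mixture-average background rate) so that relative class
rates and ω ratios stay interpretable.

Fitting strategy: branch lengths are estimated once per gene under the
one-ratio (M0) model by full smoothing sweeps; richer models hold the
*relative* branch lengths fixed and optimize their parameters together
with a free global scale — and, for models with a foreground partition, a
second free scale on the foreground edges. The two scales matter: with a
single scale, foreground branch lengths inherited from M0 already absorb
an elevated foreground rate and ω~fg~ is biased downward; letting the
foreground scale shrink restores accurate ω recovery (verified in the
branch-model recovery tests). Every richer model contains the M0
configuration (equal scales, equal ωs), so LRTs remain valid and, if
anything, conservative. κ is estimated per gene under M0 and held fixed
in the site-class models (both members of each LRT pair share it); the
branch model re-estimates κ freely.

Fits with a free positive-selection ω run a multi-start grid (0.8 / 1.0 /
1.5 by default) plus an anchor start at the null model's solution, coarse
first and refined from the best start — the anchor guarantees the
alternative never falls below its null beyond numerical noise. Model
variants: two-ratio branch model (df = 1 vs M0; "rapidly evolving" iff
Δω > 0 and p ≤ α); branch-site model A with classes 0/1/2a/2b and null
ω₂ = 1 (df = 1, plain χ²₁ by default — conservative; the 50:50 mixture is
a flag); M7 = Beta(p, q) in 10 equal-probability categories vs M8 adding
a proportion at ω ≥ 1 (df = 2; sitewise ω = NEB posterior-mean ω, emitted
only when M8 is favored); Clade Model C (purifying / neutral / divergent
classes with separate ω₂ per partition) vs M1a with df = 3 (three extra
parameters; the original report does not print its df). Site-class
posteriors are NEB (posteriors at the MLEs) — a documented approximation
to the BEB posteriors reported by the original tooling. Sites are
assigned to the Clade Model C category with posterior > 0.5, otherwise
unassigned. Alignments with no synonymous variation are flagged
(`no_synonymous_variation`) and excluded from rapid/PSG calling, since dS
is unidentifiable there.

# Convergence–selection link

Per (gene, site), mean ΔSSLS across hypotheses is joined with the M8
posterior-mean ω — only from genes where M8 was favored — and the Clade
Model C category. Within each (gene, category) stratum with ≥ 10 sites
and non-degenerate ω, ordinary least squares ΔSSLS ~ ω with a two-sided
t-test classifies the locus as positive / negative / non-significant at
α. The ω covariate is the M8 sitewise estimate (not the Clade Model C
class ω); the categories only stratify — the reading most consistent
with a "sitewise dN/dS" regression, and configurable by supplying other
tables to `join_site_metrics()`.

# Simulator and planted truth

The simulator draws the root sequence from the model's equilibrium
frequencies and samples each branch endpoint from the exact transition
probabilities, per rate category or per (site, branch) ω in the
heterogeneous codon case. The event log is recovered by endpoint
comparison — fast, and sufficient for planted-truth evaluation; an
explicit Gillespie mode samples full substitution paths when true event
counts are needed. Planted convergence features overwrite the simulated
states at chosen sites (all focal leaves set to the target amino acid;
for "unique" features background carriers are resampled away and logged),
leaving neighboring columns statistically untouched.

`generate_toy_study()` writes a complete runnable study: a 20-taxon
mammal-like species tree with three non-sister marine lineages (a
cetacean clade, a pinniped clade, a sirenian), per-gene codon FASTA under
regimes `h0` (species topology, background ω = 0.2), `ha` (a convergence
topology), `fgw` (foreground ω = 0.8 on the marine lineages), and
`parallel`/`unique` (planted substitutions), plus a truth table and a
seed manifest. Defaults — ω~bg~ = 0.2, ω~fg~ = 0.8, κ = 2.5, 300–900
codons, tree height ≈ 0.35 — are ordinary mammalian orthologs values; the
elevated foreground ω models relaxed constraint rather than pervasive
positive selection, matching the regime the branch model is meant to
flag.

What the simulator does **not** emulate: indels and alignment error,
heterotachy, GC-content variation, recombination, and the orthology,
alignment-filtering and assembly artifacts of real comparative data.
Passing tests therefore demonstrate correctness of the statistical
machinery under its own model, not robustness to real-data pathologies.

# Orchestration

`run_study()` validates its configuration, filters inputs (CDS ≥ 150 nt,
length divisible by 3, longest transcript per gene id), fans out per gene
over all enabled stages, and checkpoints each gene as JSON; reports are
always rebuilt from checkpoints, so interrupted runs resume and a rerun
after deleting checkpoints reproduces byte-identical reports for the same
seed. Per-gene seeds derive deterministically from the study seed, never
from global RNG state. Raw, Benjamini–Hochberg and Bonferroni p-value
columns are all emitted (published descriptions of this correction are
contradictory, so the report carries all three); the candidate
intersection uses unadjusted p at α, with the adjusted columns available
for stricter definitions.

# Validation scales

The automated suite validates each stage at desk scale: the pruning
engine against exhaustive state enumeration on 200 random ≤ 5-leaf trees;
ΔSSLS sign behavior over 20 replicates of 300 amino acids on 12 taxa;
scan calibration on 100 null genes of 200 amino acids (8 taxa, two
hypotheses, nulls pooled from 20 templates × 5 replicates — enough
templates that no single noisy template fit dominates the null's tail);
classifier specificity on 10,000 clean sites; branch-model type-I error
over 60 replicates (6 taxa, 80 codons) and ω recovery over 12 replicates
(12 taxa, 250 codons); M8 null behavior over 15 replicates; Clade Model C
recovery over 10 replicates (12 taxa, 300 codons); and full determinism
of study generation and execution. Larger designs simply rescale these
calls.

One validation outcome is worth stating plainly: in the Clade Model C
recovery study, ω₂ of the divergent class is recovered above 1 in every
replicate and the LRT is significant, but per-site assignment by the
posterior > 0.5 rule recalls only about half of the truly divergent
sites at 12–20 taxa. The per-site evidence carried by a handful of
foreground branches is simply weak; comfortable site-level recall needs
taxon samples closer to the 60+ genomes of large comparative datasets.
Treat Clade Model C site assignments at small taxon counts as
conservative candidate lists, not exhaustive ones.

# Known limitations

* NEB rather than BEB site posteriors; small-sample site classification
  is correspondingly optimistic about parameter certainty.
* Branch lengths of the richer codon models are profile-scaled from M0
  rather than freely re-optimized; LRTs are conservative under this
  scheme, and extremely rate-heterogeneous genes may lose some power.
* The equilibrium-frequency choice (model vs `+F`) and the branch-site
  null convention (χ²₁ vs mixture) are exposed as options; defaults are
  documented above.
* No indel model: columns with gaps lose information but cannot create
  convergence signal.
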