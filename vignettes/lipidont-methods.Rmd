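---
title: "lipidont: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lipidont: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidont)
```

This vignette is the package's own account of what it computes and why the
open design choices were made the way they were. It covers the ontology
model, the nomenclature grammar, the biophysical regression and quintile
categorization, the two enrichment statistics, the preprocessing workflow,
and the synthetic fixture generator — including what a passing test suite
does and does not demonstrate about real data.

## The ontology model

The ontology is a directed acyclic graph with four branches, each headed by
a category ("CAT"-prefixed) root: **lipid classification** (a LIPID
MAPS-style hierarchy), **chemical and physical properties**, **function**
(membrane component, lipid-mediated signaling, lipid storage), and
**cellular component** (predominant sub-cellular localization). Lipid
species are the annotated objects: each species carries direct associations
to its classification leaf, to chemical terms read off its name, to
class-level charge/curvature/function/component terms, and (when the
biophysics layer is enabled) to one quintile category term per predictable
property. The *annotation closure* rule — a species annotated to a term is
annotated to every ancestor of that term — is precomputed at build time, so
enrichment counting never walks the graph.

Species are enumerated combinatorially. Each lipid class rule (shipped as
an editable CSV, `inst/extdata/lipid_class_rules.csv`) declares a number of
acyl positions, a backbone (glycerol, sphingoid, sterol, none) and a linkage
chemistry. Molecular species are all unordered multisets of chains drawn
with repetition from a 37-chain fatty-acid alphabet (C12:0 through C26:7);
sphingoid classes take one d18:0 or d18:1 backbone plus N-acyl chains; ether
classes take one alkyl or alkenyl chain in a distinguished slot. A
*sum-composition* layer (one node per distinct total-carbon/total-double-bond
pair, for classes with at least two positions) sits alongside the molecular
layer so that inputs without resolved chains can still be matched. With the
default rule table this yields `r format(50952, big.mark = ",")` species and
over half a million edges, where an **edge** is one `is_a` link or one
direct (pre-closure) species-to-term association. Counting closure edges
would roughly triple the number and double-count information already implied
by the DAG, so we do not.

Two interpretation choices deserve a note:

* **Sum-composition biophysics.** Whether sum species inherit biophysical
  category terms directly or through their molecular children is not
  determined by the data model. We annotate both layers identically from
  (class, total length, total unsaturation), because the regression
  predictors are exactly those quantities — the molecular detail adds
  nothing to the prediction.
* **Deterministic species identifiers.** Species are keyed by their
  canonical name. A name is already a deterministic, injective, readable
  identifier; replacing it by a numeric hash would only add a collision
  risk. Non-species terms get readable scheme-prefixed ids
  (`LION:CLS:*`, `LION:FA:*`, `LION:CHG:*`, ...), with the fixed CAT ids
  for branch and sub-branch roots.

OBO 1.2 input/output is intentionally minimal: `format-version` header plus
`[Term]` stanzas with `id`, `name`, `namespace` and `is_a`. The reader
validates acyclicity and reports malformed lines by number.

## Nomenclature

Parsing accepts an explicit whitelist of shorthand dialects: class
abbreviation plus sum composition with or without parentheses
(`PC(34:1)`, `PC 34:1`); molecular species with `/`, `_` or space
separators; `d`-prefixed sphingoid bases (`SM(d18:1/16:0)`, sum form
`SM(d34:1)`); `O-`/`P-` ether prefixes at either level. Class abbreviations
are case-sensitive; a configurable synonym table handles common aliases
(`TAG`, `LysoPC`, `GlcCer`, ...). Anything outside the whitelist returns an
explicit unmatched flag with a reason — never a guess — and unmatched names
are excluded and reported rather than aborting an analysis. Names that could
belong to several classes are likewise surfaced as unmatched-with-reason.

Canonical names order chains by length then unsaturation, both ascending,
with the sphingoid base or ether chain pinned first; sn-positions are not
distinguished, so `PC(18:1/16:0)` and `PC(16:0/18:1)` are the same species
`PC(16:0_18:1)`. Canonicalization is idempotent, and matching falls back
from a molecular name to its sum composition when only the latter exists in
the ontology.

## Biophysical properties

Three properties are modeled: chain-melting **transition temperature**
(°C, inversely related to membrane fluidity), **bilayer thickness** (nm)
and **lateral diffusion** (µm²/s, positively related to fluidity). Each is
an ordinary least-squares fit of

$$ y = \beta_0 + \alpha_{\text{class}} + \beta_L \cdot \text{length} +
   \beta_U \cdot \text{unsaturation} + \varepsilon $$

with main effects only — interactions are deliberately excluded because the
predictors named for the published models are class, length and
unsaturation, and a main-effects model is the most parsimonious reading.
The reference class is the lexicographically first one; rank-deficient
designs are rejected with the offending column named. Model quality is
assessed by leave-one-out cross-validation, which the tests verify against
the closed-form leverage identity \(\hat y_{(i)} = y_i - e_i/(1-h_{ii})\).

The *shipped training tables are synthetic*. The published compilations
behind the original models (experimental transition temperatures; a
coarse-grained molecular-dynamics thickness/diffusion set) are not bundled,
so `default_biophysics_models()` generates training data from linear models
whose coefficient magnitudes follow the experimental literature: transition
temperature rises ≈ 4 °C per carbon and falls ≈ 35 °C per double bond
(e.g. DPPC ≈ 41 °C vs DOPC ≈ −17 °C), with PE above PC; thickness rises
with length and falls with unsaturation; diffusion does the opposite. The
transition-temperature set covers PC, PE, PG, PA, PS and SM; the
thickness/diffusion set covers only the five glycerophospholipid classes,
mirroring the sphingolipid-free coverage of coarse-grained sources — an SM
species therefore gets a transition-temperature category but no
thickness/diffusion terms. Untrained subclasses are mapped through a
documented proxy table (`default_class_proxy()`: ether and lyso subclasses
to their diacyl parent, BMP to PG, glycosphingolipids to SM); storage
lipids, sterol esters and free fatty acids are not predictable and carry no
biophysics terms. Sterol biophysics is excluded outright: cholesterol's
effects depend on its interaction partners and do not fit an additive
chain-composition model.

**Quintile categorization.** Predictions are mapped to five named bins
("very low" ... "very high") whose four limits are the 20/40/60/80th
percentiles of predictions over a *reference lipidome*. The quantile
estimator is fixed to inclusive linear interpolation (`stats::quantile`
type 7) — the convention matters at small n and is therefore documented and
tested. Bins are half-open with lower-inclusive interior limits:
\((-\infty, q_{20})\), \([q_{20}, q_{40})\), \([q_{40}, q_{60})\),
\([q_{60}, q_{80})\), \([q_{80}, \infty)\); only the behavior outside the
extreme limits is externally prescribed, the interior boundary side is our
convention. The default reference lipidome is sampled in code, with a fixed
seed, from the enumerated species with class weights typical of a mammalian
membrane lipidome (PC- and PE-dominated); any species list can be
substituted, and limits are then recomputed per property from model
predictions over that list.

## Enrichment statistics

Both modes test **every candidate term independently with its full closed
annotation set** — the "classic" algorithm in gene-ontology terms. No
elim/weight-style decorrelation is applied: decorrelation changes the
meaning of a term's p-value in ways that are hard to communicate, and the
redundant-parent pruning option (below) addresses the most common nuisance
directly.

**Target-list mode.** For each term a 2×2 table (annotated/not ×
target/background) is built over the matched universe, and
over-representation is tested one-tailed via the hypergeometric upper tail
\(P(X \ge a)\). Depletion is not tested. A term annotating the whole
universe has p = 1 by construction.

**Ranking mode.** Lipids are ordered by a local statistic — one-tailed
Welch t-test p-values (Welch-Satterthwaite degrees of freedom; the
alternative is "condition of interest greater", and that condition must be
named), log2 fold changes (with a global half-minimum pseudocount when a
group mean is zero, consistent with the imputation rule), one-way ANOVA
F-test p-values, or custom user values. P-value statistics rank
low-to-high, fold changes high-to-low; the direction can be overridden.
Ties are broken deterministically by canonical name — the KS p-value
depends on the order, so the tie rule is part of the method. For each term
with m annotated lipids at normalized ranks \(r_i\), the one-sided
statistic is \(D^+ = \max(0, \max_i(i/m - r_i))\), over-representation at
the top of the list.

The null distribution of \(D^+\) is *not* the textbook one-sample KS null:
the m positions are drawn **without replacement** from the n list
positions. We compute the exact tail by counting, with a prefix-sum dynamic
program over integer lower bounds, the subsets whose statistic stays below
the observed value (the integer form \(K = \max_i(i n - s_i m)\) avoids any
floating-point boundary ambiguity). The exact route is used for
\(m \le 50\); beyond that a Smirnov-type tail
\(\exp(-2 d^2 m n/(n-m))\) — the classical exponent with a
finite-population variance correction — takes over. Whether the original
web tool used exact or asymptotic p-values is not stated anywhere we could
verify, so we document our switch-over rule rather than claim equivalence.
The tests verify the exact route against an exhaustive permutation null for
all \(n \le 12\).

**Corrections and options.** Raw p-values are Benjamini-Hochberg adjusted.
The BH family is the set of terms actually tested: restricting the analysis
to a term subset (the descendants of named terms, e.g. all child-terms of
"contains fatty acid") changes the family and hence the q-values, but never
any raw p-value. The minimum term size defaults to 1, since nothing in the
method prescribes a floor; terms annotating zero universe species are
always skipped. Redundant-parent pruning — dropping the most generic term
when an ancestor and descendant annotate the identical (universe-restricted)
species set — is applied *before* testing, so pruned ancestors do not
inflate the BH family either. The significance threshold (default
q < 0.05) only labels report rows; nothing is silently filtered.

## Preprocessing workflow

The cluster workflow fixes the pipeline order: half-minimum imputation (a
global constant, half of the minimum positive value of the original matrix)
→ fraction-of-total normalization (each sample column sums to 1; missing
entries are excluded from sums and stay missing) → per-lipid z-scoring →
complete-linkage hierarchical clustering on Euclidean row distances, cut to
exactly k clusters → one Fisher enrichment per cluster against the shared
universe of all matched lipids. Z-scores are used *only* for clustering;
group statistics operate on normalized, unscaled values. Constant rows
cannot be z-scored and are dropped with a warning. Clustering is
deterministic given the input row order (ties in merge heights follow
`stats::hclust`'s fixed agglomeration order). Duplicate lipids after
canonicalization are collapsed by summation with a warning. Reports are
never truncated to a top-n; rows are flagged, not filtered.

## Synthetic fixtures, and what the tests do and do not show

`make_abundance_matrix()` emulates a two-or-more-condition lipidomics
intensity matrix: per-lipid log-normal baselines (σ_log = 1 between lipids,
σ_log = 0.25 between replicates), a multiplicative effect on the lipids
annotated to a planted term in one condition, and uniform random missing
cells. The effect is multiplicative because the local statistics are
fold-change-like. Everything is byte-reproducible from (parameters, seed),
and the generators restore the caller's RNG state.

The planted-recovery checks run at the fixture's stated study conditions —
3 vs 3 samples, effect size 4 for power, effect size 1 for the null — over
100 fixed seeds: the planted term must reach q < 0.05 in at least 95% of
power runs, and any-term detection must stay at or below 5% of null runs.
Problem sizes throughout the suite are chosen to make the oracles
exhaustive where exhaustiveness is the point: Fisher tables to margins of
30, KS permutation nulls to n = 12, linkage heights on a five-point
hand-checkable instance, and toy ontologies of two classes by four fatty
acids (20 molecular species) for the simulations.

What this does *not* show: real lipidomes have correlated lipids
(co-regulated classes, shared chains), heteroscedastic intensities,
class-structured missingness and imperfect nomenclature — none of which the
generator imitates. Passing the planted-recovery tests demonstrates that
the statistics find what the generative model says is there at the stated
effect size and replication, not that any particular biological contrast
will reach significance.

## Known limitations

* Abundances never weight the enrichment: a low-abundance lipid counts as
  much as a high-abundance one. A custom local statistic can fold
  abundance in, but no built-in does.
* The biophysics layer is only as good as its synthetic training tables;
  the categories are calibrated against a synthetic reference lipidome and
  should be re-derived from real reference data where available.
* No sn-position or double-bond-position resolution, no oxidized-lipid
  grammar, and no plant/bacterial/yeast class extensions in the shipped
  rule table (the rules CSV is editable precisely so users can add them).
* Sum-composition fallback matching is deliberately lossy: a molecular
  name matched at sum level loses its contains-fatty-acid terms.
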