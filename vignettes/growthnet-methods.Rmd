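---
title: "Methods: candidate-gene discovery for short stature with growthnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-gene discovery for short stature with growthnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthnet)
library(dplyr)
```

## The problem

Idiopathic short stature (ISS) — height at least 2 SD below the population
mean with known causes excluded — is genetically heterogeneous, and most
affected individuals remain undiagnosed after routine testing. A productive
discovery design is to exome-sequence a cohort of affected families (child
plus both parents where available), filter variants by trio inheritance
pattern and population frequency, and then weigh the surviving genes with
every available line of growth-related evidence. growthnet implements that
analysis as a set of pipeable, data-frame-first functions, together with a
synthetic-data generator so that every stage can be validated against a
known ground truth.

The pipeline has four layers:

1. **Variant level** — inheritance detection in trios and five-class
   (I benign … V pathogenic) classification; benign and likely benign
   variants are excluded.
2. **Gene level** — 8 binary evidence categories per gene (association
   studies, copy-number variants, growth GO terms, protein–protein
   interaction with a growth gene, mouse and zebrafish models, a prior
   exome study, chondrocyte expression), merged with the variant class into
   a combined 1–4 score and a high/medium confidence tier.
3. **Network level** — Fisher-exact enrichment of a known growth-gene list
   over an annotation corpus, followed by fuzzy clustering of enriched
   terms by Cohen's kappa over shared genes.
4. **Mapping** — candidate genes are projected onto the enriched clusters,
   giving a functional context for each candidate and a treemap summary.

## Inheritance detection

For each variant in a complete trio, `detect_inheritance()` applies the
definitional patterns:

* *de novo*: child heterozygous, both parents homozygous reference;
* *homozygous*: child homozygous alternate, both parents heterozygous
  carriers;
* *compound heterozygous*: at least two heterozygous variants in the same
  gene with opposite parental origin;
* *X-linked recessive*: X-chromosome variant, hemizygous alternate male
  child, heterozygous mother, reference father;
* *dominant inherited*: heterozygous variant carried by a parent;
* everything else, including affected-only families, is *unresolved*.

Three deliberate simplifications, all visible in the code and configurable
nowhere (they are the model): phasing of compound heterozygotes uses
parental origin only, so variants heterozygous in both parents are
phase-unknown and never counted toward compound heterozygosity; all X
variants in males are treated as hemizygous (pseudoautosomal regions are
not modelled); and Mendelian-inconsistent combinations (e.g. a homozygous
alternate child with a homozygous reference parent) are flagged
`mendel_error` and excluded from pattern labels rather than rescued. The
unit tests check the labels against a brute-force enumeration of every trio
genotype combination on autosomes and on X for both child sexes.

## Variant classification

The five-class scheme in `classify_variants()` is frequency-dominant and
ACMG-like. With the `default_rules()` thresholds:

| condition | class |
|---|---|
| AF ≥ 0.01 | I (benign) |
| 0.001 ≤ AF < 0.01, not loss-of-function | II (likely benign) |
| rare LoF (nonsense, frameshift, splice) + de novo or recessive-fitting pattern | V |
| rare LoF otherwise, or rare de novo missense/in-frame | IV |
| otherwise | III (VUS) |

A missing allele frequency is treated as 0: absence from a large population
reference is the strongest available rarity signal. The thresholds are a
design choice of this package — published classification practice varies in
its exact cutoffs — so the whole table is replaceable from YAML
(`read_rules()`). The property the tests enforce is structural rather than
numeric: the class is monotone non-increasing in allele frequency for every
consequence/inheritance combination, so raising a variant's population
frequency can never make it more pathogenic.

A manual `structural_override` column (for reclassifications justified by
protein-structure analysis, which is outside this package's scope) may only
raise class III to class IV.

## Combined score and tiering

`combine_scores()` merges the best variant class per family (III–V) with
the gene's evidence category count (0–8) through an explicit 3×9 decision
table. The default is

```
score = clamp(1 + (class − 3) + [count ≥ 3] + [count ≥ 6], 1, 4)
```

i.e. the floor of the scale is a VUS with no gene-level support and the
ceiling a pathogenic variant with broad support, with monotonicity in both
arguments. The exact table used in published screens of this design is
typically a supplementary detail; any 3×9 monotone matrix can be supplied
in its place. Genes report the min–max score range across families, and
tiering uses the maximum.

`tier_genes()` assigns *high* confidence only to genes hit in at least two
independent families with a maximum combined score of at least 3 — a single
family, however striking its variant, cannot make a gene high-confidence.
Genes below that but with a score of at least 2, or with any gene-level
evidence, are *medium*; the remainder are rejected. The rule is a fixed
point: re-tiering a tiered table changes nothing. On the packaged reference
table of 13 high-confidence ISS candidate genes (`iss_candidates()`), the
default thresholds tier 13/13 high, with family counts from 2 to 8. One
boundary case deserves note: a gene whose score range is 2–3 (it occurs in
the reference table) is tiered on the *maximum* of its range; tiering on
the minimum would demote it, and the package deliberately uses the
maximum because the per-family best score is what the range summarises.

## Enrichment statistics

`term_enrichment()` forms, per term, the 2×2 table of list membership
versus term membership over the background universe and reports:

* the one-sided Fisher exact p (upper hypergeometric tail) — the screen
  only interprets over-representation, so the one-sided alternative is the
  default and the classical two-sided test sits behind
  `alternative = "two.sided"`;
* the odds ratio `(a/(A−a)) / (b/(B−b))`, with documented sentinels 0 (no
  list hit) and `Inf` (term entirely inside the list, or no background
  hit);
* the fold enrichment `(a/A) / ((a+b)/(A+B))`;
* Benjamini–Hochberg adjusted p-values (`bh_fdr()`, delegating to
  `stats::p.adjust`), with significance called at FDR ≤ 0.05.

An EASE-style conservative variant (the tail computed with one list hit
removed) is available via `ease = TRUE` but is off by default: it is a
DAVID convention, not part of the Fisher test proper, and published
descriptions of this analysis name the Fisher test. Gene identifiers are
harmonised by case-insensitive exact match only; alias resolution is a
curation task the package does not attempt.

## Kappa clustering

`kappa_matrix()` scores each term pair by Cohen's kappa of their binary
gene-annotation vectors over the universe — chance-corrected agreement, so
two large terms that overlap merely because they are large score near 0.
The parameter set follows the established functional-annotation-clustering
defaults: `overlap = 5` is read as the minimum number of shared genes
before a pair's kappa is considered at all (below it the entry is gated to
0), and `kappa = 20` as a similarity threshold of 0.20 — the upstream
tool takes that parameter as an integer ×100, and a raw threshold of 20
would be outside kappa's range. Both readings are configurable in
`clustering_params()`.

Seed formation and merging follow the fuzzy heuristic: every term proposes
a seed of itself plus its above-threshold neighbours; seeds survive if they
hold ≥ 5 terms and at least 50% of all within-seed pairs pass the kappa
threshold (the published parameter lists do not state this sub-rule; the
50% membership fraction is adopted from the source heuristic and exposed
as `membership_fraction`). Seeds then merge while any two groups share at
least 50% of the smaller group's members. The source heuristic is
order-dependent; this implementation imposes a deterministic order —
highest sharing fraction first, ties by smaller merged size, then by
lexicographically smallest member — so that shuffling the input terms
provably cannot change the output (tested), and a small-instance test
checks the result against an oracle that tries every merge order.

Pruning order follows the published two-step description literally: raw
p-values drive clustering, and only afterwards are members with FDR > 0.05
pruned; clusters falling below the final size are then dropped (a
`keep_small` flag retains them). The kappa universe is the full background
gene set by default, not just annotated genes — the choice is conservative
(it inflates the "neither" cell equally for all pairs) and a restricted
universe can be passed explicitly. Cluster summaries use the source tool's
conventions: the enrichment score is −log10 of the geometric mean of member
raw p-values, and the representative label is the lowest-p member (ties:
larger gene set, then lexicographic).

`treemap_layout()` implements the classic squarified treemap (area ∝ gene
union size, placement order area-descending with lexicographic
tie-breaks), since no treemap layout engine ships with the package's
dependency set; `autoplot()` renders it with ggplot2.

## The synthetic-data generator

`sim_config()` encodes the study conditions the generator emulates: 254
families of which 69/254 ≈ 27% are affected-only; an inheritance mix of
71% de novo dominant, 17% X-linked recessive and 12% autosomal recessive
(split evenly between homozygous and compound heterozygous — the published
split between the two recessive forms is not stated); a consequence mix of
78% missense, 15% nonsense, 6% splice, 1% in-frame indel; causal variants
drawn from a rare frequency band (< 5×10⁻⁴) and, per family, 50 background
variants in a common band (0.01–0.2) with Mendelian-consistent inherited
genotypes — the background burden per exome after upstream filters is not a
published number, and 50 is a free parameter chosen to exercise the
benign-exclusion rules at realistic cost. Compound-heterozygous families
carry exactly two causal variants in one gene, one per parent: the minimal
pattern satisfying the definition.

The annotation corpus plants blocks of terms sharing a common core gene
set. Defaults are three blocks of 6 terms with a 12-gene core inside
18-gene terms over a 1000-gene universe: with those sizes a within-block
pair has kappa ≈ 0.66 noiselessly and ≈ 0.4 when 20% of core genes are
independently dropped per term, so block structure sits clearly above the
0.20 threshold under the noise level the robustness tests use, while
between-block and null-term pairs sit near 0 and below the 5-gene overlap
gate. The growth-gene list includes each core gene with probability 0.8,
which plants the enrichment signal the recovery tests look for. All
randomness flows from one root seed with per-stage derived streams, so the
cohort, the corpus and the evidence flags can be regenerated independently
and reproducibly (identical seed ⇒ byte-identical files).

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: linkage disequilibrium and recurrent variants,
sequencing or genotyping error, population stratification in allele
frequencies, the hierarchical (DAG) structure of real ontologies, and
correlated evidence flags. Recovery results on synthetic corpora bound the
method's behaviour under its own assumptions, not its sensitivity on a real
cohort.

## Numerical choices and degenerate inputs

* Missing AF → 0; AF outside [0,1] is an error.
* Unknown consequence strings classify as III with a warning.
* Odds-ratio sentinels: 0 when `a = 0`; `Inf` when `A−a = 0` or `b = 0`.
* Kappa with Pe = 1 (constant annotation vectors) is defined as 0 with a
  warning.
* All tie-breaks (significant-term ordering, representative labels, merge
  order, treemap placement) are deterministic and lexicographic, so every
  pipeline output is byte-reproducible from the same inputs.
* Percentages are rounded half-up (36% from 92/254; one decimal where the
  convention is one decimal, as in 9.5% from 6/63), matching how such
  tables are printed rather than R's round-half-even.

## Validation problem sizes

The test suite validates: the Fisher p against an exhaustive
combinatorial-sum oracle on every 2×2 table with universe ≤ 40 (≈10⁵
tables) plus 2000 random tables with universes to 200; kappa against a
scalar recomputation on >1000 random pairs; inheritance labels against a
brute-force enumeration of all trio genotype combinations; enrichment
recovery on 100 replicates of 20 planted terms among 500 nulls (mean
recovery ≥ 18 with mean false-discovery proportion within binomial error
of 0.05) and 200 global-null replicates; and block recovery with adjusted
Rand index 1 on noiseless corpora and mean ARI ≥ 0.8 across 50 replicates
at 20% annotation noise. These sizes are the package's chosen balance of
coverage against runtime.

## Known limitations

* The classification rule table and combined-score table are sensible,
  monotone defaults, not transcriptions of any particular study's
  supplementary tables; conclusions that depend on exact thresholds
  require supplying those thresholds.
* Compound-heterozygote detection cannot use read-backed phasing.
* The clustering reproduces the *algorithm family* of the annotation
  clustering tool, with determinism imposed; it does not attempt to
  reproduce any specific published cluster count, which depends on
  versioned annotation snapshots.
* Gene-level evidence flags are inputs; the package does not mine model
  organism or interaction databases.
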