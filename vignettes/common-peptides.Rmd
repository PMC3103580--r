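---
title: "Common peptides: deterministic motifs as a feature space for protein families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Common peptides: deterministic motifs as a feature space for protein families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpscan)
library(dplyr)
```

## The model

A *common peptide* (CP) is a deterministic string of at least five amino
acids that recurs across the sequences of a protein family. Unlike
position-weight matrices or alignments, CPs carry no uncertainty: a CP
either occurs verbatim in a sequence or it does not. The package builds a
feature space whose axes are CPs (plus merged CPs, below) and represents
each family by per-sequence-normalized occurrence counts, then asks
biological questions in that space: which families resemble each other,
where motifs originated on the tree of life, whether mitochondrial
sequences retain bacterial motif content, which motifs mark a structural
class, and whether prevalent motifs sit on functional sites.

### Motif extraction

Extraction works on raw substring statistics of one family's
(redundancy-reduced) corpus. For a candidate string $a_1 \ldots a_n$ define
the right-continuation probability

$$p_R(i) = \frac{c(a_1 \ldots a_i)}{c(a_1 \ldots a_{i-1})},$$

where $c(\cdot)$ is the exact occurrence count in the corpus (overlapping
self-occurrences included). Inside a conserved motif, continuation is
nearly certain and $p_R \approx 1$; at the motif's true edge the strongest
single-residue extension collapses. A right boundary closes the candidate
when the decline ratio falls below $\eta$,

$$\frac{p_R(n+1)}{p_R(n)} < \eta,$$

*and* a one-sided binomial test — the extension count as successes out of
$c(a_1\ldots a_n)$ trials against rate $\eta\, p_R(n)$ — rejects at level
$\alpha$, so that boundaries on small counts are not called from noise.
The left boundary applies the same rule to reversed strings, which needs no
second index: the count of a reversed prefix is the count of the original
suffix. A substring is emitted iff it has both boundaries, length within
$[\ell_{\min}, \ell_{\max}]$, and support in at least `min_support`
distinct sequences. $p_R(n+1)$ uses the *maximum* extension count over the
twenty residues — the strongest continuation; if even it declines sharply,
every continuation does.

Defaults: $\eta = 0.9$, $\alpha = 0.01$, $\ell_{\min} = 5$,
$\ell_{\max} = 30$, `min_support = 3`. All are exposed in `mex_params()`.
The boundary rule as stated here is this package's normative definition of
the extractor; it is validated by planted-motif recovery and by
residue-shuffle controls, not by reproduction of any particular historical
implementation. Counting is implemented by iterative extension: a substring
of length $l{+}1$ occurring twice must extend one of length $l$ that does,
so only surviving start positions are extended — exact counts at a fraction
of the naive cost.

### The CP space

Per-family motif lists are unified and pruned: any motif that strictly
contains another motif of the union is removed (`unify_and_prune()`),
leaving an antichain under the substring relation. The shortest string is
the informative one — its superstrings hit a subset of its occurrences.

All surviving CPs are searched on all sequences of all families
(`locate_hits()`), including families they were not extracted from; this is
what turns per-family motifs into a shared coordinate system. When two or
more CP hits overlap on one sequence (sharing at least one residue;
book-ended adjacent hits do not count), the chain is replaced by a *merged
CP*: a feature identified by the substring spanning the chain's union
interval, registered globally so identical overlap patterns on different
sequences map to the same feature. Constituent CPs receive no solo count on
such a sequence; every hit is accounted exactly once, solo or merged, and
the tests assert this conservation exhaustively. Because the pruned CP set
is a substring antichain, a merged span can never collide with an existing
solo CP string; for unpruned inputs a collision is disambiguated by
tagging the merged feature.

The family-by-feature matrix divides each family's counted occurrences by
its number of sequences, so families of different sizes are comparable.

### Family similarity and the shuffle null

Family similarity is the Pearson correlation of family rows across all
features. Significance comes from a permutation null: each of
`n_shuffles = 100` replicates permutes, for every feature independently,
its values across families — feature totals are conserved, association
between features and families is destroyed — and pools the off-diagonal
correlations. The empirical p-value of a pair is
$(1 + \#\{r_{null} \ge r\}) / (1 + \#null)$, add-one corrected so finite
shuffles never report zero; pairs with $p < 0.01$ are retained. The pooled
null is the default because the background model is a single global one;
`per_pair_null = TRUE` switches to pair-specific null distributions. The
whole analysis can be restricted to one analysis group
(Bacteria/Eukarya/Archaea/Mitochondria), re-running everything from hit
location onward on that group's sequences; families absent from the group
are dropped and reported.

### Kingdom origins and enrichment

Mitochondrial sequences form a fourth analysis group beside the three
kingdoms; a sequence's group is determined by its organelle flag and
kingdom. A CP's origin label is a pure function of its presence set over
the three kingdoms under a topology with Bacteria as the outgroup of
Archaea and Eukarya: `ALL3`, `AE`, `B_only`, `A_only`, `E_only`, `BE`, and
`other` (Bacteria+Archaea, which has no ancestral node on this topology).

The mitochondrial enrichment test asks, family by family: of the CPs on the
family's non-mitochondrial sequences (the urn, size $N$), those specific to
one kingdom within the family are successes ($K$); the CPs also present on
the family's mitochondrial sequences are the draw ($n$, with $k$
successes); $p$ is the upper-tail hypergeometric probability, and q-values
are Benjamini–Hochberg adjusted across the whole family-by-kingdom grid in
one batch, with enrichment called at $q < 0.01$. The choice of urn is the
main genuinely open design point; the non-mitochondrial universe is the
default because the kingdom-specific lists are themselves built from
non-mitochondrial hits, and `universe = "all"` is available for
sensitivity checks.

### Class signatures and exclusive sharing

A CP is a class signature when it appears in at least six families of one
structural class while its other-class presence stays marginal. "Marginal"
is operationalized as: at most 2 other-class families, and other-class
occurrences at most $\max(3,\ 5\%\ \text{of total})$ — wide enough to
tolerate a couple of stray hits, tight enough that a balanced CP never
qualifies. CPs containing a configured stop-list string (known signatures
such as KMSKS and HIGH) are excluded, so the output is genuinely novel
material. All thresholds are arguments.

`exclusive_shared_cps()` finds CPs whose full family presence set equals a
chosen subset, and calibrates the count by exhaustively enumerating every
same-size subset of the same class (210 quartets for a 10-family class) —
an exact null, not a sample.

### Functional sites and cross-family sharing

A CP is *prevalent* when strictly more than half of at least one family's
sequences contain it. Distances between hits and annotated sites are
counted in residues strictly between the site and the nearer hit boundary
(0 with the site inside the span counts as exact; a gap of at most 3 as
vicinity). When several annotated sequences exist per family, only those
with the best `priority` value are used, mirroring the use of one best
structure per family. Overlap significance is an upper-tail hypergeometric
test with all site-sequence-hitting CPs as the urn and the prevalent CPs as
the draw; the vicinity classification gets a separate test.

Cross-family sharing between two corpora accepts exact string equality or
full inclusion either way; the match string (the shorter of the pair) must
occur in at least 20 distinct sequences of each corpus. Equal-length
matches one substitution apart are grouped as Hamming-distance-1 clusters —
reported as variants of one motif, never silently unified.

## Redundancy reduction

Sequence collections over-represent well-sequenced strains. Within each
family, pairs at or above 90% alignment identity are chained by single
linkage; one representative per cluster is kept, chosen by maximal average
identity to the other members with ties broken by lexicographically
smallest id, which makes the result independent of record order.

Identity is the number of identical columns of the best Smith–Waterman
local alignment (BLOSUM62, gap open 11, gap extension 1) divided by the
length of the *shorter sequence*. The denominator matters: the best local
alignment between two unrelated sequences is a short near-perfect match,
so identity normalized by aligned columns alone approaches 1 for random
pairs and a 90% threshold would chain entire families. Normalizing by the
shorter sequence sends unrelated pairs toward 0 while leaving genuine
near-duplicates (strains at a few percent substitution) above 0.9.

## The synthetic corpus generator

`synth_spec()`/`synth_generate()` produce corpora in which every signal is
planted and recorded: families with class labels and sizes; per-family
mixtures over the four analysis groups (default 84% Bacteria, 11% Archaea,
3% Eukarya, 2% Mitochondria, the heavily bacterial composition typical of
enzyme-family collections); clone groups grown from one template by i.i.d.
substitutions (2% by default, keeping expected pairwise identity near
0.96); planted motifs with controlled family/group targeting and insertion
probability; and site annotations co-located with chosen planted motifs.
Background residues are i.i.d. from a configurable distribution (uniform
1/20 by default) — the simplest model under which planted motifs are the
only deterministic signal. Motifs overwrite background residues rather
than inserting, so lengths are untouched; multiple motifs on one sequence
are placed on disjoint spans. Chance occurrences of a motif string in the
background are possible and deliberately unrecorded; tests needing exact
counts use motifs of length ≥ 6, where the chance rate per sequence is
about $L \cdot 20^{-6}$ and negligible.

What the generator does *not* emulate: phylogenetic correlation structure
(no tree-based evolution), compositional bias, repeats and low-complexity
regions, domain architecture, or alignment-visible homology between
families. Passing tests therefore demonstrate that the machinery recovers
exactly what was planted under a clean null — they do not certify
performance on real corpora, where near-motifs, biased composition and
shared domains add hazards the generator omits by design.

## Numerical choices and degenerate inputs

* Constant family feature vectors (possible in small group-restricted
  analyses) have no defined correlation; they are set to 0 with a warning.
* Empirical p-values use the add-one correction; with 100 shuffles the
  smallest reportable p depends on the pooled null size.
* All coordinates are 0-based, half-open; "overlap" means sharing at least
  one residue, so book-ended hits never merge.
* Representative and cluster labels use lexicographic tie-breaks, making
  clustering order-invariant.
* Ambiguity letters (B, J, O, U, X, Z) are rejected by default;
  `map_ambiguous = TRUE` maps them to X, and X is excluded from substring
  counting so it can never enter a motif.
* The empty-urn and all-success hypergeometric corners return p = 1.

## Problem sizes

The test suite and the acceptance script run on corpora of 10 families ×
100 sequences × 300 residues for motif-recovery checks, with smaller
planted designs (2–14 families, 15–80 sequences) for the downstream
analyses, 100 shuffles for the similarity null and 20 residue-shuffle
replicates for the extraction control. These sizes give the planted
designs comfortable statistical margins while keeping a full run in the
order of a minute.

## Limitations

* The extractor is deterministic and exact-match only: single
  substitutions split a motif into variants (the Hamming-1 grouping in
  `cross_family_shared()` reports, but does not merge, such variants).
* Motifs shorter than five residues are out of scope by definition, which
  excludes signatures such as HIGH from extraction (they can still be used
  in stop-lists).
* The shuffle null conserves per-feature totals but not within-sequence
  composition; it tests association between features and families, nothing
  finer.
* Enrichment conclusions inherit the urn choice documented above.

## A compact end-to-end example

```{r example, eval = FALSE}
spec <- synth_spec(
  families = tibble::tibble(
    label = c("TyrRS", "TrpRS", "ThrRS"),
    class_label = c("I", "I", "II"), n = 30
  ),
  motifs = list(
    planted_motif("KMSKSW", c("TyrRS", "TrpRS"), insertion_prob = 0.8),
    planted_motif("WGILIEH", "ThrRS", insertion_prob = 0.7)
  ),
  seed = 7
)
g <- synth_generate(spec)

cps <- g$records |>
  extract_motifs_by_family() |>
  unify_and_prune()

space <- build_cp_space(cps, g$records)
sim <- family_similarity(g$records, cps, n_shuffles = 100, seed = 1)
tidy(sim)
autoplot(sim)
```
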