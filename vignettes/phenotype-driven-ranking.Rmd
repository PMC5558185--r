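---
title: "Phenotype-driven ranking: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-driven ranking: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdrank)
```

## The problem

In rare-disease sequencing, a standard filter cascade (call confidence,
population allele frequency, predicted deleteriousness, optionally a trio
de novo restriction) typically still leaves dozens of candidate genes per
patient. pdrank ranks the diseases those genes are known to cause or
correlate with by how well each disease explains the patient's *observed
phenotypes*, so that a clinician can read the candidate list from the top.

The substrate is a typed, directed knowledge network:

* **GD** edges connect genes to the diseases they cause or correlate with;
* **DP** edges connect diseases to their associated phenotypes;
* **PH** edges connect more general hierarchy terms to more specific ones.

There is deliberately no strict boundary between diseases and phenotypes: a
node may be both, carrying its own downstream phenotypes. Only the PH
portion is required to be acyclic; dual-role nodes legitimately create
disease–phenotype–disease chains in the full graph.

## The score

Given the variant-impacted gene set $G$ and mapped patient phenotypes $P$,
the algorithm proceeds in three steps:

1. collect the candidate diseases $D$ reachable by one GD edge from $G$;
2. from every phenotype in $P$, find all shortest paths to diseases in $D$
   such that the last edge is a DP traversal, no *other* member of $D$
   appears as an intermediate, and the path has at most `max_path_length`
   edges;
3. score each disease as
   $$S = \sum_{i \in P \text{ connected}} w_s^i \, w_p^i,$$
   drop diseases connected to no phenotype, and rank.

The two weights encode specificity and confidence:

$$w_s^i = \frac{1}{1 + b \log_{10}(\max(1, N_i))}, \qquad
  w_p^i = a^{L_i - 1},$$

where $N_i$ is the number of diseases phenotype $i$ is *directly* attached
to and $L_i$ the shortest-path length found in step 2. The logarithm makes
$w_s$ respond to the order of magnitude of $N_i$ — phenotypes attached to
1, 10, 100 or 1000 diseases are separated without suppressing unspecific
phenotypes entirely. The geometric path decay encodes that confidence in a
disease–phenotype link drops with every hierarchy edge crossed. A direct
link, and the special case where the phenotype *is* a candidate disease
itself, has $w_p = 1$ exactly.

Each phenotype contributes **once** per disease, at its shortest length,
however many distinct shortest paths exist; the full set of shortest paths
is kept only for the evidence subnetwork shown to the user. The score sums
phenotypic evidence only — variant-level evidence (ACMG class, zygosity,
mode-of-inheritance consistency) is reported alongside but deliberately not
folded into $S$, so the two lines of evidence can be weighed independently.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `a` | 0.75 | path decay per extra edge (unitless, in (0,1]) |
| `b` | 1 | specificity decay per decade of $N$ (unitless, ≥ 0) |
| `max_path_length` | 4 | maximum edges per phenotype–disease path |
| `table_limit` | 50 | disease/gene pairs kept in the result table |
| `variants_per_gene_limit` | 5 | variant rows shown per pair |

The defaults are the operating point the method was published and
benchmarked at; they are exposed via `pdr_params()` (and a flat key–value
config file for the CLI) because sensitivity to `a` matters in practice —
values near 1 promote diseases only loosely connected to the supplied
phenotypes.

## Traversal rules and their rationale

The search (`constrained_shortest_paths()`) is a breadth-first expansion
that walks DP edges *against* their stored disease→phenotype direction and
PH edges in **both** directions. Mixed-direction hierarchy traversal is
required in real cases: a specific finding such as *unilateral renal
agenesis* may connect to a disease only via a more general sibling branch
(up to *dysgenesis*, down to *unilateral renal dysgenesis*, then across a
DP edge), a three-edge path that pure upward traversal would miss.

Two subtleties in the constraint set:

* Only members of $D$ are excluded as intermediates. A dual-role node that
  happens to be a disease but is *not* a current candidate may be crossed;
  this is what lets phenotype chains pass through intermediate syndromes.
* When the starting phenotype is itself a member of $D$, it is reported as
  a direct connection with $w_p = 1$. The specificity weight is still
  computed from the node's own DP in-degree rather than forced to 1 — the
  direct-case rule is stated for the path weight only, and computing $w_s$
  uniformly keeps the score monotone in specificity. This choice is
  documented here because the alternative (forcing $w_s = 1$) is equally
  defensible.

Correctness of the search is not argued, it is tested: an independent
brute-force enumerator of *all* constraint-satisfying simple paths up to
the length cap (in `tests/testthat/helper-oracle.R`) must agree with the
breadth-first search — same reachable diseases, same minimal lengths, same
complete shortest-path sets — on hundreds of seeded random graphs that
include dual-role nodes and non-tree hierarchies.

## Term mapping

Free-text phenotype entry is noisy in spacing, capitalization and
hyphenation, so lexicon lookup happens on normalized strings (lower-case,
hyphens/underscores to spaces, whitespace collapsed). Normalization plus
exact lookup is the whole of the matching — edit-distance matching and
autocompletion are interactive-UI concerns outside this package's scope.
Identifier-shaped inputs (`HP:` + 7 digits; the synthetic fixtures use a
reserved `HPX:` prefix) are resolved against primary then alternate
identifiers. Precedence is deterministic: identifier > primary name >
synonym; when a surface matches a primary name and a different node's
synonym the name wins and a diagnostic is attached. Surfaces that are
ambiguous *within* an entry kind are detected when the lexicon is built and
deliberately match nothing — silently picking one node would corrupt
scores downstream.

## Variant filtering

The cascade retains a variant when it passes **all** of:

* call quality ≥ 20 (VCF `QUAL`; the boundary value survives);
* population allele frequency ≤ 0.5% — exceeding the threshold in *any* of
  the four sources (1000 Genomes, NHLBI-EVS, ExAC, AFC) removes the
  variant. The any-source rule matches standard rare-disease practice; an
  all-source mode is available. Absent frequencies count as rare;
* predicted deleterious: ACMG pathogenic/likely pathogenic (consumed as an
  input annotation, never computed), HGMD DM tag, a loss/gain-of-function
  consequence (frameshift, start/stop loss or gain, splice site), or
  missense.

An optional trio filter keeps only de novo candidates: proband carries the
alternate allele, both parents genotyped homozygous reference. The variant
model therefore distinguishes a `ref` genotype from a `missing` one; a
missing parental call removes the variant (conservative). Gene-level
counting of ≥ 2 distinct heterozygous variants is used as a proxy for
compound heterozygosity in the MOI-consistency display — phase is not
assessed, and the output labels it accordingly. Inputs are assumed
left-normalized; multi-allelic sites are decomposed but not re-normalized.

## The synthetic generator

No public corpus reproduces the content of the proprietary knowledge base
the method was built on, so `generate_network()` emulates its *structure*:
a multi-level hierarchy (random forest, depth 4), diseases with tens of
phenotypes, phenotypes shared across many diseases, and a small dual-role
fraction. Degree means default to the reported content statistics — 43.4
DP edges per disease, 6.8 GD edges per gene, ~6% of phenotypes dual-role —
at node counts reduced by roughly an order of magnitude (120 genes, 50
diseases, 300 phenotypes), which keeps simulation studies fast while
preserving the degree regime the weights respond to. Degree *distributions*
are not reported for the real network; Poisson is used as the
minimal-assumption choice and any distribution-sensitive conclusion should
be read with that caveat. The dual-role out-degree (mean 5) is likewise a
modelling choice, not a reported value. What the generator does **not**
emulate: literature-curation bias, hub structure beyond Poisson tails,
real HPO semantics (identifiers use a reserved `HPX:` prefix), sequencing
error, and linkage between variants. Passing planted-case tests therefore
demonstrates algorithmic correctness and ranking behaviour under the
stated degree regime — not clinical performance on real patients.

`plant_case()` builds a solved case: sampled true phenotypes from the
planted disease (rendered as a random mix of names, synonyms and
identifiers so the mapper is exercised), optional uniform noise phenotypes
from outside the disease's set, one qualifying variant in the causal gene,
one passing decoy variant per decoy gene, and optional variants
constructed to fail each filter. Noise is well-defined because it is drawn
excluding the disease's own phenotype set. All generator outputs are pure
functions of their parameters and seed.

In the validation experiments shipped with the package, zero-noise cases
must rank the planted disease first in all 50 replicates, and with half
the observed phenotypes replaced by noise plus 20 decoy genes the causal
gene must appear in the top 10 in at least 80% of 200 replicates; the
oracle-equivalence suite uses 200 random graphs of at most 60 nodes.
These problem sizes were chosen to make the full suite complete in minutes
on a single core while keeping binomial error on the recovery fractions
below a few percent.

## Numerical and determinism choices

* Contributions are computed in double precision and summed in phenotype-id
  order, so a disease's score and its printed breakdown agree to strictly
  better than $10^{-12}$ and runs are bit-reproducible.
* Ranking ties are broken by descending contribution count, then
  lexicographic disease id. The original description specifies no tie
  rule; this one is deterministic and input-order independent.
* Within a disease/gene pair, variant rows are ordered by classification
  severity (pathogenic > likely pathogenic > DM-only > LoF consequence >
  missense), then position — which five variants are shown is otherwise
  unspecified.
* Table truncation counts disease/gene *pairs* (50 by default), never
  reorders, and the truncated table is always a prefix of the full
  ranking.
* Every stochastic fixture takes an explicit integer seed; there is no
  hidden global RNG state (`withr::with_seed` scopes all generator
  randomness).
* Degenerate inputs are distinct, named conditions: an empty phenotype
  list, zero mapped terms, zero surviving variants, and an empty scored
  set each raise a typed error with a remediation hint (the CLI maps them
  to exit code 3, input/validation errors to 2).

## Known limitations

* The network contains only established disease–gene relationships, so the
  method cannot nominate novel disease genes, and it does not expand the
  search through gene–gene relationships (e.g. protein–protein binding).
* The score cannot distinguish a disease connected to many unspecific
  phenotypes from one connected to a few specific ones; the trade-off is
  set by `a` and `b`.
* Mapping is exact-after-normalization; misspelled free text simply fails
  to map (and is reported), rather than being fuzzy-corrected.
* ACMG classification, annotation frequencies and gene assignment are
  consumed from the sidecar as given; no annotation is computed.
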