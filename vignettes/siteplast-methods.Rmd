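---
title: "Quantifying functional-site plasticity in domain superfamilies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying functional-site plasticity in domain superfamilies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siteplast)
```

## The question and the measurement

Homologous protein domains are routinely assumed to carry their functional
sites — catalytic residues, and binding sites for proteins, nucleic acids
and small ligands — at equivalent spatial locations, which is what makes
homology transfer of site annotations work. siteplast quantifies how far
that assumption holds across a domain superfamily. The measurement is a
mapping protocol: choose one member as the superfamily *representative*,
structurally align every member to it, and project each member's annotated
site residues onto the representative positions they align with. A site
residue that aligns to a gap has no equivalent in the representative frame
and is ignored. Everything downstream is a summary of the resulting
per-position contributor sets:

* **Coverage** — the fraction of representative positions touched by at
  least one member's site of a given type. High coverage means different
  relatives use different parts of the common fold.
* **Preferential colocation** — the maximum, over positions, of the
  fraction of sequence subfamilies (s60 clusters) with a site at that
  position. High values mean one location is shared by most subfamilies.
* **Structural diversity** — the number of structural clusters at a
  normalised-RMSD cutoff, and its relationship with coverage.
* **Conservation enrichment** — whether conserved alignment columns of
  functional families are enriched in known functional residues, so that
  conservation can stand in for missing site data.

## Stages and their parameters

**Subfamily (s60) clustering.** Members are clustered greedily,
longest-first, at 60% pairwise sequence identity; identity is counted over
a global Needleman–Wunsch alignment (BLOSUM62, gap opening 10, extension
0.5) and divided by the shorter sequence length — the convention of the
common greedy clustering tools. Superfamilies with a single s60 cluster
carry no information about between-subfamily diversity and are excluded.

**Representative selection.** Each s60 cluster has a representative (its
first member by id unless supplied); all cluster representatives are
aligned pairwise and the domain with the highest cumulative similarity
score is chosen, ties breaking to the smallest id. This picks the member
most structurally central to the superfamily, which minimises misalignment
during mapping.

**Pairwise structural alignment.** The aligner is an iterative
superposition–dynamic-programming scheme over CA atoms. A residue
correspondence is seeded from a global sequence alignment (or, without
sequences, from the best gapless offset of centroid-distance profiles),
then iterated: rigid Kabsch superposition on the current pairs, a score
matrix $s(i,j) = 1/(1 + (d_{ij}/d_0)^2)$ with $d_0 = 3.8$ Å (one CA–CA
bond), global dynamic programming with a linear gap penalty of 0.1, and
re-pairing, until the pair set stabilises (at most 20 iterations, with a
warning and best-so-far result otherwise). Two refinements matter for
conformationally diverse pairs:

* the superposition frame is fitted only on pairs within $2 d_0$ of each
  other under the previous frame (when at least 20 such pairs exist), so a
  rigid core is matched at noise level even when part of the chain has
  swung away on a hinge;
* the iteration is started from several seeds — the full sequence seed and
  its three thirds — and the candidate with the most tightly fitting pairs
  wins. A single seed can self-lock into a shifted register when the
  initial compromise fit leaves every distance large; a fragment seed
  anchored in the rigid part escapes that local optimum.

Reported RMSD is always the optimal full-pair superposition. The
similarity score, $100 \cdot (n_{aligned}/\max(L_a, L_b)) \cdot
1/(1 + (\mathrm{RMSD}/d_0)^2)$, is 100 exactly for a self-alignment,
decreases in RMSD, increases in alignment length, and is symmetric — only
its ranking is consumed downstream. Alignment output is symmetric in its
arguments (internally the pair is ordered canonically) and pairs never
cross. Dynamic-programming ties resolve toward the diagonal, which keeps
self-alignments exactly on the identity pairing.

**Normalised RMSD and structural clustering.** Structural similarity
between two domains is RMSD × (length of the larger domain) / (number of
aligned pairs), penalising short alignments between long domains. Domains
are clustered by single linkage — two domains share a cluster iff they are
connected by a chain of pairs strictly below the cutoff — at 9.0 Å (the
diversity call) and 5.0 Å. Single linkage is the one linkage whose
clusters coincide with connected components of the thresholded graph,
which is also how the tests verify it. A superfamily is *structurally
diverse* when it has at least 2 clusters at 9.0 Å.

**Coverage filters.** Two confounders are filtered before interpreting
coverage: representatives shorter than 100 residues (small denominators
make coverage trivially high), and superfamilies where a single member by
itself covers more than 50% of the representative (strictly greater; such
coverage reflects one promiscuous domain, not diversity between members).
A superfamily with members but no site data of the requested type scores
coverage 0 and is kept; the separate `no_site_data` exclusion applies only
to superfamilies with no site data of any type, in the dataset-accounting
ledger. Coverage's denominator is the full representative length,
including positions some members do not align to, per the definition.

**Colocation.** A cluster "has a site at position p" when any of its
members contributes there; the denominator counts clusters possessing at
least one annotation of that site type — including clusters whose
annotated residues all map to gaps (they have data; they simply hit
nothing; counting them is conservative toward under-sampling). Only
superfamilies with at least 10 clusters with data are included, to avoid
meaningless fractions (a majority of 2 clusters is one cluster).

**Conservation.** Functional-family alignments are scored per column with
a Valdar-style weighted sum of pairs: Henikoff position-based sequence
weights (normalised to mean 1, gap treated as a 21st symbol) and a pair
similarity $m(a,b) = \max(0, B62(a,b)) / \sqrt{B62(a,a)\,B62(b,b)}$, with
gap-involving pairs scoring 0. This normalisation was chosen over plain
min–max scaling of BLOSUM62 because it satisfies both boundary contracts
at once: every identical pair scores exactly 1 (so an identity column
scores 1.0 regardless of residue), and a column uniform over the 20 amino
acids scores about 0.08. Exact duplicate rows are collapsed before
scoring — identical redundant sequences add no evidence, and collapsing
them makes scores exactly invariant to row order and to concatenating the
alignment with itself. Columns scoring ≥ 0.7 are called conserved; the
threshold is the conventional empirical choice and its transferability to
any particular scorer is a calibration question, not a constant of nature.
Fragment sequences — ungapped length strictly below 80% of the family mean,
the mean computed once before any removal — can be dropped first, which
sharpens conservation at genuinely constrained columns. Conserved columns
project back onto each member's residues (skipping gapped positions) as a
`conserved` site type that maps like any experimental annotation.

**Enrichment.** Per family, $P_c$ is the fraction of conserved residues
that are functional, $P_a$ the fraction of all residues that are
functional, and $E = P_c - P_a$. Families without conserved residues have
undefined $P_c$ and are excluded with a count. The test of whether
conserved residues are enriched is a one-sided Wilcoxon rank-sum of the
$P_c$ values against the $P_a$ values; family values can first be averaged
(unweighted) within superfamilies. The rank-sum wrapper uses the exact
distribution when both samples have ≤ 25 tie-free observations and the
normal approximation with tie and continuity correction otherwise; no
multiple-testing correction is applied by default, matching the practice
of reporting raw per-site-type p-values. Hub superfamilies are flagged
when any member's parent protein has ≥ 10 physical interactions.

## The synthetic-data generator

Real inputs (curated catalytic residues, interface residues from
structural databases, superfamily tables) are large, versioned and
unavailable at desk scale, so validation runs end-to-end on seeded
synthetic superfamilies with planted ground truth
(`make_superfamily()`). A superfamily is built from one compact
self-avoiding CA template (bond length exactly 3.8 Å, non-bonded contacts
> 2 Å): each cluster gets an archetype (template + per-coordinate Gaussian
noise of 1.5 Å, sequence mutated toward a 35% between-cluster identity
target), and each member adds 0.5 Å within-cluster noise, a sequence at
90% within-cluster identity, an optional inserted surface loop, and a
random rigid transform. Sites are planted in the template frame: per site
type a contiguous *preferred footprint* used by a fraction *f* of
clusters, plus *scattered* cluster-specific positions. Scattered positions
are drawn outside the preferred footprint — otherwise chance hits on the
footprint would inflate the recovered colocation fraction beyond the
planted *f*, and the generator's job is to make *f* the truth. The default
layout (12 clusters × 2 members, 120-residue template, a 12-residue
interface footprint at *f* = 0.8 with 3 scattered positions, a universal
catalytic triad, a half-shared ligand pocket) is the standard condition
under which all recovery statistics are quoted.

Structural diversity is planted as a hinge: designated clusters rotate
their distal segment (beyond 55% of the chain) by 150° about a random
axis, which puts cross-conformation normalised RMSD well above the 9 Å
cutoff while the proximal core still superposes. In the cohorts used for
the diverse-vs-similar comparison, sites are planted only in the proximal
region: the mapping is then equally accurate in hinged and unhinged
superfamilies, so *null* cohorts (no planted coverage difference) reject
at the nominal rate. This choice is deliberate — when sites are planted in
the moving segment, cross-conformation mapping noise alone inflates
diverse-group coverage, which is a real confound of the measurement, not a
test artefact; the null cohorts isolate the statistic from it. *Effect*
cohorts additionally give hinge clusters inserted loops and extra core
patches anchored near their decorations: residues planted on the loops
themselves map to gaps and are knowingly lost (the representative lacks
the decoration), so the measurable effect is carried by the core patches.

What the generator does not emulate: real side-chain packing and
energetics, correlated (non-isotropic) structural divergence, alignment
ambiguity from repeats or domain swaps, database-scale annotation bias,
and realistic sequence evolution (mutations are uniform). Passing
recovery tests therefore shows the pipeline measures what it defines on
data matching its assumptions — not that real superfamily estimates carry
the same accuracy.

## Numerical and design choices

* Positions are 1-based dense indices in file order (the natural R
  convention); file-facing residue identity is always author numbering
  with chain and insertion code. Only CA atoms are used; multi-model files
  contribute their first model; alternate locations resolve to the
  highest occupancy (ties: first in file).
* Determinism: all generators take integer seeds and derive per-unit
  sub-seeds, alignment and clustering are tie-broken deterministically,
  and `run_all()` on identical inputs yields byte-identical summary
  tables.
* Strictness at boundaries follows the definitions: dominance is
  excluded strictly above 0.5, fragments are removed strictly below 0.8 ×
  mean, high coverage counts strictly above the threshold, conserved
  columns include the threshold value, hub counts include 10, and a
  structural-cluster chain requires normalised RMSD strictly below the
  cutoff.
* Heat-map binning uses the conventional scale — exactly 0 grey, then
  half-open bins (0–20)% blue, (20–40)% green, (40–60)% yellow, (60–80)%
  orange, (80–100]% red — with boundaries assigned upward.
* Precomputed alignments (e.g. converted output of an external structural
  aligner) can replace the built-in aligner through the interchange TSV;
  given identical correspondences all downstream results are identical.

## Problem sizes used in validation

The shipped tests and the acceptance script run at sizes chosen to make
every statistic measurable with comfortable margins on a single CPU:
oracle equivalence on 240 randomised small instances; preferred-fraction
recovery at *f* ∈ {0.3, 0.5, 0.8} over 20 seeded superfamilies each
(12 clusters × 2 members); the diverse-vs-similar direction over 20
effect cohorts of 40 superfamilies, with 100 matched null cohorts for the
type-I rate (100 rather than 20 because a rejection rate estimated from
20 cohorts has granularity 0.05 and cannot sit reliably inside a
[0.01, 0.12] band); and 20 replicates each for the enrichment and
fragment-removal directions.

## Known limitations

The aligner is a CA-level stand-in with the contract downstream stages
need (deterministic, symmetric, sequential, accurate on noisy copies); it
is not a replacement for full structure aligners on remote homology, and
with conformational change its mapping in the moving region is
unavoidably noisy. The conservation threshold of 0.7 is calibrated to
this scorer's scale only in the sense that identity columns score 1 and
random columns near 0.08. Functional-family construction, database
retrieval and curation, interaction-network assembly and GO analyses are
all upstream of this package: family tables, annotations and interaction
counts are inputs, assumed pre-filtered.
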