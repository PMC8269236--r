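---
title: "Homolog-aware functional gene profiling with tiered reference databases"
author: "FamPath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homolog-aware functional gene profiling with tiered reference databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FamPath)
```

## The problem: small databases inflate false positives

Profiling a specific biological process from shotgun metagenomes usually
means searching reads against a compact, curated database holding only the
gene families of interest. Compact databases are fast and well annotated,
but they suffer from what practitioners call the *small database issue*:
a read that really originates from a *homolog* of a target family — a
related but functionally different protein — has no better place to land
than the target family itself, and is counted as a false positive. The
effect is severe precisely for processes like cobalamin (vitamin B12)
biosynthesis, where the aerobic (`cob`) and anaerobic (`cbi`) branches share
highly similar enzymes (e.g. `cysG`/`cobA`, `cobH`/`cbiC`, `cobM`/`cbiF`)
and public orthology groups routinely mix several true families.

FamPath implements the remedy: alongside the target families, the reference
database deliberately includes *homolog-decoy groups* — sequences similar to
the targets whose only job is to absorb reads that would otherwise be
misassigned. A read is `assigned` when its single best hit is a target,
`homolog_absorbed` when its best hit is a decoy, and `unassigned` otherwise.
Absorption is not loss: it is the mechanism that keeps the functional
profile clean.

## Tiered database construction

The database is built in three tiers, each adding breadth while the seed
anchors accuracy:

1. **Seed** (`buildSeed`): manually curated reference proteins per family.
2. **Core** (`recruitCore`): candidate sequences (e.g. from a large,
   lightly curated protein archive) are globally aligned against the pooled
   seeds of their nominal family *plus all families declared homologous to
   it*, and recruited to the best-hit family at a global identity cutoff of
   30%. Score ties spanning families resolve to the family holding the
   majority of the tied seeds, then lexicographically — deterministic and
   order-independent.
3. **Full** (`attachHomologGroups`, `mergeRefseqLike`, `dedupExact`):
   orthology groups are classified by searching their members against the
   core: a group with at least half its members hitting one family merges
   into it; a group with at least one member hitting any target becomes a
   homolog-decoy group; others are dropped. Genome proteins are then routed
   to their best-hit family or decoy group (carrying taxonomy), and exact
   duplicates within a family/group are collapsed.

The half-majority rule is this package's automated stand-in for curation
steps that are inherently judgment calls; every group decision is logged
with its evidence (`$report`) so a curator can review and override. Exact
deduplication collapses only byte-identical residue strings within one
label; identical sequences appearing under *different* labels are kept and
flagged, because silently deleting a family's only evidence would be worse
than carrying a duplicate.

## The packaged cobalamin registry

`loadRegistry()` ships 60 cobalamin biosynthesis gene (sub)families
organized into five pathway processes (precorrin-2 synthesis: 8 families;
aerobic: 18; anaerobic: 19; salvage and remodeling: 13; post-AdoCbi-P: 12),
with literature-derived per-family counts of core/full database sequences
and homolog groups per source orthology database. Seven families belong to
several pathways (`cobA` to three of them), so the registry distinguishes
*straight column sums* (178,322 core / 324,044 full sequences, shared
families counted once per pathway) from *deduplicated totals* over distinct
families (168,630 / 287,731; homolog groups 650 + 770 + 17,546 + 2,188 =
21,154). Both are first-class operations (`uniqueFamilyTotal`,
`homologGroupTotals`), and the fixture is validated so the repeated rows of
a shared family carry identical counts. One count cell in the packaged
table was reconciled against its own marginal totals, which disagreed with
the printed per-family entry by one; the marginal reading is the one all
other published aggregates support.

Sub-families with distinct roles keep distinct ids (`cobC-beta` vs
`cobC-ado`, `cobS-co` vs `cobS-gdp`): they are different enzymes that happen
to share a gene symbol.

Pathway rollups of per-family counts are emitted in two share modes,
because the right convention for shared families is genuinely ambiguous:
`replicate` gives a shared family its full count in every member pathway
(pathway totals can exceed the family total), `fractional` splits it
equally (total mass conserved). Both are reported; neither is silently
preferred.

## Alignment and the best-hit contract

Pairwise alignment uses the standard protein toolkit (BLOSUM62, affine gaps
with opening 11 / extension 1, a gap of length $k$ costing $11 + k$).
Global alignments penalize end gaps; identity is *identical residue pairs
divided by all alignment columns including gap and end-gap columns* (local:
columns of the local span only). The convention matters — published
pipelines name their search tools but rarely their identity formula — so
this package fixes one and applies it everywhere.

`bestHit` returns the single highest-scoring reference passing the identity
(and score) thresholds; ties break by higher identity, then smallest
reference id, making results independent of database record order.
Nucleotide reads are translated in six frames (stops `*`, ambiguous codons
`X`) and the best frame wins.

Two threshold defaults deserve explanation:

* `minIdentity = 0.30` is the global-identity recruitment and profiling
  cutoff used throughout.
* `minScore` defaults to 0 in global mode but **50** in local/translated
  mode. A local alignment can have identity 1.0 over a five-residue span;
  without a score floor every read "matches" something. External engines
  suppress such hits with e-values; for the built-in search we use the
  equivalent raw-score floor implied by gapped Karlin–Altschul statistics
  ($\lambda \approx 0.267$, $K \approx 0.041$): at desk-scale query and
  database sizes, $S = \ln(Kmn/E)/\lambda \approx 50\!-\!70$ for
  $E = 10^{-4}$. E-values themselves are honored only in the external
  adapter contract (12-column tabular interchange; a BLAST+ adapter is
  included), where database-size statistics are meaningful.

## The simulator: what it emulates, and what it does not

`simulateReferenceSet` draws one random ancestor per family and derives
members by point substitution down to a sampled identity (default
0.90–0.99). Decoys derive *from the same ancestors* at 0.40–0.60 identity —
this is deliberate: decoys must genuinely attract hits to reproduce the
small-database mechanism, which independent random sequences would not.
Unrelated proteins are i.i.d. background draws. Each family carries a
planted 7-rank lineage; members share it down to genus but get distinct
species, so taxonomic profiles can vary across replicate communities whose
family proportions are fixed. Protein lengths default to 180–240 residues
(typical single-domain bacterial enzymes), reads to 40–70 residues
(~120–210 nt fragments, the scale of merged short-read pairs).

Mutation is substitution-only, so identity to the source is controlled
exactly and ground truth needs no re-alignment. That is also the main
limitation: no indels, no rate heterogeneity, no profile-HMM-like
conservation structure, no sequencing error. Member and decoy identity
tiers are disjoint by default, which makes separability *provable* in tests
— real homologs are messier, so passing these tests demonstrates the
machinery (routing, bookkeeping, determinism), not real-data accuracy.
Published real-data percentages are correspondingly out of scope here.

`makeArtificialEvalSet` reproduces the *design* of the published artificial
evaluation — 143 target-derived, 57 homolog-derived, and 70 unrelated
full-length proteins — not its actual sequences, which are not reprinted in
the source material. Under the default simulator conditions, profiling this
set against the full database assigns exactly the 143 target-derived
queries with zero false positives and zero false negatives, and profiling
against the decoy-free core makes the homolog-derived queries leak in —
the two sides of the small-database story. On real data the published
claim is qualitative ("homologs were not assigned"); here it is exact by
construction.

`smallDbEffect` quantifies the mechanism: reads assigned under the
decoy-free core are re-evaluated under the full database, and the absorbed
fraction is reported. The published magnitude (~52% on five ocean
metagenomes) depends on real community composition and is not reproducible
at desk scale; the package instead fixes the fraction by construction (a
50/50 target/decoy read mix yields 0.5) and verifies monotonicity in the
decoy share. Because the unstated denominator could be read per-family or
overall, both are emitted.

## Statistics

Functional profiles report per-family counts with relative abundance =
count / assigned reads (not total reads, not gene-length-normalized; the
choice is recorded in the object and gene-length normalization was left
out deliberately — fragment reads of near-constant length over same-scale
proteins make it a second-order correction at desk scale). Taxonomic
profiles default to best-hit lineage transfer; an external classifier can
be plugged in.

Community comparison uses Bray–Curtis dissimilarity
($1 - 2\sum_i \min(p_i, q_i) / (\sum_i p_i + \sum_i q_i)$ over the union
support; undefined for two all-zero profiles) and classical PCoA
(double-centering of $-D^2/2$, eigendecomposition, axes scaled by
$\sqrt{\lambda}$). Negative eigenvalues are reported and their axes
dropped; no Lingoes/Cailliez correction is applied by default because the
ordination is descriptive here.

## Numerical and design choices

* **Determinism.** Every generator takes a seed and restores the caller's
  RNG state; repeated runs are byte-identical, and profiles are invariant
  under database record permutation (tested).
* **Tie-breaking.** Scores are integer-valued sums (BLOSUM62 + integer
  penalties), so exact ties are real; they resolve by identity, then
  lexicographic id, then frame order `+1..-3`.
* **Degenerate inputs.** Empty read sets profile to valid empty results;
  zero assigned reads flag the profile rather than dividing by zero;
  empty orthology groups warn and drop; an all-negative local alignment is
  the empty alignment with score 0.
* **Problem sizes.** Tests run the default simulator (10 families × 8
  members, 10 decoy groups) for the evaluation-set check and a 5-family,
  5000-read community for parameter recovery — sizes chosen so a laptop
  reproduces everything in minutes while binomial error bounds are still
  tight (3 standard errors at $n = 5000$ is ±2 points on a 40% family).
* **Candidates failing the recruitment cutoff are discarded** (with a
  logged reason), not shelved: keeping them anywhere else would blur the
  tier semantics.

## Known limitations

* The built-in aligner is exact dynamic programming with no heuristic
  seeding; it is meant for curation-scale and simulation-scale work, not
  for hundred-million-read searches (plug an external engine through the
  adapter for that).
* Decoy groups are attached only at the full tier by design; a "core"
  database is exactly the full database minus decoys.
* Lineage transfer inherits whatever taxonomy the reference carries;
  references without lineage at the requested rank count as unclassified
  rather than being interpolated.
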