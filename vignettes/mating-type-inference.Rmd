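---
title: "Inferring tetrapolar mating types from hybridization compatibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring tetrapolar mating types from hybridization compatibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mti)
```

## The inference problem

Tetrapolar basidiomycetes — including most cultivated edible and
medicinal mushrooms such as *Flammulina velutipes* — control sexual
compatibility through two unlinked multiallelic mating-type loci, A and
B. A cross between two monokaryons is fertile (forms a clamped dikaryon)
only when the partners carry different alleles at *both* loci. Breeding
programs therefore need the (A, B) allele assignment of every monokaryon
in a collection, but the assignment is not observed directly: what wet
lab work produces is

1. a **parent table** — which dikaryon each protoplast-derived
   monokaryon came from; the two monokaryons of one dikaryon (a *sibling
   pair*) necessarily differ at both loci;
2. a **compatibility matrix** — for each tested pair, whether clamp
   connections formed (`compatible`) or not (`incompatible`);
3. an **A/B loci consistency table** — for incompatible pairs assayed on
   oak-wood-extract / squeezed-orange-juice (OWE-SOJ) media, whether the
   colony phenotype indicates common A with different B, common B with
   different A, or commonality at both loci.

Formally an assignment is one set partition of the strains per locus:
two strains in the same A-class carry the same A allele. The package
infers the partitions that best explain the observations, for any number
of strains, and reports *all* co-optimal assignments in a canonical
(restricted-growth) labeling.

## The consistency score

Each observed unordered pair contributes locus-level checks worth ±1:

* a **compatible** pair expects *different* at A and *different* at B
  (two checks, contribution −2…+2);
* an **incompatible** pair *with* an OWE-SOJ record expects the record's
  relations, e.g. common-A/different-B (two checks);
* an **incompatible** pair *without* a record carries a single
  compatibility-level check: +1 if the candidate assignment shares an
  allele at A or at B (predicting incompatibility), −1 otherwise;
* an unobserved pair contributes 0.

The maximum achievable score is 2 per fully informed pair and 1 per
record-less incompatible pair. A complete, fully consistent population
of *n* strains therefore scores 2·C(*n*, 2) — 870 for the reference
design of 30 monokaryons from 15 dikaryons, with all 435 pair
observations satisfied.

A note on conventions: counting one ±1 compatibility check plus one ±1
OWE-SOJ check per pair would cap a 30-strain dataset at 445 and break
the 2·C(30, 2) identity; the two-locus-checks form used here preserves
it. Counting a single check per *ordered* pair instead (30·29 = 870) is
indistinguishable — both yield identical optima.

## The combinatorial pruning traversal

Exhaustive enumeration scores every pair of set partitions and is
hopeless beyond a dozen strains (Bell numbers grow super-exponentially).
The package exploits the structure of real populations, where most
crosses are compatible:

1. **Starting pair.** The two monokaryons of the lexicographically first
   two-strain dikaryon (or a user-chosen sibling pair) are fixed as
   A1B1/A2B2.
2. **Clique seeding.** Strains observed compatible with every member so
   far are greedily added (identifier order) and given fresh, mutually
   distinct alleles. For a pairwise-compatible sub-population this is
   exactly the optimum, so only strains entangled in incompatibilities
   remain.
3. **Branch-and-bound.** Remaining strains are traversed depth-first,
   most-conflicted first (descending incompatible-observation count,
   ties by identifier). At each strain and each locus, the admissible
   moves are: take a fresh allele; join an existing class; or unite
   several existing classes (a *merge move*). A branch is abandoned only
   when its partial score plus the maximum contribution of every pair
   touching an unassigned strain cannot reach the best score found —
   co-optimal ties are never pruned.

### Why allele sharing requires evidence

Under the default `evidence` policy (`EVIDENCE_REQUIRED`), two strains
may sit in one allele class at a locus only if OWE-SOJ "same" records
connect the class: every class must be connected in the graph whose
edges are same-locus records. This is deliberately an *order-free*
class-level criterion rather than a per-strain rule. A per-strain rule
("join a class only if you have a direct record into it, in traversal
order") would make reachability depend on the traversal order: a class
{x, y, z} whose records are x–z and y–z only cannot be assembled when z
is visited last. The merge moves close exactly this gap — z, holding
records into both the class of x and the class of y, unites them — so
the search enumerates precisely the record-connected partitions
regardless of order. The exhaustive oracle applies the same class-level
criterion as an independent connectivity filter, and the two engines
are required to agree on the full co-optimal set in the test suite.

The `free` policy drops the evidence requirement and enumerates every
set partition at both loci (no clique fixing, since with contradictory
observations an optimal explanation may regroup even mutually compatible
strains). Its search space is the full Bell(n)² grid, so it is guarded
to at most 10 strains and intended for verification against the
brute-force oracle, which is itself guarded at n = 8 (Bell(8) = 4140;
about 17 million scored partition pairs).

### Suspect-record flagging

A pair whose contribution is negative in *every* co-optimal assignment
cannot be satisfied by any optimal explanation of the data; the record
itself is then suspect. Pairs observed incompatible are flagged
`possible_false_negative`, others `inconsistent`. When the best score
equals the maximum achievable score the flag list is necessarily empty —
which is exactly why false positives are undetectable (below).

## Synthetic populations and what they emulate

`generate_population()` builds populations of 2·`n_dikaryons` strains
with the sibling constraint (each dikaryon's two monokaryons differ at
both loci) in three modes:

* **`all_distinct`** — every strain unique at both loci; every
  non-sibling cross compatible. This is the clean analytic setting in
  which score identities are exact: a complete error-free dataset has
  maximum 2·C(n, 2), and each injected false negative lowers the
  achievable maximum by 1 and the truth's score by 3.
* **`pools`** — alleles drawn uniformly from pools of `a_pool`/`b_pool`
  distinct alleles (sibling draws rejected until valid). Sharing — hence
  incompatibility — arises naturally as pools shrink; pool sizes around
  6, 9 and 20 give expected compatibility rates near 70%, 80% and 90%
  ((1 − 1/pool)² per pair). Used for the traversal-size experiments.
* **`paired`** — all-distinct alleles, then 6 disjoint non-sibling
  strain pairs share an A allele and 4 further disjoint pairs share a B
  allele (defaults). With 15 dikaryons this yields 30 strains, 24 A and
  26 B alleles, and exactly 10 incompatible pairs among 435 — emulating
  the compatibility structure of a typical 30-monokaryon *F. velutipes*
  collection (410 compatible / 10 incompatible of 420 tested pairs).
  Every shared class has exactly two members, which keeps the
  record system free of expectation triangles; this is the regime in
  which a single false positive always admits a perfect-scoring
  (wrong) optimum. A population with an allele class of three or more
  members whose internal record is deleted by a false positive leaves an
  inconsistent same/same/different triangle and a best score strictly
  below the maximum — real data with larger classes can therefore
  partially betray a false positive, something the paired preset
  deliberately does not model.

What the generator does **not** emulate: genuinely missing observations
(derived matrices are complete), mis-scored OWE-SOJ phenotypes (records
always reflect true identities unless deleted by a false positive),
linkage or population structure between loci, and uneven allele
frequencies. Passing tests on these populations demonstrate the
correctness of scoring and search, not robustness to every failure mode
of bench data.

## Error-perturbation experiments

`inject_errors()` perturbs a derived dataset the way bench errors would:
a **false positive** rewrites a truly-incompatible pair as compatible
and deletes its OWE-SOJ record (a pair scored compatible would never
enter the assay); a **false negative** rewrites a truly-compatible
non-sibling pair as incompatible and attaches no record (sibling pairs
are recorded compatible without testing, so they cannot be false
negatives). `run_error_experiment()` sweeps error type × count ×
replicate and records, per replicate, the best/maximum/truth scores, the
number of co-optimal assignments, whether the truth is among them, and
whether the flagged pairs identify the injected ones exactly.

Two sharply different regimes emerge. A single false negative leaves the truth as the unique optimum
(score 870 − 3 = 867 on the 30-strain all-distinct population, against a
ceiling of 869) and is flagged exactly. Under the evidence policy this
uniqueness persists for any number of record-less false negatives —
no evidence licenses the alternative merges — whereas an unrestricted
search would tie the truth with assignments that "explain" an injected
incompatibility by sharing an allele; both behaviors are available via
the policy switch, and the uniqueness claim is documented as
policy-dependent rather than forced. A single false positive instead
always yields a perfect-scoring optimum different from the truth, with
nothing flagged: the corrupted dataset is internally consistent, so the
error is fundamentally undetectable from compatibility data alone.

## Numerical and design choices

* **Scale of routine verification.** The oracle-agreement property uses
  200 random populations of 4–6 strains (pool sizes 3–6, up to one
  false positive and two false negatives), both policies each — small
  enough that the exhaustive oracle enumerates its full grid, large
  enough to exercise merges, ties and all record patterns. The
  perturbation experiments use 50 replicates per condition; the
  traversal-size comparison uses 12-strain populations (9 replicates
  per compatibility rate at 70/80/90/100%), where the unpruned
  traversal is still enumerable.
* **Determinism.** Every stochastic routine takes an explicit seed and
  restores the caller's RNG state. Traversal order, candidate order,
  canonical labeling and output ordering (lexicographic on label
  sequences) are all fixed, so identical inputs give byte-identical
  results and strain input order never changes the canonical optima.
* **Degenerate inputs.** Missing pairs are warnings and score 0 — they
  weaken evidence, they do not bar inference. Sibling pairs absent from
  the matrix are auto-recorded compatible (with a warning), mirroring
  the practice of recording them without testing. A dataset with scan
  errors (sibling pair recorded incompatible, a record claiming
  different at both loci, unknown strains) is refused by
  `infer_mating_types()`.
* **Co-optima cap.** All co-optimal assignments are collected up to
  `max_optima` (default 100) with an explicit truncation flag; datasets
  riddled with false negatives can otherwise tie combinatorially many
  explanations.
* **Traversal-size reporting.** `n_enumerated` counts candidate leaves
  examined. No quantitative claim is attached to absolute
  combination-space sizes — they depend on exactly which strains the
  incompatibilities entangle; the package instead verifies the
  qualitative law that the traversal shrinks monotonically as the
  compatibility rate rises (and collapses to a single leaf at 100%).

## Worked example

```{r}
parents <- parent_table(c("s1", "s2", "s3", "s4"),
                        c("D1", "D1", "D2", "D3"))
m <- compat_matrix(
  strain_a = c("s1", "s1", "s1", "s2", "s2", "s3"),
  strain_b = c("s2", "s3", "s4", "s3", "s4", "s4"),
  result   = c(rep("compatible", 5), "incompatible"),
  strains  = parents$strain_id)
lt <- loci_table("s3", "s4", "same", "different")  # common A, different B
ds <- mti_dataset(parents, m, lt)

summarize_dataset(ds)
infer_mating_types(ds)
```

The unique optimum shares one A class between `s3` and `s4` (as the
OWE-SOJ record demands), keeps all four B alleles distinct, and attains
the maximum achievable score 12 = 2 × 6 pairs.

## Limitations

* The score is a pure integer consistency count; there is no
  likelihood model, no per-record error rate, and no confidence measure
  on the inferred classes beyond co-optimality multiplicity.
* The evidence policy cannot propose allele sharing for incompatible
  pairs that were never assayed on OWE-SOJ media; such pairs can only
  be flagged, not resolved.
* Worst-case search cost remains exponential in the number of
  mutually entangled incompatible strains; the method is fast precisely
  because real monokaryon populations are predominantly compatible.
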