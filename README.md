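# mti — mating-type inference for tetrapolar fungi

`mti` infers the A/B mating-type allele assignment of monokaryon strains
of tetrapolar basidiomycetes (most cultivated edible and medicinal
mushrooms, e.g. *Flammulina velutipes*) from pairwise hybridization
data. It is aimed at fungal breeders and population geneticists who have
crossed a collection of protoplast-derived monokaryons and recorded, per
pair, whether clamp connections formed — and, for incompatible pairs,
the OWE-SOJ colony phenotype distinguishing common-A from common-B
relationships.

## The model

In a tetrapolar mating system a cross is fertile iff the partners differ
at both multiallelic loci A and B. A mating-type assignment is one set
partition of the strains per locus (same class = same allele). Given

* a parent table (each dikaryon's two monokaryons — *sibling pairs* —
  differ at both loci),
* a compatibility matrix over unordered pairs
  (`compatible`/`incompatible`/missing), and
* an A/B loci consistency table for assayed incompatible pairs
  (A=B≠, A≠B=, or A=B=),

each candidate assignment receives an integer consistency score: per
observed pair, ±1 for each locus-level expectation it matches or
violates (compatible ⇒ different at A and at B; an OWE-SOJ record ⇒ its
recorded relations), and a single ±1 compatibility check for
incompatible pairs without a record. A complete, fully consistent
*n*-strain dataset attains 2·C(*n*, 2) — 870 for the reference design
of 30 monokaryons from 15 dikaryons. The inference problem is to find
**all** maximum-score assignments.

The optimum is found by a combinatorial pruning traversal: a starting
sibling pair is fixed as A1B1/A2B2, a greedy maximal pairwise-compatible
sub-population is given fresh distinct alleles, and the remaining
(conflict-entangled) strains are resolved by an exact branch-and-bound
whose moves at each locus are *fresh allele*, *join an
evidence-supported class*, or *merge several evidence-supported
classes*. Under the default `evidence` policy, allele classes must be
connected through OWE-SOJ "same" records; a `free` policy (and a
brute-force partition-grid oracle) exists for verification on small
instances. Pairs that score negatively in every co-optimal assignment
are flagged as suspect records (`possible_false_negative` /
`inconsistent`).

## Worked example

Four strains; `s1`/`s2` are siblings from dikaryon `D1`; every cross is
compatible except `s3 × s4`, whose OWE-SOJ assay shows common A with
different B:

```r
library(mti)

parents <- parent_table(c("s1", "s2", "s3", "s4"),
                        c("D1", "D1", "D2", "D3"))
m <- compat_matrix(
  strain_a = c("s1", "s1", "s1", "s2", "s2", "s3"),
  strain_b = c("s2", "s3", "s4", "s3", "s4", "s4"),
  result   = c(rep("compatible", 5), "incompatible"),
  strains  = parents$strain_id)
lt <- loci_table("s3", "s4", "same", "different")
ds <- mti_dataset(parents, m, lt)

summarize_dataset(ds)
#> Hybridization dataset summary
#>   strains: 4 (from 3 dikaryons)
#>   pairs: 6 total = 1 sibling + 5 tested + 0 missing
#>   observed: 5 compatible (4 tested), 1 incompatible
#>   compatibility rate: 0.833; OWE-SOJ records: 1

res <- infer_mating_types(ds)
res
#> Mating-type inference (evidence policy)
#>   best score: 12 of 12 achievable
#>   co-optimal assignments: 1
#>   allele classes (first optimum): 3 A, 4 B
#>   candidate leaves examined: 2

res$assignments[[1]]
#> mti_assignment over 4 strains: 3 A alleles, 4 B alleles
#>   s1   s2   s3   s4
#> A1B1 A2B2 A3B3 A3B4
```

The unique optimum satisfies all six pair observations (12 = 2 × 6):
`s3` and `s4` share an A allele exactly as the record demands, and all
four B alleles are distinct.

Simulation utilities reproduce the method's error-sensitivity analysis:
`generate_population()` / `derive_observations()` build synthetic
populations with known truth, `inject_errors()` plants false-positive or
false-negative records, and `run_error_experiment()` sweeps error type ×
count × replicate. A single false negative leaves the truth as the
unique, exactly flagged optimum; a single false positive always produces
a perfect-scoring *wrong* optimum and is undetectable — so false
positives must be rigorously excluded at the bench. See the vignette
`vignettes/mating-type-inference.Rmd` for the scoring conventions,
policy semantics and experiment design.

A command-line interface wrapping the same functions is installed at
`system.file("cli/mti.R", package = "mti")` with subcommands `validate`,
`stats`, `infer` and `simulate`.

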