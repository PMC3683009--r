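# rdcascade

Exome-based molecular diagnosis of recessive retinal dystrophies (RD):
a tested, reusable implementation of a five-step variant filtering cascade,
a recessive-model candidate-gene caller with known/novel mutation
annotation, and an exact Mendelian cosegregation test — together with a
seeded synthetic exome cohort generator that emulates a 12-family study
design so the whole pipeline can be exercised end to end without any
sequence data.

## Who this is for

Clinical genetics and rare-disease groups prioritising variants from
whole-exome sequencing (WES) of a single index patient per family, under a
recessive (or X-linked) inheritance model, when no genotypes from other
family members are available at the screening stage. The same filtering
logic applies to any Mendelian recessive condition with a curated
disease-gene panel; the defaults here are tuned to retinal dystrophy.

## The method

Starting from the called, annotated variant set of one index patient
(~67,000 variants per exome), the cascade applies five filters in order:

1. **Coding / non-silent** — keep missense, nonsense, frameshift and
   in-frame indels, and splice-site substitutions; drop noncoding and
   synonymous changes (~12,000 survive).
2. **Disease-gene panel** — keep variants in the 160 known RD genes
   (typically 108–143 survive).
3. **Allele frequency** — remove variants catalogued with frequency
   strictly above 0.02; rare and uncatalogued variants, and catalogued
   sites with no recorded frequency, are retained (18–34 survive).
4. **Recessive model** — a gene is a candidate if it carries a homozygous
   variant (AR), two distinct heterozygous variants assumed in trans
   (AR compound het), or — in a male — any variant in a chrX gene
   (hemizygous, X-linked).
5. **Known/novel annotation** — each supporting variant is checked against
   a catalog of published mutations on `(gene, HGVS c.)`.

Candidate alleles can then be tested for cosegregation with disease in the
family. For a sibship with obligate-carrier parents, the package enumerates
every transmission vector (4 per child under AR: paternal allele × maternal
allele; 2 per child under XL) and reports the fraction consistent with all
observed genotypes and phenotypes. For *a* affected compound-heterozygous
and *u* unaffected siblings this equals the closed form
(1/4)^a · (3/4)^u; an informative sibship of 3 affected + 3 unaffected
gives 27/4096 ≈ 0.0066, i.e. 0.006 truncated to three decimals.

## Worked example

```r
library(rdcascade)

cohort <- generate_cohort(generator_params(seed = 1))
results <- run_cohort(cohort)
summarize_cohort(results, cohort$mutation_catalog)
#> # rd_cohort_summary: 10 of 12 families solved (83%)
#>   17 distinct candidate mutations, 10 novel
#> # A tibble: 6 × 2
#>   gene   n_families
#>   <chr>       <int>
#> 1 ABCA4           3
#> 2 CNGB3           2
#> 3 RP1             2
#> 4 USH2A           2
#> 5 CHM             1
#> 6 NMNAT1          1
```

Ten of the twelve synthetic families are solved (83%): the cascade
recovers every planted causal genotype, the two families that carry no
panel-gene mutation yield no candidates, and one family shows a second,
spurious compound-heterozygous candidate (USH2A) alongside its true
homozygous CNGB3 mutation — which is why the summary counts 17 candidate
mutations while the curated catalog holds 15. Per-patient traces:

```r
glance(results[["07-0366"]])
#> # A tibble: 1 × 8
#>   patient_id n_total n_coding_nonsilent n_in_panel n_rare n_candidate_variants
#>   <chr>        <int>              <int>      <int>  <int>                <int>
#> 1 07-0366      67128              11898        141     34                    1
#> # ℹ 2 more variables: n_candidate_genes <int>, solved <lgl>
```

Cosegregation in the informative six-sibling family:

```r
seg <- segregation_probability(cohort$pedigrees[["RP-1263"]], model = "AR")
seg
#> # rd_segregation (AR model): p = 0.0065918 (27 of 4096 transmission vectors,
#>     6 children, index included)
truncate_probability(seg$probability)
#> [1] 0.006
```

A small probability means the observed perfect cosegregation is unlikely
under chance transmission, supporting causality of the candidate alleles.

A command-line front end over the same functions is installed at
`inst/cli/rdcascade.R` (subcommands `simulate`, `filter`, `cosegregate`,
`report`, `run-all`).

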