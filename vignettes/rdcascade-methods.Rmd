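---
title: "Methods: recessive exome filtering, cosegregation, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recessive exome filtering, cosegregation, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdcascade)
```

rdcascade implements a molecular-diagnosis workflow for autosomal recessive
and X-linked retinal dystrophies (RD) based on whole-exome sequencing of a
single index patient per family. This vignette is the package's account of
the model behind each stage, the tunable parameters and their defaults, the
numerical and design choices that were genuinely open, and what the
synthetic cohort does and does not demonstrate.

## The filtering model

The pipeline starts from *called, annotated* variants — gene symbol and
consequence class are consumed as annotations (a single `CSQ_CLASS` INFO
key), not computed from transcripts, because in this design variant calling
and annotation are upstream services. The cascade is a composition of pure
set-filters followed by a per-gene genotype model:

* **Step 1 — consequence.** Keep `missense`, `nonsense`,
  `frameshift_indel`, `inframe_indel`, `splice_site`; drop `synonymous` and
  `noncoding`. Splice-site status is a pre-assigned class (by the
  generator's convention, the canonical ±2 intronic dinucleotide); the
  window is deliberately not recomputed here.
* **Step 2 — panel.** Keep variants whose gene is in the disease panel
  (default: 160 RD genes).
* **Step 3 — frequency.** Remove a variant only when the frequency catalog
  contains its exact `(chrom, pos, ref, alt)` **and** records a frequency
  **strictly** greater than `af_threshold` (default 0.02, i.e. 2%). Two
  edge cases are resolved conservatively in favour of retention:
  a catalogued site *without* a recorded frequency is kept (it cannot
  satisfy "frequency above threshold"), and a frequency exactly at the
  threshold is kept (strict inequality). Both choices only ever retain
  more candidates for downstream scrutiny.
* **Step 4 — recessive model.** Per gene: `AR_homozygous` if ≥1 homozygous
  variant; `AR_compound_het` if ≥2 distinct heterozygous variants;
  `XL_hemizygous` if the patient is male, the gene is on chrX, and ≥1
  variant is present. Compound heterozygotes are called *without phase* —
  an index-only analysis cannot phase, so two heterozygous variants in one
  gene are assumed in trans and left to cosegregation/validation. Male chrX
  calls are treated as hemizygous regardless of the VCF genotype encoding
  (callers typically emit `1/1` there); this is why a single X-linked
  frameshift still satisfies a "two alleles" recessive filter.
  Pseudo-autosomal regions are ignored (no PAR gene is in the panel). A
  gene with more than two qualifying variants yields one candidate listing
  all of them. Candidates are reported sorted by gene symbol.
* **Step 5 — annotation.** A supporting variant is flagged `known` iff its
  `(gene, HGVS c.)` matches a catalog record with status `known`. The
  bundled catalog transcribes the emulated study's mutation table, which
  contains both previously described mutations and that study's own (then
  novel) discoveries; only the former count as known. A later, larger
  catalog release can be attached as a second annotation, but is never
  used to *remove* variants — it post-dates the filtering design.

Steps 1–3 are pure predicates on independent fields, hence monotone,
idempotent, and pairwise commutative; the tests assert all three
properties on random exomes, and check step 4 against a brute-force
enumeration oracle on small exomes.

"Solved" at the cohort level means ≥1 candidate gene after step 5. This
deliberately counts a patient with a spurious second candidate as solved —
discriminating among candidates is the job of cosegregation and validation,
not of the cascade.

## Exact cosegregation

For a candidate gene, the package computes the probability that Mendelian
transmission alone produces the observed genotype/phenotype configuration
in the family. Parents are modelled as obligate carriers with known phase
(father carries allele A, mother allele B) — the standard assumption for a
recessive family ascertained through an affected child. Each child then
has 4 equiprobable transmissions under AR (2 under XL, maternal X), and
the probability is the consistent fraction over the full enumeration
(`4^n` vectors for `n` children; capped at `n = 12`, far beyond any
realistic genotyped sibship). Consistency requires every *genotyped*
member to match their observed carrier states and every member's affected
status to match the model: affected ⇔ both alleles under AR; affected ⇔
mutant X in males under XL, with females never affected (no
skewed-inactivation modelling). Consanguinity loops are out of scope.

When each affected sibling must be compound heterozygous and each
unaffected sibling must not be, the enumeration collapses to the closed
form `(1/4)^a (3/4)^u`, which the tests verify over a grid, along with the
normalisation (probabilities over all mutually exclusive child genotype
configurations sum to 1) and an allele-dropping Monte-Carlo cross-check.

Two reporting conventions matter when comparing with quoted values:

* `include_index` defaults to `TRUE`. For the informative six-sibling
  family (3 affected including the index, 3 unaffected) this gives
  `27/4096 ≈ 0.0066`; excluding the index gives `27/1024 ≈ 0.026`. The
  package exposes the flag; the default is the convention under which the
  three-decimal truncation reproduces the conventionally quoted `0.006`.
* Probabilities are carried at full precision; fixed-precision display
  uses *truncation* (`truncate_probability()`), not rounding — rounding
  27/4096 to three decimals would give 0.007.

## The synthetic cohort generator

The generator exists so that every stage is testable with no data
download. Its defaults *are* the study conditions being emulated, and they
are not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `mean_total_variants` | 67,000 | Poisson mean of called variants per exome |
| `mean_coding_nonsilent` | 12,000 | Poisson mean of the step-1 stratum |
| `panel_count_range` | [108, 143] | uniform range of panel-gene variants |
| `rare_count_range` | [18, 34] | uniform range of rare panel variants |
| `af_threshold` | 0.02 | rare/common boundary |

Poisson noise for the two large strata and uniform-integer draws for the
two ranged strata are stand-ins: only means and ranges of the emulated
design are known, not distributions. The strata are nested by
construction (rare ⊂ panel ⊂ coding non-silent ⊂ all), and per-patient
counts land exactly in the configured ranges because planted variants are
budgeted inside the rare stratum.

The 12 default `family_scenarios()` mirror the emulated study design: three
ABCA4 families, two RP1, two CNGB3, one X-linked CHM (male index), one
USH2A, one NMNAT1, and two families with no panel-gene mutation (their
causes are assumed to lie in unknown genes or in CNVs the pipeline cannot
see, so the cascade must return nothing for them). The CNGB3-homozygous
family additionally carries two spurious heterozygous USH2A missense
calls, emulating a false compound heterozygote that downstream validation
would reject; it therefore produces exactly two candidate genes.

Design choices a maintainer should know:

* **Synthetic coordinates.** Genes are laid out on a synthetic map
  (deterministic locus starts per chromosome); planted variants sit within
  the first 20 kb of their gene's locus and background variants in
  [+20 kb, +220 kb], so background draws can never hit a planted site.
  Rare background sites use odd positions and common (catalogued) sites
  even ones, so the two strata can never collide across patients either.
  Coordinates are therefore internally consistent but *not* genomic.
* **Background rare variants** are heterozygous, at most one per gene,
  never in a scenario's own genes, and never on chrX for a male index.
  This makes the candidate set of every synthetic patient exactly its
  planted configuration — deliberate: the cohort-level assertions (10/12
  solved, two candidates in one family, none in two) test the cascade's
  logic, not the background's accidental structure. Real exomes can and do
  produce additional incidental compound-het candidates; the spurious-call
  scenario exists precisely to keep that failure mode in scope.
* **Reproducibility.** One master seed; each patient's stream is derived
  from a hash of the patient identifier, so cohort composition is
  order-independent and byte-identical across runs.
* **Plant survivability** (kept class, panel gene, frequency-rule
  retention) is asserted at generation time, so a scenario can never be
  silently filtered away.
* The panel bundles the six real genes above plus 154 synthetic
  placeholders (`RDGP…`): the emulated study's full 160-gene panel
  membership is not public. The known-mutation fixture transcribes the 15
  distinct published mutations (8 novel at publication) exactly.

What passing tests show — and what they do not: the synthetic cohort
validates the filtering logic, count calibration, candidate calling, and
reporting under the stated statistical structure. It does not model real
human sequence context, linkage disequilibrium, population frequency
spectra, caller error profiles, or CNVs; agreement on synthetic data is
necessary, not sufficient, for performance on real exomes.

## Numerical and scale choices

Degenerate inputs are defined, not errors: an empty exome traverses the
cascade to an all-zero trace; a pedigree with no non-founders has
cosegregation probability 1 (empty product); an empty candidate list
annotates to an empty table. Duplicate keys (panel genes, catalog sites,
`(gene, hgvs_c)` pairs, patient ids, family ids) are rejected at the
boundary. A variant lacking an HGVS description is annotated `novel` with
a warning rather than dropped.

Test problem sizes are the package's own choices: full-scale cohorts
(12 × ~67,000 variants) are generated once per test run for the
end-to-end and calibration checks, while property suites (commutativity,
oracle equivalence, repeated-cohort calibration over 20 seeds) run on
reduced generator means (2,000/400 variants, panel range [30, 40], rare
range [8, 15]) — the properties under test are scale-free. Monte-Carlo
cross-checks use 10,000 replicates and a 99% binomial interval.

## Known limitations

Index-only compound-het calls are unphased (two variants in cis will be
miscalled as a candidate until cosegregation excludes them); dominant
models are out of scope; CNVs and structural variants are invisible to the
cascade; the XL model ignores skewed X-inactivation in carrier females;
and the segregation enumeration does not handle consanguinity loops.
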