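---
title: "Variant prioritization by sequential filtering: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant prioritization by sequential filtering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcfsift)
```

## The problem

Variant calling followed by annotation yields a VCF in which each data
line carries the eight mandatory columns (CHROM, POS, ID, REF, ALT, QUAL,
FILTER, INFO), optionally a FORMAT column and one genotype column per
sample. The INFO column is an open-ended set of flags and key–value
pairs, and annotation pipelines differ: population frequencies may come
from any of several cohorts, consequence predictions from VEP arrive
packed into a single `CSQ` string, and in-house annotations are common.
Prioritizing candidate disease variants therefore needs a tool that makes
*whatever* annotations are present filterable, rather than assuming a
fixed schema.

`vcfsift` treats prioritization as set refinement: the working set starts
as all variants and each applied filter keeps a subset, so the surviving
count is non-increasing and the final set is the intersection of all the
individual predicates. This makes the workflow order-insensitive in its
final result, while the recorded history preserves the order actually
used and the count after every step — the quantity an analyst reasons
about ("PASS leaves 376, the parental-genotype constraint leaves 50, …").

## Data model

Each data line is identified by the key `(chrom, pos, rank)`, where
`rank` is the line's 0-based ordinal in the file. POS is stored 1-based,
exactly as printed. Duplicated `(chrom, pos)` pairs are legal — they
arise routinely in decomposed multi-allelic call sets — and stay distinct
through `rank`. Chromosome names are matched as literal text (`"1"` and
`"chr1"` are different); no name normalization is attempted, and the
fixture generator deliberately mixes both styles so tests exercise this.

Field discovery returns the union of:

* five core fields: `CHROM+POS`, `ID`, `REF+ALT`, `QUAL`, `FILTER` (the
  two composite names treat the coordinate pair and the allele pair each
  as one filterable column);
* every INFO key and every FORMAT key, whether declared in the header or
  merely observed in the body — undeclared keys are typed `STRING` with
  arity `"."`, because real-world files frequently use keys they never
  declare;
* when a VEP `CSQ` declaration exists, one field per sub-field named
  after the `Format:` list in the header (e.g. `CSQ_Consequence`,
  `CSQ_SYMBOL`); the opaque `CSQ` key itself is replaced by these.

Only `CSQ` receives sub-field expansion. SnpEff's `ANN` key has a similar
shape, but its quoting/escaping conventions differ; `ANN` is exposed as
an ordinary string field, which `contains_keyword` can still search.

## Normalization rules

All values are carried as text and normalized once, in step 1:

* the canonical missing marker is the string `"nan"`: a literal `.`, an
  empty string, an empty CSQ sub-value and an absent key all become
  `"nan"`, and numeric comparisons treat it as missing, never as a
  number;
* flags become the value `"present"` when set and missing when not;
* multi-valued cells (INFO arity `A`/`R`/`G`/`.`, one CSQ value per
  transcript) keep *all* values, comma-joined; predicates use any-match
  over the values, and the record is kept or dropped whole. Any-match is
  chosen because a prioritization tool should err towards recall: a
  variant that is a missense change on one transcript should survive a
  missense query even if other transcripts say intron.

A variant counts as *missing* for a field only when **all** of its values
are missing; partially missing cells are judged on their non-missing
values.

## Indexes

Step 2 builds one index per selected field: a sorted association from
value to the set of ranks carrying it, plus the set of ranks whose values
are all missing. Together these partition the variant set, which is
asserted by tests for every index. Storage is a single plain-text file
per field under the workdir, beside a JSON manifest listing the source
file, the selected fields, the row count, the CSQ schema and the built
indexes — deliberately an embedded, serverless layout that needs no
administrative privileges. Numeric fields are indexed as doubles so an
integer-typed `"30"` matches a cut-off of `30.0`; VCF headers mistype
`Number`/`Type` often enough that stricter typing would misfire.

Index builds accept `cores`; rows are tabulated in parallel chunks and
merged into a canonical order (numeric or C-locale lexicographic by
value, then rank), so the artifact is byte-identical whatever the chunk
count. Determinism is the contract; parallelism is an implementation
detail.

## Filter semantics

* `greater_than` / `less_than` are **strict** inequalities and require a
  numeric-typed field — the canonical rare-variant query reads
  "AF < 0.01", which is strict.
* `equal_to` compares numerically after parsing on numeric fields (so
  `"0.5"` equals `"0.50"`) and by exact, case-sensitive string on text
  fields (the classic use is `FILTER equal_to PASS`).
* `contains_keyword` splits its argument on commas and keeps a variant
  when *any* keyword is a case-insensitive substring of *any* value;
  compound consequence strings like
  `missense_variant&splice_region_variant` therefore match the keyword
  `missense`.
* The gene-list filter instead uses case-insensitive **exact token**
  equality, after splitting values at `&`, `,` and `;` — substring
  matching would let `BRCA1` match `BRCA1P1`. A negative query keeps the
  complement of the associated set within the current working set;
  variants with no value in the gene field are not associated, hence kept
  by a negative query.
* `keep_missing` adds exactly the all-missing variants to the result:
  toggling it partitions the output disjointly, a property tested on
  every fixture.
* Genotype classes apply at any ploidy: missing if any allele index is
  missing; hom-ref if all indices are 0; hom-alt if all indices are equal
  and non-zero; het if at least two distinct indices occur (so `1/2` is
  het). Phasing is ignored (`0|1` ≡ `0/1`), and a missing genotype never
  matches any class. Sample scope is an explicit list plus an `all`/`any`
  quantifier: "one" sample is a singleton list, "some" is `any` over a
  chosen list.
* Regions are closed 1-based intervals `[start, end]`, matching the
  coordinate convention users see in the POS column. The bound order is
  validated (`start <= end`).
* Variant types are decided per ALT allele by length: SNP
  (`1 == len(REF) == len(ALT)`), MNP (equal lengths `> 1`), InDel
  (unequal lengths). Symbolic and breakend alternates (`<DEL>`, `*`,
  bracket notation) are parsed and carried but classify as none of the
  three, so no type filter ever selects them.

Malformed data lines (fewer than eight tab-separated columns, or a
non-integer POS) abort the read with an error naming the line number, in
preference to silently skipping lines: in a prioritization setting a
silently dropped variant is the worst failure mode.

## History and export

Every applied filter appends a ledger entry — ordinal, type, exact
parameters, input and output counts, timestamp — and persists its output
key set. The link `step i input = step i−1 output` is enforced at record
time. Deleting step *k* truncates steps *k..n* (each output depends on
its predecessors), reverting the working set. The exported report is
plain text with one tab-separated line per step whose parameter column is
compact JSON; `parse_history_report()` reconstructs the specifications so
a session can be replayed exactly, and replay determinism is asserted in
the tests. TSV export writes the key columns plus all selected fields
(the columns the analyst chose to work with), one row per surviving
variant in file order, missing values as `nan`, any embedded
tab/newline replaced by a space so the file stays rectangular.

## The synthetic fixtures

`fixture_spec()` generates standards-conformant VCF 4.2 with: mixed
chromosome naming styles, sorted positions with legal duplicates, a
configurable SNP/InDel/MNP mix, occasional second (insertion) ALT
alleles on SNP records, `AF` (per-allele float), `DP` (integer) and `DB`
(flag) INFO annotations, optional VEP-style `CSQ` with 1–4 transcript
blocks per record (including compound `&` consequence terms and empty
sub-values), per-sample genotypes at arbitrary and mixed ploidy with
phased and missing calls, and a per-value missing rate (default 0.1, a
level typical of merged annotation sets). Every fixture carries a
ground-truth sidecar written by construction at generation time, so
oracle tests never derive expectations from the code under test. The
same seed yields byte-identical files; the generator pins the RNG kind
and restores the session RNG state.

The `trio_preset()` embeds an exact number of rows matching the de novo
pattern (parents hom-ref, child het) and guarantees every other row does
*not* match it; `tumour_normal_preset()` does the same for rows hom-ref
in the normal sample. Preset sizes used in the automated checks — a
500-variant trio with 7 embedded de novo rows, a 400-variant
tumour/normal pair with 23 embedded candidates, 200–1000-variant
annotation fixtures — keep exhaustive oracle comparison cheap while
leaving room for all the structural features above to occur.

What the fixtures do **not** emulate: linkage structure, realistic allele
frequencies or mutation spectra, sequencing-error artefacts, cohort-scale
sample counts, or genuinely malformed files beyond the cases tested
explicitly. Passing tests therefore demonstrate correctness of parsing,
normalization, indexing and filter semantics on structurally realistic
input — not calling or annotation quality, which are upstream of this
tool's scope.

## Verification strategy

Three independent lines of evidence back the implementation:

1. a naive re-parse-and-scan oracle (test helper code sharing nothing
   with the package's preprocess/index/filter path) recomputes every
   filter's answer set on seeded fixtures, and the index-backed answers
   must match exactly — for every operator and both `keep_missing`
   settings;
2. constructed ground truth: preset fixtures embed known target rows and
   the filter chains must recover exactly those rows;
3. algebraic properties: subset/monotonicity along chains,
   chain-equals-intersection and order-invariance, the missing-value
   partition, partition of every index, permutation-invariance of
   genotype classification, and byte-level determinism (same-seed
   fixtures, single- vs multi-core index builds, gzip vs plain input,
   history replay).

An independent third-party VCF reader (`vcfR`) additionally cross-checks
the reader's column extraction on one fixture.

## Limitations

* BCF, tabix-indexed access and remote files are out of scope; input is
  local plain or gzipped VCF text, and output is TSV, never VCF.
* Indexes are rebuilt from the persisted table rather than updated
  incrementally; for the interactive use-case (at most a handful of
  selected fields) builds are cheap relative to pre-processing.
* No inheritance-model solving, compound-het detection or allele-
  frequency computation from genotypes: the tool filters existing
  annotations, it does not create them.
* A whole in-memory pass is used per file; files far beyond the
  interactive scale (hundreds of millions of lines) would need a
  streaming pre-processor behind the same contracts.
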