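# vcfsift

Sequential variant prioritization for annotated VCF files.

After variant calling and annotation, a typical exome or whole-genome VCF
holds from tens of thousands to millions of variants, only a handful of
which can plausibly cause the phenotype under study. `vcfsift` narrows that
set down through a three-step workflow:

1. **Pre-process** — read the VCF (plain or gzip), discover every
   annotation field present (core columns, INFO keys, FORMAT keys, and VEP
   `CSQ` sub-fields such as `CSQ_Consequence`), normalize missing values
   (`.` and empty become `nan`) and extract only the fields you select.
2. **Index** — build one compact on-disk index per selected field, so
   queries avoid full scans. Fields can be added at any time without
   redoing step 1; index builds accept a `cores` argument and are
   bit-identical regardless of parallelism.
3. **Filter** — apply any sequence of five filter types, each consuming
   only the variants that survived the previous one:
   * **field** — `greater_than` / `less_than` / `equal_to` /
     `contains_keyword` on any indexed field, with an explicit
     include/exclude switch for missing values (e.g.
     `AF < 0.01, keep_missing = TRUE` keeps both rare variants and
     variants absent from the frequency database);
   * **genotype** — homozygous-reference / heterozygous /
     homozygous-alternate in one, some or all samples, at any ploidy
     (de novo trio and tumour/normal designs);
   * **region** — chromosome plus a closed 1-based interval
     `[start, end]`;
   * **variant type** — SNP, InDel or MNP, decided per ALT allele by the
     length rules (`len(REF) = len(ALT) = 1` → SNP; equal lengths `> 1` →
     MNP; unequal → InDel; symbolic alleles classify as none);
   * **gene list** — variants associated (positive) or not associated
     (negative) with any symbol in a user list, by case-insensitive exact
     token match.

Every applied filter is recorded in a **filter history** (type, exact
parameters, input → output counts, timestamp); the history can be
truncated, exported as a human-readable report, re-parsed and replayed.
Surviving variants export as spreadsheet-compatible tab-separated text.

A deterministic synthetic-VCF generator (`fixture_spec()`,
`trio_preset()`, `tumour_normal_preset()`, `generate_vcf()`) produces
standards-conformant multi-sample fixtures with a ground-truth sidecar,
used throughout the test suite and usable for demonstrations and
benchmarking.

## Worked example: de novo candidates in a trio

A joint-called trio (mother, father, child): assuming a de novo germ-line
mutation, the candidates are variants where both parents are homozygous
reference and the child is heterozygous.

```r
library(vcfsift)

vcf <- generate_vcf(trio_preset(n_variants = 500, n_denovo = 7, seed = 42),
                    "trio.vcf")
wd <- preprocess_vcf(vcf, fields = c("QUAL", "FILTER", "GT"),
                     workdir = "trio_wd")
build_index(wd, "QUAL")
build_index(wd, "FILTER")

apply_filter(wd, field_filter("FILTER", "equal_to", "PASS"))
#> working set of 376 variants (origin: filter_field )
apply_filter(wd, genotype_filter("HOM_REF", c("mother", "father"), "all"))
#> working set of 50 variants (origin: filter_genotype )
apply_filter(wd, genotype_filter("HET", "child", "all"))
#> working set of 4 variants (origin: filter_genotype )

filter_history(wd)[, c("ordinal", "filter_type", "input_count",
                       "output_count")]
#>   ordinal filter_type input_count output_count
#> 1       1       field         500          376
#> 2       2    genotype         376           50
#> 3       3    genotype          50            4

head(preview(wd), 3)
#>   chrom    pos rank ref alts QUAL FILTER GT.mother GT.father GT.child
#> 1     1 166562   40   C    G 55.3   PASS       0/0       0/0      0/1
#> 2     1 853721  200   A    T  nan   PASS       0/0       0/0      0/1

export_tsv(wd, "denovo_candidates.tsv")
```

Reading the counts: 500 variants enter; 376 carry `FILTER = PASS`; 50 of
those have both parents homozygous reference; 4 of those have a
heterozygous child. The fixture embeds 7 de novo rows, but 3 of them are
non-PASS, so the quality filter removes them first — chaining the genotype
filters alone recovers all 7. The exported TSV holds the 4 surviving rows
plus a header, with missing values written as `nan`.

The same workflow is available from a shell through the bundled CLI
(`inst/cli/vcfsift.R`):

```sh
Rscript inst/cli/vcfsift.R preprocess trio.vcf --workdir trio_wd --fields QUAL,FILTER,GT
Rscript inst/cli/vcfsift.R index --workdir trio_wd --field FILTER --cores 4
Rscript inst/cli/vcfsift.R query field --workdir trio_wd --field FILTER \
    --op equal_to --value PASS
Rscript inst/cli/vcfsift.R history --workdir trio_wd --report history.txt
Rscript inst/cli/vcfsift.R export --workdir trio_wd --out candidates.tsv
```

## Documentation

The methods vignette (`vignettes/variant-prioritization.Rmd`) describes
the data model, the normalization and matching rules, the semantics of
each filter, what the synthetic fixtures do and do not emulate, and the
package's design decisions and limitations.
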