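# elimrep

Discovery and chromosomal mapping of germline-restricted tandem repeats.

Some animals eliminate whole chromosomes from their somatic cells during
early development ("programmed DNA elimination"). In the karyotype modelled
here, germ cells carry 2n = 52 chromosomes, somatic cells 2n = 36, and the
16 germline-restricted E-chromosomes are dominated by families of tandemly
repeated satellite DNA. `elimrep` provides an end-to-end, fully seeded
toolchain for studying them:

- **synthdata** — a generator for matched germline/somatic genomes with
  planted tandem arrays, shotgun reads, cloned repeat copies and
  probe-intensity profiles, plus a ground-truth manifest;
- **kmerdiff** — differential canonical k-mer counting (germline vs
  somatic), enrichment filtering (ratio ≥ 100), unitig assembly of enriched
  k-mers, tandem monomer inference and copy-number estimation;
- **repchar** — star alignment of cloned copies, majority consensus,
  gap-excluded pairwise divergence, GC content, direct repeats, circular
  ORF scan, and germline-vs-somatic consensus substitutions;
- **ispcr** — in-silico PCR with 3'-anchored primer matching and
  monomer/dimer/… ladder prediction on tandem arrays;
- **fishmap** — segmentation of 1-D chromosome intensity profiles,
  co-localization classes (coincident / largely / half / peripheral /
  dispersed / absent), symmetry scoring, karyogram pattern grouping and a
  fiber-level interspersion permutation test;
- **pipeline** — one-config orchestration (`run_all()`) with YAML round-trip,
  per-stage child seeds, text-file outputs and `compare_to_truth()` scoring.

All results are tibbles; `tidy()`/`glance()` follow the broom convention and
`autoplot()`/`plot_*()` give ggplot2 views.

## Worked example

Build the packaged family panel and genome, and inspect the four cloned
families (360 / 47 / 84 / 120 bp units):

```r
library(elimrep)

fams <- default_families(seed = 1)
fams[fams$name %in% c("EEEb7", "EEEb8", "EEEb9", "EEEb10"),
     c("name", "unit_length", "gc", "dispersed")]
#> # A tibble: 4 × 4
#>   name   unit_length    gc dispersed
#>   <chr>        <int> <dbl> <lgl>
#> 1 EEEb7          360 0.408 FALSE
#> 2 EEEb8           47 0.362 FALSE
#> 3 EEEb9           84 0.393 FALSE
#> 4 EEEb10         120 0.3   TRUE

g <- build_germline_genome(karyotype_config(), fams, seed = 1)
g
#> genome: 52 chromosomes (16 eliminated), 4.40 Mb total
```

Predict the PCR ladder of the 360-bp family on three tandem copies:

```r
pairs <- default_primer_pairs()
ladder <- predict_amplicons(strrep(fams$monomer[fams$name == "EEEb7"], 3),
                            pairs[pairs$name == "family0", ])
ladder_report(ladder, unit_length = 360)
#> # A tibble: 3 × 3
#>   band_bp n_units label
#>     <int>   <int> <chr>
#> 1     360       1 monomer
#> 2     720       2 dimer
#> 3    1080       3 trimer
```

Discover repeat families from reads (germline vs somatic), then map probe
profiles into karyogram patterns:

```r
germ <- simulate_reads(g, coverage = 20, error_rate = 0.001, seed = 1)
soma <- simulate_reads(derive_somatic_genome(g), coverage = 20,
                       error_rate = 0.001, seed = 2)
disc <- discover_repeats(germ$reads$sequence, soma$reads$sequence,
                         k = 21, ratio_threshold = 100,
                         min_germline_count = 10,
                         per_base_coverage = 20, read_length = 100)
sort(tidy(disc)$unit_length[!tidy(disc)$no_call])
#> [1]  47  60  84  90 150 180 210 300 360

kg <- build_karyogram(render_fish_profiles(g))
kg$n_patterns
#> [1] 6
```

Or run everything from one config and score it against the generator's
ground truth:

```r
run <- run_all(default_run_config(seed = 1))
compare_to_truth(run)
```

Note the dispersed family (EEEb10) is intentionally *not* germline-restricted
— it also occurs on retained chromosomes — so discovery correctly does not
report it, and recall/precision are computed over the nine exclusive
families.

## Command line

A CLI script is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "elimrep", package = "elimrep"))')" \
    run --seed 1 --out outdir
```

Subcommands: `run`, `simulate`, `discover`, `ispcr`, `fishmap`.

## Acceptance script

`scripts/acceptance.R` runs the installed package on the default synthetic
configuration and writes the headline quantities as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

## Tests

```r
testthat::test_dir("tests/testthat", package = "elimrep",
                   load_package = "installed")
```
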