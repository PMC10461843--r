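---
title: "Methods: discovering and mapping germline-restricted tandem repeats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and mapping germline-restricted tandem repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(elimrep)
```

# Background

Some animals discard whole chromosomes from their presumptive somatic cells
during early development while the germ line keeps the full complement —
programmed DNA elimination. In the karyotype modelled here, germ cells carry
2n = 52 chromosomes and somatic cells 2n = 36, so 16 chromosomes (8 pairs)
are germline-restricted ("E-chromosomes"). These chromosomes are dominated
by families of tandemly repeated satellite DNA. `elimrep` implements the
computational side of characterizing such repeats:

1. **synthesis** of a seeded ground-truth genome pair (germline/somatic)
   with planted tandem arrays,
2. **discovery** of germline-enriched families by differential canonical
   k-mer counting and unitig assembly,
3. **characterization** of monomers from cloned copies (consensus,
   divergence, GC, direct repeats, ORFs),
4. **in-silico PCR** ladder prediction,
5. **chromosomal mapping** of probe-intensity profiles into co-localization
   classes, karyogram patterns, and fiber-level interspersion.

Every stochastic step derives a stage-specific child seed from one master
seed, so a whole run is reproducible byte for byte.

# The synthetic truth

`default_families()` builds ten repeat families. Unit lengths and GC targets
follow the published consensus values (e.g. 360, 47, 84 and 120 bp for the
four cloned families), the published primer pairs are embedded at the unit
boundaries so that PCR ladders come out in exact unit multiples, and two
families carry fixed germline-vs-somatic consensus substitutions (3 and 5).

```{r}
fams <- default_families(seed = 1)
fams[, c("name", "unit_length", "gc", "dispersed")]
```

`build_germline_genome()` places tandem arrays on the 16 E-chromosomes
following six layout templates (two templates are used by two chromosome
pairs each, giving 8 pairs over 6 patterns), and `derive_somatic_genome()`
simply drops the E-chromosomes. One family is *dispersed*: it also occurs as
scattered single copies on retained chromosomes and is therefore **not**
germline-restricted — a deliberate negative control for discovery.

```{r}
cfg <- karyotype_config()
g <- build_germline_genome(cfg, fams, seed = 1)
g
```

# k-mer discovery

Counting uses canonical k-mers (the lexicographic minimum of a k-mer and its
reverse complement), making all downstream calls strand-independent. The
enrichment rule keeps a k-mer when

\[
\frac{\mathrm{germ}}{\mathrm{soma} \cdot s + \mathrm{pseudocount}} \ge
\mathrm{ratio}
\quad\text{and}\quad \mathrm{germ} \ge \mathrm{min\_count},
\]

where \(s\) scales the somatic counts to the germline total. The default
ratio of 100 reflects the "frequencies over 100 times higher in germline
reads" criterion that defines these families.

Enriched k-mers are assembled by greedy unique-extension unitigging over
(k−1)-overlaps. A tandem monomer's k-mers form a simple cycle, but genuine
junction k-mers at array boundaries cut that cycle at two nodes (the branch
out of the unit's last base and the branch into its first). A unitig is
therefore marked circular when its end re-enters its own start via a
(k−1)-overlap: either the walk returns to its starting k-mer, or an end
overlap d ∈ {k−1, …, 0} exists such that the d-base prefix equals the
suffix and every k-mer spanning the joint of the implied cycle is itself a
member of the enriched set. The monomer is the smallest rotation period of
the circular contig, reported as the lexicographically minimal rotation over
both strands. Copy number is the median k-mer count divided by the effective
k-mer coverage `coverage * (R - k + 1) / R` for read length `R`.

```{r, eval = FALSE}
germ <- simulate_reads(g, coverage = 20, error_rate = 0.001, seed = 1)
soma <- simulate_reads(derive_somatic_genome(g), coverage = 20,
                       error_rate = 0.001, seed = 2)
disc <- discover_repeats(germ$reads$sequence, soma$reads$sequence,
                         k = 21, ratio_threshold = 100,
                         min_germline_count = 10,
                         per_base_coverage = 20, read_length = 100)
tidy(disc)
```

# Monomer characterization

Cloned copies of a family are star-aligned against a centroid clone,
consensus is the per-column majority, and intraspecific divergence is the
mean pairwise proportion of mismatching sites with gap-containing site pairs
excluded. GC content is reported to one decimal with half-up rounding.
Direct repeats are maximal exact substrings occurring at non-overlapping
positions; the ORF scan treats the monomer as circular (tandem context), so
reading frames may wrap across the unit boundary.

```{r}
clones <- sample_clones(fams[fams$name == "EEEb9", ], "germline",
                        n = 12, mutation_rate = 0.02, seed = 5)
characterize_clones(clones)
```

# In-silico PCR

Primer sites require an exact 3'-anchor match (last 5 bases) and allow a
configurable number of mismatches elsewhere; products are enumerated between
plus-strand forward sites and minus-strand reverse sites. On a tandem array
with one internal site per unit this yields the classic monomer/dimer/…
ladder; consecutive bands differ by exactly the unit length.

```{r}
pairs <- default_primer_pairs()
ladder <- predict_amplicons(strrep(fams$monomer[fams$name == "EEEb7"], 3),
                            pairs[pairs$name == "family0", ])
ladder_report(ladder, unit_length = 360)
```

# Chromosomal mapping

Probe-intensity profiles (one value per genomic bin) are segmented with a
robust threshold (median + 3 MAD of the lower 75% of bins; a zero threshold
falls back to strict positivity), and each probe's localization relative to
the reference probe's segments is classified by its in-segment mass
fraction:

| fraction | class |
|---|---|
| ≥ 0.90 | coincident |
| ≥ 0.60 | largely_overlapping |
| ≥ 0.35 | half_overlapping |
| < 0.35 | peripheral |
| diffuse floor signal | dispersed |
| < 5% of reference total | absent |

Pairs of homologs are averaged after orientation, pairs with identical
signatures share a karyogram pattern (the packaged placement yields exactly
6 patterns over 8 pairs), and a mirror-symmetry score flags isochromosome-like
profiles. On chromatin fibers, the interleaving of two probes is summarized
by an interspersion index (observed probe alternations over the maximum
possible) with a permutation null.

```{r}
profiles <- render_fish_profiles(g)
kg <- build_karyogram(profiles)
kg$n_patterns
head(tidy(kg))
```

# One-call pipeline

`run_all()` executes every stage from a single validated config and
`compare_to_truth()` scores discovery against the generator's manifest
(recall and precision over the germline-restricted families, unit-length
exactness, and the Rand index between planted and recovered karyogram
partitions).

```{r, eval = FALSE}
run <- run_all(default_run_config(seed = 1))
glance(run)
compare_to_truth(run)
```

# Reporting conventions

All tabular results are tibbles; `tidy()` and `glance()` methods follow the
broom convention; `autoplot()`/`plot_*()` give ggplot2 views of profile
sets, karyograms and amplicon ladders.
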