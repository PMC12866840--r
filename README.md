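# geomgenome

Genome architecture analysis under a mass-fractal chromatin packing-domain
model, for computational biologists studying how exonic and non-exonic (NE)
DNA are geometrically coupled.

Interphase chromatin folds into nanoscopic packing domains whose genomic
content scales with radius as `N(r) = Nc·A_D·(r/rc)^D` with fractal
dimension `D` between 2 and 3. If transcription concentrates in an
intermediate-density shell of such domains (the ideal or "Goldilocks" zone),
exon content should behave like a surface while intron/intergenic content
supplies the volume, giving two coupled power laws for a gene of length
`L`, exon content `E` and intron content `I`:

```
E = Y · L^C,            C = (D − β) / D
I = E^γ / p,            γ = 1 + D/(D − β) = 1 + 1/C
```

where `β ∈ [0, 1]` measures how completely exons fill the shell (`β = 0`:
no shell geometry, γ = 2 for any D; `D = 2, β = 1`: γ = 3) and `p` is a
depth scalar in basepairs. The package implements:

* the closed-form model (`gamma_from()`, `C_from()`, `volume_fraction()`,
  `mass_in_radius()`, `shell_content()`, `goldilocks_radius()`,
  `exon_content()`, `chromstem_genomic_size()`, `chain_estimate()`,
  `compression_factor()`);
* annotation handling: genePred/BED12/GTF readers, per-gene E/I metrics,
  strand-oriented projection of exons onto a chromosome with the
  multi-start/multi-stop omission rule (`read_annotation()`,
  `gene_metrics()`, `project_exons()`);
* hinge segmentation — the core algorithm: pair every exon with its
  adjacent downstream NE, flag pairs totalling ≤300 bp as hinges, and split
  the chromosome into power-law segments between them (`build_pairs()`,
  `detect_hinges()`, `split_at_hinges()`, `segment_chromosome()`);
* scaling fits in log10 space with both residual-space conventions
  (`fit_power_law()`, `fit_ei_vs_length()`, `classify_geometry()`,
  `compare_to_null()`), with broom-style `tidy()`/`glance()` and
  `autoplot()` methods;
* the two null models: exon-only repositioning and exon+NE pair
  permutation, with exact conservation accounting (`randomize_exons()`,
  `permute_pairs()`, `null_ei_distribution()`);
* sequence and feature statistics: GC content, CTCF-core motif (`CCCTC`,
  both strands) region fractions, peak-overlap enrichment against matched
  300 bp random controls, midpoint distance profiles, loop exon/NE
  composition and packing ratios, mutation-frequency grouping;
* seeded synthetic-genome generators (`genome_spec()`, `generate_genome()`,
  `generate_sequence()`, `generate_peaks()`, `generate_loops()`) so the
  entire pipeline is testable without any downloads, plus a config-driven
  `run_pipeline()`.

## Worked example

Generate a 2000-gene synthetic genome with the packing architecture
(γ = 2.3, p = 5000 bp), segment it at hinges, and recover the scaling law
from the segment scatter:

```r
library(geomgenome)
library(dplyr)

spec <- genome_spec(gamma = 2.3, p = 5000, n_genes = 2000)
genome <- generate_genome(spec, seed = 1)

seg <- segment_chromosome(genome$layouts$chr1, hinge_max = 300)
nrow(seg$segments); nrow(seg$hinges)
#> [1] 2000
#> [1] 2000

fit <- fit_power_law(filter(seg$segments, exon_bp > 0, ne_bp > 0),
                     exon_bp, ne_bp)
fit
#> <power_fit> y = 0.0002149 * x^2.292  (R^2 [log10] = 0.9767, n = 2000, excluded = 0)
```

The fitted exponent 2.292 recovers the generating γ = 2.3, and the
prefactor 2.149e-4 corresponds to `p̂ = 1/2.149e-4 ≈ 4650 bp`, within 0.04
log10 units of the generating depth scalar. Exon-only randomisation
destroys the coupling: every gene window collapses to the chromosome-wide
exonic fraction `f` (here ≈1.5%, as this genome carries no intergenic
padding), with no length dependence:

```r
null <- null_ei_distribution(
  genome$layouts$chr1,
  tibble::tibble(gene_id = genome$genes$gene_id,
                 start = genome$genes$tx_start, end = genome$genes$tx_end),
  seed = 2)
sprintf("median E/I = %.3f (n_hat = %.3f)", null$median_ei, null$n_hat)
#> [1] "median E/I = 0.012 (n_hat = 0.009)"
```

The beads-on-a-string calculator reproduces the compaction yardsticks for
three classic long genes (a 26 kb myosin heavy chain, 268 kb thyroglobulin,
and the 1.53 Mb mouse Rbfox1):

```r
chain_estimate(c(26000, 268000, 1527000), 200, c(5.5, 11, 11))
#> # A tibble: 3 × 5
#>        bp bp_per_nucleosome extent_per_nucleosome n_nucleosomes chain_length_nm
#>     <dbl>             <dbl>                 <dbl>         <dbl>           <dbl>
#> 1   26000               200                   5.5           130             715
#> 2  268000               200                  11            1340           14740
#> 3 1527000               200                  11            7635           83985
```

An 84 µm stretched chain observed within a ~1 µm transcription-site extent
is an ~84-fold compression (`compression_factor(83985, 1000)`).

See the methods vignette (`vignettes/packing-domain-geometry.Rmd`) for the
model derivation, the segmentation semantics, what the synthetic generators
do and do not emulate, and the reasoning behind every numerical default.

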