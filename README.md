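# phageprofiler

Computational characterization of newly sequenced bacteriophage genomes, for
phage biologists and genomics bioinformaticians who have an assembly (and
ideally the reads) and want to know four things about a new isolate:

1. **Basic genome features** — size, GC content, a simple six-frame ORF scan
   (`gc_content()`, `find_orfs()`, `summary_table()`).
2. **Genome termini / packaging mechanism** — mapped-read coverage and
   read-start profiles classify a genome as carrying a long or short **direct
   terminal repeat (DTR)**, a **headful (pac)** packaging signature, or
   neither (`map_reads()`, `build_coverage()`, `classify_termini()`).
3. **Nucleotide-level placement** — fragment-based average nucleotide
   identity (**ANIb**: 1020 bp query fragments, local alignment against the
   reference, mean identity of fragments with ≥ 70% aligned fraction and
   ≥ 30% identity), symmetrized and clustered into a dendrogram
   (`anib_pair()`, `ani_matrix()`, `cluster_ani()`).
4. **Domain-level placement** — protein-domain hit tables are collapsed into
   a binary genomes × Pfam-accessions presence–absence matrix, clustered
   with Ward's method (Ward-D2: squared distances in the update, heights on
   the distance scale), cut into clusters with explicit singleton flagging,
   plus a rule-based temperate-evidence flag from integrase/repressor marker
   domains (`build_pa_matrix()`, `ward_dendrogram()`, `cut_and_flag()`,
   `lifestyle_flags()`).

Agreement between the nucleotide- and domain-based classifications is scored
with the adjusted Rand index, ARI = (RI − E[RI]) / (max RI − E[RI]), computed
from the pair-count contingency table (`adjusted_rand()`, `congruence()`).

Because real phage panels come without ground truth, the package ships a
first-class synthetic community generator (`community_spec()`,
`plant_community()`, `simulate_packaged_reads()`): clusters of genomes
related at a planted substitution rate, unrelated singletons, per-genome
domain tables with controllable pool sharing, and single-end reads carrying
the termini-dependent coverage signatures (~2× folded depth over a DTR with
single-base boundaries; a fixed-start pileup at a pac site). Everything is
deterministic under one root seed.

All user-facing functions take data frames first and return tibbles, so the
steps chain with the pipe; results have `tidy()`/`glance()` methods and
`ggplot2::autoplot()` plots.

## Worked example

```r
library(phageprofiler)

spec <- community_spec(
  clusters = tibble::tibble(
    n_genomes = 2, ancestor_length = c(20000, 24000), gc_target = c(0.66, 0.48),
    within_cluster_substitution_rate = 0.02,
    domain_pool_size = 30, domains_per_genome = 20),
  n_singletons = 1, singleton_length = 21000, singleton_gc = 0.69,
  shared_domain_fraction = 0, seed = 42)

report <- run_pipeline(pipeline_config(community = spec, seed = 42))
report
#> <phage_report> 5 genomes
#>
#> # A tibble: 5 × 6
#>   id    genome_size_kb gc_percent orf_count termini_class lifestyle_flag
#>   <chr>          <dbl>      <dbl>     <int> <chr>         <chr>
#> 1 C1_g1             20       65.1        49 Headful (pac) no-temperate-evidence
#> 2 C1_g2             20       65.2        52 Headful (pac) no-temperate-evidence
#> 3 C2_g1             24       48.4        14 Headful (pac) no-temperate-evidence
#> 4 C2_g2             24       48.3        15 Headful (pac) no-temperate-evidence
#> 5 S1_g1             21       69          69 DTR (short)   no-temperate-evidence
#>
#> Congruence (adjusted Rand):
#> # A tibble: 3 × 2
#>   comparison      adjusted_rand
#>   <chr>                   <dbl>
#> 1 ani_vs_truth                1
#> 2 domain_vs_truth             1
#> 3 ani_vs_domain               1
```

Reading the output: the two planted clusters and the singleton are recovered
identically by ANI and by domain content (all three adjusted Rand indices are
1.0); the two `C` clusters were simulated under headful packaging and the
singleton under a 1 kb terminal repeat, and the coverage-based caller
recovered both labels. GC columns sit at the planted 66%/48%/69% targets.

The ANI matrix shows the planted structure directly — siblings evolved at
substitution rate 0.02 sit near 96% identity (two independent 2% divergences
from the ancestor), and unrelated genomes share no qualifying fragments:

```r
report$ani
#> <ani_matrix> 5 genomes; 8 pair(s) without detectable homology
#>       C1_g1 C1_g2  C2_g1  C2_g2 S1_g1
#> C1_g1   100    96     NA     NA    NA
#> C1_g2    96   100     NA     NA    NA
#> C2_g1    NA    NA 100.00  96.15    NA
#> C2_g2    NA    NA  96.15 100.00    NA
#> S1_g1    NA    NA     NA     NA   100
```

A single pair call behaves the same way — a 50 kb genome against its 3%
variant:

```r
g <- generate_genome(50000, 0.55, seed = 1)
anib_pair(g, evolve_variant(g, 0.03, seed = 2))
#> [1] 96.99029
```

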