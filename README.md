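# haplozein

Comparative analysis of maize α-zein (prolamin) gene-family haplotypes.

The α-zein seed-storage proteins are encoded by tandem clusters of
near-identical gene copies at six loci. Different inbred lines carry
*haplotypes* of these loci that differ not just in SNPs but in gene-copy
number, retroelement content and intergenic spacing, and the copies
differ strongly in expression and promoter methylation. `haplozein`
provides the full analytical toolchain such a comparison needs, plus a
synthetic-haplotype simulator with a complete truth ledger so every
estimator in the package can be validated by parameter recovery.

## What it computes

* **Retroelement insertion dating.** An LTR retrotransposon's two long
  terminal repeats are identical at insertion; their subsequent
  divergence dates the event. The package estimates the Kimura
  two-parameter distance from the transition proportion *P* and
  transversion proportion *Q* (pairwise deletion of gap/N columns),

  K = −½ ln((1 − 2P − Q) √(1 − 2Q)),

  with the delta-method variance, and converts it by the molecular
  clock: age = K / (2 r_LTR), default r_LTR = 1.3×10⁻⁸
  substitutions/site/year (twice the genic rate, both configurable).
* **Tandem duplication dating.** Synonymous-site distance between
  duplicates by Nei–Gojobori (1986) counting with Jukes–Cantor
  correction, Ks = −¾ ln(1 − 4 p_s/3); age = Ks / (2 r_gene),
  default r_gene = 6.5×10⁻⁹.
* **Paralog phylogenies.** K2P or p-distance matrices, neighbor-joining
  and UPGMA trees, column-resampling bootstrap with integer percent
  supports, Newick output (`ape::phylo` objects throughout).
* **Expression attribution.** cDNA clones assigned to near-identical
  paralogs by best local-alignment score; counts → percent of total
  transcripts; detection threshold p_min = 1 − (1 − c)^(1/n); profile
  comparison (reactivated / silenced / enhanced / reduced / unchanged)
  with two-proportion exact tests.
* **Bisulfite methylation.** Per-cytosine CG/CHG/CHH context
  classification, conversion-aware read matching, percent methylation
  per site and per context, tissue comparisons with coverage masking.
* **Locus annotation.** Gene-copy status (intact / premature stop /
  truncated / start loss / RE-disrupted), promoter motif scanning
  (P-box `GTGTAAAG`, configurable O2 site; IUPAC patterns, both
  strands), base-composition partitions, cross-haplotype conserved
  coverage, insertion chronologies with nesting checks, and a helitron
  terminal-structure test (5′-TC…CTAG-3′ plus subterminal hairpin).

## Worked example

```r
library(haplozein)

sim <- simulate_locus_pair(simulation_config(seed = 42))
f <- sim$hapA$features
ltrs <- f$feature_id[f$kind == "ltr" & f$parent == "re1"]
date_ltr_pair(extract_feature_sequence(sim$hapA, ltrs[1])$seq,
              extract_feature_sequence(sim$hapA, ltrs[2])$seq,
              event_id = "re1")
#> <dated_event> re1 (re_insertion): K = 0.17055, age = 6.560 +/- 0.553 mya
```

The simulated element was configured at 6.2 mya; a single 1-kb LTR pair
dates it to 6.56 ± 0.55 mya — the truth is well inside one standard
error. The full pipeline runs every stage and returns a report bundle:

```r
b <- run_pipeline(validate_config(list(seed = 42, n_boot = 200)))
b$dating[, c("event_id", "kind", "K", "age_mya", "age_se_mya")]
#>     event_id             kind       K age_mya age_se_mya
#> re1      re1     re_insertion 0.17055   6.560     0.5527
#> re2      re2     re_insertion 0.05929   2.280     0.3053
#> re3      re3     re_insertion 0.03375   1.298     0.2273
#> re4      re4     re_insertion 0.00200   0.077     0.0545
#> zg2      zg2 gene_duplication 0.04500   3.461     1.2334
#> ...

b$expression_comparison[, c("copy_id", "pct_ref", "pct_alt", "class")]
#>   copy_id pct_ref pct_alt       class
#> 1     zg1   88.89   36.81     reduced
#> 2     zg2    4.86    4.51   unchanged
#> 3     zg3    2.78   38.89    enhanced
#> 4     zg4    3.47    2.08   unchanged
#> 5     zg5    0.00   17.71 reactivated

sapply(b$methylation, context_averages)
#>     leaf endosperm cultured_endosperm
#> CG  88.9      50.7               81.1
#> CHG 70.0      30.3               59.6
#> CHH 10.6       5.5               10.3
```

The four retroelements were simulated at 6.2, 2.04, 1.19 and 0.12 mya
(the fifth, age 0, is carried by the other haplotype); the dated ages
recover them within their standard errors, and the nested element (re3
inside re2) is confirmed younger than its host. The expression table
shows the tissue-culture resetting scenario the simulator encodes: the
dominant copy reduced, a minor copy enhanced, a silent copy
reactivated. The methylation averages show cultured endosperm
re-methylated above its normal counterpart in all three contexts.
`detection_threshold(960)` gives 0.31%: a copy expressed above that
fraction is seen with 95% probability in 960 clones.

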