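# ripclass

Count-based discovery of the **direct substrates of nonsense-mediated mRNA
decay (NMD)** from paired RNA-seq and UPF1/SMG-2 RIP-seq experiments.

Inactivating NMD changes the abundance of a large part of the
transcriptome, but an abundance change alone cannot tell a direct
substrate (an mRNA degraded by NMD) from an indirect effect. Because the
NMD helicase UPF1/SMG-2 stays bound to PTC-containing mRNAs, an SMG-2
immunoprecipitation — compared both to its input and to a mock IP from a
strain lacking functional SMG-2 — provides the missing evidence. ripclass
implements the full analysis for the six-condition *C. elegans* design
(N2 wild type, *smg-1(−)*, *smg-1(−) smg-2(−)*; input and IP fractions;
three biological replicates each), for bioinformaticians who want the
procedure as a tested, reusable, end-to-end pipeline.

## What it computes

Three two-group comparisons on filtered count matrices:

| comparison | groups | threshold |
|---|---|---|
| up / down | NMD(−) inputs vs N2 inputs | fold-change > 1.5, FDR < 0.05 |
| ipA | *smg-1* IP vs *smg-1* input | fold-change ≥ 2, FDR < 0.05 |
| ipB | *smg-1* IP vs *smg-1 smg-2* mock IP | fold-change ≥ 2, FDR < 0.05 |

With S = ipA ∩ ipB, features are classified as **Class I** (up ∩ S, direct
substrates), **Class II** (S only — SMG-2-associated, abundance
unaltered), **Class III** (up, in neither IP set), **Class IV** (down, in
neither IP set), or unclassified. The same scheme runs over an
**intron-only catalog** (gaps between each gene's merged exons) to catch
PTC-bearing, intron-retaining minority isoforms that the gene-level test
misses; genes with a Class I intron join the gene-level Class I set in the
high-confidence substrate list.

The differential machinery — TMM normalization, conditional-likelihood
negative-binomial dispersion estimation with empirical-Bayes shrinkage,
the conditional exact test (p = sum of the probabilities of all splits of
the group total no more probable than the observed one, under NB-sum laws
with variance μ + φμ²), and Benjamini–Hochberg FDR — is implemented in the
package and cross-checked in the test suite against independent oracles
and an established reference implementation. Hypergeometric and binomial
over-representation tests with Bonferroni correction cover gene-family and
category enrichment. A synthetic-data module generates toy genomes,
counts and spliced reads with known substrate labels, so the whole
pipeline is testable without external data; see the methods vignette
(`vignettes/ripclass-methods.Rmd`) for the model and every default.

## Worked example

```r
library(ripclass)
res <- run_pipeline(run_config(out_dir = "results", sim = sim_params(seed = 42)))
#> [ripclass] simulating genome and counts (n_genes=2000, seed=42)
#> [ripclass] 2000 of 2000 gene features pass the 3 CPM filter
#> [ripclass] gene sets: up=184 down=8 ipA=220 ipB=221
#> [ripclass] gene classes: I=182 II=37 III=2 IV=8 unclassified=1771
#> [ripclass] 8234 of 9064 intron features pass the 3 CPM filter
#> [ripclass] 84 Class I introns over 84 genes
#> [ripclass] high-confidence substrates: 201
#> [ripclass] recovery vs truth: precision=1.000 recall=0.918
res$summary
#> Class sizes: I=182, II=37, III=2, IV=8, unclassified=1771
#> Up-regulated features: 184 (Class I = 99% of up)
#> Class I pseudogene share: 56%
#> High-confidence substrates: 201
```

Reading the output: of 2000 simulated genes (10% true substrates), 182 are
called Class I directly; 37 true substrates with a small PTC-isoform share
are SMG-2-associated but not significantly up (Class II), and the
intron-level stage rescues most of them — 84 genes carry a Class I intron,
lifting the high-confidence list to 201 genes with precision 1.00 and
recall 0.92 against the known labels. All intermediate tables
(`de_*.tsv`, `classes_*.tsv`, `substrates.tsv`, `summary.json`,
`manifest.json`) land in `results/`.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/ripclass.R introns  --gtf genes.gtf --out introns.bed
Rscript inst/cli/ripclass.R simulate --out-dir sim --n-genes 2000 --seed 42
Rscript inst/cli/ripclass.R run      --out-dir results --seed 42
```

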