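# arsiscan

Unsupervised detection of gene-expression regulatory information in coding
and non-coding genomic regions, using the **Average Repetitive Substring
Index (ARSI)**.

Regulatory motifs — for transcription, splicing, translation — recur
across the genes of a genome, and they recur *exactly* in genes under
strong selection while decaying by point mutation in weakly expressed
genes. ARSI measures this from sequence alone: for a query sequence `S`
and a reference set `G` of genetic elements,

```
ARSI(G, S) = (1 / |S|) * sum_i | longest substring of S starting at i
                                 that occurs in some element of G |
```

Elements dense in shared subsequences score above composition-matched
randomized sequences, and the score ranks 5'UTRs, ORFs, introns and
3'UTRs by the expression-related information they carry — with no
expression data, motif database or training step.

The package provides:

* exact per-position longest-match profiles via a suffix automaton, with
  exact two-pass **leave-one-out scoring** of every element against all
  the others (`buildIndex()`, `matchLengthProfile()`, `arsiScore()`,
  `arsiLeaveOneOut()`, `scoreRegions()`);
* **anchor-aligned sliding-window profiles** (metagene profiles) around
  ORF start/end and the 5'/3' splice sites (`windowArsi()`,
  `anchorProfile()`), with multi-intron genes duplicated one retained
  intron at a time;
* **composition-preserving null models** — genome-wide synonymous-codon
  permutation, intron permutation fixing the splice consensus
  (5'SS/branch-site/3'SS), cyclic UTR shifts fixing the start-codon
  context — and per-offset **Z-score profiles** against replicate
  ensembles (`randomizeGenome()`, `nullEnsemble()`, `zscoreProfile()`);
* **expression statistics**: Spearman and length-controlled partial
  Spearman correlation, median/quartile high-vs-low splits, Wilcoxon
  rank-sum and paired signed-rank comparisons;
* a **synthetic-genome generator** with fully known motif placements and
  expression classes (`synthesizeGenome()`), the ground truth behind the
  test suite;
* an `arsi` command-line tool (`exec/arsi`) with subcommands
  `simulate | score | profile | randomize | zscore | correlate`.

Real genomes (e.g. *S. cerevisiae*, *S. pombe*, *E. coli* FASTA + GFF3
from their standard databases, expression tables from PaxDb and friends)
are consumed through the same `readGenome()` / `readAnnotation()` /
`readExpression()` entry points; nothing in the package downloads data.

## Worked example

```r
library(arsiscan)

## the index and the score ------------------------------------------------
idx <- buildIndex(c(a = "ACGTA"))
matchLengthProfile(idx, "ACGTACGT")
#> [1] 5 4 3 2 4 3 2 1
arsiScore(idx, "ACGTACGT")
#> [1] 3

## a synthetic genome with known ground truth -----------------------------
g <- synthesizeGenome(syntheticSpec(nGenes = 200, seed = 101))
sc <- scoreRegions(g$genome, g$models, "orf")   # leave-one-out, per ORF
head(sc, 3)
#>    element_id gene_id region length_nt     arsi
#> 1 g0001|orf|1   g0001    orf       540 9.631481
#> 2 g0002|orf|1   g0002    orf      1302 9.068356
#> 3 g0003|orf|1   g0003    orf       561 8.802139

## real vs. randomized ----------------------------------------------------
rg  <- randomizeGenome(g$genome, g$models, seed = 202)  # codons+introns+utrs
scr <- scoreRegions(rg, g$models, "orf")
pt  <- pairedRealVsRandomTest(sc$arsi, scr$arsi)
c(p = pt$p.value, real = pt$median_real, random = pt$median_random)
#>             p          real        random
#>  1.210854e-27  8.979969e+00  8.744186e+00

## scores track expression ------------------------------------------------
gs <- perGeneScores(sc)
spearmanCorr(gs, g$expression, "mrna")[c("rho", "p.value", "n")]
#> $rho
#> [1] 0.6904833
#> $p.value
#> [1] 1.154409e-29
#> $n
#> [1] 200
```

The match profile reads: at position 1 of `ACGTACGT` the longest
substring present in the reference `ACGTA` is `ACGTA` itself (length 5),
at position 2 it is `CGTA` (4), and so on; the mean over the eight
positions is the ARSI score 3.0. On the synthetic genome, real ORFs beat
their codon/intron/UTR-randomized counterparts in the paired signed-rank
test (median 8.98 vs. 8.74, p ~ 1e-27), and per-gene scores correlate
with the known expression levels (Spearman rho 0.69 at n = 200) — genes
of the high-expression class carry intact motif copies, the low class
carries mutated ones.

From a shell, the same pipeline:

```sh
arsi simulate --n-genes 200 --seed 101 --out sim
arsi score    --genome sim/genome.fa --annotation sim/annotation.gff3 \
              --regions orf --out scores
arsi zscore   --genome sim/genome.fa --annotation sim/annotation.gff3 \
              --anchor orf_start --WL 41 --R 50 --seed 1 --out z
arsi correlate --scores scores/arsi_orf.tsv \
               --expression sim/expression.tsv --field mrna --out corr
```

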