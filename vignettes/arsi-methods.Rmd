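---
title: "Scoring regulatory information with the Average Repetitive Substring Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring regulatory information with the Average Repetitive Substring Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arsiscan)
```

## The measure

Transcripts accumulate short regulatory motifs — binding sites for the
transcription, splicing and translation machinery — that are shared across
the genes of a genome. In highly expressed genes these motifs tend to be
present in their precise, functional form; in lowly expressed genes they
drift and accumulate substitutions. The Average Repetitive Substring Index
(ARSI) turns this into an unsupervised, sequence-only score: for a query
sequence $S$ and a reference set $G$ of genetic elements, find at every
position $i$ of $S$ the longest substring starting at $i$ that occurs
contiguously in at least one element of $G$, and average the lengths:

$$\mathrm{ARSI}(G, S) \;=\; \frac{1}{|S|}\sum_{i=1}^{|S|} \bigl|S_i\bigr|,$$

where $|S_i|$ is that longest-match length. Elements rich in shared (hence
plausibly functional) subsequences score above composition-matched
randomized sequences, and the score ranks genetic elements by how much
expression-related information they carry.

Two conventions matter and are fixed throughout the package: a match never
spans the boundary between two reference elements, and the ambiguity code N
matches nothing, on either side. Sequences are scored in transcript
orientation only; pre-mRNA regulatory motifs are strand-specific, so no
reverse-complement matching is performed (a deliberate choice — the
biology, not the data structure, dictates it).

## Exact computation

`buildIndex()` compiles the reference set into a suffix automaton over the
separator-joined concatenation; the separator character is unreachable from
any query, which enforces the no-boundary-spanning rule for free.
`matchLengthProfile()` runs the query through the automaton once, obtaining
for every end position the longest matching suffix, and converts those
end-anchored lengths to start-anchored lengths with a single forward
pointer (the match start is monotone in the match end). The whole profile
costs $O(|S|)$ after an $O(\|G\|)$ build.

Leave-one-out scoring — every element scored against all the others —
uses two linear passes instead of rebuilding the index per element: a
prefix automaton grown in input order and a suffix automaton grown in
reverse, with each element queried against both and the per-position
maximum taken. This is exact, and it naturally supports the default
exclusion policy in which all elements of the same gene are excluded
together (so the duplicated transcripts of a multi-intron gene can never
match their own siblings). A strict element-only policy is available via
`exclude = "element"`.

The test suite pins all of this to an independent brute-force oracle
(fixed-string search over all reference substrings) on hundreds of random
instances, together with the two structural invariants every profile must
satisfy: $0 \le L(i) \le |S| - i + 1$ and $L(i+1) \ge L(i) - 1$.

## Regions, transcripts, anchors

`readGenome()`/`readAnnotation()` load a FASTA genome and a GFF3
annotation (first mRNA per gene; UTRs inferred from exon minus CDS span
when not annotated explicitly). Intervals are stored 1-based inclusive in
`IRanges`, the Bioconductor convention, so GFF3 coordinates need no
conversion at the boundary. `extractRegions()` produces the 5'UTR, ORF,
introns, 3'UTR and up to 250 nt of upstream/downstream flanking sequence
per gene, all in transcript orientation; flanks truncate silently at
chromosome edges. For annotations without UTR features (common in
prokaryotes) an optional fixed-length flank fallback (default off, 50 nt
suggested) stands in for the missing UTRs, with a logged notice.

Profile analyses work on anchored pre-mRNA transcripts
(`buildAnchoredTranscripts()`). A gene with $m > 1$ introns is duplicated
$m$ times, each duplicate retaining one intron with the others spliced
out; every transcript then has at most one donor/acceptor pair and
well-defined anchors: the first start-codon nucleotide (`orf_start`), the
first stop-codon nucleotide (`orf_end`, with the stop codon taken as part
of the annotated CDS), and the first/last intronic nucleotides (`five_ss`,
`three_ss`).

## Window profiles and anchor alignment

`windowArsi()` computes the score of every length-`WL` window (odd `WL`,
default 41, with 31/51/71 as standard alternatives) directly from the
full-transcript match profile using the min-truncation identity: a match
inside a window is exactly a full-sequence match truncated at the window
end, so the windowed score at center $i$ is the window mean of
$\min(L(p),\, \text{window end} - p + 1)$. This is provably identical to
extracting each window and scoring it as its own query — the tests verify
the identity on random instances — but costs `WL` vectorized operations
per transcript instead of a quadratic rescan.

`alignAndAverage()` aligns the per-transcript window profiles on a common
anchor and averages per offset over all transcripts whose complete window
fits at that offset (no partial windows). The flank extent is
$\pm\lfloor (n - 1/2)\,WL \rfloor$ with $n = 4$ by default, i.e. offsets
$\pm 143$ at `WL = 41`; $(n - 1/2)WL$ is not an integer for odd `WL` and
the floor is the conservative, symmetric choice. The reference set for
window profiles is all pre-mRNA transcripts of the genome excluding the
query gene: windows straddle region boundaries, so region-matched
references would be ill-defined exactly where the profiles are most
interesting. Per-region leave-one-out scoring (`scoreRegions()`), in
contrast, is region-matched: introns are scored against all other genes'
introns, ORFs against ORFs, and so on.

## Null models and Z-scores

Selection on sequence content is read off by comparing the real genome
against randomized genomes that keep the boring properties and destroy the
interesting ones. Three schemes, applied in any combination (all three by
default) and written back into chromosome coordinates so the entire
pipeline reruns unchanged:

* **codons** — synonymous codons pooled genome-wide by amino acid and
  permuted within each family. Every protein and the genome-wide codon
  multiset (hence codon-usage bias) are conserved *exactly*; pooled
  genome-wide rather than per gene because that is the weakest constraint
  that still conserves both (a per-gene flag exists). Stop codons form
  their own family, so internal stops (which the motif-bearing synthetic
  ORFs do contain) cannot migrate into coding frames elsewhere.
* **introns** — per-intron uniform permutation with the 6 nt donor prefix,
  3 nt acceptor suffix and the best TACTAAC branch-site hit (3'-most IUPAC
  match within the last 60 nt; only the termini if no hit) held fixed.
  Per-intron nucleotide composition, hence GC, is conserved exactly.
* **utrs** — cyclic shift by a uniform random offset; for 5'UTRs the 6 nt
  immediately preceding the start codon (the ATG context) stay fixed and
  only the remaining prefix rotates; 3'UTRs rotate whole. Composition is
  conserved exactly.

Each scheme draws from its own seed stream derived from the master seed,
so schemes commute and any application order yields the same genome — the
tests assert this equality, not just distributional similarity.

`nullEnsemble()` evaluates an arbitrary statistic on `R` independent
replicates (default 50; the validation runs use `R = 20`, which already
stabilizes the null standard deviation for the peak-localization checks at
a quarter of the cost). `zScore()` standardizes the real signal per offset
with the sample standard deviation (denominator $R - 1$); offsets with
zero null variance are flagged `NA`, never turned into infinities.
`pairedRealVsRandomTest()` compares real per-element scores against one
matched randomized replicate with the two-sided Wilcoxon signed-rank test.

## Relating scores to expression

`spearmanCorr()` reports Spearman's rho with pairwise exclusion of missing
measurements; `partialSpearman()` implements the rank-based partial
correlation (rank-transform everything, regress the ranked variables on
the ranked controls by least squares, correlate the residuals, t
approximation with $n - 2 - k$ degrees of freedom), used to control for
sequence length — long elements accumulate long matches for purely
combinatorial reasons. With no controls it reproduces the plain Spearman
correlation to machine precision, which the tests assert.
`splitHighLow()` partitions genes at the median (ties to the high set;
top/bottom-quartile optional) and `compareGroups()` applies the two-sided
Wilcoxon rank-sum test. P-values are reported uncorrected, matching how
such per-region comparisons are conventionally presented; a
Benjamini–Hochberg adjustment can be applied downstream with
`p.adjust()` when many regions are screened at once.

## The synthetic benchmark

`synthesizeGenome()` builds the ground-truth world every recovery test
runs in. Defaults describe a compact fungal-like genome: 200 genes, ORFs
of 100–500 codons (stop-free background codons at 40% GC, start and stop
in place), 5'UTRs of 40–150 nt, 3'UTRs of 60–200 nt, 0–2 introns per gene
(Binomial(2, 0.3)) of 80–400 nt carrying canonical GTATGT … TACTAAC … YAG
signals, random strand, 300 nt spacers, one chromosome per 100 genes. A
library of 30 distinct motifs (8–25 nt) is placed by a distance-to-anchor
density — 3 placements per 100 nt within ±50 nt of any anchor, 0.3 per
100 nt elsewhere — never overlapping each other, the splice consensus or
the start/stop codons. Copies in low-expression genes are mutated at 0.15
per nt; expression is log-normal by class (meanlog $\ln 100$ vs. $\ln 10$,
sdlog 0.5). These values were fixed once as a plausible caricature of the
biology: band-enriched motif densities an order of magnitude above
background, and a mutation rate that leaves ~2–3 hits in a typical motif,
enough to break long exact matches without erasing composition.

Expression is assigned by *class*, not by each gene's realized motif
integrity, so the score–expression correlation target is deliberately
attenuated — recovering it is the honest version of the test. What the
generator does not emulate: realistic codon-usage structure, overlapping
regulatory codes, phylogenetic correlation between genes, and
position-specific motif grammars. Passing the recovery tests therefore
demonstrates that the machinery detects shared-substring enrichment where
it exists, not that any particular real genome will show the same effect
sizes.

Validation problem sizes, chosen as the package's own working points: the
recovery battery runs on the 200-gene default; peak localization is
checked on 10 independently seeded genomes with `R = 20` replicate nulls,
requiring the maximal Z offset within ±70 of the ORF start (the ±50
enriched band plus the ±20 half-window smear at `WL = 41`); the
sequencing-error robustness check scores an 800-gene (~1.2 Mb) reference
before and after uniform $10^{-3}$ substitutions, ten times.

## Numerical and degenerate-input choices

Empty regions are omitted rather than emitted as zero-length strings;
transcripts shorter than one window yield an empty profile with a warning;
leave-one-out with a single element, an empty reference set, constant
expression in a median split, and fewer than $3 + k$ complete cases in a
partial correlation are all hard errors. All-zero paired differences give
$p = 1$ with a notice instead of a degenerate test. Ties in reference
occurrence (a maximal substring occurring in several elements) are
irrelevant by construction: only the length enters the score. Randomness
always flows through explicit seeds; seeded calls restore the caller's RNG
state.

## Limitations

ARSI weights a position only by its longest match; the number of
occurrences of that match is ignored, and weighting repeats by abundance
is an obvious refinement left out deliberately. Overlapping genes are
processed independently. Only the first annotated isoform per gene is
used. Approximate (edit-distance) matching is out of scope — the measure
is defined on exact substrings, and its robustness to sparse substitution
noise comes from averaging, not from fuzzy matching.
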