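---
title: "Detecting zygotic transcription from F1-hybrid allele-specific RNA-seq"
author: "zygosnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting zygotic transcription from F1-hybrid allele-specific RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zygosnp)
```

## The problem and the model

The early fly embryo is a syncytium whose nuclei divide synchronously,
doubling every cycle (`expected_nuclei(c)` = $2^{c-1}$), with interphases
under ten minutes. The classical view holds that these stages run entirely
on maternally deposited transcripts and proteins. Whether any gene is
*transcribed by the embryo itself* before the blastoderm stage is a
parent-of-origin question, and an F1 hybrid of two fully sequenced inbred
lines makes it answerable with RNA-seq:

* Transcripts loaded into the egg during oogenesis carry only the
  **maternal** genotype.
* Transcripts made by the embryo's own diploid genome come from both
  homologs, so they carry maternal and paternal genotypes in roughly equal
  measure.

The two parental lines differ by single-nucleotide substitutions at
intervals of roughly 200 bp, so a sizeable fraction of short reads overlap
at least one discriminating SNP. zygosnp assigns each such *informative*
read to a parental chromosome, tabulates per-gene maternal ($M$) and
paternal ($P$) counts per staged pool (nuclear cycles 3–6 pooled, cycle 7,
cycle 8), and classifies each gene–stage.

### The decision rule

Sequencing errors put a floor under the paternal count even for purely
maternal transcripts: an error hitting a SNP base converts it to the other
parent's allele with probability $e/3$ per base-call error rate $e$, which
at default $e = 0.005$ predicts a paternal fraction of roughly 0.17%, in
the empirically observed 0.1–1% band. A gene–stage with $N = M + P$
informative reads is therefore called:

* **low_information** when $N < 5$: nothing can be said either way;
* **zygotic** when the paternal fraction $P/N \ge f_{\min} = 0.10$ *and*
  the exact one-sided binomial tail
  $\Pr[X \ge P],\ X \sim \mathrm{Bin}(N, p_0)$ with error ceiling
  $p_0 = 0.01$, Benjamini–Hochberg-adjusted within the stage, is
  $\le \alpha = 0.05$;
* **maternal** otherwise, flagged `confident` when $N \ge 100$.

Two design points deserve emphasis. First, "roughly equal maternal and
paternal reads" is deliberately *not* operationalized as a test against
0.5: genes with a large maternal deposit plus genuine zygotic synthesis
(e.g. 76 maternal vs 15 paternal reads) are real zygotic transcription
with a strongly unbalanced ratio, and a symmetric test would wrongly
reject them. The rule instead asks for a paternal fraction clearly above
anything sequencing error can produce. Second, BH adjustment within each
stage is applied even though a desk-scale table barely needs it: the same
rule is exercised on simulated panels of hundreds to thousands of genes,
where uncorrected per-gene tests at $\alpha = 0.05$ would not meet the
intended specificity. For a single gene–stage
(`classify_gene_stage()`) the raw p-value is the adjusted p-value.

The reported `zygotic_fraction_estimate` $z = \min(1, 2P/N)$ assumes
balanced biallelic zygotic transcription on top of a maternal-only
deposit: if a fraction $z$ of transcripts are zygotic, half of those carry
the paternal genotype, so $P/N \approx z/2$.

### Onset calling

Per gene, the earliest stage called zygotic (in the order c3_6 < c7 < c8)
is the onset stage. The packaged published cohort
(`load_zygotic_gene_counts()`) contains one gene twice with discordant
counts; both rows are retained and classified but excluded from gene-level
onset aggregation, since the duplication is unexplained in the source.
Blank cells in that table are read as "no informative reads detected", not
as zero expression, and produce no count row — absence of evidence is the
conservative encoding.

```{r fixture}
fx <- load_zygotic_gene_counts()
cl <- classify_table(fx$counts)
cl$summary
subset(cl$onset, gene_id %in% c("zen", "sisA"))
```

## The synthetic-data generator

Real staged single-embryo libraries are not reproducible at desk scale, so
the generator produces the ground truth the analysis assumes, and every
claim the tests make about the pipeline is a claim about data with these
properties:

* **Diploid transcriptome** (`build_diploid_transcriptome()`): the
  reference is the maternal haplotype; the paternal copy differs only at
  SNPs whose inter-site distances are geometric with mean 200 nt
  (memoryless — "about every 200 bp" is an average, not a lattice), the
  substituted base uniform over the three alternatives.
* **Expression programs** (`expression_program()`,
  `simulate_expression()`): maternal deposits sit on the maternal
  haplotype only; zygotic output begins at an onset cycle, is split
  equally between haplotypes in expectation, and by default scales with
  the nuclei count of each pooled cycle, so zygotic signal roughly doubles
  per cycle.
* **Reads** (`simulate_reads()`): 36-nt single-end reads — no read length
  is standard for early short-read instruments, and a short read is the
  conservative choice because it maximizes the fraction of single-SNP
  reads, the hardest case for assignment. Reads are drawn proportional to
  copy number × transcript length, starts uniform, substitution errors
  i.i.d. per base at rate 0.005 with the erroneous base uniform over the
  alternatives. Every read carries its true haplotype of origin.
* **Crosses** (`simulate_cross()`): independent uniform gamete choice,
  genotype→phenotype map supplied by the caller; a heterozygous ×
  heterozygous null cross yields the Mendelian quarter of mutant progeny.

What the generator does **not** emulate: indels, paired ends, position- or
quality-dependent error profiles, PCR duplicates, mappability and
alignment bias, allele-specific expression of X-linked genes, or
transcript degradation. Passing tests therefore demonstrate that the
assignment and classification logic is correct for SNP-bearing substrings
with i.i.d. substitution errors — not that an aligner-based pipeline on
real libraries would be free of reference bias.

Reads are taken with known transcript placements (the simulator's truth
table, or `place_reads()`, which places FASTQ reads at unique exact
substring matches). Heuristic alignment is deliberately out of scope: the
contribution is the assignment step, and error-bearing reads that no
longer match exactly are simply dropped by the placer rather than
mis-placed.

Reads overlapping several SNPs that vote for different parents are called
`conflict` and excluded from $M$ and $P$ rather than majority-voted. With
36-nt reads and 200-bp spacing such reads are rare, and exclusion cannot
inflate the zygotic signal. In reciprocal crosses the roles of the two
lines swap; `orient_snps()` relabels the allele columns so counts are
merged only after both samples are expressed in maternal/paternal terms.

## Normalization

`rpkm()` is the textbook reads per kilobase per million mapped reads.
`normalize_autosomal()` rescales every sample so its summed
autosomal-gene RPKM equals the first sample's — the constraint is
"constant across samples", so any anchor works and the first sample makes
runs reproducible. X-linked genes are rescaled by their sample's factor
but never enter the constraint, because X dosage changes across these
stages while autosomal output should not.

## Kinetics

`transcript_time()` and `protein_time()` are straight length-over-rate
arithmetic with defaults of 1500 nt/min elongation (a measured fly rate;
4300 nt/min is the mammalian tissue-culture alternative) and 540 aa/min
translation; `expression_feasible()` asks whether the summed times fit
within a 10-minute interphase window, boundary-inclusive since the
question is feasibility rather than a sharp cutoff. A 4207-nt transcript
elongates in about 2.8 min at the slow rate and under a minute at the
fast one — comfortably within one early interphase:

```{r kinetics}
signif(transcript_time(4207, 1500), 2)
expression_feasible(transcript_time(4207, 1500), protein_time(540, 540))
```

## Numerical and implementation choices

* All internal coordinates are 0-based half-open; on-disk formats follow
  their standards (SNP TSV positions 1-based as in VCF, BED 0-based
  half-open). Readers and writers round-trip exactly.
* The binomial tail is computed with `stats::pbinom(P - 1, N, p0,
  lower.tail = FALSE)`; the test suite checks it against a brute-force
  log-pmf summation to $10^{-12}$ absolute for $N \le 500$.
* One master seed feeds named sub-streams (`substream_seed()`) per
  operation and stage, so a full `run_pipeline()` run is byte-for-byte
  reproducible from a single integer, and changing the read depth of one
  stage does not perturb another's draws.
* Result TSVs print doubles with 17 significant digits so round-trips are
  lossless.

### Problem sizes used in validation

The shipped validation experiments are sized for interactive runs: the
error-band measurement simulates a strictly maternal 60-gene × 2-kb
transcriptome until 200,000 informative reads accumulate (~1.2 million
raw reads); the classifier panel uses 170 maternal-only plus 30
zygotic-only genes with onsets spread over cycles 1–8 at 150,000 reads
per stage, giving maternal genes on the order of a hundred informative
reads per stage and zygotic genes well over ten at cycle 8. At those
depths the panel yields sensitivity ≥ 0.90 at post-onset stages and
specificity ≥ 0.99 for maternal genes with $N \ge 100$.

```{r panel, eval = FALSE}
panel <- simulate_recovery_panel(seed = 17)
cl <- classify_table(panel$counts)
evaluate_recovery(cl$results, panel$truth)[c("sensitivity", "specificity")]
```

## Known limitations

* The published cohort's membership criterion was never stated
  numerically; the default thresholds reproduce it approximately (about
  94% of its genes are called zygotic at some stage), not exactly — a few
  rows with a single paternal read do not clear the adjusted binomial
  test.
* Two large-transcript cohort members are flagged as likely false
  positives on size grounds in the source; no size/intron filter is
  applied here, but sizes, intron counts and footnote flags are carried
  through so users can filter.
* `place_reads()` is quadratic in transcriptome size and intended for
  small demonstrations; real libraries should arrive as truth tables or
  pre-placed reads.
* The classifier treats stages independently; no smoothing or borrowing
  of strength across stages is attempted.
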