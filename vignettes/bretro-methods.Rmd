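---
title: "Detecting and characterizing retrotransposed pseudogenes on B chromosomes"
author: "bretro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing retrotransposed pseudogenes on B chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bretro)
```

## The biological problem

B chromosomes are dispensable supernumerary chromosomes carried by some
individuals of a population in addition to the standard (A) complement.
Retrotransposon machinery active on such chromosomes occasionally
reverse-transcribes the mRNA of an A-chromosome gene back into the genome,
leaving a processed pseudogene: an intronless, often truncated copy that may
subsequently be amplified to many copies. Individuals carrying one B
chromosome ("1B") can then be contrasted against B-lacking individuals
("0B") with ordinary sequencing libraries, because every extra pseudogene
copy changes what the reads look like in four measurable ways:

1. **Depth.** Over the truncated region, 1B genomic DNA shows elevated
   coverage relative to 0B; the excess is proportional to the pseudogene
   copy number on the B chromosome.
2. **Exon–exon junctions.** Genomic 1B reads span exon boundaries without
   the intervening intron — impossible for the intact gene — which is the
   defining signature of a retrocopy.
3. **B-specific SNPs.** The pseudogene copies diverge, so alternative
   alleles appear in every 1B library and in no 0B library, at a depth
   consistent with at least one B-located copy.
4. **Arrangement.** Long reads through the pseudogene carry its genomic
   flanks: identical flanks across reads mean one insertion locus (and
   head-to-tail hits mean a tandem array); unrelated flanks mean dispersed
   copies.

Finally, carrying the pseudogenes can feed back on the canonical genes: the
package quantifies the 0B/1B expression contrast both from RNA coverage and
from RT-qPCR tables using the $2^{-\Delta\Delta C_q}$ relative expression
method with bootstrap estimation statistics.

`bretro` implements this complete comparative analysis, together with a
fully ground-truthed synthetic data generator so that every stage can be
validated end to end without any external data.

## The depth model and the copy-number estimator

Reads are mapped to the **spliced** gene sequence (the mRNA), the natural
reference for a retrocopy-bearing contrast: the truncated region is then a
single contiguous interval in spliced coordinates. Mapping uses an
affine-gap local aligner (match $+1$, mismatch $-1$, gap open $-2$, gap
extend $-1$; a gap of length $L$ costs $2 + L$), seeded with 13-mers and
retained under the contract *score ≥ 40 and identity ≥ 0.80*, where
identity is matches over aligned columns. The score floor of 40
corresponds to roughly 40 net matched bases under these weights; users
porting thresholds from aligners with different scoring should recalibrate.
Alignment ends are additionally trimmed back to a run of at least 5
consecutive matches (`end_anchor`): a local alignment happily gains a
net-positive `=X=` overhang past a template junction — for example from a
retrocopy edge into its genomic flank — and those chance columns would
otherwise inject systematic false mismatches into the pileup.

Let $d_\ell(p)$ be the depth of library $\ell$ at spliced position $p$.
Each library is normalized by its mean depth over a **single-copy control
interval** — a part of the gene outside the amplified region, carried only
by the two A-chromosome copies — so normalized depth is measured in units
of "diploid A coverage" and ratios become copy-number ratios. Because the
control interval is not known before the amplified region has been called,
the pipeline runs two passes: library-size normalization plus a
baseline-corrected ratio threshold yields a provisional region; the longest
non-amplified segment then becomes the control for the calibrated second
pass.

The per-position ratio of group-mean normalized 1B to 0B depth is smoothed
with a centered 25-bp moving average; maximal runs with smoothed ratio
$\ge 1.5$ and length $\ge 100$ bp are reported, with runs closer than the
smoothing window merged and positions of zero 0B coverage masked rather
than treated as infinite. The threshold of 1.5 is the expected ratio of a
single extra copy on a diploid background, i.e. the smallest biologically
meaningful signal; the window and minimum length are set so that a
single-copy-scale step survives smoothing while isolated noise does not.
All three are arguments.

With two copies of the gene on the A chromosomes ($a = 2$ by default) and
$r_{0B} \approx 1$, $r_{1B}$ the mean normalized depths over the called
interval, the copy number per B-carrying genome is

$$\hat n_B = a\,(r_{1B} - r_{0B}),$$

clipped at zero, with per-library estimates retained for dispersion
reporting. On noise-free input the estimator is exact by construction; on
30× simulated libraries it recovers $n_B = 20$ within a few percent.

## Junction evidence

A junction catalog holds, for each adjacent exon pair, the terminal
`arm_length` bases of the upstream exon concatenated with the leading bases
of the downstream exon (arms truncate at short exons). The default arm
length equals the read length so that any fully contained spanning read can
be placed. A read supports a junction when it aligns to that catalog entry
with at least 15 aligned bases on **each** side of the boundary and
identity $\ge 0.90$ — stricter than the mapping floor, because boundary
artifacts are the dominant error mode. The identity requirement is applied
to the whole alignment *and to each side separately*: a long perfect arm
must not subsidize a low-quality chance extension into the other arm,
which is exactly what reads from the intron-containing genome would
otherwise produce. With these rules, fifty simulated intron-containing
(0B-only) read sets yield zero junction calls while every in-window
junction gains support at 20× in 1B simulations.

The presence/absence table emits `"all"` when every junction inside the
amplified region is supported, `"none"` when none is, and the explicit
list (e.g. `"8-9, 9-10"`) otherwise. A junction counts as inside the
region only when its boundary sits at least 25 bp (the smoothing
resolution of the region caller) interior to the region edge; an edge
junction between a truncated and a non-truncated exon is structurally
absent from the retrocopy and must not be demanded. The minimum read count
for "present" defaults to 1 and is an argument, since presence/absence
rather than a count threshold is the natural reading of the table this
reproduces.

In-silico PCR complements the read-level evidence: primer sites are matched
with up to 2 mismatches but none in the 3 terminal 3'-bases (a deliberate
approximation of primer-extension chemistry), and every forward × reverse
product up to 2 kb is reported, on both template orientations. A
junction-spanning reverse primer yields a product only on intronless
templates, so a three-primer multiplex distinguishes 0B (one band) from 1B
(two bands) — `genotype_b()` is the computational twin of that gel.

## The two-filter B-specific SNP caller

From per-library pileup counts (A, C, G, T, insertion, deletion per
position; insertions attributed to the position left of the insertion
point), a candidate allele at a position passes:

* **Filter 1** — the alternative allele occurs (count ≥ 1 by default) in
  *every* 1B library;
* **Filter 2** — the mean per-library 1B alternative count is at least half
  the mean per-library 0B total occurrence at that position. The factor ½
  encodes the copy-number argument: two A copies produce the 0B depth, so
  one B copy contributes about half of it.

A SNP is reported only if both filters pass *and* the allele is absent from
every 0B library — the exclusivity that "B-specific" implies even though
it is not a numbered filter. Filter 2 is computed on per-library means by
default so that unequal group sizes do not bias the comparison; a
merged-group variant (summed 1B counts against the 0B per-library mean) is
available behind `filter2 = "merged"` for compatibility with merged-BAM
workflows, since the original description does not disambiguate the two.
Positions with zero 0B coverage leave filter 2 undefined and are skipped
(their count is recorded on the result). Indels travel through both
filters as two extra alleles per position.

Raising either threshold can only shrink the call set (a monotonicity the
tests assert over parameter grids), and cross-variant sharing tables are
exact set intersections over (reference, position, allele) keys, validated
against brute-force membership enumeration. On the default simulation
regime (1% divergence, 30×, three libraries per group, 0.2% sequencing
error) the caller reaches ≥ 0.90 recall at ~1.0 precision against
generator truth; the residual misses are true variants that drew a
chance sequencing error of the same allele in a 0B library, which the
exclusivity rule then vetoes.

## Long-read arrangement analysis

Long reads are scanned for local copies of the pseudogene query with
k-mer-seeded, diagonal-clustered windowed alignment — each tandem copy
produces its own diagonal cluster and hence its own hit. A read is
reported when the union of its hits covers ≥ 70% of the query at
per-hit identity ≥ 0.80; this identity + query-cover contract replaces
database e-values, which are meaningless at single-gene scale.

Same-strand hits on a read closer than 2 kb chain into an array whose
length is the copy count; the pipeline-level count is the modal value over
reads that contain their array completely. Flanks of 1 kb are taken
*outside the whole array span* (the sequence between copies is pseudogene,
not flank — a rule the tandem case requires), oriented to the
pseudogene-forward strand, and truncation at read ends is recorded rather
than padded.

Flanks are clustered by greedy single-linkage on pairwise local-alignment
identity (matches over the shorter flank), with a shared-k-mer prefilter
so unrelated flanks never reach the aligner. The link threshold defaults
to **0.85**, not a rounder 0.90: two reads with per-base error $e$ agree
at $\approx (1-e)^2$ of positions, which is ~0.90 at the 5% error typical
of older long-read chemistry — sitting a threshold exactly on the expected
same-locus identity would split true loci, while cross-locus identity
stays below ~0.5, so 0.85 separates the two distributions with margin.
Left and right flanks are never linked across sides; a locus is supported
by a (left-cluster, right-cluster) pair co-occurring on a read.

The final label combines the two statistics: *tandem* (modal copies ≥ 2 at
a single locus), *dispersed* (single copies at ≥ 3 loci), *single-locus*,
*mixed*, or *no-call* without hits. Across twenty simulations (ten
dispersed with five loci, ten three-copy tandem, 5% read error) the label
is correct 20/20 and the tandem copy count is exactly 3.

## Expression statistics

Technical qPCR replicates are averaged per (sample, gene);
$\Delta C_q = C_q^{target} - C_q^{ref}$;
$\Delta\Delta C_q$ subtracts the arithmetic mean calibrator-group (0B)
$\Delta C_q$; $\mathrm{NREQ} = 2^{-\Delta\Delta C_q}$. Calibrating on mean
$\Delta C_q$ makes the *geometric* mean of 0B NREQ exactly 1 (an identity
the tests assert to machine precision); calibration on the arithmetic NREQ
mean is available behind a flag since "calibrated to the mean expression
level of the 0B group" admits both readings. The fold change is the ratio
of arithmetic NREQ group means — the definition under which per-sample
NREQs and a quoted FC coexist — with the log-scale alternative
$2^{\overline{\Delta\Delta C_q}(1B)-\overline{\Delta\Delta C_q}(0B)}$
reported alongside.

The two-group effect size (mean 1B − mean 0B) carries a
bias-corrected-and-accelerated (BCa) bootstrap 95% CI with within-group
resampling, 5,000 resamples by default, and the acceleration constant from
a delete-one jackknife — the defaults of the estimation-plot method this
mirrors. The implementation is seed-deterministic (bitwise-identical CIs
under a fixed seed) and collapses the interval onto the observed effect
when the bootstrap distribution is degenerate; it is cross-checked against
an independent BCa implementation in the test suite, and its empirical
95% CI coverage over 500 simulated two-group normal datasets is ~0.94.

## What the generator emulates — and what it does not

`simulate_bchrom_dataset()` draws a multi-exon gene (default 10 exons of
120–250 bp, introns 250–400 bp, GC 0.42), builds the B haplotype as the
spliced truncation of exons 4–10 with i.i.d. substitutions at 1%
divergence, and amplifies it to $n_B$ copies — dispersed, each inside its
own independently generated 2-kb background (distinct flanks per locus), or
head-to-tail with random spacers at one locus. A 1B individual is sequenced
as two A-chromosome copies plus one univalent B haplotype, so `depth` is
defined on the diploid A baseline and a region carried by $2+n_B$ copies is
expected at $(2+n_B)/2$ times the flank depth. Defaults: three paired-end
libraries per group at 30×, 100-bp reads, 300±30 insert, 0.2% substitution
error; ~12-kb log-normal long reads at 5% error (substitutions, insertions
and deletions); RNA libraries mixing the target transcript with a constant
reference transcript, the 1B target output scaled by the underexpression
factor (default 0.2), optionally routed partly through B-copy transcripts;
and duplicate Cq values at σ = 0.2 cycles. Every generated parameter —
truncation interval in spliced coordinates, variant list, copy number,
locus table, arrangement, expression factor — is recorded as truth.

Deliberate simplifications, which bound what the passing tests prove about
real libraries: coverage is uniform (no GC or fragment-length bias, no
mappability structure), short-read errors are substitutions only (indel
errors are reserved for long reads, keeping the pileup oracle exact),
qualities are constant, there are no PCR duplicates or chimeric reads, all
B copies share one divergence event (no post-amplification divergence
between copies), and one univalent B per 1B individual (no mosaicism).
These are the assumptions the estimators themselves make; real-data
deviations (e.g. GC-correlated depth) would widen the copy-number error
beyond what the synthetic benchmarks show.

## Numerical choices and degenerate inputs

Problem sizes in the test-suite benchmarks are chosen to exercise the
stated regimes at desk scale: the copy-number and SNP criteria run the
full default simulation (a ~9-kb A chromosome, ~108-kb B haplotype,
~65,000 reads), arrangement runs use 14 long reads per simulation, and
bootstrap coverage uses 500 datasets of 12 samples per group. Alignment
tie-breaks are deterministic (best score, then leftmost reference start,
then lexicographic reference id, then plus strand); the DP core itself
prefers the earliest-ending co-optimal cell in row-major order.
Zero-depth control intervals, empty references, reads shorter than the
seed, zero-coverage 0B positions, single-hit "arrays", flankless reads and
degenerate bootstrap distributions all have defined, tested behavior
rather than errors where a result is still meaningful. GFF3 input is
converted from 1-based closed to internal 0-based half-open coordinates at
the boundary, and minus-strand genes are reverse-complemented into
transcription orientation at load time so every downstream module is
strand-free.

## Known limitations

The aligner is exhaustive within a seeded window and is built for
single-gene references, not genomes; there is no base-quality model, no
split-read mode, and multi-mapping reads keep a single best placement
(which flattens paralog signal if two near-identical references are
supplied). Locus counting equates flank clusters with insertion loci,
an approximation that undercounts when distinct loci share repetitive
flanks and when few reads carry both flanks. The copy-number estimator
assumes the control interval is strictly single-copy; a segmental
duplication there would deflate all estimates. The qPCR module implements
the ideal-efficiency $2^{-\Delta\Delta C_q}$ model without
amplification-efficiency correction or multi-reference normalization.
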