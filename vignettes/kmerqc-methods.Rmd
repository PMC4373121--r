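---
title: "Quality control of shotgun metagenomes from canonical k-mer spectra"
author: "kmerqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control of shotgun metagenomes from canonical k-mer spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the metric

Shotgun metagenomic sequencing of complex communities (for example human
gut microbiota) produces millions of short raw reads whose quality is hard
to judge before the expensive downstream steps — mapping to a gene
catalogue, abundance profiling — have been run. `kmerqc` implements a
composition-based QC score that needs nothing but the raw reads: count all
overlapping k-mers, and summarize the k-mer spectrum by its normalized
Shannon entropy

$$ H \;=\; \frac{-\sum_{i=1}^{M} p_i \log p_i}{\log M}, \qquad
   p_i = \frac{c_i}{\sum_j c_j}, $$

where $c_i$ are the per-bin k-mer counts and $M$ the number of bins. $H$
is 1 for a perfectly even spectrum and 0 when all mass sits in one bin.
The working hypothesis: a deep shotgun sample of a *complex mixture* of
organisms has a nearly uniform tetranucleotide spectrum ($H \approx
0.99$), markedly more uniform than any single bacterial genome
($H \approx 0.95$–$0.98$), and technical artifacts — above all adapter
(barcode-cassette) self-ligation products that dominate libraries built
from too little input DNA — push spectral mass onto a small set of k-mers
and depress $H$. Low entropy therefore predicts poor downstream mapping
rates, and the aberrant bins identify the contaminant.

## Canonical k-mer space

Shotgun sequencing does not preserve strand, so a k-mer and its reverse
complement are the same observation. `kmer_space(k)` enumerates the
canonical bins: each equivalence class $\{w, \mathrm{rc}(w)\}$ is one bin,
labelled by its lexicographically smaller member. For even $k$ there are
$4^{k/2}$ palindromic k-mers ($w = \mathrm{rc}(w)$, e.g. `AGCT`) forming
singleton classes, so

$$ M = \frac{4^k + 4^{k/2}}{2} \quad (k\ \text{even}), \qquad
   M = \frac{4^k}{2} \quad (k\ \text{odd}); $$

$k=4$ gives the 136 tetranucleotide classes used throughout. Colour-space
(SOLiD/CSFasta) reads are supported natively: the colour encoding is
invariant under complementation, so the strand equivalence is plain string
reversal. Note that for odd $k$ the colour alphabet *does* have
self-equivalent words (odd-length strings can be palindromes under plain
reversal, with a free middle symbol), so the implementation always derives
$M$ from explicit class enumeration rather than from the even/odd closed
form; the closed form above is asserted only for the base alphabet.

Counting walks every read with a window of length $k$: a read of length
$l$ contributes $l-k+1$ windows, windows containing an ambiguous symbol
(`N`, or a missing colour call `.`) are skipped, and reads are independent
fragments (no window spans two reads). Internally k-mers are base-4
integer codes; because `A<C<G<T` matches the digit order, the numeric
minimum of a code and its reverse-complement code is also the
lexicographic canonical label.

One consequence of canonical aggregation worth knowing: a maximally random
sequence does *not* score exactly 1. Under a uniform base process the 120
two-member bins each receive mass $2/256$ while the 16 palindromic bins
receive $1/256$, so the ceiling is $H \approx 0.9965$ for $k=4$. The
normalization denominator is $\log M$ of the canonical space by default
(`normalization = "canonical"`); `"raw"` divides by $\log 4^k$ instead for
comparison with pipelines that do not aggregate reverse complements.

## Preprocessing and tunable parameters

Defaults reproduce the method's reference conditions:

* `k = 4` — small k keeps the bin count (136) far below the k-mer count of
  even a modest sample, so the spectrum is densely sampled.
* `trim_length = 35` symbols — reads are truncated to a common length so
  per-read window counts are homogeneous; colour reads containing missing
  calls are discarded before trimming. Reads already shorter than the trim
  length are kept at native length by default (`drop_short = FALSE`);
  dropping them is available because retention subtly changes totals and
  either convention is defensible.
* `fold_threshold = 4` — a bin is *aberrant* relative to a reference
  profile when its frequency exceeds the reference frequency at least
  4-fold, with empty reference bins floored at one pseudo-observation
  ($1/\text{total}$) so the fold-change stays finite. The published
  evidence for contamination shows bins overrepresented by an order of
  magnitude; 4 is a conservative operationalization and is exposed as a
  flag.
* `entropy_warn = 0.95` — the QC report flags samples below this entropy
  as WARN. QC is advisory: the tool never hard-fails on a low score,
  because the appropriate reaction (resample, reprocess, sequence deeper)
  is a study-level decision.

Spearman rank correlation is used for all profile–profile and
entropy–mapping associations (two-sided; exact p-value below 10 samples,
t-approximation otherwise). Gene-mapping efficiencies are *inputs* — the
package never maps reads; it correlates its entropy score against mapping
rates computed by external pipelines.

## Clustering genome signatures

Tetranucleotide spectra are genome signatures: `cluster_profiles()`
reproduces the classification workflow. Ward's minimum-variance
agglomeration (`hclust(method = "ward.D2")`) runs on Euclidean distances
between per-bin frequency vectors — Ward is defined for squared Euclidean
geometry, which is why no other distance is offered. The number of
clusters is selected *objectively* from the dendrogram: find the largest
difference between successive junction heights and cut below that
junction; ties go to the earliest gap (the larger cluster count), a
declared and tested convention. The partition is then re-derived
non-hierarchically by k-means (10 restarts, fixed seed, pre-specified
cluster count) and the agreement between the two labelings is summarized
by Cohen's kappa. Because cluster labels are arbitrary, kappa is computed
after a maximum-agreement one-to-one relabelling (exact assignment over
label permutations up to 8 clusters, greedy above); two partitions that
are identical up to renaming score exactly 1. Degenerate inputs are
handled explicitly: when the requested cluster count reaches the number of
distinct frequency vectors, each distinct point becomes its own cluster
(the exact within-SS optimum), which `stats::kmeans` itself refuses.

## The synthetic study generator

Everything above is testable offline because the package ships a seeded
generator that emulates the structure of a dilution-series experiment.

**Genomes.** A genome is a first-order Markov chain over `A,C,G,T` with a
random transition matrix whose rows are symmetric Dirichlet draws. The
concentration `alpha = 6` was calibrated so that single-genome
tetranucleotide entropies fall in the 0.95–0.98 band reported for real
bacterial genomes (mean ≈ 0.973 over draws); a 10-genome equal-weight
mixture then scores ≈ 0.992–0.995, matching deep real metagenomes. A
first-order chain is the simplest generator giving genomes distinct,
clusterable signatures; it does not model repeats, coverage bias, GC skew
along the replichore, or any other genome feature — passing tests show the
*method's* behaviour under compositional structure, not performance on any
particular real taxon.

**Reads.** Each read draws a genome by mixture weight, a uniform start, a
uniform strand, and substitutes symbols at a configurable error rate.
Default read length 35 and sample size 50,000 reads per step keep the full
dilution experiment around ten seconds on one CPU while leaving the
entropy's Monte-Carlo error near $10^{-4}$; these sizes are stated here as
the package's chosen study scale.

**Dilution as contamination.** The mechanism by which dilution degrades
real libraries is limited input DNA: ligation increasingly produces
insert-free, self-ligated cassette concatemers, and the sequencer reads
them. The generator models a dilution step directly by its contamination
fraction $f$: a step consists of $(1-f)\,n$ genome-derived reads plus
$f\,n$ random fragments of cassette concatemers, with the default series
$f = (0, 0.01, 0.05, 0.3, 0.7)$. Mass-based modelling of the wet-lab
dilution itself (input nanograms, PCR cycles) is out of scope.

Three design choices here deserve explanation:

* *Common random numbers.* One master pool of genome reads is drawn per
  series; the step at fraction $f$ takes the first $(1-f)n$ pool reads and
  adds fresh cassette reads. Successive steps therefore re-sequence the
  same library at graded contamination, and entropy differences between
  steps reflect contamination, not read-resampling noise.
* *Balanced pool order and systematic cassette phases.* The pool is
  reordered round-robin by genome (quantile position) so every prefix has
  near-proportional genome representation, and cassette fragments take
  equidistributed phases within the cassette period with one random
  offset. Both are classical variance-reduction devices; they change
  nothing about the marginal read distributions that the counting step
  sees.
* *A low-complexity default cassette.* The default cassette is a 12-nt
  poly(A) homopolymer, so the contaminant's entire k-mer mass lands on the
  single canonical bin {`AAAA`,`TTTT`}. The reason is quantitative: at
  small $f$ the entropy response to a concentrated contaminant is
  second-order, $\Delta H \approx f(\log M - H - \sum_i q_i \log r_i) -
  \tfrac12 f^2 \chi^2(Q\|P)$, where $Q$ is the contaminant spectrum and
  $r_i$ the background abundance of its bins. A contaminant spread over
  many bins (as a true random barcode would be) has a small $\chi^2$ term,
  and the first-order term — whose sign depends on whether the
  contaminant's bins happen to be rare or common in the background — can
  make 1% contamination *raise* the entropy. (Real data show the same
  physics: entropies of mildly diluted samples are essentially flat.)
  Palindromic k-mers are particularly treacherous: they occupy
  single-member canonical bins that carry half the background mass of
  ordinary bins, so palindrome-rich contaminants systematically look
  "rare" and push entropy up at first order. A homopolymer maximizes the
  spectral concentration per unit of contaminant mass
  ($\chi^2 \approx M - 1$), making the entropy decrease monotone in $f$
  across the whole default series for essentially every random genome set
  — and homopolymer stretches are themselves the canonical low-complexity
  artifact of real libraries. Any specific cassette sequence can be
  supplied instead; with a long random cassette, expect the $f \le 0.05$
  steps to be indistinguishable by entropy even though the aberrant-bin
  comparison still identifies the cassette k-mers.

**Planted clusters.** For cluster-count recovery the generator plants
$g$ groups of genomes. Group transition matrices are bias directions of
fixed magnitude away from the uniform matrix, and candidates are accepted
on their *expected tetranucleotide profiles* (computed analytically from
the chain's stationary distribution): comparable deviation norms, low
mutual alignment. This matters because the matrix-to-profile mapping is
anisotropic — equal matrix-space separations can differ two-fold in
profile space, and the largest-gap rule for selecting the cluster count
assumes separations of comparable scale. Members jitter the group matrix
by mixing in 8% of a fresh random matrix. With 20-kb genomes the
within-group spread (jitter plus counting noise) stays well below the
between-group distances, and the planted count is recovered essentially
always; k-means then reproduces the Ward partition with kappa ≈ 1. On real
genome collections — where group separations are whatever nature provides
— neither property is guaranteed, which is precisely why the kappa
cross-validation is part of the workflow.

## Numerical conventions and edge cases

* $0 \log 0 = 0$; no pseudocounts in the entropy (plug-in estimator). The
  plug-in bias at the default scales ($\sim M/2N$ nats with
  $N = 1.6\times10^6$) is far below reporting precision.
* Entropy of an empty profile (no counted k-mers) is an error, not 0.
* Rank correlation of constant frequency vectors (e.g. two exactly
  uniform profiles) is undefined; `compare_profiles()` reports `NA` there
  rather than failing, since the QC report must survive degenerate inputs.
* Cassette filtering with `max_mismatches = 0` is exact substring
  matching: a read is removed if the cassette (or its reverse complement)
  occurs in it, or if a read window of `min_match_length` (clipped to the
  read length) occurs in a doubled-cassette concatemer on either strand —
  the doubling catches fragments spanning self-ligation junctions. The
  mismatch-tolerant mode scans all alignments and is quadratic; it is
  meant for small, targeted screens.
* All generator randomness derives from one user seed through fixed
  per-stage offsets, so an entire simulated study is bit-reproducible.
* `kmer_space()` supports $k \le 12$; the code-to-bin lookup is
  $O(4^k)$ memory, about 130 MB at the top of that range.

## Known limitations

* The entropy score detects *compositional* pathology. Contamination by a
  sequence whose k-mer spectrum resembles the community's (say, another
  genome) moves the score little; restricted to genuinely genome-derived
  reads, entropies across a whole dilution series are nearly identical.
* The synthetic generator's genomes are stationary first-order chains;
  claims validated on them transfer to real data only insofar as
  tetranucleotide composition drives the phenomenon, which is the method's
  own premise.
* Reproducing published per-sample entropy values requires the original
  read sets (public under their archive accession) and, for the
  entropy-vs-mapping association, externally computed mapping rates;
  neither is bundled. The normalization flag (`canonical` vs `raw`) exists
  so both plausible conventions for such published values can be tried.
* Decomposing a metagenome's spectrum into a linear combination of genome
  signatures is explicitly not attempted.
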