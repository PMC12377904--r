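---
title: "Uniqueness-normalized strain quantification: model and design notes"
author: "StrainQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uniqueness-normalized strain quantification: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StrainQuant)
```

## The problem

Defined (synthetic) microbial communities are assembled from known,
genome-sequenced isolates, so every shotgun read can in principle be
assigned to a member genome. The difficulty is strain relatedness: when two
members are near-clonal isolates of the same species, most reads from
either of them match both genomes and carry no strain information. Any
estimator that divides mapped reads by *total* genome length (FPKM/RPKM)
therefore systematically underestimates strains that have close relatives
in the community, because only the reads covering their few discriminating
sites survive an unambiguous-mapping filter.

StrainQuant normalizes by the number of *uniquely mappable sites* instead.
For each slice of each genome it counts the canonical k-mers that occur
exactly once in the entire community reference, and rescales
perfect-unique fragment counts into

$$\mathrm{FUKM} = \frac{F}{(U/10^3)\,(M/10^6)}$$

fragments per thousand unique k-mers per million mapped fragments, where
$F$ is the slice's perfect-unique fragment count, $U$ its unique canonical
k-mer count, and $M$ the sample's total mapped fragments. If a strain
keeps only a fraction $u$ of its sites discriminative, both $F$ (the reads
that can map uniquely) and $U$ (the k-mers counted as unique) shrink by
essentially the same factor $u$, so their ratio — and hence the abundance
estimate — stays unbiased.

## Reference side: subcontigs and the uniqueness index

Each member genome is supplied as one FASTA (strain id = file stem).
Contigs are split into **subcontigs**:

* The maximum core size is the smallest per-genome N50 in the community
  (overridable), so every genome is sliced to the build quality of the
  worst assembly and no strain gains estimates merely from longer contigs.
  A contig of length $L$ is cut into $\lceil L/\mathrm{max}\rceil$ pieces
  of core size $\lceil L/\mathrm{pieces}\rceil$, the last core absorbing
  the remainder; the cores tile the contig exactly. This equal-split rule
  is the simplest one that maximizes subcontig size under the N50 bound;
  the bound applies to cores, with the 500 b flanks added on top.
* Each subcontig's stored sequence extends its core by `overlap` (default
  500) bases on each side so fragments straddling a core boundary can
  still map end-to-end. The duplicated flank k-mers of adjacent subcontigs
  of the same contig consequently become non-unique; likewise a fragment
  falling entirely inside a shared flank hits two subcontigs and is
  discarded as ambiguous. Both effects are accepted: they touch a fixed,
  small band per boundary, affect all strains alike, and vanish for
  inserts longer than the overlap.
* Contigs shorter than `minContigSize` (default 10 kb) are kept whole and
  flagged `excluded`. They are plausible multi-copy elements (plasmids,
  transposons): their k-mers still mark shared content non-unique and
  reads mapping to them still count toward total mapped fragments, but
  they contribute no FUKM estimate.

The k-mer size is twice the mate length plus one (301 for 150 b reads,
incremented if ever even so canonical forms are palindrome-free). The
choice ties the uniqueness index to mappability: a read pair covers
$2 \times 150 = 300$ bases, so the probability that a fragment is
unambiguous (at least one discriminating site under its mates) tracks the
probability that a 301-mer window is unique, which is what makes the FUKM
numerator and denominator shrink together for near-clonal strains.

K-mers are canonicalized (lexicographic minimum of window and reverse
complement) and hashed with FNV-1a 64-bit — a fixed, documented,
platform-stable hash; at desk scale ($<10^7$ distinct k-mers against a
$2^{64}$ space) collisions are negligible. Windows containing any non-ACGT
character emit nothing. Uniqueness means *multiplicity exactly one across
the concatenated k-mer streams of all subcontigs*: a k-mer repeated within
one subcontig is non-unique just like one shared between strains. This
multiplicity-1 contract is verified in the tests against a brute-force
dictionary oracle.

## Sample side: perfect-unique fragment counting

Reads are filtered before mapping: trailing poly-G runs of at least 10
bases are trimmed from 3' ends (two-color chemistry artifact; the run
threshold is the conventional trimmer default), then pairs with any
ambiguous base or a mate under 50 b are dropped.

The mapper is exact: a pair hits a subcontig only when both mates match
its sequence perfectly, full-length, on opposite strands in convergent
orientation with non-negative inner gap. No mismatches, gaps or clipping —
sequencing errors simply cost a fragment, which the normalization absorbs.
Pairs whose hits span two or more subcontigs are discarded as ambiguous;
multiple hit positions on a single subcontig still count as unique to it
(repeats within one subcontig carry no cross-strain ambiguity). There is
no upper insert bound; the span is implicitly bounded by the subcontig.
Implementation is seed-and-verify (every 31-mer of the reference indexed,
candidates verified full-length), which cannot miss a perfect hit; the
tests compare its verdicts against an all-offsets scan. Base qualities are
ignored — a perfect match is a sequence-level criterion. External
alignments can be imported from SAM/BAM instead, keeping only primary,
properly-paired, edit-distance-0, full-length-match templates.

## Per-strain estimates

Excluded subcontigs and subcontigs with zero unique k-mers (FUKM
undefined, no information) are dropped from the estimate lists; their
fragments remain in the total mapped denominator, since they are real
mapped data. Per strain the package reports:

* **mFUKM** — the median subcontig FUKM (mean of the central pair for even
  counts, the standard convention).
* **wpFUKM** (recommended) — subcontigs are sorted ascending by FUKM (ties
  broken by subcontig id for run-to-run determinism) and the FUKM of the
  first subcontig at which the running unique-k-mer sum reaches $p\%$ of
  the strain's total is returned (no interpolation; default $p = 60$).
  Weighting by unique k-mers lets slices rich in uniquely mappable sites
  dominate; higher $p$ trades false negatives for false positives in
  presence calling.
* **FPKM** — the baseline from the same fragment counts, total genome
  length (all contigs, including excluded ones) in place of unique k-mers.
* **relative abundance** — the strain's share of summed wpFUKM; a strain
  is called present iff its wpFUKM is positive.

When nothing maps, all estimates are reported as zero.

## The simulator

The simulator generates the *study conditions*, not arbitrary data:

* **Relatedness** — an ancestor sequence (i.i.d. bases at a set GC) is
  mutated by independent per-site substitution. The benchmark community
  (`uniformCloneDesign`) derives 8 lineages at 5% divergence from one
  100 kb ancestor (pairwise ~10%) and gives 4 of them near-clonal partners
  at 0.2% divergence — a few hundred substitutions per 100 kb, the
  same-species regime (ANI ≈ 99.8%) where FPKM collapses; divergences are
  parameters, not constants.
* **Assembly quality** — genomes are cut at random positions so the contig
  N50 lands within a factor two of a target (default 20 kb), exercising
  the smallest-N50 splitting rule and the small-contig exclusion;
  concatenating contigs always reconstructs the genome.
* **Abundance scenarios** — uniform; log-normal; zero-inflated log-normal
  (absence probability 0.3); exponential; log-step (2 tiers, 30-fold
  apart by default); and "missing" (uniform with a subset absent).
* **Reads** — fragments are allotted to strains by a multinomial with
  weights proportional to abundance × genome length (abundance means
  *cell* abundance, so coverage is proportional to abundance); starts are
  uniform; insert lengths are Normal(400, 50) truncated to
  [2 × read length, genome length] (the insert distribution is a package
  choice, not a community property); mates are read inward from opposite
  strands; substitution errors are i.i.d. at a configurable rate (0 for
  the benchmarks — the perfect mapper discards errored fragments anyway,
  so the error rate only rescales depth). Reads are drawn from the full
  genome, not the fragmented assembly, so a small fraction of fragments
  spanning contig breaks is unmappable — as with real assemblies.

All randomness flows from explicit seeds (one per design, with fixed
offsets between generation stages), making every artifact byte-reproducible.

What the simulator does **not** model: indels and structural variation,
position- or quality-dependent error profiles, GC or fragmentation bias,
duplicates, contamination. Passing benchmarks therefore demonstrate the
normalization logic under controlled relatedness and composition — not
robustness to every artifact of real libraries. On real data those
artifacts mainly reduce the number of perfectly mapping fragments, which
FUKM tolerates by construction, but they are not exercised here.

## Benchmarks and problem sizes

The evaluation module scores an estimate against the design truth with
Jensen–Shannon divergence (base 2, so values lie in [0, 1]; inputs
normalized to proportions first; $0\log 0 = 0$, so strains absent from
both vectors contribute nothing — the convention, rather than row
dropping, implements the "absent strains don't count" rule), the
coefficient of variation (sample sd over mean, in percent — flatness for
uniform designs), max/min fold-range, log10 Pearson correlation (zeros
replaced by the minimum finite log10 across both vectors minus 1), and
presence/absence precision/recall/F1 with presence = positive.

The packaged benchmark sizes are chosen for a laptop-class run: the
12-strain uniform community uses 100 kb genomes at 40× mean coverage
(160 000 pairs); composition-recovery designs use 10 strains × 30 kb with
depth set so the least abundant present strain reaches 12× coverage
(~25 000–190 000 pairs depending on the drawn composition); oracle
equivalence suites use ~100 toy communities (k ∈ {5, 7, 31}) and >10 000
fragments. At these scales the uniform benchmark reproduces the method's
qualitative signature — wpFUKM CV of a few percent and fold-range near 1
while FPKM CV is an order of magnitude larger — and skewed compositions
are recovered with JSD well under 0.02 and perfect presence calls.

## Numerical and degenerate-input choices

* Empty estimate list (strain with no usable subcontigs): mFUKM and
  wpFUKM are reported as 0 with `n_subcontigs_used = 0` flagging it.
* All strains absent in a drawn composition: an error, nothing to simulate.
* Insert resampling: draws outside [2 × read length, genome length] are
  redrawn, with a hard failure after 1000 rounds.
* The wpFUKM percentile threshold uses "first subcontig reaching ≥
  $p/100 \times U$" — no interpolation at exact boundaries.
* The reference writer emits uncompressed FASTA/TSV/JSON so that repeated
  builds are byte-identical.

## Known limitations

* Exact matching means long-read or high-error chemistries would retain
  few fragments; the method targets short accurate paired reads.
* Abundances are relative; absolute calibration (copies per gram) is out
  of scope.
* A strain whose genome is entirely contained in another member (zero
  unique k-mers everywhere) is unquantifiable and reported absent; the
  unique-k-mer fraction accessor (`uniqueKmerFraction`) is the screen for
  that situation.
* Ambiguity is defined at the subcontig level; a fragment shorter than
  the overlap that lands wholly inside a shared flank is discarded even
  though it is strain-unambiguous. Negligible for inserts > overlap.
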