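---
title: "Negative training data for regulatory sequence models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Negative training data for regulatory sequence models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(negbench)
```

## The problem

Sequence classifiers for regulatory activity — gapped k-mer support vector
machines, convolutional networks — are trained on putative active elements
(open-chromatin regions such as DNase I hypersensitive sites) against a
*negative* set of putatively inactive sequence. Two constructions dominate
practice:

* **k-mer-preserving shuffles** of the positive sequences: cheap, synthetic,
  and exactly composition-matched per sequence;
* **matched genomic background**: real genome windows matched to the
  positives for length, repeat content and GC.

The choice is consequential. A model trained against shuffles can score
highly on its own hold-out yet collapse when the negatives are natural
sequence, because part of what it has learned is *artificiality* — the rare
words that shuffling creates — rather than regulatory signal. negbench
implements both constructions, a reference linear classifier over explicit
gapped k-mer counts, the three evaluation tasks (hold-out classification,
tissue-specific classification, quantitative activity prediction), and the
composition diagnostics that explain the differences. A synthetic-genome
simulator with planted transcription-factor motifs makes the entire study
reproducible from a single seed, with no external data.

## k-mer-preserving shuffling

`kmer_shuffle(x, k)` permutes a sequence while conserving its exact k-mer
multiset. For `k >= 2` this is the Altschul–Erickson construction: the
sequence is an Eulerian path on the de Bruijn graph whose vertices are its
(k−1)-mers and whose edges are its k-mers. We draw a uniform random
arborescence oriented toward the terminal vertex with Wilson's
loop-erased-random-walk algorithm, place each vertex's arborescence edge
last in an otherwise random edge order, and walk from the initial vertex.
Every emitted sequence has exactly the input's k-mer counts (hence all
j-mer counts for j ≤ k, hence identical GC), and the first and last
(k−1)-mers equal the input's. Every valid shuffle has positive probability
of being emitted; the distribution over valid shuffles is approximately,
not exactly, uniform, which is the accepted trade-off for this family of
algorithms. `k = 1` is a plain seeded permutation of the letters.

As in common practice, `select_min_overlap_shuffle()` draws a configurable
number of candidate shuffles per positive (200 by default) and keeps the
one sharing the fewest **distinct** 8-mers with the original; counting
shared 8-mers with multiplicity is available via `multiset = TRUE`. Each
record gets its own RNG stream derived from `(seed, record id)`, so results
are independent of processing order and of which subsets are generated.

## Matched genomic background

`sample_matched_background()` re-implements null-sequence sampling with the
operational parameters used for open-chromatin studies: candidate windows
are drawn uniformly over the genome in batches (`batchsize = 10000`) for at
most `n_max_trials = 100` rounds; tolerance 0 for length and repeat content
(soft-masked base counts must match exactly; lowercase is the only mask
signal in a soft-masked FASTA); GC within `t_gc` (0.02, 0.05 and 0.1 are
the studied settings); no overlap with the positives, a caller-supplied
exclusion set, or previously accepted negatives; sampling without
replacement within a run. Each negative is paired to one positive, greedily
in input order — the stricter reading of the aggregate-matching
alternative. If fewer than `min_match_rate = 80%` of positives can be
matched the sampler fails with a per-GC-bin report of the unmatched
positives; between 80% and 100%, datasets are balanced by dropping the
unmatched positives, so classification sets stay 1:1 and the
"random AUPRC equals prevalence" baseline remains interpretable.

`sample_histogram_matched()` implements the improvement suggested by the
tolerance mode's known failure: instead of `|ΔGC| ≤ t_gc`, the negative
must fall in the *same GC histogram bin* (width 0.02) as its positive, so
the negative set reproduces the positive GC distribution bin-exactly
wherever the genome supplies windows; shortfalls are reported per bin and
never silently substituted. Tolerance matching drifts systematically — for
a GC-rich positive most qualifying windows sit at the low edge of the
tolerance band, and the hardest positives go unmatched entirely — which is
visible as a larger Kolmogorov–Smirnov distance between positive and
negative GC distributions, especially when the positive distribution is
bimodal.

## The reference classifier

The learner is a ridge-regularised logistic regression over **explicit**
gapped k-mer counts: all `C(l, k) * 4^k` tokens of `l`-long words with `k`
informative positions, counted over every window, with a token and its
reverse complement collapsed to one canonical feature. The weighted
gkm kernel of LS-GKM is deliberately not reproduced: an explicit feature
map with a linear model preserves the feature space that matters for the
questions studied here — negative-set composition, not kernel weighting —
while remaining exactly testable and fast at desk scale. The package
default is `l = 10, k = 6` (the standard setting for regulatory sequence
prediction); the synthetic benchmark uses `l = 6, k = 4`, which keeps the
feature space at `15 * 256 = 3840` and training at a few seconds without
changing any qualitative behaviour. Regularisation strength comes from a
fixed small grid (1, 0.1, 0.01, 0.001), selected on the validation
chromosome when one is supplied; nothing else is tuned.
`train_replicates()` reproduces the repeated-training protocol used for
stochastic learners (train n times, keep the validation-median model,
lower index on ties); with this deterministic learner all replicates
coincide. A configurable convolutional model was left out deliberately:
the benchmark's conclusions concern the negative data, and the linear
learner exercises every contract the pipeline defines.

## Evaluation

`auroc()` computes the Mann–Whitney statistic from mid-ranks (ties count
half) with the score-sweep ROC curve; `auprc()` uses the non-interpolated
step-curve area (precision at each achievable recall), under which a
random scorer's expected AUPRC equals the positive prevalence;
`recall_at_threshold()` defaults to probability 0.5 — the threshold is a
documented choice, recorded in the result, since margin 0 is the natural
cut for a logistic model. `spearman()` is the Pearson correlation of
mid-ranks. `wilcoxon_signed_rank()` drops zero differences, uses average
ranks, and computes the exact two-sided p for up to 25 pairs by dynamic
programming over the full sign-assignment null (ties handled exactly);
beyond that, a normal approximation with continuity and tie corrections.

## The synthetic genome

`generate_genome()` builds a multi-chromosome soft-masked genome designed
to carry the statistical structure the benchmark's questions depend on:

* **Higher-order word structure.** Background sequence is an order-2
  Markov chain whose transition preferences are Gamma-perturbed
  (`chain_concentration = 5`, i.e. transition multipliers with SD ≈ 45%)
  and CpG-depleted (`C→G` damped to 0.25), with the base distribution
  re-solved numerically so the stationary GC hits `background_gc = 0.41`.
  This matters: a genome with no structure beyond its nucleotide
  composition makes k = 2 shuffles of non-motif sequence statistically
  indistinguishable from the original, and the entire
  shuffle-versus-background contrast collapses to motif presence. Real
  genomes are strongly non-uniform in word usage; the perturbed chain
  reproduces that property (common and rare words, size-biased sampling of
  common words by genomic windows) at a strength where composition signal
  and motif signal coexist rather than one swamping the other.
* **GC-rich islands** (rate 12/Mb, 2 kb, stationary GC 0.62) emulate
  CpG-island/promoter territory. With a fraction of elements placed inside
  islands (default 0.15, a free parameter — promoter-like elements are a
  minority of open chromatin), the positive GC distribution is bimodal;
  with the island rate at zero it is unimodal.
* **Repeats** are soft-masked blocks copied with 10% substitution from a
  few family consensus sequences, so repeat-derived words are genuinely
  frequent genome-wide and repeat-count matching is meaningful.

`plant_elements()` places non-overlapping 300 bp elements outside repeats,
assigns a shared pool across cell lines (default 30%) plus line-exclusive
elements, and writes motif instances into the genome: instances are
sampled from the PWM columns on a random strand and rejection-sampled to
score above the scanner's detection threshold, so planted sites are bona
fide detectable binding sites and a scan of the emitted positives recovers
them. The synthetic motif library holds 8 PWMs of width 8–12 with one
dominant base per column (probability 0.9, IC ≥ 8 bits), partitioned into
per-line active sets with controlled overlap. `make_replicate()` produces
jittered/thinned replicate peak sets; `simulate_activity()` produces
reporter-style log2 readouts that are linear in motif density and GC with
Gaussian noise.

What the simulator does **not** model: nucleosome positioning, DNA shape,
three-dimensional contacts, read-level noise, cooperative or spaced motif
grammar, and the full heterogeneity of real repeat families. Passing
benchmarks on this genome therefore demonstrates that the pipeline's
machinery reproduces the studied phenomena under controlled conditions —
not that any particular real dataset would show effects of the same size.

## Composition diagnostics

`build_kmer_table()` counts every overlapping 8-mer on the forward strand
of all chromosomes (65,536 entries, zeros allowed, non-ACGT windows
skipped) and Z-transforms the counts; `sequence_kmer_zscores()` looks up
each record's 8-mers. On the synthetic benchmark the class ordering of
mean genome-frequency Z-scores — shuffles < positives < genomic background
— reproduces the rarity phenomenon that explains shuffle-trained model
bias. `scan_motifs()` scans both strands with log-odds matrices; the
threshold is the smallest score whose exact p-value under the background
base distribution, computed by dynamic programming over the discretised
PWM score distribution, is at most 1e-4 — the semantics of
p-value-thresholded scanners without importing one. 8-mer counting is
forward-strand (canonical collapsing available via a flag); whether the
original analysis collapsed strands is not documented, so the simpler
behaviour is the default.

## The benchmark and its scale

`run_benchmark()` wires everything together: genome and peaks, negative
sets (a shuffle-k sweep and GC-tolerance sweep), chromosome hold-out
splits (validation chr21, test chr8, everything else — autosomes and sex
chromosomes alike — trains), one model per negative set per evaluated cell
line, the three tasks, and the diagnostics; the report carries every
metric keyed by line × model × test composition plus a manifest with all
effective parameters. Determinism is end to end: one global seed fans out
to per-stage, per-record streams.

Default problem sizes are deliberately desk-scale: a 4.8 Mb four-chromosome
genome, two cell lines of 500 peaks each, 20 shuffle candidates per
positive, and `l = 6, k = 4` features; a full two-line benchmark runs in
about a minute. These sizes were chosen once, as the smallest at which the
hold-out, tissue and activity contrasts are comfortably resolved, and are
config values — the paper-scale settings (seven datasets of 10^5 peaks,
200 candidates, `l = 10, k = 6`) are reachable through the same
configuration surface given hardware.

Two reporting conventions follow the source study's: cross-composition
drops are summarised as means across the evaluated cell-line models (the
original figures report means over seven models), and the tissue-specific
sets are evaluation-only, restricted to the hold-out chromosomes.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout; odd-length interval
  centers floor to the lower coordinate; narrowPeak summit columns are
  ignored in favour of the geometric center.
* The 70% peak-overlap rule is implemented against the shorter peak
  (one-sided), with a reciprocal mode available; the original phrasing
  does not disambiguate, so neither mode is asserted as canonical.
* Tissue-specific overlap (30% rule) is measured relative to the peak
  under consideration.
* Sequences shorter than the featurizer's word length give empty feature
  rows with a warning; records containing non-ACGT characters are
  filtered before modelling, with per-reason drop counts.
* The exclusion-pattern defaults for chromosome filtering are suffixes
  `_alt`, `_random` and prefix `chrUn`; the categories are fixed, the
  patterns configurable.
* All-zero difference vectors make the signed-rank test degenerate
  (flagged, no p); constant inputs make Spearman undefined (flagged NA).
* Ties: mid-ranks everywhere (AUROC half-credit, Spearman average ranks,
  signed-rank average ranks with exact-tie DP).

## Known limitations

The linear explicit-feature learner is a stand-in for kernel gkm-SVMs and
will not reproduce kernel-specific effects; absolute metric values on
synthetic data are not comparable to values measured on ENCODE-scale real
data (the package reproduces directions and mechanisms, not magnitudes);
and real-mode inputs must already be on the working assembly — no liftover
is provided.
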