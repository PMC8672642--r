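---
title: "Simulating and benchmarking long-read structural-variant detection with svforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and benchmarking long-read structural-variant detection with svforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svforge)
```

## Why simulate structural variants?

There is no fully resolved gold-standard set of structural variants (SVs —
genomic variants of at least 50 bp: deletions, insertions, duplications,
inversions, translocations) for any human genome, so the accuracy of SV
callers on long sequencing reads cannot be measured directly on real data.
svforge provides the alternative: plant a known set of SVs into a reference,
simulate long reads with realistic context-specific errors, run callers (or
the bundled pseudo-callers), and score their output against the planted
truth. The same machinery drives a rule-based consensus combiner that merges
several callers' VCFs into one call set.

## The diploid SV model

Events live in a plain data.frame (`sv_events()`): type, 1-based start on
the reference, the reference span consumed, the variant length, an inserted
sequence where applicable, a copy number for duplications, and a genotype
(`HOM`, `HET_H1`, `HET_H2`). `apply_svs()` rebuilds each chromosome in one
left-to-right pass and returns both haplotypes plus a merged sequence in
which every event is applied homozygously. The length of every output is
exactly the reference length plus the signed sum of per-event deltas
(+L for insertions, −span for deletions, +L·copies for tandem and inverted
duplications, +L−span for complex substitutions, 0 for inversions and
reciprocal translocations); this identity is asserted in the tests for
thousands of random event sets, not sampled.

Two event types deserve comment:

* **Complex substitutions (CSUB)** delete a region and replace it with
  sequence copied from a randomly chosen distant locus of the same genome.
  The deleted span and the inserted length are drawn independently, so a
  CSUB generally changes the haplotype length.
* **Translocations (TRA)** are modelled as a reciprocal exchange of
  chromosome-end segments, written to VCF as two breakend (BND) record
  pairs. The exchanged segment length follows the same per-type length law
  as other events; an arbitrary interior breakpoint would make the exchanged
  tails megabase-scale and impossible to place without overlap at realistic
  event densities. A consequence worth knowing: each translocation consumes
  the ends of two chromosomes, so at most `floor(n_chroms / 2)` are
  placeable, and the generator says so explicitly rather than spinning.

Random placement (`generate_random_svs()`) draws per-type log-uniform
lengths — a heavy-tailed but bounded law that reproduces the qualitative
shape of real SV length spectra without committing to a parametric fit the
data do not support — and positions under a telomere-biased law: every
position inside the terminal `window` bp of a chromosome carries `weight`
times the placement mass of an interior position, giving a telomeric
fraction of exactly `w·u / (1 + (w−1)·u)` for uniform telomere mass `u`.
This mirrors the elevated SV density seen near telomeres in real genomes.
Overlaps are resolved by vectorized rejection rounds; a set that cannot be
placed fails loudly after `max_rounds` rounds.

One deliberate strictness: intervals are reserved globally, not per
haplotype. The contract only requires events on the *same* haplotype to be
disjoint, but the merged all-SV output applies every event to a single
sequence, which is constructible only if H1-only and H2-only events never
overlap either. We prefer the stronger invariant over emitting a merged
sequence that silently drops events. For the same reason we forbid nesting
of events of any type; nothing in the truth-set semantics would define the
coordinates of a nested event unambiguously.

Coordinates are 1-based inclusive throughout (the VCF convention);
insertions attach *after* their `start` base. Truth sets round-trip through
both a TSV truth list and a VCF 4.2 writer that emits sequence-resolved
REF/ALT for deletions, insertions and complex substitutions (left-anchored;
right-anchored at position 1) and symbolic ALTs for the rest. Phase is kept
in the genotype column (`1|0`, `0|1`, `1/1`); an unphased `0/1` read back
from external files is assigned to haplotype 1 by convention.

## Context-specific error profiles

A sequencing-error profile stores, for each of the 64 trinucleotide
contexts, the substitution, insertion and deletion rate of the middle base,
a substitution-target distribution, and global indel-length distributions.
The generative model in `corrupt_sequence()` walks the template: at each
base with a full context the context's rates apply (the two terminal bases
use the profile's mean rates); a deletion removes a run drawn from the
deletion-length law and bases inside the run generate no further events; an
insertion of random bases may follow any emitted base and is attributed to
the context of the base 5' of the insertion point.

`train_profile()` is the exact inverse tabulation: for every reference
position it counts visits (match, mismatch, or deletion-run start — run
interiors are not independent observations and are excluded), substitution
and deletion-start events against that denominator, and insertions against
the emitted-base denominator. The first and last aligned column of every
read are skipped (no symmetric context), and deletion runs ending at a
read's final column are excluded from the length tally because they may
have been clipped by the read end — for genuine runs exactly one start
position per length meets that condition, so the exclusion does not distort
the length distribution. Contexts never observed receive the genome-wide
mean rate; substitution-target distributions fall back to uniform below 10
observations. Training indels longer than `l_max` (default 100 bp) are
clipped with a warning: at that scale they are structural variants, not
sequencing errors. Because trainer and generator are exact inverses, the
train→simulate→retrain loop closes: in replicated calibration runs the
per-context z-scores of retrained rates against generating rates are
standard normal (2304 replicated values: mean −0.02, sd 1.01). The closure
test therefore uses a bound calibrated for the 192 simultaneous comparisons
(|z| ≤ 4.5, false-failure ≈ 0.1%); a per-comparison 3σ bound would falsely
fail about 40% of perfectly calibrated runs.

Overall accuracy is never stored: it is recomputed as one minus the
expected errors per template base on a uniform-context genome
(substitutions count 1, indel events their expected length).
`scale_profile()` multiplies all 192 rates by the single closed-form factor
`(1 − target) / (1 − current)`, preserving relative context differences;
contexts pushed past `sub + del = 1` are clipped with a warning and an
unreachable target raises. Profiles serialize to a sectioned plain-text
format and reload to within 1e-9.

The trainer consumes either text SAM (CIGAR M/=/X/I/D, soft/hard clips
skipped; convert BAM with `samtools view` first) or the package's own
alignment records; `align_reads_to_reference()` wraps
`Biostrings::pairwiseAlignment()` so toy-scale training needs no external
aligner. SAM stores sequences in reference orientation, so reverse-strand
alignments need no special handling; the read simulator likewise records
truth edits in template orientation before reverse-complementing the output
read.

## Read simulation

Four metrics control a run: coverage, median read length, a length range,
and accuracy. Read lengths follow a log-normal law truncated to the range,
with the location parameter solved numerically so the *truncated* median
equals the requested median (a plain log-normal median would drift once
truncation is asymmetric). Reads pick a haplotype with probability 1/2 per
read (Bernoulli rather than an exact half-half split — the tiny extra
variance is what a real diploid library shows), a chromosome proportional
to length, a strand 50/50, and a start position either uniform or driven by
a windowed depth profile (windows weighted by depth × width, so realized
per-window coverage is proportional to requested depth; zero-depth windows
get no reads). Reads are clipped at template ends rather than wrapped;
simulation stops once the summed template span reaches the coverage target,
so realized yield overshoots by at most one read. FASTQ output carries a
constant quality derived from the profile accuracy (−10·log10(1−acc));
per-base quality realism is out of scope. Everything derives from one seed
via fixed per-stage sub-seed derivation (`derive_seed()`), so outputs are
byte-identical across reruns and independent of any execution order.

## The benchmark

Calls are filtered (FILTER PASS — with '.' and missing treated as PASS,
since many callers emit them — length ≥ 50 bp with length-undetermined
records kept, and ≥ 3 supporting reads by default, 5 recommended at 30×
depth and above; records lacking any support field are kept rather than
invented). A call matches a truth SV when its position lies within 1600 bp
and, if the caller determined a length, the lengths agree within 35% of the
truth length for truth SVs longer than 300 bp and exactly for shorter ones.
The short-SV rule is genuinely ambiguous ("no margin" could mean "no length
check"); we default to the strict reading and expose `short_len_margin` for
the other. Type and genotype never gate matching. Assignment is one-to-one,
greedy by smallest position difference with ties broken by smaller length
difference then input order — with a 1600 bp window and realistic SV
densities the assignment graph is almost always trivial, so a full optimal
matching would buy nothing.

A matched call scores

    0.4·max(0, 1 − |Δpos|/1600) + 0.2·max(0, 1 − |Δlen|/(0.35·truth_len))
      + 0.2·[type correct] + 0.2·[genotype correct]

so a perfect match scores exactly 1. Length-undetermined calls (e.g. BND)
earn no length credit. Reports carry recall, precision,
F = 2·(precision·recall)/(precision+recall), the total score
100·(Σ scores − #FP)/#truth floored at zero (each false positive costs one
full SV score; the floor covers the pathological all-FP case), per-type
recall/precision, mean per-parameter sub-scores and the perfect-match
count. Degenerate conventions: zero calls give recall = precision = F = 0.

## The consensus combiner

Caller VCFs are parsed tolerantly (symbolic ALTs, SVLEN/END/SVTYPE,
support from SUPPORT/RE/DV/SU INFO keys or the DV FORMAT field, anchor-base
normalization of sequence-resolved indels) and records below the
alternative-allele coverage floor (default 3 reads) are dropped at load
time. Calls from different callers cluster by a position-sorted
single-linkage sweep within the 1600 bp window, reusing the benchmark's
length-compatibility rule (margin taken on the larger length — the rule
needs to be symmetric between two calls, unlike the benchmark's
truth-anchored version); a group holds at most one call per caller, nearest
to the seed wins. A group is emitted when at least `min_callers` distinct
callers support it — 2 when 2–5 callers are combined, 3 when 6 are — or
when it matches a rescue rule admitting a low-false-positive single-caller
category (defaults: homozygous calls from SVIM; heterozygous insertions and
deletions from Sniffles; `--no-singletons` disables rescues). Position and
length come from the highest-priority present caller under the
position/length ranking (pbsv first), the genotype under the genotype
ranking (cuteSV first), and the type from the highest-priority caller with
a resolved (non-BND) type; conflicting types among lower-priority callers
are simply outvoted by rank, which is deterministic and transparent. The
rankings beyond the two anchored choices are configuration defaults in the
stated caller order and fully user-overridable. Absence of all of cuteSV,
Sniffles and pbsv warns but does not fail. Combining a consensus with
itself reproduces it record-for-record.

## Pseudo-callers and the round trip

`perturb_truth()` turns a truth set into a caller-style call set with
controlled error modes — drop-out, Gaussian breakpoint jitter,
multiplicative length jitter, genotype flips, type confusion (e.g.
insertions typed as duplications, a failure mode real callers show), and
uniformly placed false positives at a deterministic per-Mb count. These
pseudo-callers emulate error *modes*, not any real caller's measured error
distribution, and they perturb the truth directly rather than calling from
reads: passing round-trip tests therefore demonstrates the bookkeeping and
scoring machinery, not SV-calling difficulty on real alignments.
`run_roundtrip()` chains every stage — toy genome, random truth, diploid
haplotypes, read simulation, a pseudo-caller panel, per-caller benchmarks,
combination, and a benchmark of the consensus under the same configuration
— into one seeded, rerunnable report.

## Numerical and scale choices

* Default test and round-trip scales (genomes of 0.1–24 Mb, tens to
  thousands of events, coverages of 3–200×) are chosen so every property is
  measured at sound statistical power while the whole suite stays
  single-CPU friendly; the profile-closure check runs at 200× over 100 kb,
  the composition check at the full 24,600-event scale on a 24 Mb genome.
* The synthetic-data defaults (50 bp minimum SV, 1600 bp matching window,
  35%/300 bp length margins, 0.4/0.2/0.2/0.2 weights, support floors 3/5,
  combiner thresholds 2/3 and rescue rules) are the reference conditions of
  the evaluation scheme, not tuning knobs.
* All randomness flows from one integer seed through `derive_seed()`
  (a fixed 31-bit string hash), so stages can be rerun independently and
  in any order.

## Known limitations

* No SNP or small-indel simulation: small variants influence small-SV
  detection in real data, and their absence makes simulated precision
  optimistic.
* No chimeric/junk reads, no per-base quality model, no signal-level
  simulation; FASTQ qualities are a constant placeholder.
* Pseudo-callers do not reproduce any real caller's error distribution;
  conclusions about real callers require running them on the simulated
  reads outside this package.
* TRA partner tails are reserved during generation, but events supplied by
  the user inside an exchanged tail on the partner chromosome are not
  remapped — the translocation wins.
* The combiner does not re-genotype from reads and performs no breakpoint
  refinement; it is a rule-based merge of existing records.
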