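---
title: "Haplotype phasing and segmental-duplication analysis of an IGHV-like region"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype phasing and segmental-duplication analysis of an IGHV-like region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ighvdup)
library(dplyr)
```

# The problem

The human immunoglobulin heavy chain variable (IGHV) locus on chromosome 14
contains large, recent segmental duplications. Allelic copies (the same
locus on the two homologous chromosomes) and paralogous copies (duplicated
loci on the same chromosome) of a gene segment can be diverged to similar
degrees, so diploid sequencing cannot reliably separate them. Sperm typing
resolves this: each sperm carries exactly one parental haplotype, so
allelic variants segregate into different gametes while paralogs travel
together. Typing a panel of short unique sequence tags across many single
sperm therefore reads each parental haplotype directly.

`ighvdup` implements that analysis end to end on synthetic material:

1. **synthetic genome** — IGHV-like regions with a planted tandem
   duplication (two complete copies plus one truncated copy) and donor
   haplotype pairs differing by repeat-copy deletion and private divergence;
2. **tag design** — unique non-coding tags at regular spacing and the four
   oligos per tag (forward/reverse/nested primers plus a single-base
   extension probe);
3. **sperm assay** — sequence-level tag detectability plus a noisy binary
   presence/absence assay over a sperm panel;
4. **phasing** — partitioning sperm into the two parental haplotypes and
   calling per-tag consensus statuses (`+`, `ud`, `-`);
5. **duplicate blocks** — dot-matrix self-comparison, diagonal-run
   chaining and tandem-unit inference;
6. **divergence** — pairwise alignment and the percent-difference
   arithmetic for allelic vs paralogous gene-segment pairs;
7. **mutation clock** — closed-form pseudogenization and divergence-time
   estimates.

# The synthetic generator: what it emulates

The generator's defaults mirror the structure of the studied region: a
region of several tens of kb; a duplication unit of ~24.5 kb copied into
two complete tandem copies plus a ~1 kb truncated copy; per-copy
substitution fraction 0.022, so two copies are ~4.4% diverged pairwise;
six donors whose haplotypes are either intact, missing one or both
complete copies, or privately diverged within the repeat; tags at ~5 kb
spacing, at most 225 bp; panels of 49–60 sperm per donor.

Mutation is substitution-only (`mutate_seq()`): the replacement base always
differs from the original, so the generator's reported count *is* the
Hamming distance, which keeps the difference accounting downstream
unambiguous. Spacer sequence has uniform base composition — none of the
tested statistics depends on composition. The generator does **not**
emulate transposon insertions, recombination or gene conversion, realistic
human base composition, or the quantitative two-channel microarray
intensities (detection is binary with noise). Passing tests therefore
demonstrate the correctness of the algorithms under clean substitution
divergence, not robustness to every feature of real genomic data.

The duplicated reference is built truncate-then-duplicate: gene templates
(including truncated pseudogene layouts) are placed first, then the unit is
copied. The opposite order is possible by planting the duplication before
adding features, but truncation-before-duplication matches the observation
that paralogous copies of the truncated segments have nearly equal lengths.

# Tag design and the oligo geometry

Tags are selected greedily left to right (`select_tags()`): past each
spacing boundary, the first window that overlaps no gene segment and
occurs exactly once in the region becomes a tag. Uniqueness is an exact
forward-strand scan (`count_occurrences()`, `max_mismatch = 0`); a
genome-wide homology search is out of scope for synthetic regions, where
the in-region scan is the binding constraint. Names follow the "VHS" +
kb-offset convention and are made unique if spacing drops below 1 kb.

Each tag gets four oligos (`design_oligos()`), all on the published
panel's geometry: forward primer at the tag start; nested primer internal
to the forward amplicon, same orientation; probe internal and close to the
nested primer but reverse-oriented; reverse primer at the tag end. The
probe's 3' end is placed so that the adjacent template base is A or G —
that base templates the single dye-labelled ddNTP (ddUTP vs ddCTP) in the
extension assay, and a placement with no A/G available is a design
failure. Primer lengths default to 20 nt (within 18–27), probes 20 nt
(within 20–24); melting-temperature balancing is deliberately not
modelled, since no thermodynamic claim is tested.

Multiplex compatibility (`check_compatibility()`) scores each unordered
primer pair by its longest perfectly complementary 3'-suffix (the
configuration that seeds primer-dimer extension) and reports pairs at or
above the threshold, default 4.

# Detectability and the noise model

A tag is undetectable on a haplotype (`tag_detectability()`) when any
primer or the probe has no site within tolerance anywhere in the sequence,
when primer mismatches fall in the 3'-terminal window (default: none
tolerated in the last 5 nt), or when the extension-template base no longer
matches the designed A/G base. Defaults (2 mismatches per primer, 1 per
probe) encode the observed failure modes: a two-base substitution centred
in a probe footprint, or a polymorphic extension base alone, abolishes
detection, while a single peripheral mismatch does not.

The assay simulation (`simulate_sperm_panel()`) assigns each sperm H1 or
H2 with probability 1/2 (no crossover within the region — the region
behaves as a single locus in gametes) and flips entries independently:
dropout 0.05 and false-positive 0.01 by default. True intensities are not
modelled; re-amplification validation in the underlying assay justifies
treating detection as binary.

# Phasing

`phase_sperm()` partitions sperm by similarity of their binary call
vectors: the two most dissimilar sperm seed two clusters, nearest-centroid
reassignment runs to convergence, and per-tag consensus per cluster is `+`
at ≥ 70% detected, `ud` at ≥ 70% undetected, `-` otherwise. Two guards
make the bipartition meaningful:

* each cluster needs at least `min_support = 5` sperm (panels of ~25 per
  haplotype make 70% consensus robust to 5–10% dropout);
* at least one tag on which the cluster consensuses disagree must
  segregate at an intermediate overall rate (20–80% detected). A genuinely
  heterozygous tag is transmitted to about half the gametes; apparent
  splits driven by correlated dropout sit near 0 or 1 and are rejected, in
  which case both haplotypes report the common pattern.

Labels are broken deterministically (the first sperm's cluster is H1);
all downstream logic treats the pair as a set. The unresolved symbol `-`
counts as "not detected" for run-finding and classification but is kept
distinct in outputs, since the assay cannot distinguish deletion from
heavy divergence.

`classify_tags()` calls a tag `undetectable_in_all` when no haplotype
detects it, `polymorphic` when detection varies, and
`non_polymorphic_detected` otherwise; `find_undetectable_runs()` extracts
maximal runs of consecutive undetectable tags per haplotype, and
`delimit_polymorphic_region()` reports the minimal polymorphic span with
its nearest detected flanks.

# Duplicate-block discovery

`dot_matches()` reports every window pair within the mismatch tolerance
(window 9 and exact matching by default, mirroring the dot-matrix tool
classically used on this region). Matching is hash-seeded: exact windows
via a window index; tolerant windows via pigeonhole seeding (a window pair
with ≤ m mismatches must share one of m + 1 exact segments) followed by
verification — the output contract is identical to the naive all-vs-all
definition, which the tests enforce against an independent per-diagonal
oracle.

`diagonal_runs()` chains matches on a diagonal when consecutive starts
differ by ≤ `max_gap` (default 50 bp — at ~4.4% pairwise divergence exact
9-mers still cover about two-thirds of a duplicated span, and 50 bp
bridges the gaps between them). `find_repeat_units()` then reads the
tandem structure off the self-comparison: the smallest diagonal ≥
`min_unit` carrying a sufficiently dense run is the unit length; the union
of run spans on that diagonal delimits the repeat; copies are laid out at
unit steps and flagged complete at ≥ 90% of a unit. Two numerical details
matter. First, runs must hold at least `min_density = 0.3` matches per bp:
genuine diverged copies keep most windows matching while chance chains of
isolated 9-mer hits (density ≤ ~0.06) would otherwise pass the span
filter. Second, `min_unit` constrains the *diagonal*, not the run span, so
a haplotype that has lost one complete copy is still recognised from the
short run between its remaining complete copy and the truncated copy.
Forward strand only by default: the region's repeats are direct repeats.
Unit boundaries are the chained window extremes; no base-level realignment
is attempted, so boundary error up to about one window is expected.

# Divergence accounting

`global_align()` wraps Needleman–Wunsch global alignment (match +1,
mismatch −1, gap open −2, gap extend −1; a length-k gap costs 2 + k).
Because the published difference counts do not state how indels or length
differences enter, both conventions are explicit configuration:

* difference counting: `subs_only`, `subs_plus_indel_events` (default —
  the most conservative reading that still counts unequal-length pairs),
  or `subs_plus_indel_columns`;
* denominator: `len_b` (default — the second sequence's length divides
  the printed percent in the reference table's rows), `len_a`, `longer`,
  `shorter`, or `alignment_columns`. The reference rows themselves are
  not perfectly uniform: the two boundary comparisons against the
  truncated copy in one assembly divide by the first length, and one row's
  length cells cannot be reconciled at all; `ighv_divergence_rows()`
  records each row's self-consistent denominator and flags the
  irreconcilable row.

Percentages round half-up at 2 decimals; the per-1,200-bp translation
(`per_1200()`) rounds at 1 decimal. Rounding happens only at presentation;
all internal values are unrounded.

# The mutational clock

With mutation rate $\mu$ (substitutions/base/haploid genome/generation),
generation time $G$ years, exon length $L$ bp and stop-reachable fraction
$f$:

$$T_\text{point} = \frac{G}{\mu L f}, \qquad
  T_\text{all} = \frac{T_\text{point}}{1 + s}, \qquad
  T_\text{div}(d) = \frac{d\,G}{\mu}.$$

Defaults: $\mu = 1.1\times10^{-8}$, $G = 25$ y, $L = 355$ bp,
$f = 18/61$, structural multiplier $s = 2$ (structural inactivations
outnumber point inactivations about 2:1 among surveyed IGHV pseudogenes).
$f$ is computed by exhaustive enumeration (`single_hit_stop_codons()`):
18 of the 61 sense codons are one substitution from TAA/TAG/TGA. Treating
$f$ as the per-mutation probability of creating a stop is a deliberate
simplification of the calibration; the stricter per-mutation fraction
(counting stop-landing mutations among all $61 \times 9$ single-base
changes) is available as `stop_mutation_fraction(mode = "per_mutation")`
but is off by default. Divergence time uses single-lineage accumulation
($dG/\mu$, not $dG/2\mu$); halving it for two lineages would halve every
reported divergence time, so the choice is stated prominently rather than
buried. The ~355 bp exon total is approximate in origin but treated as an
exact default. At $d = 4.36\%$ the formula gives 99.1 million years at
one-decimal precision (99.09 unrounded).

```{r clock}
clock_report(0.0436)
```

# Problem sizes used by the test suite

The suite exercises every operation at sizes chosen to keep the geometry
of the study while remaining quick: planted-duplication recovery uses
500 bp units with a 120 bp truncated copy at 1.25% per-copy divergence
(100 seeds); dot-matrix matching is verified against the brute-force
oracle up to 2 kb; phasing recovery uses 17-tag truth patterns over panels
of 49–60 sperm at dropout 0.05 / false-positive 0.01 (100 replicates);
divergence self-consistency uses 100 substitution-only pairs up to 10%
divergence; the end-to-end pipeline determinism check runs a 6 kb region
with a 1.5 kb unit. The full-scale configuration (`pipeline_config()`
defaults) runs in well under a minute and is exercised interactively
rather than in the suite.

# Known limitations

* Real-data mode (FASTA + BED for an actual assembly region) is untested
  scaffolding; the published block lengths of 24,696/24,387/961 bp cannot
  be reproduced without the external assemblies and are out of scope.
* Substitution-only divergence means indel-mediated tag loss and Alu
  insertions are not simulated.
* Phasing assumes no crossover between tags within the region and exactly
  two parental haplotypes; contamination and diploid carry-over are not
  modelled.
* Inversions and reverse-strand repeats are invisible to the default
  forward-only dot-matrix scan.
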