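---
title: "bandmap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bandmap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandmap)
```

## The problem

Single-molecule sequencing platforms (PacBio, Oxford Nanopore) produce reads
of thousands to tens of thousands of bases with per-base error rates of
5--30%, dominated by insertions and deletions rather than substitutions.
Classical seed-and-extend mappers select a candidate region from exact seed
matches and align only within it, leaving the read ends soft-clipped; the
aligned fraction of each read (its coverage ratio) suffers. `bandmap`
implements the alternative strategy of committing to a *single alignment
starting position* per read and then aligning outward from it to **both**
read ends, so that every mapped read is covered end-to-end (soft clips can
arise only where the reference itself ends).

## The pipeline

### 1. Word index

The reference is indexed by every overlapping word of fixed length $k = 14$
on the forward strand. The index answers one query: all 0-based start
positions of a given word. A word-to-positions table keyed by 2-bit packed
integer codes (A=0, C=1, G=2, T=3; hence $k \le 15$) implements this
contract; a compressed full-text index (BWT-FM) would answer the same
queries in less memory, and at desk scale the answers, not the memory, are
the tested property. Integer codes also matter operationally in R: looking
words up by string would intern ~10^4 fresh strings per read in R's global
string cache, degrading garbage-collection time over long runs, while
integer `match` allocates nothing persistent. Words containing N are never indexed. Words occurring
more than `occurrence_cap` (default 512) times are masked -- they answer no
positions -- which bounds worst-case anchor collection on simple repeats
without affecting non-repetitive sequence. Multi-sequence references get one
index per sequence; anchoring and alignment never cross sequence
boundaries.

### 2. Anchor location by diagonal credibility

For a read $r$ of length $l_r$, every sampled read offset $i$ (default
step 1) contributes its word's match positions $p_i^1, \dots, p_i^{L_i}$
and their *modified positions* $o_i^l = p_i^l - i$. A modified position is
constant along a gap-free alignment diagonal, so true matches pile up near
one value of $o$ while spurious matches scatter. The credibility of a
candidate $(i, l)$ is

$$S(o_i^l) \;=\; \sum_{j} \sum_{k=1}^{L_j}
  \mathbf{1}\!\left[\,|o_j^k - o_i^l| \le L(r)\,\right],
  \qquad L(r) = 0.2\, l_r ,$$

a window count over *all* pooled modified positions, including the
candidate itself (so $S \ge 1$). The window tolerates the diagonal drift
that indels cause: with up to 30% errors the end-to-end drift is bounded by
$0.3\, l_r$ in the worst case and is far smaller in expectation, so
$0.2\,l_r$ is generous in practice. $L(r)$ is used as a real number; no
rounding is applied in the comparison. The efficient implementation sorts
the pooled positions once and counts each window by binary search; the test
suite proves exact agreement with the literal double loop.

The candidate with maximal credibility fixes the anchor: read offset $i$
and genome position $p_i^l$. Both the read and its reverse complement are
scored against the forward index, and the strand with the larger winning
credibility is aligned (ties prefer forward). Candidates are counted over
positions, not distinct words -- the literal double sum.

**Tie-breaking (a deliberate design choice).** Equal credibility scores are
common: on a clean diagonal every sampled word shares one modified position
and therefore one score. Among tied candidates `bandmap` picks the read
offset closest to the read midpoint, then the smaller genome position, then
the smaller read offset. The midpoint rule is not cosmetic: the banded
alignment stage sizes its band from the *full* read length
($b = \lceil 0.1\, l_r \rceil$) while each alignment segment runs from the
anchor to a read end. The band geometry (below) covers a unit-slope
alignment path exactly when the segment is at most $l_r/2$ -- that is, when
the anchor sits near the read middle. An anchor forced to a read end would
push the true path out of the band halfway through the matrix. Centring the
anchor is therefore the reading under which the default band coefficient
$\alpha = 0.1$ "just" covers realistic paths, which also matches how the
coefficient behaves empirically on noisy reads.

### 3. Low-column banded alignment

The anchor splits the read into an upstream segment $r_u$ (anchor to read
start) and a downstream segment $r_d$ (anchor to read end), and carves
genome segments $g_u, g_d$ of $\lceil 1.2 \times |r_{u/d}| \rceil$ bases
(clipped at the reference boundaries). The factor 1.2 gives the genome side
headroom for deletion-rich reads.

Each segment pair is aligned by a banded global dynamic program stored in a
*low-column* matrix of $(|r_{seg}|+1) \times (2b+1)$ cells, independent of
the genome segment length. Row $u$ holds genome columns
$sci(u), \dots, sci(u) + 2b$ where

$$ sci(u) = \max(\lfloor 1.2\,u - b \rfloor,\; 0), \qquad
   b = \lceil \alpha\, l_r \rceil,\; \alpha = 0.1 .$$

Cell $(u, v)$ of the reduced matrix is cell $(u, c)$ of the conceptual full
matrix with $c = v + sci(u)$; the previous row's copy of column $c$ sits at
$v' = v + sci(u) - sci(u-1)$. The recurrence is the textbook
match/insert/delete maximum with linear gap penalty $d$ (defaults: match
$+2$, mismatch $-2$, $d = 2$; the linear model coincides with gap-open
$-2$/gap-extend $-2$). Two indexing subtleties in the printed form of this
recurrence are resolved as follows: the genome base index of cell $(u,v)$
is $v + sci(u)$ (a function of the row, not of the column), and the
within-row gap term addresses $(u, v-1)$ -- the previous-row shift $v'$
does not apply inside a single row. N never matches anything.

**End conditions.** The alignment is global in the read and anchored at the
segment origin: row 0 is gap-penalized, every read base must be consumed,
and the reported score is the maximum over the deepest reachable row with
traceback from that cell. The genome overhang beyond the traceback end is
free -- the $1.2\times$ slack is deliberate headroom, and penalizing it
would punish every alignment. When a reference boundary truncates the
genome segment so severely that the band runs off the genome end before the
last read row, the unaligned read tail is reported as a soft clip rather
than forced into gap ops; this is the only source of S ops in the output.

**Tie-breaking.** Inside the recurrence: diagonal, then up (read-consuming),
then left. In the final row: the smallest genome column. These choices make
the output deterministic; equal-scoring alternatives exist for essentially
every noisy read.

The upstream pair is aligned by reversing both segments and reusing the
downstream algorithm; its ops are reversed back before the two halves are
concatenated (adjacent equal ops merged) into one CIGAR. The record's
reference start is the anchor genome position minus the genome bases the
upstream alignment consumed, and the alignment score is the sum of the two
segment scores. The anchor word's bases are re-aligned as ordinary members
of the downstream segment (re-alignment can only equal or improve a forced
match).

**Band coverage in practice.** The band is centred on the corner diagonal
of the $|r_{seg}| \times 1.2|r_{seg}|$ rectangle (slope 1.2), while
realized alignment paths have slope close to 1. With a centred anchor the
unit-slope path of an error-free read meets the lower band clamp exactly at
the final row of a half-read segment, and indel-rich paths can leave the
band over the last few percent of rows. The consequence is benign --
whole-read alignment, exact recovery of error-free reads, and stable
correct-read fractions are all preserved (and tested) -- but per-base
agreement near segment ends can degrade at high error rates. The aligner
reports an `edge_touch` flag per segment for diagnosing this; a larger
`alpha` widens the band at linear memory cost.

## The simulator: what it emulates, and what it does not

The simulator stands in for quality-aware SMS read simulators to keep every
test self-contained. It models: uniformly placed templates (drawn where the
whole template fits, so boundary reads are never truncated), random strand,
normal template lengths truncated to $[15, \text{genome length}]$, and a
flat per-template-base error probability with a fixed substitution /
insertion / deletion mix, default $(0.2, 0.5, 0.3)$ -- indel-dominated, as
in real SMS data. An insertion event emits one random base before its
template base. Every read carries an exact edit script from which the read
is reproducible base-for-base, giving the per-base truth coordinates the
evaluation metrics need. Structural variants (insertion of random donor
sequence, deletion, inversion) can be injected before simulation, with
breakpoint coordinates reported on the variant genome.

Not modelled: quality-value-conditioned error rates, homopolymer-dependent
indels, chimeric reads, coverage biases, diploidy. A green test on this
generator therefore establishes correctness of the mapping machinery under
idealized indel-dominated noise, not performance on any particular
instrument's error profile.

Defaults follow the evaluation regime the mapper targets: coverage-style
depths, 10 kb mean read length, error rates swept over 5--30%. Test and
acceptance runs scale the genome (100--200 kb) and read counts down so the
whole suite runs in minutes on one CPU; the per-read behaviour being tested
is scale-free.

## Evaluation metrics

With truth (simulated data): a read is *correctly aligned* when mapped to
the right sequence and strand with reference-interval overlap of at least
$0.9 \times$ its read length against the truth interval. A *matched base*
is a read base inside an M CIGAR op (mismatching M bases count; the CIGAR
does not distinguish match from mismatch), and it is *correct* when its
reference coordinate from the CIGAR walk lies within $T = 5$ bases
(inclusive) of its truth coordinate; truth-inserted bases are never
correct. From these: cFAR (correct reads / all reads), cFAB (correct
matched bases / matched bases of correct reads), cACR (mean per-correct-read
correct fraction), base sensitivity (correct matched bases / all read
bases) and precision (correct matched bases / matched bases of mapped
reads). Both coordinate walks run in the genome-forward read orientation,
which makes minus-strand comparisons well-defined.

Without truth (real data): FAR, FAB (matched bases over *all* query bases),
ACR, and the ACR standard deviation, computed as the population
(divide-by-$n$) standard deviation of the per-read coverage ratios on the
ratio scale.

Agreement between mappers: alignment $x$ *covers* $y$ when their
reference-interval overlap is at least 90% of $y$'s interval (inclusive);
normalising by the covered alignment makes the agreement matrix
asymmetric. A read *spans* a structural variant when its alignment strictly
brackets a breakpoint its own truth interval contains; each read counts
once. Spanning is evaluated on the variant genome: reads are simulated from
and mapped back to the genome carrying the variants, whose breakpoint
coordinates the simulator reports.

## Numerical and formatting choices

* All internal coordinates are 0-based half-open; SAM's 1-based POS appears
  only at the SAM boundary. Reverse-strand SEQ is stored
  reverse-complemented (reference orientation), flag 0x10; unmapped reads
  get flag 0x4; MAPQ is 255 (no mapping-quality model); the alignment score
  is the `AS:i:` tag and the anchor credibility `XC:i:`.
* Band geometry uses real arithmetic inside `floor()` for `sci(u)` and
  `ceiling()` for genome segment lengths, so the genome side never
  under-covers.
* The truth sidecar is a tab-separated table with a PAF-like column order
  (`read_id`, `read_length`, `ref_id`, `strand`, `ref_start`, `ref_end`,
  `edit_script`). Edit scripts carry substituted and inserted base
  identities (`<n>M`, `<n>D`, `X<base>`, `I<base>`) so a script applied to
  its template reproduces the read exactly; conservation on both the read
  and reference side is validated on every read/write.
* Degenerate inputs are answers, not errors: reads shorter than $k$, all-N
  reads, and reads without any indexed word match are reported unmapped.

## Known limitations

* One best record per read; a chimeric read still yields a single position.
* Linear gap penalties only; no affine model, no SIMD/bit-parallel DP.
* The band slope of 1.2 combined with `alpha = 0.1` leaves indel-rich path
  tails marginally covered near segment ends (see above); per-base metrics
  at 25--30% error reflect that.
* `threads` is accepted for interface compatibility but execution is
  single-threaded; output is independent of it by construction.
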