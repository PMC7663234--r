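---
title: "Methods: segmental classification and comparative analysis of spliceosome-fraction miRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmental classification and comparative analysis of spliceosome-fraction miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceomiR)
```

## The analysis in one paragraph

Small-RNA reads from nuclear spliceosome fractions (SF) align to miRNA
hairpin precursors well beyond the annotated mature products. spliceomiR
models each precursor as a window — the hairpin extended by 50 nt of
genomic flank on both sides — partitioned into disjoint labelled segments:
the annotated mature 5p/3p products, an *undefined complement* opposite a
single annotated mature (the star-like duplex partner with no annotation
support), and *extension* for every remaining window position. Filtered
reads are assigned to one segment (or to `overlap` when they cross a
segment border), counted into a miRNA × sample matrix, presence-filtered
and RPM-normalised, and compared across cell-line groups by Venn
partitioning, Up/Down/Same trend discretisation, and consistency scoring
against literature-reported directions.

## Segment maps

All internal coordinates are 1-based and closed, the native convention of
GFF3, GRanges, and R itself; BED input/output is converted at the boundary
by rtracklayer. Hairpin-local coordinates run 5'→3' with position 1 at the
first precursor base, so the upstream flank occupies local positions
≤ 0 and the downstream flank positions > L (precursor length L).

**Arm calling.** A mature product is assigned to the 5p arm when its local
midpoint lies at or before the hairpin midpoint, otherwise 3p. Ties go to
5p. This is deterministic and needs no annotation beyond coordinates; for
real miRBase hairpins, whose matures sit near the termini, it agrees with
the `-5p`/`-3p` name suffixes.

**Undefined complement.** Annotation databases do not define the star-like
interval geometrically. We place it by the duplex mirror rule: with a
single mature at local $[s, e]$ on a hairpin of length $L$, the complement
is $[L-e+1+v,\; L-s+1+v]$ with $v = 2$, the canonical 2-nt 3' overhang
left by RNase-III processing of the duplex. The interval is clipped to
$[1, L]$ and, should it still touch the mature (only possible on very
short hairpins), truncated away from it with a warning. The rule is its
own inverse — mirroring the complement recovers the mature exactly — which
the test suite asserts. We deliberately do not fold the hairpin: a
secondary-structure prediction would add a heavy dependency and an
uncontrolled source of variation for a ±2-nt refinement.

**Extension.** Every window position not covered by a mature or the
complement is labelled `extension` — including the loop between the arms,
not only the outer tails. The alternative (loop as its own category) would
split a region the read classifier cannot distinguish biologically and
would break the clean partition property; the inclusion of the loop is
recorded in the segment-map metadata (`loop_in_extension`). The invariant
the package maintains and tests position-by-position: the labelled
intervals of every hairpin partition its window exactly — pairwise
disjoint, no gaps.

## Read classification

A read is assignable to a hairpin only when **both** its start and end lie
inside that hairpin's window, and (by default) its strand matches the
hairpin strand, since mature miRNAs are strand-specific; `strand_mode =
"both"` relaxes this for protocols without strand information. An
assignable read contained in a single labelled segment takes that label;
a read touching two or more segments is `overlap`. There is no fuzz
tolerance at borders — a read extending 1 nt past a mature boundary is
`overlap`, while trimmed/shifted isomiRs that stay inside the mature
segment still count as mature.

Reads contained in the windows of several hairpins (possible for clustered
precursors closer than two flank widths) are resolved to the window whose
midpoint is nearest the read midpoint; exact ties go to the
lexicographically smallest hairpin identifier and are reported. This makes
multi-mapping resolution deterministic and reproducible; ambiguity is
logged rather than silently duplicated.

Read filtering applies three independent predicates — length ≥ 17 nt,
mismatches ≤ 2, identity ≥ 0.90 (identity computed as
$1 - \mathrm{mismatches}/\mathrm{length}$) — so the filter is
order-independent and idempotent. Note the predicates interact: 2
mismatches pass the mismatch cap but fail identity on reads shorter than
20 nt.

## Quantification

Every assignable read counts toward its hairpin regardless of segmental
category (an `include_categories` argument supports mature-only counting).
A miRNA is *present* in a group iff its raw counts summed over the group's
replicates reach 10 — the replicates are pooled because the study design
this mirrors combines the three preparations per cell line before
thresholding. The boundary is sharp: a group sum of 9 is absent, 10 is
present. RPM normalisation divides each sample by its own total of
miRNA-assigned reads (not total library size, which is unavailable once
only miRNA-aligned reads are retained) and scales to $10^6$.

Replicate correlations are Pearson on $\log_{10}(x+1)$-transformed
values by default — the common choice for count profiles spanning orders
of magnitude — with Spearman available by flag. A constant profile has no
defined correlation and is reported as `NA` rather than an arbitrary
number.

Differential-expression testing is *not* reimplemented: the pipeline
ingests any externally produced table with adjusted p-values (e.g. a
DESeq2 results export) and applies a strict `padj < 0.05` cut, ranking by
significance. Re-deriving a shrinkage-based NB test would duplicate a
mature, widely validated package for no methodological gain.

## Comparative layer

**Venn partitions** are exact membership enumerations of three presence
sets into the seven exclusive regions; `venn_sets_from_regions()` inverts
the operation so that published region counts can be re-analysed.

**Trend discretisation.** With reference mean $r$ and test mean $t$, the
label is Same iff $0.8 \le t/r \le 1.2$, boundaries inclusive — a literal
reading of "stable within ±20% of the reference". Zeros are handled
symmetrically: $r=t=0$ is S; $r=0, t>0$ is U regardless of magnitude;
$t=0, r>0$ is D. The label is scale-invariant, so raw and RPM means give
identical labels when library sizes are equal, and the band decision is
validated against 25 published mean triples whose printed labels it
reproduces exactly (50/50). Partition percentages are rounded half away
from zero to integers, matching how such tables are conventionally
printed.

**Consistency scoring** compares each miRNA's SF trend (test vs reference
cell line) against literature direction counts: no record (or zero
publications) → `not_available`; 1–2 publications → `minimal_support`;
3+ publications split across directions → `mixed`; a unanimous direction
agreeing with the trend (U with Up, D with Down) → `consistent`;
unanimous and opposing → `opposite`. A stable (S) trend against a
unanimous literature direction has no natural verdict in this scheme; we
emit `mixed` and set a dedicated flag (`stable_vs_unanimous`) so
downstream users can treat these cases separately. The verdict mapping is
total, which the suite checks by enumerating the full trend × literature
grid.

## Synthetic data: what it emulates, and what it does not

The generator plants every quantity the pipeline later estimates:

* **Layout** — non-overlapping precursors (60–110 nt) on a toy
  chromosome; a configurable fraction placed as cluster pairs separated by
  0.2–5 kb while all other gaps are ≥ 15 kb, so the planted pairs are
  provably the only sub-10-kb neighbours. Matures (20–23 nt) sit 0–3 nt
  from the termini; a configurable fraction of precursors is single-arm to
  exercise the undefined complement.
* **Reads** — per-miRNA counts are negative binomial with mean
  `base_mean × fold_change` and size `dispersion` (default 10), the
  standard replicate-noise model for RNA-seq counts. Each read's category
  is drawn from the spec's mixture, renormalised over the categories
  feasible for its precursor, and coordinates are placed to realise the
  category exactly; `overlap` reads straddle a mature's downstream border
  by ≥ 2 nt on each side, making their category unambiguous. Optional
  decoys (sub-17-nt or 3–5 mismatches) are flagged in the truth so filter
  behaviour can be checked read-for-read.
* **Counts** — baseline abundances are log-normal (median 200 reads per
  miRNA per sample, sdlog 1, spanning the 2–3 orders of magnitude typical
  of such libraries); non-reference groups receive planted fold changes of
  magnitude $2^{1}$–$2^{3}$ with Up/Down/Same probabilities 0.3/0.5/0.2,
  mirroring a decrease-dominated design. Trend truth is derived from the
  planted fold changes with the same ±20% band the caller uses.

Everything is a pure function of `(spec, seed)`; the generator saves and
restores the caller's RNG state.

What the generator does **not** emulate: sequence content (no FASTQ, no
alignment errors, mismatches are labels rather than edits), multi-mapping
across paralogous miRNA families, chimeric or spliced small-RNA reads,
composition differences *between* groups (the mixture is shared), and any
form of library-preparation bias. Passing tests therefore demonstrate
correctness of the interval arithmetic, counting, and discretisation
machinery under the stated noise model — not robustness to alignment
artefacts in real libraries.

## Numerical and testing choices

* Normalised partition rows must sum to 1 within $10^{-9}$; RPM columns to
  $10^6$ within $10^{-6}$ relative.
* The classifier is validated against an independent position-by-position
  brute-force oracle (label every covered base, apply "one label → that
  label, more → overlap") on ≥ 10,000 simulated reads plus off-window and
  antisense strays; cluster detection against an $O(n^2)$ all-pairs scan
  at $n = 500$.
* Parameter-recovery checks run at the scale where their tolerances are
  meaningful and the suite stays fast: segmental mixtures at ~2,000 reads
  per miRNA (recovered within 3 percentage points), trend labels at
  ~10,000 reads per sample over 50 miRNAs (≥ 90% agreement on planted
  $|\log_2 \mathrm{FC}| \ge 1$).
* Degenerate inputs fail loudly and early: hairpins without matures,
  matures outside their parent, zero-count samples under RPM, unknown
  groups, negative coordinates or publication counts are all errors, not
  silent coercions.

## Known limitations

* The mirror rule is an approximation to the true duplex register; without
  folding, the complement can be off by a few nt for precursors with
  asymmetric bulges. Overlap/complement proportions near segment borders
  inherit that uncertainty.
* Single-assignment of multi-window reads undercounts miRNAs in dense
  clusters relative to fractional assignment; the tie events are logged so
  the magnitude is visible.
* The presence filter's pooled-replicates reading of "≥ 10 reads per cell
  line" is one of two defensible interpretations (the other: ≥ 10 in each
  replicate); pooling matches a design in which per-line preparations are
  combined before thresholding.
* Whether trend ratios should be computed on raw or normalised reads is
  protocol-dependent; the functions accept either matrix and the labels
  are scale-invariant, so the choice only matters when library sizes
  differ strongly between groups.
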