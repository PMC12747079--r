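---
title: "Methods: detection of endogenous viral elements, telomere accounting, recruitment gating and growth kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection of endogenous viral elements, telomere accounting, recruitment gating and growth kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evekit)
```

This vignette documents the models and procedures implemented in evekit,
the assumptions behind them, the tunable parameters with their defaults,
and the design choices made where the methodology was genuinely open. The
package targets a recurring analysis pattern in protist genomics: a
heterotrophic nanoflagellate nuclear assembly carrying integrated
polinton-like viruses (PLVs), giant-virus genomes quantified across
metagenomes, CARD-FISH lineage surveys, and culture growth curves.

## Coordinates

All coordinates are 1-based and closed, the GFF3/IRanges convention native
to R and Bioconductor. Interval arithmetic (coverage, overlaps, exclusion
windows) is delegated to IRanges, so no half-open/closed ambiguity arises
in the implementation. BED export converts to 0-based half-open at the
boundary, as the format requires.

## Endogenous viral element detection

### Model and assumptions

An integrated PLV is modelled as a contiguous interval that (i) sits well
below the host baseline GC, (ii) contains at least one hallmark gene
(major/minor capsid protein or similar), (iii) is usually bounded by a
terminal repeat pair — inverted (TIR) or direct (TDR) — of at least ~100 bp,
and (iv) may be bracketed by a 4–8 bp target-site duplication of host
sequence. Detection is *hallmark-first*: a GC anomaly alone never produces
a call, because AT-rich host regions (introns, repeat deserts) are common
while hallmark capsid genes are diagnostic.

### Procedure

1. **GC track** (`gc_track`): sliding windows of `window` bp every `step`
   bp; the GC denominator excludes ambiguous bases, and windows more than
   half ambiguous are treated as missing (so hard-masked regions can never
   re-trigger candidates — this is what makes element calling idempotent
   under masking).
2. **Baseline with one refinement pass**: the baseline is genome-wide GC;
   candidate intervals from a first segmentation are masked and the
   baseline recomputed once. With elements at ~35% GC inside a ~52% host,
   a naive baseline is biased downwards by the elements themselves; one
   iteration removes essentially all of that bias and further iterations
   change nothing detectable.
3. **Segmentation** (`segment_low_gc`): maximal runs of windows at or
   below `baseline − min_delta/100`, merged across single-window gaps
   (one high window inside an element, e.g. a GC-rich gene, should not
   split it), converted to base intervals and length-filtered.
4. **Anchors**: either exact six-frame peptide scans (`scan_anchor_peptides`)
   on the candidate neighbourhood or user-supplied GFF3/tibble
   annotations. Anchors are accepted on either strand.
5. **Boundary refinement**: a seed-and-extend search for the best repeat
   pair between the two ends of the padded candidate region. Exact 20-mers
   shared between the left zone and the (reverse-complemented) right zone
   seed gapless extensions; a mismatch is crossed only when the next 8
   positions match exactly, so extension stops at the repeat boundary
   instead of drifting into flanking host sequence on a percentage budget.
   The element span becomes the outermost repeat coordinates; without a
   repeat the GC segment stands.
6. **TSD** (`find_tsd`): exact match only, on the 20-bp flanks of the
   refined span — the longest k in [4, 8] such that the k-mer ending at
   the last left-flank position equals the k-mer starting the right flank.
   No mismatch tolerance is offered because a duplicated target site is a
   literal copy; anything looser manufactures TSDs from AT-rich flanks.

### The anchored terminal-repeat finder

`find_terminal_repeats` compares the first `search_margin` bp with the
last `search_margin` bp in both orientations and must choose a repeat
length. Among lengths whose mismatch fraction is within
`max_mismatch_frac`, it maximises a score of +1 per match and −2 per
mismatch (ties to the longer length; TIR preferred over TDR on an exact
tie). The naive alternative — simply the longest length within the
mismatch budget — is not used because it provably over-extends: an exact
500-bp repeat followed by random flanks admits ~534 bp at 5% mismatch,
since the budget earned by the exact stretch pays for garbage at the
boundary. The score criterion stops exactly where matches stop paying.
The same selection rule is recomputed exhaustively, length by length, by
the brute-force oracle in the test suite.

### Defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `window` / `step` | 1000 / 200 | bp | resolves 14–40 kb elements to ±1 window |
| `min_delta` | 8 | pp | half the host−element GC gap (~17 pp); robust to window noise |
| `min_len` / `max_len` | 5 000 / 60 000 | bp | brackets the 14–40 kb class with margin |
| `repeat_min_len` | 100 | bp | below this, random anchored hits appear at 5% mismatch |
| `max_mismatch_frac` | 0.05 | — | tolerates post-integration divergence without chaining junk |
| `search_margin` | 2 000 | bp | terminal repeats of hundreds of bp, searched from each end |
| TSD k-range | 4–8 | bp | the field's reported 5–6 bp with one unit of margin |

The classifier's rules are categorical: TDR + tyrosine recombinase (YREC)
elements form one class, TIR + retroviral-like integrase (rve-INT) the
canonical class, everything else is left unclassified rather than guessed.
A TDR element carrying a TSD is reported with a warning because
recombinase-mediated integration through a circular intermediate is not
expected to duplicate the target site.

## Telomere accounting and assembly statistics

A contig end is telomeric when a tandem run of at least `min_copies` motif
copies (either orientation) starts within `max_offset` bp of the terminus;
run counting tolerates one mismatching base per motif copy and one
mismatch per three copies overall. The defaults (6 copies within 100 bp)
operationalise a "high-quality" telomere; a permissive screen can use 4
copies within 1 kb. Both are configuration, not biology: the thresholds
are declared substitutes for a criterion the upstream literature leaves
undefined, and the telomere motif itself is always supplied by the caller
(the package ships no organism-specific default motif claim). The right
end is scanned on the reverse complement, which makes the call invariant
under reverse-complementing a contig by construction.

`min_chromosomes(n_both, n_one) = n_both + ceil(n_one / 2)` is the floor
implied by two telomeres per chromosome: complete (telomere-to-telomere)
contigs count once, and single-telomere contigs can at best pair up.
`asm_stats` uses the standard descending-sort N50 and excludes N from the
GC denominator.

## Read recruitment and ANI

Alignments arrive as a 5-column TSV (`read_id`, `ref_id`, `start`, `end`,
`identity`) or SAM; SAM is converted with Rsamtools and only primary
mapped records are kept, matching the semantics of the usual
coverage tools. Covered fraction is computed at base resolution (depth ≥ 1),
not depth-weighted. The presence gate is *strictly* greater than 0.5, and
an absent genome reports RPKM 0 regardless of its mapped-read count — a
deliberate guard against claiming abundance for genomes recruited only at
a few conserved loci.

Metagenomic islands are maximal runs of bins with depth ≤ `max_depth`
(default 0), bridged across single-bin interruptions (one spuriously
covered bin from a mismapped read should not split an island) and
reported when at least `min_len` (default 5 kb) long, with `bin` = 100 bp.
These thresholds are configuration; the quantity of interest — a ~27-kb
uncovered region in an otherwise well-covered ~671-kb genome — is far from
all of them.

`fragment_ani` cuts the query into consecutive 1020-bp fragments, places
each in the subject by exact 16-mer seeding on both strands, and scores a
global(fragment)–local(subject) affine-gap alignment
(match +1, mismatch −1, gap open 6, extend 1) in a window around the
seeded diagonal. Fragments reaching 70% identity and 70% aligned coverage
contribute, and ANI is their mean identity. The 1020/0.7/0.7 convention is
the widely used fragment-ANI parameterisation; it is declared here as the
package's own choice since no tool or parameter set is prescribed by the
analyses this package emulates. Under independent substitutions at rate
*p* the expected identity is 1 − *p*, which is what the acceptance test
checks at *p* = 0.05 over 100 kb.

## Survey statistics

Lineage relative abundance is `100 · cry1a_count / hnf_count` per sample;
samples without a usable HNF denominator are excluded and counted, never
imputed. Summaries use the sample (n−1) standard deviation and *strict*
category bounds (>10%, <1%). The correlation screen computes both Pearson
and Spearman on pairwise-complete observations and flags a covariate when
either absolute coefficient exceeds the threshold (default 0.5) — a
conservative reading adopted because the correlation type behind the
published threshold is unstated. No multiple-testing correction is
applied: the screen reports a threshold scan, not hypothesis tests.
In-situ doubling time over consecutive increasing abundance pairs is
`(t₂−t₁)·ln 2 / ln(N₂/N₁)`, and the fastest (minimum) is reported.

## Growth kinetics

`fit_exponential` considers every contiguous window of at least
`min_points` (default 4) timepoints whose observed fold-change is at least
`min_fold` (default 2) and whose log-linear slope is positive, and selects
the window maximising R² (ties: more points, then earlier start). Windows
containing zero counts are skipped for fitting; zeros are retained for
collapse detection. Fitting is by ordinary least squares on natural-log
counts. This window rule is the package's own — the source analyses report
doubling times without naming a procedure — and all knobs are arguments.

One honest consequence, measured rather than assumed: with 10%
observation noise and 24-h sampling, R²-maximising 4-point windows are
noisy estimators — across 100 simulated replicates the doubling-time
estimate falls within ±10% of the true 29 h in about 87% of runs (mean
essentially unbiased; the μ bias at 12 timepoints is ≈ 0.4%). The test
suite asserts the fraction this simulation actually produces. Larger
`min_points` tightens the distribution markedly (97% at 5 points), at the
cost of assuming longer clean exponential phases.

`detect_collapse` emits an event whenever a count has fallen by at least
`drop_frac` (inclusive) relative to the running maximum, provided that
maximum was attained within the last `horizon` sampling intervals — a
stale peak followed by slow decline is senescence, not a collapse. Every
qualifying timepoint is reported; consumers wanting one event per episode
can take the first row per run.

## The synthetic-data generators

The generators exist so that every detector can be scored against a known
truth without any external download; each one returns its truth record
next to the data.

* **Host genomes** are i.i.d. base sequences with P(G)+P(C) = `gc` —
  deliberately free of higher-order composition, since the detectors under
  test only consume GC and exact matches. Telomere tracts (default 12
  motif copies) are planted exactly at the termini.
* **Implanted elements** are built literally from the element model:
  repeat + core + (repeat | reverse-complemented repeat), anchor peptides
  encoded as real ORFs (deterministic codon choice so translation is
  exact; reverse-strand anchors by flag), TSD created by duplicating host
  bases at the insertion point. Length bookkeeping is exact:
  genome growth = element + TSD.
* **Alignments** are uniform read placements over the positions whose
  read interval avoids the excluded windows, so island truth is forced,
  and expected depth outside is `n_reads · read_len / usable_len`.
* **Survey tables** draw HNF densities log-normally and lineage fractions
  from Beta(a, b); the default Beta(0.73, 3.69) has mean 16.5% and SD
  ≈ 16 pp, the dispersion scale reported for large lake surveys of this
  lineage. Covariates are independent unless a coupling (normal-scores
  correlation) is requested.
* **Growth series** follow lag → exponential → multiplicative collapse
  with log-normal observation noise at a stated CV (mean-unbiased
  parameterisation). Default timepoints are 24-h sampling over 600 h with
  a ~1-week lag, mirroring typical DAPI-count experiments on slow
  flagellates.

What passing on synthetic data does **not** show: robustness to
sequencing error, chimeric assembly, nested mobile-element insertions,
genuinely compositional (non-i.i.d.) host sequence, degraded/partial
terminal repeats beyond the modelled mismatch rate, or survey tables with
structured missingness. Those phenomena are outside the generators'
model, deliberately: the suite validates the algorithms' contracts, not
field performance.

## Scenario scale and runtime

The shipped study-scale scenario (`inst/extdata/scenario-study-scale.yaml`)
uses a ~5-Mb, 12-contig host with three implanted elements, a 671-kb
giant-virus-like reference carrying a 27-kb island at 425–452 kb, a
263-row survey and three growth replicates; it runs the full chain in a
few seconds on one CPU. Oracle-driven property suites use hundreds of
kilobases per seed. These sizes were chosen so the whole test suite stays
in the minutes range while every quantity of interest (window resolution,
repeat lengths, island size, survey n) is at the scale the methods target.

## Known limitations

* The EVE caller assumes elements are GC-divergent from the host; an
  isoGC element with hallmark genes will be missed by design.
* Terminal-repeat search is anchored to candidate-region ends; repeats
  buried deep inside an element (e.g. after boundary erosion much larger
  than the padding) are not recovered.
* `fragment_ani` seeds with exact 16-mers: sequence pairs below ~80%
  identity rarely seed and are reported as not-comparable fragments,
  which is the intended regime for same-genus genome comparisons, not for
  distant homology.
* SAM support covers plain single-end primary alignments; no CIGAR-aware
  split-read handling beyond what the reference span encodes.
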