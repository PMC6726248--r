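---
title: "Detecting protointrons from splice-junction evidence: models and choices"
author: "protointrons package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting protointrons from splice-junction evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protointrons)
```

## The problem

In budding yeast, most splicing capacity is consumed by the ribosomal
protein gene (RPG) transcripts. When RPG transcription is repressed — for
example with rapamycin — the freed "hungry" spliceosome begins to act on
weak substrates it normally ignores. Deep RNA-seq of such cells (ideally
NMD-deficient, so unstable spliced products survive) reveals splice
junctions at genomic locations that do not overlap any annotated intron.
These *protointrons* are rare, inefficiently spliced (median around 1%
versus ~93% for standard introns), poorly conserved in sibling
*Saccharomyces* species, and have no established role in gene expression.
They are interesting precisely because they look like raw material for the
evolutionary creation of new introns ("intronization").

The package implements the full computational side of this analysis:

1. **Detection** — parse per-library splice-junction tables, orient the
   junctions against the genome, and apply an aggressive artifact filter
   cascade; merge surviving events into intron locations and classify them
   against the annotation.
2. **Quantification** — junction/intron/exon2 coverage summaries, three
   log2 splicing indices, their between-condition deltas, and a bounded
   percent-spliced estimate.
3. **Signal profiling** — position weight matrices of the 5' splice site,
   branchpoint and 3' splice site; conservation-score windows; intron
   length distributions and their two-sample comparison.
4. **Genome composition** — codon-permutation backgrounds for hexamer
   depletion Z-scores, and the uORF/5'UTR-intron contingency analysis.
5. **Simulation** — a generator that plants all of the above with known
   truth, so every stage is testable without external downloads.

## Detection model

A junction record is the genomic interval of the removed sequence (we store
it 1-based closed, the native convention of both `GRanges` and the
STAR-style junction table; conversions for 0-based formats happen only
inside the readers). Strand-undefined junctions are tried in both
orientations; the orientation with a valid donor (GT/GC) and acceptor (AG)
is kept, and junctions valid in both or neither orientation are dropped —
the data cannot distinguish them.

The filter cascade records **every** applicable rejection reason rather
than stopping at the first, so filter behavior is auditable:

| reason | rule | default |
|---|---|---|
| `min_reads` | total unique reads across libraries below threshold | 3 |
| `donor` | donor dinucleotide not GT/GC | GT, GC |
| `acceptor` | acceptor dinucleotide not AG | AG |
| `gag_3ss` | last three intron bases are GAG | on |
| `no_branchpoint` | no positioned branchpoint motif (below) | on |
| `jackpot` | support in fewer than 2 libraries and fewer than 2 distinct alignment positions | 2 |
| `mismap` | the spliced flank concatenation occurs contiguously in the genome | 20 nt flanks |

Two of these deserve comment. *Jackpot* amplification (a PCR artifact)
manifests as a junction abundant in a single library; the testable
operationalization we chose is "kept only if seen in at least two libraries
OR at two distinct duplicate-collapsed alignment positions". Junction
tables carry no alignment-position count, so for parsed data the second arm
only engages when the caller supplies positions. *Mismap* generalizes the
check used for subtelomeric Y'-repeat introns: if the last 20 exonic bases
upstream plus the first 20 downstream occur contiguously anywhere in the
genome (either strand), reads "supporting" the junction may simply be
mismapped reads from that contiguous copy, and the junction is rejected.
GAG 3' splice sites are rejected by default — a few may be genuine, so the
filter is a flag, not a hard rule.

Accepted events overlapping an annotated standard intron by one or more
same-strand bases are set aside; the remainder are protointron candidates.
Overlapping candidates merge into *locations* (connected components of the
interval-overlap graph, per strand). Each location is classified by its
relation to the sense-strand gene with the largest overlap: `coding`,
`5'UTR`, `3'UTR`, the boundary-spanning `5'UTR^coding` and `coding^3'UTR`,
or `non-coding` (antisense, intergenic, ncRNA). Coding locations whose
length is a multiple of three and whose in-silico excision leaves the host
CDS free of new in-frame stops are flagged in-frame: these could produce
functional alternative proteins.

## Branchpoint search

Yeast branchpoints derive from the UACUAAC consensus, in which the branch
adenosine is the A before the final C. The search scans the intron
(transcript orientation) for three motif tiers in order — `ACTAA`, then
`RYTRAYR`, then `YTRAY` (R = A/G, Y = C/T) — stopping at the first tier
with a *valid* match. Validity is geometric and measured from the branch A
itself, which keeps the rule independent of motif length: the branch A must
lie at least 45 nt from the 5' splice site (0-based index >= 45) and at
least 7 nt upstream of the 3' splice site. Among valid matches within the
winning tier, the one closest to the 3' splice site is returned; introns
with no match in any tier have "no good match" and fail the
`no_branchpoint` filter. The branch-A offsets within the motifs (ACTAA ->
4, RYTRAYR -> 4, YTRAY -> 3) follow from aligning each motif to UACUAAC. A
single-tier relaxed mode (`bp_params_relaxed()`, motif RYTRAY) is exposed
for sensitivity analyses; `N` never matches any motif position.

## Quantification

For a location whose member events overlap, quantities are computed on the
*minimal intron* — the intersection of the member intervals (most
downstream start, most upstream end; we read the alternative phrasing
"most upstream start" for the end as a transcription slip, since an end
cannot precede a start). Three coverage numbers are taken per condition:

* `J` — junction reads crossing the splice junction;
* `I` — mean per-base read depth across the minimal intron (absent
  positions are zero depth);
* `E2` — mean depth over the 100 exonic bases immediately downstream of
  the most downstream 3' splice site, truncated (and flagged) at the
  transcript boundary.

The three indices are `log2(I/E2)`, `log2(J/E2)` and `log2(J/I)`, each
defined only when both terms are positive; no pseudocounts are used and
undefined values propagate as `NA` rather than being imputed. The
between-condition splicing change is
`delta = log2(J60/I60) - log2(J0/I0)`; positive values mean improved
splicing after treatment. For display, standard introns require at least
35 junction reads and protointrons at least 50, and genes whose total
transcript level changes two-fold or more between conditions are excluded
(median-of-ratios size factors, computed here because the pipeline
consumes junction tables and coverage rather than raw counts; the gate's
spirit is a 2-fold threshold, not a particular normalization tool).

Percent spliced is `100 * J / (J + I)`. No formula is canonical for
"efficiency judged by comparing junction reads to intron coverage"; this
bounded estimator is consistent with near-complete splicing reading as
~100% and with the protointron regime reading as ~1%, and it recovers
planted efficiencies within binomial error in simulation (tested at depth
2000). The raw `log2(J/I)` index is also reported for users who prefer the
unbounded form.

## Signal profiles

PWMs are built from raw counts by default (pseudocount 0, configurable):
column probabilities are `(count + pc) / (total + 4 pc)`, with `N`
contributing nothing. Window widths follow the field's display
conventions: 6 nt of intron at the 5' splice site, the 8-mer from 5 nt
upstream to 2 nt downstream of the branch A, and the final 3 nt at the 3'
splice site. Conservation summaries average per-base phastCons scores
(in [0, 1]) over windows of 10 nt each side of the signal anchors —
widths are a package choice, exposed as parameters, since no standard
exists. Only scored positions enter the mean; a window with no scored
positions is `NaN`, not zero, because unscored is not the same as
unconserved.

Length distributions are compared with a two-sample Kolmogorov-Smirnov
test implemented directly: `D` is the supremum of the ECDF difference over
the pooled points, and the p-value uses the asymptotic Kolmogorov
distribution at `sqrt(ne) * D` with effective size
`ne = na * nb / (na + nb)`. The implementation is cross-checked in the
test suite against both a brute-force oracle and `stats::ks.test`.

## Codon-permutation hexamer background

If intron-like signals within ORFs are deleterious, splice-site and
branchpoint hexamers should be rarer in real coding sequence than chance
allows. The null model permutes the internal codons of every ORF (start
and stop fixed), preserving length, GC content, codon usage and the
encoded protein while scrambling nucleotide-level words. Hexamers are
counted at every offset within each ORF (overlapping, no counting across
ORF boundaries), and each of the 4096 hexamers gets
`Z = (extant - mean) / sd` against the permutation mean and sample
standard deviation (n-1 denominator; fixed for reproducibility even though
the distinction vanishes at 10,000 permutations). Ranks ascend from the
most depleted hexamer, ties broken lexicographically. Reproducibility uses
a documented counter scheme: permutation *p* runs under seed
`master_seed + p`, so any single permutation can be regenerated in
isolation and results do not depend on iteration order. ORFs that do not
start with ATG, do not end with a stop, are shorter than 9 nt, have length
not divisible by 3, or contain internal stops are excluded with a warning.
Stop-containing (759 of 4096) and start-containing (255) hexamer classes
are tracked because stop codons are themselves depleted in frame, and the
interesting comparison for a branchpoint proxy like ACTAAC is against
other stop-carrying hexamers. The default is 10,000 permutations
(`n_permutations`); the test suite uses 200-1000 on 200-ORF synthetic sets,
which is sufficient for the calibration and power properties it asserts.

## uORFs and 5'UTR introns

A uORF is an ATG in any frame of the (unspliced) 5'UTR whose in-frame stop
lies entirely within the UTR and which has at least five sense codons
("longer than 4 codons, counting the AUG but not the stop"). The strict
stop-within-UTR reading is the default; a flag admits ORFs running into
the main CDS, since the convention is not universal. Overlapping and
nested qualifying ATGs count separately, which does not affect the
presence/absence contingency analysis. The comparison contrasts
intron-bearing 5'UTRs with intronless 5'UTRs restricted to the same
unspliced length range (default 240-950 nt), and the association is tested
with a one-sided Fisher exact test (hypergeometric tail toward uORF
enrichment in the intron-bearing row, computed in log space; degenerate
margins give p = 1). A uORF counts as *removed by splicing* when its ATG
lies inside the intron: excising the start codon abolishes the uORF even
if the rest of it straddles the 3' boundary.

## The synthetic-data generator

`simulate_genome()` builds a single chromosome with genes on both strands
(5'UTR, single-interval CDS with no internal stops, 3'UTR), standard
introns with canonical signals (GTATGT / TACTAAC / YAG) inserted at codon
boundaries, and protointrons with weaker signals (GT/GC donors with varied
interiors, ACTAA-family branchpoints with varied context, CAG/AAG
acceptors) planted in all six context categories. Six decoys — one per
filter class — are planted so that each violates exactly its own rule,
which makes filter tests diagnostic. `simulate_junctions_and_coverage()`
draws, for a feature with per-condition depth `d` and efficiency `e`,
junction reads per replicate as Poisson(`d e / 2`), intron base depth as
Poisson(`d (1 - e)`) and exonic depth as Poisson(`d`), across two
conditions times two replicates. Efficiencies come from Beta(60, 4.5) for
standard introns (median ~0.93) and Beta(2, 198) floored at 0.003 for
protointrons (median ~0.008); treatment multiplies protointron efficiency
by 3 and shrinks the unspliced fraction of standard introns by the same
factor, so the delta index is positive for most features. Default depth is
2000 per condition.

Deliberate simplifications, and what they mean for the tests:

* **Intron interiors are A-free filler.** Every branchpoint-tier motif
  requires an adenosine, so the planted branchpoint is provably the unique
  match and truth tables are exact. Real intron interiors contain decoy
  motifs; the brute-force oracle comparison on fully random sequence (not
  the simulator) is what exercises tie-breaking and tier fall-through.
* **Counts are Poisson.** The indices are ratio-based and no dispersion
  claim is being tested; an overdispersed generator would only widen the
  tolerances.
* **Clean features are conditioned on detectability** (counts redrawn
  until >= 3 reads in >= 2 libraries). The observed protointron set in any
  real experiment is conditioned the same way — a junction below the read
  floor is not a detection failure, it is undetectable by definition.
* **The ORF depletion knob follows its rejection rule literally**: ORF
  draws are rejected until the target hexamer count is at most
  `depletion x` that ORF's permutation expectation. Per-ORF expectations
  are well below one count, so accepted ORFs carry essentially no copies
  and the realized depletion is at most the nominal factor — the planted
  signal is conservative in the direction that makes detection *harder to
  fake*: a Z-score near zero would still be a genuine failure.
* Passing tests on this generator demonstrate correctness of the
  machinery, not performance on real libraries: real data adds overlapping
  alternative splice sites, expression heterogeneity, mismapping beyond
  the planted class, and annotation errors.

## Numerical and engineering choices

* Coordinates are uniformly 1-based closed (`GRanges`); 0-based formats
  (BED12, bedGraph) are converted at the file boundary by `rtracklayer`.
* Degenerate motifs are matched with zero-width lookahead so overlapping
  matches are all seen.
* The Fisher tail and the KS series are computed in log space / with 100
  series terms; both are exact to double precision on the scales used.
* Output tables round floats to 4 significant digits and sort by
  (chrom, start, end) so repeated runs are byte-identical.
* All simulator randomness flows from one master seed through named
  substreams (genome, counts, orfs, utrs), so stages can be regenerated
  independently.
* Problem sizes in the test suite: 10,000 random introns for the
  branchpoint oracle, 1,000 random instances each for the KS and Fisher
  oracles, 200-ORF x 300-codon sets with 200-500 permutations for the
  calibration and power checks, and depth-2000 simulations for efficiency
  recovery. These sizes give the asserted bounds comfortable margins while
  keeping the default run fast.

## Known limitations

* The pipeline consumes junction tables and coverage; it does not re-call
  junctions from alignments, so junctions the mapper missed are invisible.
* Alternative splice sites overlapping *standard* introns are set aside,
  not analyzed.
* Cross-species conservation analysis is limited to per-base score
  summaries; no alignment or synteny logic is included.
* The uORF analysis does not model translation (no Kozak scoring, no
  reinitiation), only presence/absence.
* `hexamer_depletion()` at the full 10,000 permutations on a genome-scale
  ORF set is compute-intensive in pure R; plan for an extended run or
  reduce `n_permutations` for exploration.
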