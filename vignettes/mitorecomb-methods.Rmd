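---
title: "Methods: repeat-mediated recombination analysis in multipartite organelle genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-mediated recombination analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Plant mitochondrial genomes are often *multipartite*: the assembly is a small
set of circular chromosomes, but the molecules in a cell are a dynamic mixture
of arrangements interconverted by homologous recombination between pairs of
repeated sequences. A single crossover at a **direct** repeat pair splits one
circle into two (fission) when both copies sit on the same circle, or fuses
two circles into one when the copies sit on different circles; a crossover at
an **inverted** pair inverts the segment between the copies. Which
arrangement dominates — and at what ratio the recombined (alternative) form is
present — can be read out from long reads: a read that spans an entire repeat
copy *plus* flanking sequence on both sides is anchored in unique sequence and
identifies the arrangement of the molecule it came from. The ratio of
alternative-supporting to all conformation-informative spanning reads is the
repeat's *recombination frequency*.

`mitorecomb` implements this analysis end to end: repeat-pair detection,
flank-swap reference construction, spanning-read classification and frequency
estimation, prediction of the recombination products themselves, and detection
of mitochondrial plastid transfers (MTPTs) against a chloroplast genome. A
seeded synthetic-data generator stands in for raw sequencing data so that the
entire pipeline is testable on a desk.

## The flank-swap construction

For a repeat pair with copies $C_1$ and $C_2$, let $U_i$/$D_i$ be the
`flank_len` (default 1000 bp, configurable) bases upstream/downstream of copy
$i$, with copy 2 first reverse-complemented — and its flanks transformed
accordingly — when the pair is inverted, so that "upstream" and "downstream"
are defined in a common repeat orientation. The four references are

* `major1` $= U_1 R_1 D_1$, `major2` $= U_2 R_2 D_2$ — the observed contexts,
  exact substrings of the (possibly origin-wrapped, possibly
  reverse-complemented) source chromosomes;
* `alt1` $= U_1 R_1 D_2$, `alt2` $= U_2 R_1 D_1$ — the downstream flanks
  exchanged, modelling the arrangement a single crossover produces.

Two conventions deserve a note, because the construction is stated in the
literature only for the generic case:

* **Orientation of inverted pairs.** Exchanging flanks is only meaningful in
  a common repeat orientation; we reverse-complement copy 2 (swapping and
  reverse-complementing its flanks) before the exchange. This is the only
  orientation-consistent reading we are aware of, and it makes the product
  molecules of an inversion event contain exactly the `alt` references.
* **Which repeat sequence a reference carries.** For non-identical copies the
  major references each carry their own copy's sequence (keeping them exact
  substrings of the source), while both alt references carry copy 1's
  sequence — matching the product predictor's consensus convention (below).
  At 100% identity, the overwhelmingly common case, the choice is invisible.

Flanks wrap the origin on circular chromosomes; on linear chromosomes they are
truncated and the reference is flagged. A flank that overlaps the partner
copy's footprint (copies closer than `flank_len`) is flagged
(`flank_overlap`): the references then share sequence beyond the repeat and
have reduced distinguishing power, but the construction is still well defined.

## Read classification

A read supports a reference if it (or its reverse complement) aligns over the
**entire repeat span plus at least `min_anchor` bp on both sides** with an
alignment error rate at most `max_error_rate`. The parameters, with defaults:

| parameter             | default | units    | why                                                         |
|-----------------------|---------|----------|-------------------------------------------------------------|
| `min_anchor`          | 100     | bp       | enough unique flank to distinguish conformations, far below the 1000 bp flank so sensitivity is preserved |
| `max_error_rate`      | 0.15    | fraction | comfortably above nanopore-scale error (~5–10%), far below the ~50% distance of an unrelated flank |
| `min_identity_margin` | 0.02    | fraction | a read is assigned to the best reference only when its identity beats all others by this margin; otherwise `ambiguous` |

The alignment engine is deliberately a contract, not a fixture: any engine
that classifies error-free reads identically to a brute-force
substring-containment oracle is acceptable, and that equivalence is asserted
in the test suite on 1,000 reads with zero mismatches. The shipped engine
locates the repeat core in the read by exact k-mer seed voting (k = 13), then
computes banded semi-global edit distances — the core once (it is shared by
all four references), plus the two short flank anchors per reference. The
band (±60 by default at 1 kb scale) generously covers indel drift at a 15%
error rate; the decomposition makes classification ~1 ms/read, which is what
allows the acceptance suite to run hundreds of full replicates.

Decision rule: if exactly one reference qualifies, or the best reference's
identity exceeds all others by at least `min_identity_margin`, the read gets
that label; two or more qualifying references within the margin give
`ambiguous`; otherwise `unclassified`. A read consisting of repeat sequence
only carries no flank anchor, so it qualifies for no reference and is
`unclassified` — uninformative about conformation either way, and excluded
from the denominator below.

**Frequencies.** With spanning-read counts $m_1, m_2, a_1, a_2$,
$$\hat p_\text{alt} = \frac{a_1 + a_2}{m_1 + m_2 + a_1 + a_2},
\qquad \hat p_\text{major} = 1 - \hat p_\text{alt}.$$
Ambiguous and unclassified reads are excluded from the denominator; published
survey tables are exactly these four-count ratios, which is only consistent
with classified-reads-only denominators. Fractions are reported rounded
half-up to 4 decimals to match the printed convention (base `round()` is
banker's rounding and would disagree on ties). The alternative fraction is
what the field usually calls the recombination frequency — though survey prose
occasionally applies that term to whichever column is being emphasized, so
the package always labels both fractions explicitly.

## The recombination-product algebra

`predict_products()` implements one crossover at a repeat pair on circular
molecules. With $d$ the start-to-start distance from copy 1 to copy 2 in the
`+` direction of the host circle of length $L$:

| case                      | products                                   |
|---------------------------|--------------------------------------------|
| direct, one circle        | two circles of $d$ and $L - d$ bp, one copy each |
| direct, two circles       | one circle of $L_1 + L_2$ bp, both copies  |
| inverted, one circle      | one circle of $L$ bp, segment between the copies reverse-complemented (an involution) |
| inverted, two circles     | one circle of $L_1 + L_2$ bp, one contribution reverse-complemented |

Total length is conserved in every case (asserted over 200 random instances).
The crossover is modelled *within* the repeat such that each product carries
one intact copy; for non-identical copies the products carry copy 1's sequence
in the exchanged region. This is an explicit simplification — a real crossover
at, say, a 96.6%-identity pair yields hybrid copies whose exact breakpoint is
unknowable from the data — and it is flagged in the product provenance. Both
a sequence mode (string surgery, used by the simulator) and a length-stub
mode (pure arithmetic, usable at full genome scale) are provided. Assembly
graphs and multi-event conformational state spaces are out of scope; the
module exposes the single-event algebra those figures summarize.

## MTPT detection

`find_mtpts()` is a local similarity search (exact 11-mer seeds, ungapped
X-drop extension, both strands) between the chloroplast and mitochondrial
genomes, scored with match +2 / mismatch −3 and filtered at a
Karlin–Altschul e-value threshold, default $10^{-5}$:
$E = K m n e^{-\lambda S}$ with $m, n$ the genome lengths, $\lambda$ solved
exactly for the scoring scheme under uniform base composition
($\lambda \approx 0.637$ for +2/−3) and $K = 0.71$, the customary nucleotide
approximation. Hits overlapping or abutting on the mitochondrial axis are
merged into disjoint blocks, which is how such transfers are conventionally
reported. The acceptance surface is *planting recovery* (recall 1.0 with
≤10 bp boundary error across 50 seeded experiments), not hit-count parity
with any particular published scan: parity would require the exact aligner
build and chloroplast accession, which the package deliberately does not
claim. Gene-content annotation of transferred segments is limited to
intersecting user-supplied feature tables; annotation itself is out of scope.

## What the synthetic data emulates — and what it does not

`generate_genome()` builds a stated world, not a tuning dial:

* two circular chromosomes of 30 kb + 13 kb (the shape of a real two-part
  mitogenome at one-tenth scale, for desk speed) at GC 0.452;
* planted repeat pairs — defaults: an 800 bp direct intra-chromosomal pair
  and a 124 bp direct inter-chromosomal pair, the tenth-scale stand-ins for
  the large recombinationally active repeats of such genomes — mutated to a
  requested identity by substitutions at random positions;
* alternative-conformation fractions attached per pair (defaults 0.5467 and
  0.0111, the observed extremes in the motivating system);
* a 15 kb AT-rich (GC 0.37) chloroplast stand-in with five segments of
  880/320/150/90/60 bp at 95–100% identity copied into the mitochondrial
  chromosomes as planted MTPTs, mirroring the reported length spread (mostly
  short, one near-kilobase);
* nanopore-like reads: log-normal lengths (mean 8 kb, shape 1.6), 5% errors
  split 40/30/30 substitution/insertion/deletion, constant placeholder
  qualities. The motivating study reports no read-length statistics, so these
  are config defaults chosen once as field-plausible values, not claims.

Placement keeps planted features ~2.5 kb apart and clear of the origin, so
1 kb flanks are unique sequence. One master seed drives everything;
generation restores the caller's RNG state, and read simulation takes its own
seed so changing the read count never perturbs the genome.

Deliberate non-realism, hence what a green test does *not* establish:
substitution-only repeat divergence (no indel'd repeat copies), i.i.d. random
background (no gene content, no low-complexity or tandem repeat structure),
no basecaller-realistic error or quality model, and no chimeric reads. The
suite establishes that the *method* is correct on its stated model — exact
oracle equivalence, planting recovery, unbiased mixture estimation — not that
any particular biological genome will be this clean.

**Spanning-read simulation.** The end-to-end recovery criterion needs ≥1,000
informative reads per replicate across 300 replicates. Reads drawn uniformly
from a 30 kb circle span a 1 kb window only a few percent of the time, so the
simulator offers `spanning = TRUE`: read positions are drawn conditioned to
cover a repeat copy plus `span_anchor` bp on each side, with molecules
weighted per repeat copy (in a uniform-position run, each copy is an equal
spanning opportunity regardless of molecule length). The conformation each
read samples is still chosen with probability `alt_fraction`, so the
estimator's sampling distribution is exactly the binomial the recovery bound
describes — this is importance sampling of the informative reads, not a
change of the estimand. The recovery tests also use a ~2 kb read-length
scale for throughput; read length does not enter the estimator once a read
spans the window.

One statistical caveat is worth stating plainly: a "within 3σ in ≥ 99 of 100
replicates" check has a per-replicate miss probability of a few tenths of a
percent *for a perfect estimator* (more in the skewed small-`np` regime), so
a fixed seed set can land at 98/100 with no implementation error. The suite
runs these checks at pre-registered seeds and reports whatever they produce;
the confusion-matrix tests separate classifier error (zero on error-free
reads by oracle equivalence, and observed zero at 5% error) from this
sampling noise.

## Numerical and degenerate-input choices

* **Coordinates.** 1-based inclusive everywhere (idiomatic for R and for the
  reporting convention); a printed position whose first number exceeds the
  second is parsed as the minus-strand copy spanning the reversed range —
  the only reading consistent with printed repeat lengths.
* **Alphabet.** Inputs are upper-cased; characters outside `ACGTN` are
  rejected loudly rather than remapped. All-`N` sequences have undefined GC
  and raise an error. An empty FASTA is an empty genome, not an error.
* **Repeat finder.** Exact k-mer seeds (k = 15) with ungapped X-drop
  extension (+1/−2, X = 30), then trimming to match-bounded ends satisfying
  the identity floor; defaults `min_length = 50`, `min_identity = 90` capture
  the shortest (89 bp) and most diverged (96.6%) repeats that matter in this
  problem class. Gap-free extension is sufficient because near-identical
  organelle repeats (and the generator) diverge by substitutions; an indel'd
  repeat would be reported as two collinear pairs. "Manual exclusion" of
  curated surveys is replaced by deterministic filters: mirror duplicates and
  self-hits dropped, and a pair is dropped when *both* its copies overlap a
  longer kept pair's footprint by more than 50%. Copy 1 is the
  lexicographically smaller `(chrom, start)` and is always represented on the
  plus strand (an inverted pair is the same object under flipping both
  strands), which makes output invariant under chromosome input order. Ties
  in length are broken by position keys; size classes are `<100` short,
  `100–1000` medium (inclusive at both boundaries), `>1000` large.
* **Degenerate events.** A direct pair with coincident copy starts cannot
  fission deterministically and raises an error; overlapping inverted copies
  are unsupported in sequence mode; linear hosts are an unsupported-topology
  error for the product predictor.
* **Chance extensions.** A planted repeat may gain a base or two when the
  adjacent background happens to match — maximal-match semantics make this
  correct behaviour, and boundary tests assert small tolerances rather than
  byte equality.

## Known limitations

* Repeats that wrap a circle's origin are not detected (planted and real
  assembled repeats are reported in unwrapped coordinates; flanks do wrap).
* Repeat families with more than two copies are reported as all qualifying
  pairs, not clustered into families.
* One read spanning two different repeat pairs contributes to each pair's
  tally independently; phasing repeats along single reads is out of scope.
* The topology model is per-chromosome circular/linear only; a "branched"
  whole-assembly label, where used in the literature, is a statement about
  the molecule population, which this package represents as the conformer
  pool instead.
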