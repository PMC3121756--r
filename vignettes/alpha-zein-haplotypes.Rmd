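---
title: "Dating, expression and methylation of tandem zein haplotypes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating, expression and methylation of tandem zein haplotypes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplozein)
```

This vignette is the package's own account of its models, parameter
choices and numerical conventions. The headline numbers it mentions are
the ones the test suite and `scripts/acceptance.R` themselves compute;
nothing here is asserted that the code does not check.

## The biological setting

Maize α-zein storage-protein genes sit in tandem clusters at six loci.
Because the copies within a cluster are recent duplicates (most younger
than ~2 million years), they are nearly identical in sequence, yet they
differ sharply in three measurable ways this package quantifies: when
they and the retroelements around them arrived (molecular-clock
dating), how much each copy contributes to the transcript pool
(clone-based expression attribution), and how their promoters are
methylated (bisulfite profiling). Inbred lines carry different
*haplotypes* of each cluster — same locus, different retroelement
content, copy number and spacing — so every analysis is designed around
a pair of annotated haplotypes.

## Molecular-clock dating

**LTR insertion ages.** An LTR retroelement inserts with two identical
long terminal repeats; each then accumulates substitutions
independently. We estimate the Kimura two-parameter distance between
the two LTRs of one element from the transition proportion $P$ and
transversion proportion $Q$:

$$K = -\tfrac12 \ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big),$$

with delta-method variance $[c_1^2 P + c_3^2 Q - (c_1 P + c_3 Q)^2]/n$,
$c_1 = 1/(1-2P-Q)$, $c_2 = 1/(1-2Q)$, $c_3 = (c_1+c_2)/2$. Columns
containing a gap or an ambiguous base in either sequence are removed
before counting (pairwise deletion); unaligned pairs are first globally
aligned (affine-gap Needleman–Wunsch, match +1, mismatch −1, gap open
5, extend 1). When $1-2P-Q \le 0$ or $1-2Q \le 0$ the distance is
inestimable and a classed saturation error is raised rather than a
number returned.

The age is $K/(2 r_\mathrm{LTR})$: the factor 2 because both LTRs
diverge. LTRs are non-coding, so we deliberately compute plain K2P on
the full LTR alignment and reserve synonymous-site methods for coding
sequences, even though LTR divergence is often loosely called "Ks" in
this literature.

**Duplication ages.** For coding duplicates we count synonymous sites
and differences by Nei–Gojobori (1986): fractional synonymous sites per
codon (changes to stop codons counted as nonsynonymous), observed
differences averaged over all mutational pathways between codon pairs
(pathways through stops excluded; codon pairs containing a stop are
excluded from both counts), then $K_s = -\tfrac34\ln(1 - 4p_s/3)$. The
age is $K_s/(2 r_\mathrm{gene})$. Whether whole-gene K2P or a
synonymous-site method is preferable for such young duplicates is
genuinely open; both are exposed, and NG86 is the default for coding
input because synonymous sites are the better neutrality proxy inside a
conserved protein family.

**Clock rates.** No single published rate fits all maize loci; the
package defaults are $r_\mathrm{gene} = 6.5\times10^{-9}$ and
$r_\mathrm{LTR} = 1.3\times10^{-8}$ substitutions/site/year — the
conventional 2:1 LTR:genic ratio used in maize retroelement dating.
Both are configurable; breaking the 2:1 ratio warns but is honoured,
and every dated event records the rate used, so results remain
interpretable under any clock.

## Paralog trees

Distance matrices use the same pairwise machinery (per-pair deletion).
Neighbor joining is the Saitou–Nei algorithm (via `ape::nj`), exact on
additive matrices — the test suite verifies its topology against an
exhaustive least-squares search over all unrooted topologies for up to
six taxa. Negative NJ branch lengths, which arise on noisy matrices,
are clamped to zero with the deficit shifted to the sibling branch
(standard practice; path lengths approximately preserved). UPGMA is
average-linkage clustering with node depth at half the merge distance,
hence ultrametric by construction. Bootstrap support resamples
alignment columns with replacement; replicates in which any pair
saturates are skipped and counted rather than silently dropped, and
supports are integer percentages of the replicates actually used.
Tie-breaking inside the clustering follows the deterministic order of
the underlying implementations, so identical inputs give identical
trees on any platform.

## The synthetic generator and what it does (not) emulate

`simulate_locus_pair()` builds an ancestral tandem array — each unit a
500-bp promoter (with the P-box planted 300 bp and the Opaque2 site,
on the lower strand, 171 bp upstream of the ATG) plus a 750-bp CDS —
and derives the copies along a duplication chain, each copy evolved
from its parent by $2 \cdot \mathrm{age} \cdot r_\mathrm{gene}$
expected substitutions/site. Retroelement insertions are applied oldest
first: each element gets a fresh ancestral LTR pair and internal
region, each LTR is evolved independently by
$\mathrm{age}\cdot r_\mathrm{LTR}$ (so the pair's expected divergence
is twice that), the insertion duplicates a 5-bp target site, and nested
elements are placed wholly inside their host's internal region, with
the host's span growing accordingly. A retroelement's feature span
includes its two flanking TSDs, so the LTR and TSD children always lie
within their parent — one uniform containment rule for validation.

The substitution process is per-site independent K2P: a site changes by
a transition with the model's exact time-$d$ event probability and by
each transversion with half the transversion probability, so multiple
hits are built in and the K2P estimator is consistent with the
generator — estimator-versus-generator closure is itself a test. The
defaults encode the study conditions the package is designed around:
five copies; insertions at 6.2, 2.04, 1.19 (nested), 0.12
(haplotype-specific) and 0 mya (haplotype-specific, identical LTRs);
transition/transversion ratio $\kappa = 2$; a 288-clone library (three
96-well plates) with per-base error 0.5% and transcript fractions
(0.90, 0.05, 0.03, 0.02, 0); 96 bisulfite reads per tissue with 0.5%
conversion failure.

Deliberate simplifications, and hence what passing recovery tests do
*not* show about real data: no indels, no recombination or gene
conversion (so no solo LTRs arise spontaneously; they can be annotated
by hand), no rate heterogeneity across sites, no read-quality model,
and shared retroelements are evolved independently in the two
haplotypes over their full age rather than sharing a pre-divergence
trunk — within-haplotype LTR-pair divergence (what the dating uses) is
exact, but between-haplotype identity of shared elements is
understated. Real clone libraries also carry chimeras and primer bias
that the multinomial model omits.

All randomness flows from integer seeds; every simulator call restores
the caller's RNG state, and the pipeline derives per-stage seeds
deterministically from one master seed, so a synthetic run is a pure
function of (config, seed).

## Expression attribution

The original analysis assigned clones by database best-hit; here a
deterministic local aligner (match +1, mismatch −2, gap open 5, extend
2) replaces it so scores are platform-stable. A clone is *unassigned*
below `score_min` (default 80% of its self-alignment score) and
*ambiguous* when the best two copies are closer than `margin_min`
(default 2 score units); ambiguous clones are excluded from the
percent denominator rather than split fractionally — conservative and
auditable, since every profile reports its assigned/ambiguous/
unassigned counts. With copies ≥3% divergent and 0.5% clone error,
recovery tests show ≥99% of clones return to their true source.

The detection threshold solves $1-(1-p)^n = c$: with 960 clones at 95%
confidence, 0.31%. Profile comparisons classify each copy as
reactivated (absent in the reference, at or above the alternative
library's detection threshold), silenced (the reverse), or
enhanced/reduced when the fold-change reaches `fold_min` (default 2)
*and* a two-proportion exact test rejects at `alpha` (default 0.05);
everything else is unchanged. Reciprocal-cross samples are ordinary
samples distinguished by label; no imprinting statistics are computed.

## Bisulfite methylation

Analysis is top-strand only, matching a single-amplicon primer design;
bottom-strand symmetric-CG methylation is out of reach and not
inferred. Context is decided solely by the two reference bases 3′ of
each C (CG; CHG; CHH), with trailing cytosines defaulting to CHH and
flagged — an edge case real 500-bp windows rarely exercise. Reads are
matched to the reference with conversion-aware identity (reference C
matches read C or T) and dropped below 90% identity; at each site,
reads showing neither C nor T (sequencing error) leave that site's
denominator. No conversion-efficiency correction is applied — there are
no spike-ins in this design — but the overall converted fraction is
recorded as a QC note. Tissue comparisons mask sites below
`min_coverage` (default 10 reads) before averaging deltas by context.

## Conserved coverage and composition

How "percent conserved" was computed in the original comparisons is
unstated, so the package defines a transparent stand-in: exact 50-mer
seeding, merging of seeds on a common alignment diagonal across gaps up
to 150 bp (a point substitution interrupts seeds for at most 49 bp),
base-level verification of each merged block at its diagonal, and
retention at ≥95% identity and ≥1 kb — the conventional homology
threshold. On constructed truth this yields 100% for identical 100-kb
haplotypes and 90.9% for a pair differing by one 10-kb insertion. It
will understate conservation when indels are dense (diagonal splits
below `min_block`) and is quadratic-memory-free but single-diagonal, so
it is a screening statistic, not an aligner.

Composition assigns every base exactly one of retroelement, DNA
transposon, genic, intergenic — precedence in that order for overlaps,
nested elements counted once via interval union — so the four
percentages always close to 100 within rounding; conserved percentage
is computed independently of the partition.

## Copy status and motifs

Status precedence is `re_disrupted` > `start_loss` > `truncated` >
`premature_stop` > `intact`: a physical insertion dominates point
defects, and a missing start makes frame-dependent calls unreliable, so
it outranks them. The truncation threshold (length < 0.8 × the intact
model's CDS, or no in-frame stop at all) is a package choice exposed as
a parameter — the family's known truncated copies (e.g. a 332-bp
fragment of a 750-bp model) fall far below it. Motif offsets are
measured from the A of the ATG to the hit's upstream-most base on the
coding strand, on both strands, matching how positions like "300 bp
upstream" are conventionally quoted; the P-box core `GTGTAAAG` ships as
a default, while the Opaque2 site consensus varies between studies, so
the shipped ACGT-core pattern is explicitly a configurable default.

## Numerical conventions and problem sizes

Internal coordinates are 0-based half-open; GFF3 I/O converts at the
boundary. Minus-strand feature sequences are returned
reverse-complemented. Saturation, frame, degenerate-input, validation
and configuration errors are classed conditions
(`haplozein_saturation_error` etc.) so callers can branch on them. The
test suite exercises recovery at the sizes a single workstation handles
comfortably — 400 simulated LTR pairs of 1 kb for age recovery, 100
random additive matrices of up to six taxa against exhaustive least
squares, 1,000 bootstrap replicates, 288-clone libraries, 96-read
bisulfite plates, 100-kb conservation benchmarks — chosen to make
sampling error small relative to the tolerances being asserted.

## Known limitations

Ages inherit the clock's calibration uncertainty wholesale; standard
errors quantify sampling noise only. NG86 saturates quickly
($p_s \ge 0.75$) and is unreliable for ancient duplicates. The
expression module cannot resolve copies more similar than the clone
error scale; ties are reported, not resolved. Methylation calls are
per-amplicon averages over chromosomes, not single-molecule patterns.
The pipeline's user-data mode expects externally produced annotations
(gene models, repeat families); the package classifies and dates what
it is given but performs no de-novo discovery.
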