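---
title: "CGI-dependent promoter-like characteristics of transcribed enhancers: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CGI-dependent promoter-like characteristics of transcribed enhancers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerCGI)
```

## Scope and rationale

`enhancerCGI` compares transcribed enhancers with promoters according to CpG
island (CGI) status. FANTOM5-style transcribed enhancers are divergently
transcribed: CAGE tags accumulate on the reverse strand upstream of the
element midpoint and on the forward strand downstream, defining two TSSs per
element. The package asks, on data with known ground truth, whether
CGI-associated elements display the promoter-like properties reported for
the human regulome: broader transcription initiation, lower tissue
specificity, higher expression and directionality, and denser transcription
factor binding.

All coordinates are BED-style 0-based half-open; relative coordinates place
position 0 at the anchor base (TSS or enhancer midpoint), negative values
upstream in the transcription direction. For a bidirectional enhancer the
reverse-strand TSS is the interval start, the forward-strand TSS is
`end - 1`, and the midpoint is `floor((start + end) / 2)`. Strand "." on an
enhancer record is resolved by this convention; it is asserted, not derived
from the data, since divergent elements carry no single strand.

## CpG island calling

A 100-nt window slides in 1-bp steps. Per window we compute the GC
percentage and the CpG observed/expected ratio in the
Gardiner-Garden/Frommer form `(n_CpG × L) / (n_C × n_G)` (0 when the window
lacks C or G; overlapping CpG dinucleotides are counted). A maximal run of
consecutive qualifying windows (GC ≥ 50%, obs/exp ≥ 0.6) is emitted as a CGI
call when its span — first window start to last window end — reaches 200 bp.
Windows containing N cannot reach the GC threshold through N bases and
qualify only on their literal A/C/G/T content, a conservative choice that
never fabricates composition.

Two association rules follow two different phrasings of the same idea:
a *promoter* is CGI-associated when any call occurs in the scanned
[−200, +200] window around its TSS; an *enhancer* is CGI-associated only
when a call contains at least one of its two TSS bases. Both thresholds are
inclusive (≥), and the span rule applies to the union span of qualifying
windows. Note a geometric consequence of the span rule: a GC-rich block of
length `b` in a GC-free background yields qualifying windows spanning up to
`b + 100` nt, so blocks somewhat shorter than 200 nt can still produce a
call; the brute-force equivalence tests cover this regime explicitly.

## Core promoter elements

Twelve CPEs (TATA, Inr, BREu, BREd, DPE, MTE, DCE I–III, XCPE1, TCT, Pause
Button) are represented as position weight matrices with log-odds weights

&nbsp;&nbsp;`w_bi = log2( ((f_bi + c·q_b) / (1 + c)) / q_b )`

with pseudocount `c = 0.01` and uniform background `q_b = 0.25`. A window
matches when its summed weights reach the matrix cutoff; the cutoff is
*inclusive* (≥), one consistent convention that avoids floating-point
knife-edges. The shipped matrices are built from published IUPAC consensus
sequences (dominant bases at frequency 0.85, split across degenerate
codes), with cutoffs fixed at a per-matrix fraction of the maximum
achievable score, and live in an editable YAML asset
(`inst/extdata/pwms.yaml`: matrix, cutoff fraction, expected TSS-relative
start position, optional required partner). They are deliberately
swappable: any laboratory matrix set with cutoffs can be dropped in. DPE is
reported only in elements that carry an Inr hit inside Inr's functional
window, reflecting the cooperative TFIID binding of the two elements.

### Localized overrepresentation

For each CPE the *functional window* is its expected start position ±2 nt.
`n_plus` counts elements with a hit starting inside it. The background
slides a 5-nt window in 1-bp steps across the scan range [−500, +200],
counting per location the elements whose hit start falls inside the window;
the mean μ and standard deviation σ are taken over all locations that do
not overlap the functional window. Both window counts and `n_plus` count
*elements*, not hits, so the two sides of the comparison share semantics.
Significance requires both the Gaussian upper tail of `z = (n_plus − μ)/σ`
and the upper tail of Binomial(n_elements, μ/n_elements) at `n_plus` to
fall below α = 0.001 (configurable; requiring both is the conservative
reading of a two-distribution test, and no multiplicity correction is
applied across the twelve CPEs). When σ = 0 the z-score is undefined; the
result is flagged degenerate and never declared significant.

### Co-occurrence

For each pair of CPEs the 2×2 table over functional-window presence is
tested with two one-sided hypergeometric tail sums — overrepresentation of
co-occurrence, and of mutual exclusion — evaluated in log space
(`lchoose` + log-sum-exp) so p-values remain accurate far below the
smallest positive double; results carry both linear and log10 forms. The
Bonferroni threshold is 0.05 / (12·11/2) = 0.05/66. The separate two-sided
Fisher test used for contingency tables sums all tables with point
probability not exceeding the observed one (with the standard 1 + 1e-7
tolerance), again in log space; the one-sided tails bracket it from below.

## CAGE metrics

*Dispersion.* Per library, the dispersion index is the tag-count-weighted
standard deviation of initiation positions within ±50 nt of the TSS, same
strand. Elements are sharp when the mean over informative libraries
(≥1 tag in the window) is ≤ 2.5 — the boundary is inclusive — broad
otherwise, and unclassified with fewer than one informative library (the
minimum is configurable; the source analysis does not state one).

*Tissue specificity.* Expression is tags-per-million within each library,
summed over [−100, +100] on the TSS strand, averaged over the libraries of
each tissue/primary-cell group (including member libraries where the
element is silent), scaled by 1000 and transformed as `log2(1 + x)`. The
`1 +` guard deviates from a bare binary logarithm: elements unexpressed in
a group would otherwise produce −∞. τ = Σ(1 − x̂)/(n − 1) is computed over
the top 15 tissue and top 15 primary-cell groups by total log expression,
ties broken lexicographically so the selection is deterministic. τ is
undefined (flagged, not zeroed) for elements silent in all selected groups.

*Directionality.* Tags are pooled over libraries; R counts reverse-strand
tags in [mid−200, mid), F forward-strand tags in [mid, mid+200], and
directionality is (F − R)/(F + R), undefined below a minimum of one tag.
The half-open boundary at the midpoint assigns the midpoint base to the
forward window once, avoiding double counting; the inclusivity of the outer
edges is a convention fixed once here.

## Peak overlap

A binding event is one narrowPeak record intersecting the region by at
least one base (half-open arithmetic; a single shared base overlaps,
abutting intervals do not). ChIP-seq peak resolution (~500 nt average peak
length) does not justify summit-based assignment, though summit containment
is available. Maximum signal per element is taken across all supplied peak
files pooled. Densities are peaks per 1000 nt over promoter regions
[−500, +200) (700 nt, strand-aware), enhancer bodies, or CGI spans.
Duplicate peaks across files count separately; within a file each record
counts once. Group comparisons use the two-sided Mann–Whitney U test —
exact for small tie-free samples, otherwise the normal approximation with
continuity and tie correction.

## Synthetic data: what it emulates and what it does not

The generator's defaults are the study conditions: 58.6% of promoters and
5.7% of enhancers CGI-positive; enhancer lengths Normal(384, 100) with a
CGI flag vs Normal(289.2, 100) without; sharp-promoter probability 3%
given a CGI and 20% without; single-group (specific) expression probability
20% given a CGI and 80% without; 29 tissue and 36 primary-cell groups at
200 tags per informative library; peak densities 5.06/1.89 per kb for
CGI/non-CGI promoter regions and 3.26/1.15 for enhancers with lognormal
signal; directionality drawn from Beta shapes mapped to [−1, 1], flatter
for CGI enhancers so they are more directional. Effect *directions* mirror
the study system; magnitudes beyond the printed values are not claimed.

Planted CGI blocks are tiled from randomized 20-mers containing exactly 13
G/C and three CpG dinucleotides. Any 100-nt window of such a block carries
at least 52 GC bases and 12 CpGs, provably above both calling thresholds,
so planted truth satisfies the definition it is later tested against —
a requirement for meaningful sensitivity estimates. The price is a
per-window obs/exp around 1.2–1.4, CpG-richer than typical genomic islands;
recovery tests measure caller correctness, not the marginal composition
distribution of real CGIs. The i.i.d. 41%-GC background occasionally
produces genuine GC-rich stretches that legitimately satisfy the CGI
definition, as real non-island sequence does; specificity is therefore
high but not 1. Sharp profiles are point masses with ±1 nt noise; broad
profiles Normal(0, 20) truncated to ±50 nt, placing broad elements above
the 2.5 threshold by construction. Motif planting writes consensus
oligonucleotides at the expected position plus rounded Normal(0, 1) jitter,
with overlap resolved by priority TATA > Inr > DPE > others and DPE planted
only alongside Inr.

Not emulated: chromatin state, read-level CAGE noise, library-size
heterogeneity, correlated tissue profiles, genome-scale element counts.
Passing recovery tests therefore demonstrates correctness of the
computations under controlled conditions, not that real FANTOM5/ENCODE
downloads would reproduce the published genome-scale numbers.

## Problem sizes and numerical choices

The test suite and the acceptance script run the pipeline at 150–400
promoters/enhancers (2000 regions for density recovery, 1000 replicates
for the type-I-error check, 1000 random 2-kb sequences for the caller
equivalence check) — sizes at which every recovery criterion is stable
across seeds while the full suite completes in minutes on one CPU.
Deterministic iteration order and per-stage seed offsets make every run
byte-reproducible given the seed. Degenerate inputs are contracts, not
silent defaults: empty groups, zero-length regions, all-zero expression
and σ = 0 backgrounds raise errors or carry explicit flags.

## Known limitations

The shipped PWMs are consensus-derived and will not numerically match any
specific laboratory matrix set; motif-level results are therefore
demonstrations of the machinery. Whether TCT's functional window should
differ between promoters and enhancers (−25..−10 has been suggested for
enhancers) is left configurable, defaulting to the promoter window.
Library normalization is tags-per-million with arithmetic group means;
other conventions (sum, median) are plausible and the function is the
single place to change them.
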