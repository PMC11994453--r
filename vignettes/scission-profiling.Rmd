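---
title: "Nominating Cas9 cut sites and profiling their scission structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nominating Cas9 cut sites and profiling their scission structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbscan)
library(dplyr)
```

## The measurement

SpCas9 cleaves DNA three nucleotides upstream of the PAM, but not always
bluntly: the RuvC domain can cut the non-target strand one to three
nucleotides PAM-distal of the HNH cut, leaving a 5' overhang. End-capture
sequencing of digested genomic DNA tags every double-strand-break (DSB) end
with an 8-nt UMI, and after end repair the terminal aligned base of each
read reports where its strand was cut. `dsbscan` works entirely from these
strand-resolved read-end pileups.

The coordinate convention is fixed throughout the package. A target is a
20-nt protospacer, position 1 PAM-distal and position 20 PAM-adjacent,
stored 0-based half-open. *Boundary label* `b` (14--20) names the break
boundary between protospacer positions `b` and `b + 1`. For a plus-strand
target starting at `s`, a PAM-proximal read end at label `b` has its
terminal base at `s + b` on the `+` strand, and the PAM-distal read end
sits fixed at `s + 16` on the `-` strand: because end repair fills in
toward the PAM, the distal side always maps to label 17 no matter how the
non-target strand was cut. Minus-strand targets are the mirror image. This
makes the footprint a direct arithmetic fact: label 17 means a blunt cut,
labels 16--14 mean 1--3-nt 5' overhangs (proximal and distal stacks
overlap), labels 18--20 mean 3' overhangs (stacks separated by a gap), and
`infer_footprint()` is simply `17 - label`.

## From reads to molecules

Reads carry an 8-nt UMI and an 8-nt sample barcode at the 5' end
(`extract_umi_barcode()`); alignments below MAPQ 60 are discarded to keep
only uniquely mapped ends (`filter_mapq()`). PCR duplicates are collapsed
by `dedup_ends()`: within a sample barcode, chromosome and strand, records
within 30 nt of an open cluster anchor whose UMIs are within Hamming
distance 2 of the anchor's are folded into it, the first-seen record
surviving at its own position. `N` counts as a mismatch to every base, and
the anchor is the cluster's first record in position order, which makes the
procedure deterministic (the window is anchored at the cluster start, not
slid along the chain). Surviving molecules are aggregated into a BED6
pileup with the count in the score column.

One property of this rule matters for simulation studies: two *distinct*
molecules at the same position collide with probability
$\sum_{k \le 2}\binom{8}{k}3^k/4^8 \approx 0.4\%$ per open anchor, so
deep stacks are thinned slightly, and unevenly, because anchors accumulate
in scan order. The generator emits error-free UMIs and jitter-free
positions (sequencing-error models are deliberately out of its scope), so
for parameter-recovery analyses on simulated data the matched setting is
exact-duplicate collapse (`max_umi_mismatch = -1`); the fuzzy rule remains
the default for real libraries, where it absorbs UMI sequencing errors.

## Nomination

`find_candidate_sites()` scans both strands for every 20-mer adjacent to a
PAM (default `NGG`, IUPAC patterns allowed) within 7 substitutions of the
guide spacer; matches are substitution-only, with no RNA/DNA bulges.
`call_targets()` then tallies unique molecules in the scission window
(labels 14--20 plus the fixed distal position) and tests candidates
carrying at least 3 molecules for enrichment over a non-target control.

The enrichment test form was an open choice; we use a one-sided Poisson
upper tail, the standard model for count enrichment against a matched
control: `P(X >= obs)` with rate `(ntc + 1) * size_ratio`, where the +1
pseudocount guards empty control windows and `size_ratio` is the
target-to-control library-size ratio (totals ratio by default, 1 when the
control is empty). Benjamini--Hochberg FDR is computed across all tested
candidates of a run. Note one consequence: a bare 3-molecule stack against
an empty control has `p = P(Pois(1) >= 3) = 0.080`, so the minimum stack is
detectable but not significant at FDR 0.05 on its own -- at realistic
depths this is immaterial. Loci whose protospacers lie within Hamming 7 of
two or more pooled guides cannot be attributed and are removed
(`remove_ambiguous()`).

## Scission profiles

`scission_profile()` reports two blunt-rate forms per site: the raw
fraction `c17 / sum(c14..c20)` and the log2 ratio
`log2((c17 + 1) / (outside + 1))`. The pseudocount is applied to every
log2 form for consistency (avoiding division by zero); the fraction stays
pseudocount-free so that it is an unbiased binomial proportion. Without
pseudocounts the two are equivalent via `ratio = log2(f / (1 - f))`, so
50% blunt molecules correspond to ratio 0 and 80% staggered to ratio -2 --
the two thresholds used downstream. Sites are classed by staggered
fraction into left-closed intervals `[0, 1/3)` blunt, `[1/3, 2/3)` middle
and `[2/3, 1]` staggered; the boundaries themselves were not specified
beyond the percentages, and left-closed intervals make the map
deterministic (a `1e-9` snap keeps exact count ratios like 1/3 on their
intended side of the double-precision boundary). Rate statistics require
at least 16 proximal molecules by default; 8 is the conventional floor for
nuclease-variant comparisons, and both are configurable.

## The blunt-rate model

`train_blunt_model()` regresses the log2 blunt rate on a one-hot encoding
of the protospacer/guide pair: per position a 4x4 indicator matrix
(protospacer base x guide base), flattened column-major and concatenated
-- 320 binaries -- plus two mismatch counts (positions 1--10 and 11--20),
322 variables in total. The reduced flavor keeps positions 11--20 plus the
seed mismatch count (161 variables); whether mismatch counts belong in the
reduced set was unspecified, and we keep the seed count since the reduced
model still scores mismatched pairs. Any consistent cell ordering is
model-equivalent; ours is fixed (guide base outer, A < C < G < T).

The regressor is a DART-boosted tree ensemble (xgboost) with trees of
unlimited depth, 1,000 rounds and 5-fold cross-validation by default;
the reported quality metric is the Pearson correlation between out-of-fold
predictions and observed responses. Training instances are restricted to
sites with at least 16 raw proximal molecules, capped at 100 per guide,
and class-balanced: with `K` the staggered (blunt fraction < 0.2) to blunt
(> 0.8) ratio per guide, staggered sites are kept with probability `1/K`
when `K > 1`. As written the rule yields probabilities above 1 when
staggered sites are the minority, so we balance symmetrically and subsample
the blunt class with probability `K` in that regime.

Model interrogation follows three routes: gain importance per variable,
aggregated per (position, protospacer base) and scaled to the maximum;
independent per-position least-squares fits of the observed rate on base
identity under a sum-to-zero contrast (`per_position_effect()`); and the
4x4 grid of mean predictions over backgrounds with positions 17/18
substituted (`combo_grid_17_18()`).

## Allele deltas and deletion triage

`enumerate_snp_targets()` emits every NGG placement (reference allele, both
strands) in which a biallelic SNV occupies protospacer position 17 or 18;
VCF coordinates are 1-based and converted centrally to the internal 0-based
convention. `predict_allele_delta()` scores each placement for the
reference and the variant allele with matched guides (0 mismatches) and
reports `delta = alt - ref`, antisymmetric by construction.

For pathogenic 1-nt deletions, `place_guides()` searches the *deletion
allele* for NGG PAMs on either strand with the deletion junction 0--4 nt
from the PAM-proximal protospacer edge (offset 0 = PAM directly adjacent).
A staggered cut at such a site favours a templated +1 insertion duplicating
the protospacer base at position 17; `templated_insertion_outcome()`
applies that insertion at the blunt boundary (between positions 17 and 18
mapped to the genome), rebuilds the transcript CDS for both alleles, and
reports whether the reading frame and the exact protein sequence are
restored -- codon degeneracy often restores the protein even when the
inserted base differs from the deleted one. When the insertion point falls
outside the coding exons only the DNA-level frame flag is computed and the
protein flag is NA. Candidates are ranked by predicted log2 blunt rate,
with `<= -2` ("highly staggered", at least 80% staggered molecules)
marking the regime in which templated insertions dominate.
`design_t7_construct()` assembles the in-vitro-transcription template:
T7 promoter, spacer with its 5'-terminal (PAM-distal) base replaced by G
for transcription initiation, and the SpCas9 scaffold handle (59 nt). The
G-substitution is applied at the spacer's 5' terminus; descriptions of
this step sometimes number that base "position 20" in the opposite
convention, but the transcription start is unambiguous.

## The synthetic-data generator

`sim_config()`/`gen_genome()`/`sim_break_ends()` emulate the end-capture
chemistry on a uniform-random genome: planted protospacer+PAM instances
(one exact on-target per guide plus mutated off-targets, non-overlapping),
`depth_per_site` molecule pairs per site, per-molecule blunt/staggered
outcomes, random 8-nt UMIs, PCR duplicates re-emitted at identical
position+UMI, and uniform background read ends on both strands. Defaults:
one 50-kb chromosome, 5 guides with 3 off-targets each (up to 7 planted
substitutions), depth 100, overhang lengths 1/2/3 nt at probabilities
0.6/0.3/0.1 (1-nt overhangs dominate staggered Cas9 cuts), background
1e-4 read ends per bp per strand (the true background DSB rate in gDNA is
not established; this yields a realistic ~10 background molecules per
50 kb), and PCR duplication 0.1.

A site's true blunt fraction follows an additive sequence rule on
protospacer bases 17/18 (`blunt_rule_default()`): G17 strongly blunt (+2),
G18 strongly staggered (-2), with milder secondary effects (T17 -1,
C18 +1) so all 16 combinations are distinct; the blunt fraction is the
logistic transform `2^r / (1 + 2^r)` of the summed log2 effects, and an
optional per-mismatch penalty lowers it on the logit scale. The generator
emulates the geometry, UMI chemistry and background of real libraries but
not sequencing errors, indels, alignment artefacts or chromatin-biased
background -- so passing recovery tests demonstrate correctness of the
estimators under the generative model, not robustness to those real-data
features.

## Validation problem sizes

The test suite and the acceptance script exercise: footprint recovery on
~315 simulated cuts (Cas9 and restriction modes, signed overhangs -3..+3,
zero noise; exact recovery required), blunt-fraction recovery on 500 sites
at depth 100 against exact binomial 99% intervals, nomination recall and
false-call control on a 100-kb genome (8 guides, 48 planted sites, 50
noise-only replicates) with the guided search checked exactly against a
brute-force Hamming scan, and rule recovery by a 100-round DART model on
5,000 synthetic instances (held-out r >= 0.9; 100 rounds matches the
plateau of the planted-rule problem, while the default stays 1,000).
Deletion-triage flags are compared with an independent per-base-mask
translation oracle on 500 random toy CDS cases.

## Known limitations

Bulge-tolerant (gapped) off-target matching is out of scope, as is de novo
hotspot discovery without a guide. 3' overhangs are modelled for
restriction fixtures and treated as non-blunt signal for Cas9. The
deletion triage takes the first overlapping transcript and does not
arbitrate isoforms; insertions landing exactly on an exon boundary are
treated as intronic. Reported dataset-scale statistics (genome-wide site
counts, population-variant tallies) require real sequencing data and
external databases and are outside what the synthetic conditions can or
should reproduce.
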