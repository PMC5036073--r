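---
title: "Methods: dual-tag reconstruction of near full-length 16S sequences"
author: "long16s"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-tag reconstruction of near full-length 16S sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical rules
behind `long16s`, in the spirit of the methods sections of mature
Bioconductor pipelines: what each stage assumes, which knobs matter, and
what the simulation-based tests do and do not demonstrate.

## The measurement model

A template molecule is tagged once on each end with an independent uniform
random 10-nt sequence before any amplification. Amplification copies the
tag pair along with the template, so after sequencing, the pair of tags
identifies the progenitor molecule: reads sharing (approximately) the same
tag pair are replicate observations of one molecule, and their consensus
removes both sequencing error and amplification-count bias (each molecule
counts once regardless of how strongly PCR favoured it).

Two artefacts complicate this picture and drive the design:

* **Sequencing error in the tags themselves.** Tags are decoded from raw
  reads, so a cluster of near-identical tag-pair observations, not an exact
  key, represents a molecule. We cluster 64-nt composite signatures (both
  tags, both sample barcodes, and the first 14 nt of gene sequence from
  each end) at > 89 % Hamming identity. Appending the gene prefixes makes
  accidental tag collisions between different templates visible as
  divergent composites.
* **PCR template switching.** A chimeric molecule carries tag_f from one
  parent and tag_r from another — a *novel* tag pair that forms its own
  cluster. Because chimeras arise later in the reaction, they are almost
  always less abundant than their parents, and each parent's cluster shares
  one tag with the chimera's cluster. The filter discards any cluster
  sharing a consensus tag with a strictly more abundant cluster.

## Stage-by-stage numerical rules

**Layout decoding.** Phaser lengths are scanned in ascending order (0–3);
the first offset where the barcode window matches exactly one known barcode
with ≤ 1 mismatch *and* the primer annealing sequence follows the tag with
≤ 2 mismatches wins. Barcode sets are required to have minimum pairwise
Hamming distance 3, which makes 1-mismatch decoding provably unambiguous
(verified by exhaustive corruption in the tests). Degenerate primer
positions (e.g. M in 27F) match their IUPAC expansions; an N in a read
matches nothing, anywhere in the package. Mates parsing as the same end, or
as both ends, are counted as anomalies and excluded rather than guessed.

**Clustering.** Identity is Hamming on equal-length composites — every
component is fixed-length synthetic sequence, so indels are not a relevant
error mode and alignment-free comparison suffices. Unique composites are
processed in (multiplicity desc, lexicographic) order; each joins the
*first* existing cluster within the threshold, else founds one. One
consensus-refinement pass (weighted per-position plurality, reassignment,
one recomputation) follows; iteration to convergence is deliberately
avoided for bounded, deterministic runtime. The canonical processing order
makes the outcome invariant to input permutation. Consensus ties break by
fixed base order A < C < G < T, and N never wins a tie it is part of. The
> 89 % threshold applied to the 64-mer allows ≤ 7 mismatches; it is
configurable (`identity_threshold`) because the protocol description could
also be read as per-tag ("one out of 10 bases").

**Chimera filter.** "More abundant" is read strictly: equal-abundance tag
sharers are all kept, because neither is evidence against the other.
Tag sharing is exact on consensus 10-mers — sequencing-error divergence has
already been absorbed by clustering (a ≤ 1-mismatch sharing mode exists,
default off). Singleton clusters are *not* auto-discarded; they fall only
to the tag-sharing rule, and are separately excludable in the bias
estimate, where they are flagged as possible recombinants. The filter is
idempotent and order-invariant.

**Binning.** Tags resolve against kept-cluster consensus tags with
unique-best-match semantics at budget 1 (mirroring the clustering radius):
an exact match beats a 1-mismatch match; equidistant candidates, or tags
carried by two equal-abundance surviving clusters, leave the read
unassigned. Reads whose cluster was discarded are dropped, not reassigned —
filtering precedes assembly. End+internal reads from chimeric fragments
that carry a kept tag are accepted by construction (they are
indistinguishable here); the coverage filter downstream is the defence.

**Assembly.** Reads are oriented to the 27F→1391R strand using their parsed
end (or their mate's), then trimmed: synthetic prefix, 3' adapter-stub
read-through (exact then 1-mismatch), 3'-quality trimming by the BWA
running-sum rule at Q20 (ties resolve to the shortest trim), and partial
primer sequence at the extremities (≥ 8 nt overlap, ≤ 1 mismatch,
IUPAC-aware — primer-annealing sequence is primer-derived, hence synthetic
wherever it appears). Error correction replaces a base only when *every*
covering k-mer is below `min_count` (3) and *exactly one* substitution
lifts them all; ambiguity leaves the base alone, at most 2 edits per read,
and a read whose weak region exceeds 2k is treated as low coverage, not
error. The de Bruijn graph uses k = 31 with solid count ≥ 2 (floor 1 for
bins under 10 reads, so low-coverage true templates are not erased);
dead-end tips shorter than 2k hanging off branches are pruned once, and
contigs shorter than 2k are dropped whenever anything longer assembled —
such leftovers are unresolvable error or chimera debris. Bins are
single-template and tiny, which is why a minimal single-strand de Bruijn
assembler is adequate and fully deterministic. The 10-fold coverage rule is
strict (`mean_coverage * 10 < max` drops; exactly 10-fold keeps), and is
scale-invariant and idempotent.

**Consensus quality.** Reads anchor by their first 15-mer that is unique in
the contig, extend gaplessly (substitutions only — no indel mode in bins of
one template), and must reach 90 % identity over the overlap. The per-base
score `min(93, max(0, Σq_agree − Σq_disagree))` is an explicit, declared
model: it grows linearly with agreeing evidence, is penalised by
disagreement, and caps at the FASTQ '~' ceiling. No claim of equivalence
with any external consensus caller is made — profiles are compared
qualitatively (ends deeper than interior, quality tracking coverage).

**Bias estimate.** "Relative mean error" is the coefficient of variation of
end+end cluster abundances (sample n−1 SD over mean; population SD via a
switch). It is scale-invariant, and the per-cluster abundance/mean vector
gives the spread of amplification around the average.

## The simulator: what it emulates, and what it does not

Defaults mirror the study-scale conditions: ~5,000 templates of 1,365 nt
across 12 samples, mean sequenced depth 8 end+end copies per template,
lognormal amplification bias with σ = 1.27 (CV ≈ 2, matching an abundance
spread of roughly 0.06–32× the mean), a 10 % per-copy template-switch
chimera rate, tagmented fragments of 400–1,500 bp pooled 7:1 with
full-length amplicons, 2×250 reads, and 0.5 % substitution error with a
linearly decaying quality profile (Q38 → Q26 plus noise). Chimera parents
are drawn within the copy's sample by default — chimeras form during each
sample's own amplification — with `chimera_cross_sample_prob` available to
model recombination after pooling, which surfaces as invalid barcode
combinations. Tag collisions are allowed (tags are drawn independently), so
birthday-collision behaviour at scale is part of the model.

Tagmentation cut points are drawn uniformly *between* the primer annealing
sites rather than over the whole molecule. The annealing sites are ~3 % of
the cut space; excluding them means no internal read begins or ends inside
a primer site, so the reconstructable region (the inter-primer insert) has
an unambiguous boundary. Without this, reads carrying 1–7 nt of primer
sequence at an extremity are undecidable at the read level (the same bases
could be template), which blurs the last few bases of a reconstruction.

Deliberate non-features: no indel sequencing errors (substitutions dominate
the platform's error mode), no primer-binding or GC amplification bias, no
per-cycle error accumulation inside the enrichment PCR (unmeasurable by the
protocol itself), no thermodynamic PCR model. Passing the simulation tests
therefore shows the *logic* of the pipeline is correct under the stated
generative model — it does not certify performance on real data with indel
errors, degraded ends, or reference-database idiosyncrasies.

## Test problem sizes and statistical choices

The validation suite runs, at fixed seeds:

* **Round trip** — 200 error-free templates at depth 8 with a 25:1
  tagmentation ratio; every inter-primer insert must be recovered exactly.
  The ratio is raised above the 7:1 default because exact recovery requires
  interior k-mer coverage ≥ 2 everywhere; at 7:1 the interior is thin and
  assemblies fragment — the same coverage limitation the protocol shows at
  full scale — which would test coverage, not correctness.
* **Chimera recovery** — 1,000 templates, r = 0.10, study-like depth/bias/
  error, end+end pool only (tagmented fragments play no part in the
  recombination estimate, whose denominator is the end+end pool). The
  estimated read-level rate must land in the 99 % binomial interval of r,
  and every strictly dominated chimeric cluster must be discarded.
* **Bias recovery** — 1,000 clusters at σ = 0.8 and depth 20, error-free.
  σ = 0.8 (CV ≈ 0.95) is chosen on sampling-theory grounds: the sampling SE
  of a sample CV at n = 1,000 is ≈ 9 % at σ = 0.8 but ≈ 50 % at the
  study-like σ = 1.27 (the lognormal's fourth moment explodes), so no
  correct estimator could reliably sit within the 15 % recovery tolerance
  at study σ. Depth 20 keeps integer rounding of copy numbers from
  distorting the generative CV.
* **Clustering oracle** — 50 random 64-mers against an independent
  plain-loop reference implementation of the same published rules.
* **Boundary cases** — strict 10-fold filter behaviour, exhaustive 1-error
  barcode corruption, quality-trim against a brute-force running-sum
  oracle.

## Known limitations

* Indel-free assumptions run through clustering, mapping and assembly; an
  indel-rich platform would need an alignment-aware variant of all three.
* The consensus quality model is additive and treats reads as independent;
  PCR duplicates within a bin violate independence, so high scores are
  upper bounds on confidence, consistent with the capped scale.
* Short assemblies from thin interior coverage are reported, not rescued;
  paired-end distance information is deliberately unused.
* The chimera filter cannot flag a chimera whose parents are both absent
  from (or not more abundant in) the end+end pool, nor end+internal reads
  from chimeric fragments carrying a kept tag; the coverage filter is a
  mitigation, not a guarantee.
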