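---
title: "Methods: LUTI discovery and characterization"
author: "lutiscan developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LUTI discovery and characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope and model

A LUTI (long undecoded transcript isoform) locus has two promoters on the
same strand: a distal promoter producing a 5′-extended mRNA whose leader is
studded with AUG uORFs, and a CDS-proximal (PROX) promoter producing the
translatable isoform. LUTI transcription represses the PROX promoter in
*cis*; the uORFs repress CDS translation in the extended transcript. The
package implements the computational side of characterizing this switch in
a two-timepoint design (here labelled premeiotic vs meiotic prophase):
isoform discovery from 5′-end tag data validated by long reads, uORF
translation state from ribosome footprints, promoter chromatin scoring,
nucleosome repositioning, and a correlation analysis of which features
track transcriptional repression.

All internal coordinates are 0-based half-open; the 5′ end of a
minus-strand feature is its highest covered base. This matches
bedGraph/BED, removes ±1 ambiguity between modules, and confines
1-based/0-based conversion to the GFF3 boundary.

# TSS clustering

5′-end tag counts are normalized per sample to tags per million
(`normalize_tpm`). Clustering is distance-based: positions whose **pooled**
TPM (summed over all samples) reaches the seed threshold merge transitively
when consecutive positions are at most `max_dist` bp apart; a resulting
single-position cluster is dropped when `remove_singletons` is set unless
its pooled TPM strictly exceeds `keep_singletons_above`. Promoter-level
aggregation then merges clusters whose boundary gap is at most 50 bp,
provided they carry at least 1 pooled TPM. The strict parameter set
(threshold 2, maxDist 5, removeSingletons with keepSingletonsAbove 3, then
aggregation) is used for discovery; the permissive set (threshold 1, no
singleton removal, no aggregation) for quantification. Whether thresholds
apply per-sample or pooled is not fixed by common practice; pooled is the
permissive reading and is what this package uses (the threshold arguments
are plain numbers, so a caller can pre-filter per sample if preferred).

The dominant position of a cluster is its pooled-TPM maximum; ties are
broken toward the 5′-most member so the result is deterministic and
strand-symmetric.

**Fold changes.** Timepoint fold changes are pseudocount log2 ratios of
replicate-mean TPM, `log2((m_b + c)/(m_a + c))` with `c = 0.1` TPM by
default. A shrinkage-based count model (DESeq2-style) is deliberately not
used: the downstream decision is a hard threshold (log2FC > 2) on heavily
induced clusters, where the pseudocount ratio and a shrunken estimate agree
except within the noise floor; the pseudocount is exposed in every API that
computes a fold change. The significance filter that would accompany a
count model is consequently not reproduced.

# Isoform discovery

A cluster is *induced* when its mean TPM over both timepoints is > 2 and
its log2 fold change is > 2 (both strict). Induced clusters pass a cascade:

1. **Long-read validation**: at least one same-strand long read whose 5′
   end lies within `near_window` (default 50 bp) of the cluster's dominant
   position and which covers an entire neighboring CDS. 50 bp tolerates 5′
   degradation of long reads; where the original workflow used manual
   genome-browser inspection, this check is automated and the window is a
   parameter. When several genes qualify, the gene whose CDS 5′ end is
   nearest downstream is taken — the conservative reading of "neighboring".
2. **Downstream-promoter requirement**: a second same-strand promoter-level
   cluster whose dominant position lies strictly between the candidate TSS
   and the CDS 5′ end. With it, the call is `luti_candidate` (the
   intervening cluster nearest the CDS becomes the PROX promoter); without
   it, `canonical`.
3. Failing spanning evidence, a TSS inside an opposite-strand CDS is
   `antisense`; inside a same-strand CDS, `intragenic`; otherwise
   `intergenic`. "Gene body" means the annotated CDS interval — the only
   extent the annotation guarantees.

# uORF translation

uORFs are ATG occurrences on the transcript strand between the distal and
PROX TSSs — all offsets, frame-agnostic, no stop-codon or context
requirement, because the leader metric of interest is literally the ATG
count. A uORF is *translated* when at least 4 footprint 5′ counts fall in
its first 6 codons; the ATG codon is codon 1, so the window is 18 nt
including the ATG. Footprints are used at their recorded 5′ positions —
P-site offsetting, if desired, belongs upstream.

The first-2/last-2 summary reports the fraction of qualifying genes (≥ 4
uORFs by default; a strict `> 4` switch exists because both conventions
appear in practice) whose uORF at rank 1, 2, n−1, n is translated. Under
leaky scanning — initiation at uORF i with probability
pᵢ·Π_{j<i}(1−pⱼ) — these frequencies are non-increasing in rank whenever
all pᵢ ∈ (0,1), which the synthetic study reproduces.

The background ATG frequency for non-LUTI genes uses the 500 bp upstream of
the TSS. For i.i.d. uniform bases the expectation is (498/64)/500 ≈ 0.0156
ATGs per bp (498 scannable offsets, each ATG with probability 4⁻³); the
test suite checks the implementation against this closed form.

# Promoter chromatin

Per mark and replicate, fold-enrichment is summed over the 50 bases 5′ of
the PROX TSS and the 500 bases from the TSS 3′-ward (strand-aware;
uncovered bases are 0). The score is the ratio of the two sums. The ratio's
orientation is genuinely ambiguous in prose descriptions of this analysis;
this package uses downstream/upstream so that a *gain* of
co-transcriptional mark over the PROX promoter *raises* the score, making
the expected repression correlation negative. Only the sign of downstream
correlations depends on this choice, and it is a flag
(`orientation = "up_over_down"` inverts it). The timepoint fold change is
computed per replicate and averaged arithmetically (triplicates by
default); replicates with an undefined ratio (zero upstream sum) drop out
of the mean.

TF target calling consumes narrowPeak files: a replicate qualifies when a
peak with linear enrichment > 4 (log2 > 2) has its **summit** within
300 bp of the TSS; 2 of 3 replicates make a target. Summit-to-TSS distance
is used because the summit is the most localized statistic a peak file
carries; with no summit call (offset −1) the interval midpoint substitutes.

# Nucleosomes

The caller is a defined, dependency-free stand-in for DANPOS-class tools,
preserving the three quantities downstream analyses need — position,
occupancy, fuzziness — without attempting score-level reproduction:

* density = Gaussian-kernel smooth of dyad counts (bandwidth 15 bp,
  truncated at 4 SD);
* calls = local density maxima accepted greedily in decreasing density
  order subject to 120 bp minimum spacing;
* occupancy = raw dyads within ±73 bp (a nucleosome half-width);
  calls under 20 dyads are dropped;
* fuzziness = weighted SD (bp) of raw dyad positions within ±73 bp,
  operationalizing "how often the nucleosome is found away from its
  consensus position" as a dispersion.

Because the ±73 bp window truncates the dyad distribution, the measured
fuzziness of a nucleosome with dyad SD σ is the truncated-normal SD — for
σ = 25 bp about 24.6 bp, a 1.7% shrinkage at the SDs used here. The
recovery tests compare against the planted values within the stated ±20%
band, which absorbs this truncation bias at the simulated noise levels.

The +1 nucleosome is the nearest call strictly 3′ of the PROX TSS within
500 bp (strand-aware), the −1 the nearest strictly 5′. The shift feature is
the strand-oriented dyad displacement between timepoints, negative when the
nucleosome moves toward the TSS (into the NDR); fuzziness change is
meiotic − premeiotic.

# Feature statistics

Repression classes come from the PROX TPM fold change: repressed < 0.25,
non-repressed > 1, otherwise intermediate; both inequalities strict, genes
with zero premeiotic TPM flagged undefined. Spearman's ρ is the Pearson
correlation of mid-ranks; p-values use the t approximation for n > 10 and
exact permutation enumeration (all n! arrangements, tie-aware, implemented
in C++) for n ≤ 10. The feature clustermap uses pairwise-complete ρ and
average-linkage clustering on 1 − ρ; p-values are reported raw, with a
Benjamini–Hochberg column added as a clearly-labelled extension. The paired
Wilcoxon signed-rank test drops zero differences, uses the exact
signed-rank null for n ≤ 25 without ties, and a normal approximation with
continuity and tie corrections otherwise.

# The synthetic study

`generate_study` plants 30 LUTI / 30 canonical / 10 antisense / 10
intergenic / 10 intragenic loci by default in fixed 5 kb slots on two
chromosomes (strand drawn per locus; minus-strand loci are mirrored within
their slot). Defaults and why:

* **Tag counts**: negative binomial around the expected per-position count
  (dispersion 0.2; 0 = deterministic). Overdispersion is the realistic
  stress case for count data. TSS tags are jittered ±2 bp (weights
  .1/.2/.4/.2/.1) so the maxDist-5 clustering is genuinely exercised.
  Non-induced background positions (10 per slot, expected count 400) give
  the TPM normalization a realistic denominator; because the meiotic
  libraries gain planted LUTI tags, TPM fold changes are compressed ~10%
  relative to count fold changes, and the planted FC windows
  (repressed 0.08–0.20, intermediate 0.35–0.80, non-repressed 1.4–1.9)
  leave margin so classes survive quantification at zero noise.
* **Leaders**: the genome is uniform random with leader ATGs scrubbed and
  exactly `n_uorfs` (2–10) ATGs re-inserted ≥ 24 nt apart, so uORF counts
  are exact ground truth and footprint windows do not overlap.
* **Footprints**: multinomial allocation of `fp_depth` ribosomes by the
  leaky-scanning probabilities (p = 0.5 per uORF), deposited uniformly over
  each uORF's first 18 nt. The Monte-Carlo oracle in the tests re-derives
  expectations with explicit per-ribosome scans.
* **ChIP**: baseline fold enrichment 1.0 in 10 bp bins with Gaussian noise
  (SD 0.1); at meiotic timepoints the 500 bp downstream of repressed PROX
  TSSs is multiplied by the planted gain, `1 + 2(1 − min(FC, 1))` for
  H3K36me3 (≈ 2.6–2.8 at repressed loci) and a 1.5× gain of H3K4me2
  restricted to repressed loci — encoding "strong K36 signature, limited
  K4 changes". TF peaks are planted at bound promoters in all replicates
  (enrichment 8×), with single-replicate and weak-enrichment decoys at
  unbound loci so the 2-of-3 and >4× rules are both load-bearing.
* **Nucleosomes**: dyads from Gaussians at −140, +60, +225, +390, +555 bp
  (transcript-oriented; 165 bp spacing, SD 15 bp; 300 dyads for the +1,
  175 for the others ≈ 1000 per locus) plus a sparse uniform background
  below the occupancy floor. At meiotic timepoints, repressed loci shift
  the +1 by −15 bp toward the NDR and add +10 bp to its SD; the rest of the
  array (not the −1) gains half the SD increment, encoding array-wide
  blurring at repressed promoters; intermediate loci get −6 bp/+4 bp. These
  magnitudes were chosen once, before any tests were run, as the kind of
  repositioning MNase studies report.
* **TSS distance and CDS length** are drawn independently of repression
  (300–800 bp and 600–1500 bp), so TSS distance serves as the planted
  *negative control* in the correlation analysis.

What a green test establishes — and what it does not: the generator
emulates geometry, noise and effect directions, not real library-size
distributions, mappability, splicing, sequence composition, or batch
effects. Recovery of planted truth demonstrates the pipeline's internal
correctness, not field performance on deposited data.

# Numerical and design choices

* The downstream-promoter test uses dominant positions, which give an
  unambiguous strand-aware ordering; cluster boundaries are member min/max.
* Ties in the dominant position, in Spearman ranks (mid-ranks), and in the
  nucleosome greedy acceptance (density order, then position) are broken
  deterministically; re-running any stage is bit-reproducible for a fixed
  seed.
* One known sampling subtlety: with 30 LUTI rows, the null SD of ρ is
  ≈ 0.19, so a per-seed bound of |ρ| < 0.2 on the independent TSS-distance
  feature would fail by chance ~28% of the time; the acceptance test
  therefore requires the three planted signs per seed but bounds the
  *mean* |ρ| of the control feature across five seeds.
* `exact_perm_spearman_p` enumerates distinct permutations of the (possibly
  tied) rank vector; each distinct arrangement has equal multiplicity among
  the n! equally likely permutations, so the count ratio is exact.

# Limitations

* Fold changes are pseudocount ratios, not shrinkage estimates; very
  low-abundance clusters near the induction threshold are decided by the
  pseudocount.
* The nucleosome caller is not DANPOS; its occupancy/fuzziness values are
  not numerically comparable to DANPOS output, only to themselves.
* uORF calling ignores near-cognate starts, stop codons and Kozak context
  by design.
* Long-read validation is containment-based and splice-naive.
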