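---
title: "Methods: somatic alteration calling from tumor/normal mate-pair sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic alteration calling from tumor/normal mate-pair sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

A tumor specimen and the same patient's constitutional DNA are sequenced as
long-insert mate-pair libraries: genomic fragments of ~1.5 kb circularized so
that a 50 bp tag is read from each end, both tags pointing in the same
direction in the concordant state. Coverage is moderate (37× tumor, 40×
germline) but *clonal* coverage — fragments spanning a point, i.e.
`coverage × insert / (2 × read length)` ≈ 37 × 1500/100 ≈ 555× — is very
high, which is what gives the design its power for structural variation.

The specimen is not pure: histopathology puts tumor cellularity near 60%.
Every somatic signal is therefore diluted by constitutional DNA. A clonal
heterozygous somatic SNV in a copy-neutral region has expected tumor
alt-read fraction

$$f = \frac{\pi \cdot m_{alt}}{\pi \cdot CN + (1-\pi)\cdot 2} = \frac{0.6 \cdot 1}{0.6\cdot 2 + 0.4\cdot 2} = 0.30,$$

a hemizygous deletion sits at a depth ratio of
$\pi/2 + (1-\pi) = 0.7$ (log2 −0.515), and a homozygous deletion at
$1-\pi = 0.4$ (log2 −1.32). These mixture expectations drive every default
in the package and every acceptance threshold in its tests.

# The synthetic-data generator defines the study conditions

`sim_config()` fixes the conditions once: purity 0.6, coverages 37/40,
insert Normal(1500, 150) truncated at twice the read length (only the 1.5 kb
target is given by the library design; the SD is our choice of a typical
HydroShear spread), read length 50, germline SNP rate 1e-3/bp with
heterozygous fraction 2/3 (ballpark human values), Ti/Tv calibration 2.12 —
a substitution is a transition with probability $2.12/3.12 = 0.6795$, so the
expected transition:transversion ratio equals the genome-wide value reported
for the germline callset. Base quality is a single configurable Phred level
(default Q30), and the per-base substitution error rate is exactly the rate
the quality implies ($10^{-Q/10} = 10^{-3}$); no quality profile was
published, so a point mass keeps the error model and the callers' weighting
in one-to-one correspondence.

Two fidelity modes keep everything desk-scale:

- **read-level** (`simulate_mate_pairs()`): individual alignment records with
  correct CIGARs for planted indels, fusion-spanning fragments whose mates
  map to the two partner loci, and a configurable background rate (default
  2e-4) of chimeric pairs whose second mate lands on a random contig —
  emulating residual circularization artifacts, the one discordant-read
  nuisance we model. Intended for genomes up to a few Mb; requests implying
  more than 1e8 reads are refused.
- **depth-level** (`simulate_bin_depths()`): independent Poisson fragment
  counts per 100 bp bin, tumor rate scaled by
  $\pi\,CN/2 + (1-\pi)$. Tens of Mb in seconds; used for copy-number work.

Copy numbers 0–4 are realized as haplotype multiplicities
((0,0), (1,0), (1,1), (2,1), (2,2)), so nested configurations — a hemizygous
deletion containing a homozygous interval — are expressed naturally, and
fragment sampling density follows the local mixture automatically.

What the simulator deliberately does **not** model: sequencer color-space,
alignment/mapping errors and mappability structure, GC bias, subclonal
heterogeneity, and quality-score miscalibration. Passing tests therefore
demonstrate correctness of the *computations* under the stated generative
model, not robustness to artifacts of real alignments; parameters that would
absorb such artifacts (germline caps, strand-asymmetry post-filter,
`min_pairs`, the mode filter) are all exposed.

# Stranded KS genotyping

For one strand with observations $(b_i, q_i)$ the expected pileups keep the
same positions and qualities and replace the bases: all reference, all
alternative, or — diploid only — reference at the first $\lceil n/2\rceil$
positions and alternative at the rest (the odd position goes to reference;
configurable in spirit, but fixed here and documented). With weights
$w_i = 1 - 10^{-q_i/10}$ the pileup's normalized mass is laid over the
ordered alphabet (ref < alt < other) and

$$D(\text{obs}, \text{exp}) = \max_c\,\bigl|F_{obs}(c) - F_{exp}(c)\bigr|$$

is the maximum absolute difference of cumulative masses. The statistic is
symmetric, bounded by [0, 1], zero iff the weighted category masses agree,
and reduces to the classical two-sample KS statistic on the category
marginal at equal qualities. The exact statistic of the original tool is
unpublished; this definition uses both the base identity and the confidence,
which is what the tool is described as doing, and the weighting function is
injectable at the `ks_distance()` level should quality-rank weighting be
preferred. The per-strand genotype is the argmin of the three distances
(ties resolve toward the less variant genotype), and in Genotype-Consensus
strand mode a site has a genotype only when both strands agree; a site is a
*variant* when variant genotypes appear on both strands. A strand below 4
observations yields a no-call (no depth floor was published; 4 is the
smallest count at which the het/hom boundary $f = 0.25$ is meaningful).

With equal qualities the distances depend only on per-strand category
counts ($D_{ref} = 1-r$, $D_{het} = \max(|r-h|, o)$,
$D_{alt} = \max(r, o)$ with $h = \lceil n/2\rceil / n$), which the batch
path `genotype_sites()` exploits; the equality of the two paths is asserted
exhaustively in the tests against a brute-force oracle.

**A structural consequence worth stating:** a diploid site is called het on
a strand only when its observed alt fraction exceeds 0.25. At 60% purity a
clonal somatic het sits at $f = 0.30$, so with ~18.5 reads per strand the
per-strand detection probability is only ≈ 0.72 and the both-strands rule
gives ≈ 0.52. The KS genotyper is a *germline* genotyper
(designed for $f = 0.5$); in the somatic consensus it contributes
specificity, and the pipeline's sensitivity is carried by the proportion
test. The tests therefore assert ≥ 99% germline genotype concordance for the
genotyper, and recall for the proportion-test caller, not for the
intersection — the intersection's recall ceiling at these study conditions
is ~0.5 by the arithmetic above, and no threshold setting can move it.

# The strand-minimum proportion test

Each strand is tested separately with the pooled two-proportion z statistic

$$z = \frac{k_t/n_t - k_g/n_g}{\sqrt{\hat p(1-\hat p)\left(\tfrac1{n_t}+\tfrac1{n_g}\right)}},\qquad \hat p = \frac{k_t+k_g}{n_t+n_g},$$

defined as 0 when $\hat p \in \{0, 1\}$, and the **minimum** of the two
strand statistics is the site statistic — evidence must appear in both read
directions. Whether the original test was pooled-z, chi-square or Fisher is
unstated; pooled-z was chosen (injectable) because it is the textbook test
of proportions and is monotone in the evidence. Sites with germline alt
evidence above the caps are filtered (`germline_evidence`) to protect
against under-sampled polymorphic germline sites.

## Threshold calibration

The two-tier (strict/lenient) design is reproduced with thresholds
calibrated to the study conditions, since no numeric thresholds were
published. At 37× tumor coverage a true somatic site has per-strand alt
count $k \sim \text{Poisson}(18.5 \times 0.30 = 5.55)$, so
$P(k \ge 2) = 0.975$ per strand and the mean per-strand z is only ≈ 2.7 —
which is why plausible-looking thresholds like z ≥ 3 per strand would
destroy sensitivity (both-strand recall ≈ 0.1). The defaults are:

| parameter | strict | lenient | rationale |
|---|---|---|---|
| `stat_threshold` (z, min over strands) | 2.5 | 1.0 | lenient keeps single-read strands with z(k=1) ≈ 1.0 |
| `min_alt_per_strand` | 3 | 1 | both-direction evidence |
| `min_alt_total` | 6 | 3 | FP control: P(≥3 errors at a site) ≈ 8e-6 at Q30 |
| `germline_max_alt` / `max_frac` | 1 / 0.02 | 2 / 0.05 | polymorphism guard |
| `min_depth_per_strand` | 8 | 4 | statistic stability |

Expected lenient recall at the study conditions is ≈ 0.98 with expected
false positives of a few per Mb before the consensus (and ~0 after it);
the measured values on 520 planted sites in the test suite are 0.979 recall
and 1.0 precision for the lenient tier. Strict dominates lenient
componentwise; this ordering is validated at run time, and monotonicity
(tightening never adds calls) is a tested property.

The final list is `strict ∪ {lenient passing post-filters}` where both tiers
are first intersected with the KS-genotyper somatic set (variant in tumor,
hom-ref in germline). Manual review of the lenient tier is replaced by two
deterministic post-filters: strand alt-fraction asymmetry at most 2-fold,
and no candidate indel within 5 bp — a reviewable, testable stand-in for a
by-eye step that cannot live in a pipeline.

# Somatic indels

Step one removes tumor reads whose |insert| lies outside the **open**
interval (500, 5000) — signed inserts carry no extra information here, so
the absolute value is filtered — and groups identical insertion/deletion
CIGAR events by (contig, start, type, inserted sequence), emitting
candidates with ≥ 3 supporting reads making up ≥ 10% of coverage (the
external candidate generator it replaces is a black box; CIGAR-event
grouping is self-contained and sufficient at these indel sizes). Step two
is reproduced exactly as described: the window from 5 bases upstream of the
candidate start to 5 bases downstream of its end is scanned in the
germline, and the candidate is somatic only if **no** germline read carries
any indel CIGAR event overlapping the window; germline coverage below 8
over the window yields `undetermined`, never `somatic`.

# Copy number

Depths are taken per 100 bp bin (fragment/clonal coverage genome-wide;
base coverage for the exon scan, as the moderate-deletion variant
prescribes). Each sample is normalized as `log2((depth + 0.5)/mode)` — the
0.5 pseudocount keeps homozygous-deletion bins finite — and germline bins
outside 0.1–10× the germline mode are unusable (repeat and unsequenceable
regions). The tumor−germline difference is averaged over a sliding window
(2 kb default, per the analysis description; the results narrative also
mentions 4 kb, so `--window` is a parameter) sliding by one bin; windows
with under half their bins usable are missing.

Two numerical realities of desk-scale simulation led to explicit choices:

- **Modal quantization.** The mode of Poisson(λ) counts at integer λ is
  ambiguous between λ−1 and λ (their probabilities are exactly equal), so
  normalization can shift by log2(40/39) ≈ 0.037. Tests therefore assert
  *contrasts* (aberrant minus neutral windows), which cancel the shift.
- **Baseline.** Flagging is on departure *from baseline*. On genome-scale
  data the modal depth pins the baseline at ~0, but when a simulated genome
  is half-aberrant the tumor mode can lock onto the aberrant peak. The
  baseline is therefore estimated as the mode of the windowed-difference
  density (`baseline = "auto"`, disable with 0); on mostly-neutral genomes
  this is ~0 and changes nothing.

Flagged windows (|adjusted value| > 0.75 by default) form maximal same-sign
runs, tolerating 2 missing windows (unpublished; a small gap bridge),
discarding runs under 5 windows (isolated noise at lowered thresholds), and
splitting where the value crosses the homozygous-loss (−1.0) or
amplification (+1.0) boundary for at least one window-width — this is what
isolates a 2 Mb homozygous interval inside a 20 Mb hemizygous deletion as
its own segment. States come from the purity-0.6 mixture expectations:
homozygous_loss ≤ −1.0 < hemizygous_loss ≤ −0.4; gain ≥ 0.32,
amplified ≥ 1.0. All are configurable.

One tension is recorded rather than resolved: at 60% purity a single-copy
loss (−0.515) never exceeds the 0.75 departure rule, yet a 20 Mb hemizygous
deletion is part of the reported landscape. Whether the original analysis
used a purity-adjusted threshold or a different baseline is unknown; here
the flag threshold is a parameter (the nested-deletion analyses run at 0.4)
while the *classification* thresholds recover the zygosity states whenever
the flag rule admits the segment. Whole-chromosome events, which shift a
chromosome's entire window distribution without focal departures, are
reported separately as per-chromosome median differences
(`chromosome_medians()`; a +1 chromosome at 60% purity sits at
log2(1.3) = 0.378).

# Translocations

The genome is walked in non-overlapping windows with step equal to the
insert size. Per window: total aligned reads, discordant reads (mate on a
different contig), the highest-hit partner contig (ties by name order), and
the hit proportion. Aggregated per chromosome, the proportions are treated
as approximately normal and windows above mean + 3 SD are candidates
(zero-variance chromosomes degenerate to the mean). Regions are the spans
of the hit reads and of their mates; mates scattered more than twice the
step apart split into clusters, clusters under `min_pairs = 5` pairs or
spanning over 1 Mb are discarded as scatter (both unpublished guards,
configurable), adjacent candidate windows with the same partner merge, and
the same event seen from both partner chromosomes is collapsed into one
call. Tumor and germline are called separately with identical parameters
and a tumor call is somatic only if no germline call with the same contig
pair overlaps either corresponding region. Output is a paired-line GFF3
whose source column carries a shared event id; a reader reconstructs the
call table for round-trip checking.

Intrachromosomal rearrangement rules (orientation-violating pairs,
|insert| > 3× mean) were described only in supplementary material not
available to this implementation; the interchromosomal walker above is the
documented method, and intrachromosomal detection is out of the tested
surface here.

# Reporting and validation arithmetic

`class_counts()` tallies missense, nonsense (consequence ending in a stop),
coding point mutations (their sum) and frameshift indels from the packaged
annotation table, and the Damaging fraction among missense calls rounded to
a whole percent (19/28 → 68%). `titv()` counts A↔G and C↔T as transitions.
`coverage_summary()` returns fold coverage and read-pair (clonal) coverage
`pairs × insert / genome length`; the published run-statistics table is
internally inconsistent with its own clonal-coverage formula at the unit
digit (the printed example itself evaluates to a different number than the
formula), so the test compares `pairs × 1500 / 3.0 Gb` with the printed
values at ±1 and documents, rather than resolves, the discrepancy.
`ddct_fold_change()` is the standard relative quantification: per-sample
ΔCt against the reference gene (GAPDH in the packaged synthetic plate),
ΔΔCt tumor minus normal, fold `2^(−ΔΔCt)` at efficiency 2. The packaged
qPCR plate is synthetic (labelled so in its filename), constructed from the
mixture arithmetic: a homozygous deletion at purity 0.6 leaves 40% of the
DNA → fold 0.4; hemizygous → 0.7; control loci → 1.

# Problem sizes and determinism

All simulations fix their seed through `sim_config()`; a fixed config is
bit-reproducible (FASTA, reads, truth). The test suite uses read-level
genomes of 10 kb–1.2 Mb (1 Mb with 520 planted SNVs for the
recall/precision suite; twenty 150 kb matched pairs for the null suite;
1.2 Mb across three contigs for the fusion suite) and depth-level genomes
of 1–40 Mb for copy number, sizes chosen so each property has comfortable
statistical margin. The acceptance script simulates ~200,000 germline SNPs
for the Ti/Tv calibration and a 40 Mb chromosome for the nested-deletion
recovery.

# Known limitations

- The KS-genotyper intersection caps full-consensus somatic SNV recall near
  0.5 at 60% purity (derivation above); sensitivity figures refer to the
  proportion-test caller.
- No GC/mappability correction, BAF integration, or purity/ploidy inference
  in the CNV caller; no base-quality recalibration or realignment.
- Translocation calling is interchromosomal; breakpoints are reported at
  region (not base-pair) resolution and without gene annotation.
- The simulator's error model is substitution-only at a single quality
  level; indel sequencing errors and homopolymer artifacts are not modeled,
  which flatters indel precision relative to real data.
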