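---
title: "Methods: paired-guide deletion-screen design and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-guide deletion-screen design and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`pgdecko` implements the computational workflow of a pooled paired-guide
(pgRNA) CRISPR-Cas9 deletion screen read out by FACS sorting and amplicon
sequencing. Two guides delivered on one vector cut at two genomic
positions, deleting the intervening segment — coding exons for
protein-coding genes, the TSS region for lncRNAs. After induction of a
differentiation process, cells that progress normally and cells that lag
behind are sorted at two timepoints (day 3 and day 6), the integrated
guide pairs are amplified and sequenced, and constructs enriched in the
lagging ("delayed") fraction point to genes whose loss delays the process.

The pipeline has five computational stages, mirrored by the numbered
drivers in `analysis/`:

1. **Input simulation** (`sim_config`, `make_toy_annotation`,
   `make_timecourse`, `make_toy_library`, `make_screen_reads`) — every
   input is generated synthetically, so the pipeline runs self-contained
   and every downstream claim can be checked against planted truth.
2. **Target nomination** (`select_targets`) from two-replicate FPKM time
   courses.
3. **Library design** (`build_library`) of ranked guide pairs with
   cloning oligos and controls.
4. **Quantification** (`quantify`) of guide pairs from paired FASTQ.
5. **Candidate calling** (`compute_dde`, `decile_hits`,
   `call_candidates`, `control_concordance`).

## Target nomination

Genes are nominated from FPKM matrices sampled at 12 timepoints
(0–168 h) in two biological replicates. Filters (all exposed in
`selection_params()`):

* protein-coding: mean FPKM ≥ 1 and max/min fold change ≥ 4;
* lncRNA: mean FPKM ≥ 0.1, fold change ≥ 2, ≥ 1 FPKM in at least one
  timepoint, and TSS isolation — no other gene body within 5 kb on the
  same strand or 50 bp on the opposite strand (windows inclusive of both
  ends, coordinates 0-based half-open internally).

Profiles are log10(FPKM + 0.01)-transformed, z-scored per gene, and
clustered per replicate with k-means (squared-Euclidean, 10 restarts,
fixed seed; defaults k = 36 for protein-coding and 16 for lncRNA, the
screen-scale settings). Cluster centroids are labelled with explicit
thresholds replacing visual inspection: *upregulated* when the last
z-value is the maximum and exceeds the first by ≥ 1 z-unit; *peaking*
when the maximum is internal with ≥ 1 z-unit of rise before it and ≥ 1
of fall after it; otherwise *other*. The thresholds (`delta_up`,
`delta_down`) are configurable; 1 z-unit separates genuine shape from the
≈ 0.3 z-units of jitter that the default simulation noise produces.
Genes labelled peaking or upregulated in **both** replicates are the
candidate targets.

Numerical choices where the procedure is silent: the pseudocount 0.01
preserves rank below 0.1 FPKM without producing −∞; a zero profile
minimum is clamped to the pseudocount in fold ratios; zero-variance
profiles are dropped before clustering (their z-score is undefined) with
a warning.

**A deliberate permissiveness worth knowing about:** at the default
simulation noise (σ = 0.1 on log10 FPKM), a noise-only flat profile has
a realized max/min fold of ≈ 2.2×, so the 2× lncRNA fold rule lets a
minority of flat lncRNAs through (flat protein-coding genes are blocked
by the 4× rule). This is a property of the published thresholds, not of
the implementation; the recovery tests therefore assert complete
protein-coding specificity and ≥ 95% sensitivity, and bound — rather
than forbid — flat-lncRNA leakage.

## Library design

For each target, protospacers (20-mers followed by an NGG PAM) are
enumerated on both strands; the cut site is fixed between protospacer
positions 17/18 (3 bp 5′ of the PAM), the universal SpCas9 convention.
Guides are scored, off-target filtered, paired, and ranked by

1. position of the deletion start in the ORF (earlier first; for
   lncRNAs, genomic position),
2. pair score — the sum of the two guide scores,
3. predicted out-of-frame deletions (deletion length not divisible by 3)
   before in-frame ones,

with a deterministic tie-break on guide start coordinates, making the
ranking a total order. "Location in the ORF" is not defined by the
original procedure; earliest-deletion-start was adopted as the natural
reading (it preferentially truncates the protein early).

*Scoring.* On-target activity scoring is a pluggable contract: any
deterministic function of the 30-nt context (4 nt upstream + protospacer
+ PAM + 3 nt downstream) to [0, 1]. The default `surrogate_scorer()` is a
documented position-nucleotide weight sum plus a GC-window penalty,
squashed through a logistic — it encodes the canonical qualitative guide
preferences but is *not* a trained model; externally trained scorers can
be plugged in unchanged.

*Off-targets.* Sites are counted genome-wide (NGG-adjacent 20-mers, both
strands, no NAG) by exact Hamming distance 0–4, excluding the on-target
locus; the default thresholds `(0, 0, 0, ∞, ∞)` allow no additional site
within 2 mismatches. For lncRNA targets the distance-2 allowance grows by
one for each window expansion, mirroring the progressive relaxation of
the published design runs.

*Placement rules.* Coding targets fill from the first coding exon,
extending to exons 2–3 only when fewer than `n` designs fit (guides must
lie within one exon — junction-spanning guides would not match the
genome). lncRNA pairs must straddle the TSS, with a symmetric window
growing through 500–5,000 bp total width; guides overlapping any coding
gene body are discarded. The "minimum distance of 50 bp between any pair
of gRNAs" is enforced under **both** readings — ≥ 50 bp between the two
cuts of a pair *and* ≥ 50 bp between any two cut sites among a target's
accepted designs — each independently switchable.

*Oligos.* Each design emits a 165-nt cloning oligo: 5′ arm +
protospacer-1 + central cloning segment + protospacer-2 + 3′ arm. The arm
and cloning-segment sequences shipped here are synthetic placeholders
(structurally faithful, including unique EcoRI/BamHI sites in the central
segment); only the geometry — 165 nt total, two recoverable 20-nt
protospacers — is contractual. Guide 1 is stored as 21 nt (a leading
transcription-start G plus the protospacer), matching the 21-bp guide-1
segment that quantification expects.

*Controls.* Positive controls are designated genes given extra designs;
negative controls are seeded intergenic regions sampled ≥ 1 kb from any
annotated gene.

## Quantification

Counting uses a 41-bp *artificial reference*: per construct, the 21-nt
guide-1 segment concatenated with the reverse-complemented 20-nt guide-2
protospacer; constructs with identical fused sequences collapse into one
record carrying all source ids (counts are reported at this merged
granularity by default, with a per-source expansion available).

Read pairs are reduced to the same 41-nt fused sequence by anchor
matching: the 21 nt after the first `ACCG` whose match start (1-based)
lies in positions 15–55 of read 2, plus the 20 nt after the first `AAAC`
in positions 100–150 of read 1 (the read-1 segment is sequenced in
reference orientation, so the concatenation is direct). Pairs missing
either anchor are dropped with a per-anchor status; fused sequences
shorter than 20 nt (read-end truncation) are dropped as `too_short`;
shorter-than-41 survivors are compared against reference prefixes.

Assignment is an exact Hamming matcher, not an external aligner: the
references are fixed-length 41-mers and the published settings disallow
indels, so unique-best Hamming assignment is equivalent — an equivalence
enforced in the tests by a brute-force oracle rather than assumed. A read
is assigned to the unique record at minimal distance ≤ `max_mm`,
`multimapped` on ties, `unmapped` beyond the limit. The default
`max_mm = 2` suits the synthetic data (error rate 0.1%/base); 13 is the
documented setting for deeply sequenced real data, where allowed
mismatches are raised until mapping saturates while multi-mapping stays
below 1%. Per-sample accounting (`pairs = fused + no_anchor1 +
no_anchor2 + too_short`; `fused = assigned + unmapped + multimapped`) is
emitted and asserted.

## Candidate calling

Constructs need ≥ 5 counts in the initial (T0) sample of each replicate.
The differentiation-delaying effect is the per-construct ratio

\[ \mathrm{DDE} = \frac{\text{counts in delayed fraction}}
                      {\text{counts in differentiated fraction}} \]

computed independently per replicate at T3 and T6. Division by zero is
handled by a declared policy: the default `raw` reports +∞ (always a
hit, excluded from percentile computation) and treats 0/0 as undefined;
an optional pseudocount policy adds a constant to both counts. The T0 ≥ 5
filter makes zeros rare in practice.

Per (replicate, timepoint) stratum, the threshold is the
linear-interpolation 90th percentile of the finite DDE values (the
standard order-statistic definition; the source procedure names no
percentile convention), and hits are constructs **strictly** above it. A
target is called at a timepoint when at least 2 of its designs are hits
in replicate 1 *and the same identical constructs* are hits in
replicate 2; the final candidate list is the union over T3 and T6 (an
intersection variant is exposed, since the source describes both
semantics in different places). Replicate-mean DDE deciles are reported
alongside for comparability with screen-wide quoted cutoffs. No
multiple-testing correction is applied — the procedure is rank-based by
design, and adding one would silently change it.

QC contrasts control sets: Spearman correlation of DDE between replicates
per control set and timepoint, plus medians. Rank correlation handles
infinite ratios naturally.

## The synthetic-data generator

The generator defines the study conditions under which every quantitative
claim in the tests is made:

* **Expression**: four profile classes (`peaking`, `upregulated`,
  `flat`, `down`), 40 genes per class by default, split evenly between
  biotypes. Templates run 0.5–4 FPKM (8-fold; peak at 36 h for the
  peaking class); replicates are independent Gaussian draws of σ = 0.1
  around the template on log10(FPKM + 0.01) — the same scale the
  clustering z-scores, which is why that noise model was chosen.
* **Counts**: negative-binomial with mean `depth` (100 by default) and
  dispersion 0.2 (variance = μ + 0.2 μ²), the standard over-dispersion
  model for pooled screens. Spiked targets multiply their
  delayed-fraction mean by a configured fold **times a per-construct
  lognormal guide-efficiency factor (log-sd `spike_cv = 0.8`) drawn once
  and shared across replicates**. Real guide efficiencies span orders of
  magnitude, and it is precisely this shared construct-level
  heterogeneity that makes positive-control DDE values correlate between
  replicates while intergenic nulls do not; without it the replicate
  correlation of a uniformly spiked set would be zero by construction.
* **Reads**: read 2 = stagger prefix (0–7 nt) + vector context + `ACCG`
  + guide 1; read 1 = stagger + longer context + `AAAC` +
  reverse-complemented guide 2; 150 bp paired (the screen geometry; the
  125-bp QC geometry is reachable through the config, which is why read
  lengths are exposed rather than fixed). Substitution errors at
  0.1%/base. The vector-context sequences are synthetic placeholders
  chosen free of in-window anchor matches; only the anchors and window
  geometry are contractual.

Not emulated (and therefore not demonstrated by passing tests): quality
scores, indels, PCR duplicates, chimeric amplicons, FACS gating error,
cell-population bottlenecks, and any genomic provenance for
`make_toy_library()` guides. Results on real data additionally depend on
annotation quality (especially lncRNA TSSs) and on the trained on-target
scorer used.

## Problem sizes and determinism

The test suite and the acceptance script run, per invocation: toy genomes
of 3–120 kb; 160-gene time courses; designed libraries of tens of
constructs plus fabricated libraries of up to 12,000; a
2,100-construct screen at depth 100 (≈ 2.3 M read pairs end-to-end
through FASTQ-level simulation, extraction, assignment and calling); and
1,000-instance brute-force oracle comparisons for enumeration,
off-target counting, ranking and assignment. Every random draw flows
from a single integer seed; identical configurations produce
byte-identical outputs, which the tests assert on the FASTA/GTF writers
and the library builder.

## Known limitations

* The surrogate scorer ranks guides plausibly but is not predictive of
  real cutting efficiency; plug in a trained model for real designs.
* Off-target counting is exact Hamming over NGG sites — no bulges, no
  alternative PAMs, no chromatin context — and scans the genome index in
  memory, which is intended for toy-to-bacterial-scale genomes, not
  mammalian ones.
* Frame status uses the genomic distance between cut sites; for pairs
  spanning an intron the spliced frame shift can differ.
* The expression filters inherit the permissiveness of the published 2×
  lncRNA fold rule discussed above.
* With merged duplicate-construct records, per-construct attribution of
  counts is ambiguous by construction; the per-source expansion copies
  the record count to every source rather than dividing it.
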