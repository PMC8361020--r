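---
title: "Preventing heterosplicing of heterologous coding sequences: methods and design"
author: "hskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preventing heterosplicing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hskit)
```

# The problem

When an intronless mammalian cDNA is expressed in a plant host such as the
moss *Physcomitrium patens*, the host spliceosome can mis-read stretches of
the coding sequence as introns. Such "heterosplicing" of cryptic GT-AG
introns yields shortened transcripts, truncated or frameshifted protein
isoforms, mislocalized product and sharply reduced yields. Two sequence
properties of the host drive the effect: the consensus context of its real
splice sites (donor junctions dominated by a `CAG|GT` motif) and the
AT-richness of its introns relative to its coding exons. Both suggest a
computational remedy: raise the GC content of the transgene by synonymous
codon exchange and destroy any strong splice-site motifs, without touching
the protein.

`hskit` implements that remedy end to end: codon-usage analysis and
synonymous optimization, genome-wide splice-site profiling, PWM-based
cryptic intron prediction with in-silico splicing and proteomic
characterization, and the 3-D fluorescence quantification pipeline used to
measure the protein-level consequence. Deterministic generators create toy
genomes, planted-intron CDSs and synthetic image stacks so that every step
is testable without external downloads.

# Codon usage and synonymous optimization

For a two-fold degenerate amino acid the genetic code offers exactly two
codons, differing at the third position. A codon usage table (frequencies
per thousand codons, Kazusa convention) classifies one of them as
under-represented and the other as over-represented. The optimizer derives
one rule per amino acid - replace the under-represented codon by the
over-represented one - for the eight amino acids Cys, Glu, Phe, His, Lys,
Asn, Gln, Tyr by default (Asp, also two-fold degenerate, is accepted on
request). For *P. patens* all eight rules swap a third-position T for C or
A for G, so optimization never lowers GC content, and because no rule's
target is itself a source the map is idempotent.

```{r}
map <- derive_substitution_map(usage_table_fixture("ppatens"))
map
optimize_cds("ATGTGTGAATAA", map)$record$seq
```

Design choices:

* **Ties.** If both codons are equally frequent there is no usage-bias
  rationale for a substitution; the amino acid is dropped with a warning.
* **Validation is advisory.** Length, start, stop and internal-stop checks
  produce warnings, never hard failures; only a length not divisible by
  three aborts optimization, since codon identity is then undefined.
* **Partial tables.** The packaged reference tables carry only the sixteen
  codons they document; frequencies absent from a table rank as zero where
  a ranking is needed and raise an error where a classification is.

Cross-species comparison counts, per species, the amino acids whose
over-represented codon matches a reference species' choice - the moss
pattern agrees with rice, human, CHO and insect-cell usage almost
everywhere but with tobacco at a single amino acid (Lys).

# The splice-site atlas

Donor (exon|intron) and acceptor (intron|exon) junctions of every
transcript are profiled with windows of 9 bases on each side of the
junction point - an 18-base window whose positions 10-11 read the intron's
first two bases (donors) or the exon's first two (acceptors). Windows are
always reported 5'→3' on the transcript strand; minus-strand windows are
reverse-complemented at extraction. GFF3 input is converted from 1-based
inclusive to 0-based half-open coordinates at the parser boundary only.

From the windows the atlas builds position frequency matrices (windows
containing N are excluded but tallied), an information-content logo matrix
(per column, letter height `p * (2 - H)` bits with no small-sample
correction), and anchored junction-motif fractions. The default motif
`CAGGT` at anchor -3 asks for CAG as the last three bases before the
junction and GT as the first two after it.

Two counting interpretations are available because annotated isoforms share
introns: the default counts each intron once per transcript in which it
appears; `dedupe_introns = TRUE` counts each genomic intron once. A
`gtag_only` flag restricts denominators to canonical GT-AG introns. On real
annotation the choice shifts fractions by a few percent; both are exposed
so either convention can be reproduced.

# Cryptic intron prediction

PFMs become log-odds PWMs with a +1 pseudocount per cell against a uniform
0.25 background, scored in bits. A donor candidate is any position with GT
immediately after the putative junction whose 18-base context scores at
least `min_score`; acceptors require AG immediately before it. The default
threshold is the PWM's consensus score minus 6 bits - permissive enough to
keep plausible sites, strict enough that a random GT in a 50% GC sequence
almost never qualifies; it is a tunable parameter, not a calibrated
constant. Candidate donors and acceptors are paired into candidate introns
(acceptor downstream, length at least 50 nt by default - real cryptic
introns observed in expressed transgenes exceed 120 nt, and 50 nt excludes
micro-deletions - with optional length and GC ceilings), ranked by combined
score.

In-silico splicing removes non-overlapping introns and characterizes the
variant: standard-code translation, premature-termination-codon detection
(a stop before the final codon), the average molecular mass of the
stop-truncated product (classical average residue masses plus one water;
average rather than monoisotopic to match gel-level kDa statements, reported
to 0.1 kDa), and the junction position at codon resolution. Tryptic
digestion cleaves C-terminal of K/R except before proline, so a
`...AKP...` junction context survives as a single junction-spanning peptide
- the mass-spectrometric signature of a spliced isoform.

# Splice-site ablation and hardening

Ablation removes a candidate's splicing signals without changing the
protein. For each candidate intron the donor's GT dinucleotide is attacked
first by exhaustive synonymous enumeration of the codons it overlaps; if
the GT is pinned (e.g. spanning a Met codon's G and a Trp codon's T,
neither of which has a synonymous alternative) the exonic AG context is
attacked instead; the acceptor's AG is treated the same way. Among
successful edits the fewest-codon solution wins and ties go to the
replacement with the highest usage frequency. Candidates with no synonymous
escape are reported as unresolvable rather than dropped.

`harden_cds()` chains the full recipe - scan, ablate, optimize, rescan -
and reports residual candidates. On planted-intron fixtures the residual
count is zero and a second pass is the identity.

# The 3-D quantification pipeline

Stacks are non-negative arrays in (Z, Y, X) order (default voxel size
0.300 x 0.080 x 0.080 um). The pipeline runs five stages on a working copy
and then averages the *original* voxel intensities under the final mask, so
filtering never biases the reported means; all stacks in a comparison run
with identical parameters.

1. **Median denoise**, window (3,3,3), reflected boundaries.
2. **Unsharp mask**: `out = in + amount x (in - gaussian(in, sigma))`,
   clipped at zero; sigma and amount default to 1 (the classical
   single-sigma setting; both configurable).
3. **Richardson-Lucy restoration**, 3 iterations with a uniform (3,5,5)
   averaging PSF - used to smooth while preserving thin structures, not as
   true deblurring. With reflected boundaries a constant image is a fixed
   point and outputs stay non-negative.
4. **Skewness-based local equalization**, boxes of (7,7,7) voxels, weights
   clamped to [0.5, 2] and trilinearly interpolated between box centers to
   avoid block artifacts. The weight statistic is the signed cube root of
   the box's third central moment, `a_b = cbrt(m3_b)`: unlike standardized
   skewness, which is invariant under intensity scaling and therefore blind
   to the very gradients this stage must correct, `a_b` scales linearly
   with a multiplicative gradient, so `w_b = clamp(median(a)/a_b)` flattens
   it. Boxes whose standardized skewness is statistically indistinguishable
   from zero (below twice its standard error, `2*sqrt(6/n)`) carry no
   usable signal and stay at weight 1 - this keeps the stage neutral on
   skewness-flat regions instead of amplifying estimation noise into a
   patchwork of extreme weights. If every box has the same skewness the
   stage is the identity.
5. **Adaptive Otsu segmentation**: Otsu thresholds on non-overlapping
   (7,19,19) tiles, trilinearly interpolated to voxels; a voxel is
   foreground only if it also exceeds 0.66 x the whole-stack Otsu threshold
   (the global floor that suppresses over-segmented background).
   Constant tiles have no Otsu threshold and inherit the global one.
   Otsu's method maximizes between-class variance over a 256-bin histogram.

Group comparison uses fixed-effects one-way ANOVA (for two groups, F equals
the square of the pooled t statistic).

# Synthetic data: what it emulates and what it does not

* **Toy genomes** (default 100 genes x 4 introns, exons 60-120 nt, introns
  80-200 nt, exonic GC 50% / intronic GC 30%, reflecting the moss coding
  vs intronic composition): every intron is GT-AG with a `...CAG` acceptor,
  and an exact, chosen fraction of donors carries the `CAG|GTAAGT`
  junction; genes alternate strands so strand handling is always
  exercised. Not emulated: isoform structure, repeats, non-canonical
  introns, N runs.
* **Planted-intron CDSs** (default 900 nt with a 132-nt intron at 39% GC,
  inside the 38-40% range observed for real cryptic introns): a valid ORF
  whose single intron carries consensus cores, with the option of planting
  full 18-base consensus contexts taken from a genome atlas; ground truth
  records the junction offsets. The intron's GC is adjusted to within 2
  points of target without creating in-frame stops.
* **Synthetic stacks** (default 16 x 48 x 48; the test suite uses
  12 x 36 x 36, large enough for two tile layers per axis yet small enough
  to keep the full pipeline fast): a cube (side = half each dimension), a
  diffuse blob field (smoothed-noise threshold, ~10% volume) or a thin
  filament network on a dim background (mean 0.5) with Gaussian noise
  (default SD 0.5, separately settable for foreground) and an optional
  multiplicative X gradient. The cube emulates a compact bright organelle
  region, "diffuse" a mislocalized cytosolic signal, "network" an
  ER-like web.

Passing the synthetic suite shows the pipeline recovers planted intensities
(noise-free recovery within 1%, two-class Dice above 0.9 across seeds, a
planted ~12-fold group difference recovered within [8, 12]) under
*these* noise models. Real confocal stacks add Poisson photon statistics,
optical anisotropy, bleed-through and depth-dependent attenuation that the
generator does not model, so absolute means from real data depend on the
acquisition and the equalization variant in a way the synthetic checks
cannot certify.

# Numerical choices and degenerate inputs

* All sliding filters reflect at boundaries (edge-repeating symmetric
  reflection).
* Sample skewness uses the bias-corrected (type 2) estimator; boxes with
  fewer than 3 voxels or zero variance are neutral.
* Otsu uses 256 equal-width bins; fewer than two distinct values yield an
  empty mask with a warning, as does an all-zero stack (mean reported
  as 0).
* Tile interpolation is trilinear from tile centers, clamped at the
  volume's edge tiles.
* RNA (U) input is normalized to DNA (T) at parsing; all internal logic is
  T-alphabet. Codons containing N are never substituted and windows
  containing N never enter a PFM.
* Generators require an explicit integer seed and restore the caller's RNG
  state, so they are pure functions of their arguments.

# Known limitations

* The scanner scores context strength but not splicing efficiency; no
  branch-point or polypyrimidine-tract model is included, and minor-
  spliceosome (AT-AC) introns are out of scope.
* The optimizer applies exactly the two-codon rule set; 4- and 6-fold
  degenerate families are untouched by design (the rule map is pluggable).
* The equalization weight rule is one member of a family the underlying
  protocol leaves open ("weights based on the skewness value"); absolute
  foreground means on real stacks shift under other members even though
  planted-truth recovery holds for this one.
* Mass computation assumes unmodified standard residues; no glycosylation
  or other post-translational mass shifts.
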