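---
title: "Methods: nucleosome dynamics from multi-condition MNase-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleosome dynamics from multi-condition MNase-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`nucdyn` analyzes nucleosome positioning dynamics in a compact eukaryotic
genome (the motivating system is budding yeast grown on different nitrogen
sources) from aligned MNase-seq fragments: occupancy-track construction,
nucleosome calling, per-gene +1/−1/NFR architecture, TATA-stratified
metagene profiles, differential NFR occupancy between conditions, and
concordance with qRT-PCR expression fold changes. A seeded synthetic
generator with full ground truth makes every stage testable without any
external download. This vignette explains the models, the parameters that
matter, the numerical choices, and what the synthetic results do and do not
show about real data.

# Coordinates

All coordinates are 0-based, half-open (BED convention), in memory and on
disk. A 147 bp nucleosome footprint starting at $s$ occupies $[s, s+147)$
and its dyad is $s + 73$. Track vectors map index $i$ to coordinate $i-1$.
For minus-strand genes every definition is transcription-oriented:
"upstream" means higher genomic coordinate, and metagene windows are
reversed so positive offsets are always transcription-downstream.

# Occupancy tracks

Each fragment contributes unit mass at its midpoint — the midpoint of a
mononucleosomal fragment is the natural dyad estimate. The midpoint pileup
is smoothed with a Gaussian kernel (default sd 20 bp, truncated at 4 sd,
renormalized to unit mass) and the track is divided by its genome-wide mean
so values read as fold-over-genome-average. Design notes:

* The Gaussian dyad-density estimator stands in for wavelet-based occupancy
  mappers. Any smooth, symmetric dyad-density estimate preserves the
  downstream definitions (peak positions, region read counts); the
  bandwidth is exposed as a parameter. With a 20 bp kernel and ≥50
  fragments per nucleosome, peak positions are stable to a few bp.
* Kernel mass falling off a chromosome end is truncated, not reflected.
  The bias is confined to the terminal ~80 bp, and genes are kept ≥1000 bp
  from ends, so no per-gene quantity touches it.
* Normalization `genome_mean_one` is exactly idempotent and makes the
  caller's `min_height` interpretable as a fraction of the genome average.
  `per_million` scaling is available for read-count-style tracks.
* Single-end SAM records are shifted +73 bp along their strand to the
  inferred dyad and represented as a 147 bp core — the standard MNase
  convention; paired records use the mate span.

# Nucleosome calling

Candidate dyads are strict local maxima of the smoothed track (plateaus
contribute their leftmost point, so ties resolve deterministically).
Candidates below `min_height` (default 0.25, a quarter of the genome mean)
are discarded as naked-DNA noise; the rest are accepted greedily in
descending height with an exclusion radius `min_spacing` around each
accepted call.

`min_spacing` defaults to 147 bp — exactly one core footprint. Two calls
closer than this would describe physically overlapping nucleosomes, which
the core particle forbids; and because the package models NFRs as strictly
sub-core gaps (below), a 147 bp radius provably covers the whole NFR
interior from its flanks, so disordered sub-nucleosomal signal inside an
NFR can never spawn a spurious −1 call. A smaller radius (e.g. 120 bp)
admits such calls at realistic NFR signal levels and empties the called
NFR; this failure mode drove the choice.

The occupancy score of a call is the logarithm of the estimated read count
at the peak:

$$\mathrm{score} = \log_{10}\!\left(h \cdot \frac{N}{L} \cdot 147 + 1\right)$$

with $h$ the normalized peak height, $N$ total fragments, $L$ genome
length. Base 10 and the +1 pseudocount are declared conventions (recorded
in output metadata); the score is monotone in peak height, which is all
downstream analyses rely on.

# Per-gene architecture

The +1 nucleosome is the call whose footprint overlaps the TSS (nearest
dyad wins; exact ties go transcription-downstream). If none overlaps, the
nearest call with a dyad within 200 bp transcription-downstream is rescued
— without this window, slightly shifted +1 nucleosomes (common at this
smoothing) orphan genes; the window is a parameter. The −1 is the nearest
call strictly transcription-upstream of the +1. The NFR runs from the 3′
edge of the −1 footprint to the 5′ edge of the +1 footprint
(transcription-oriented, which yields positive widths on both strands — the
genomic-oriented reading would make minus-strand widths negative);
touching or overlapping footprints give width 0 and an empty interval.

Region read counts use fragment midpoints in half-open intervals — the same
statistic as the track, and a fragment spanning a boundary is counted
exactly once. Counts are reported both raw and scaled to reads-per-million.
NFR intervals are fixed from the reference-condition calls so that
per-condition counts are measured on the same genomic interval; the gene
coding region is [TSS, stop codon], transcription-oriented.

# Metagene profiles

Profiles average the normalized track over −1000..+1000 bp (inclusive, 2001
points, offset 0 = the anchor base) around the TSS or the stop codon,
optionally stratified by the TATA flag (1 = TATA-containing, 0 =
TATA-less). Genes whose window overhangs a chromosome end are excluded and
counted. Linear (not log) occupancy is averaged, declared in metadata. The
all-genes profile is exactly the stratum-size-weighted mean of the two TATA
strata; this partition identity is asserted to 1e-9 in the tests.

# Differential NFR occupancy

For each comparison (reference condition vs a second condition), per gene:

* **Ratio** $(\mathrm{ref} + c)/(\mathrm{cmp} + c)$ on normalized NFR
  counts, pseudocount $c = 0.5$ by default (0 gives the pure textbook
  ratio). Ratio > 1 is activation (the NFR loses occupancy in the
  comparison condition, i.e. the promoter opens), < 1 repression.
* **Scaled chi-square**: the 2×2 proportion chi-square without continuity
  correction on `[[k_ref, N_ref − k_ref], [k_cmp, N_cmp − k_cmp]]`, where
  the totals are the per-condition genome-wide fragment counts — library
  size scaling enters through the totals, and the statistic reduces to the
  standard two-proportion test. Raw counts (not RPM) feed the test. A
  zero-margin table is degenerate: chi2 = 0, p = 1, flagged.
* **Benjamini–Hochberg q-values** over all genes tested in the comparison
  (one family per condition pair), via the standard step-up.
* **Significance filter**: |log2 ratio| > 1 (2-fold) and q below a
  threshold. The default threshold 1e-30 is the genome-scale setting used
  with real sequencing depth; at the synthetic study's desk-scale totals
  (~1.6e5 fragments/condition) it is unattainable by construction, so the
  analysis scripts and acceptance checks use q < 0.05 and say so.

Occupancy classes take the top and bottom `ceiling(0.1 n)` genes by NFR
occupancy ("high"/"low"), ties broken by gene id so runs are reproducible.
Correlations are Pearson on complete pairs; group comparisons use the
two-sided Wilcoxon rank-sum test (exact for tie-free groups of ≤12, normal
approximation with tie correction otherwise) with the usual star coding
(0.05/0.01/0.001).

# qRT-PCR concordance

Fold changes use the 2^−ΔΔCt method: replicate Ct values are averaged on
the Ct scale, ΔCt = Ct(gene) − Ct(reference gene, default ACT1) within each
condition, ΔΔCt = ΔCt(condition) − ΔCt(control), fold = 2^−ΔΔCt. Adding a
constant to all Cts of one condition cancels through the reference.
Concordance tabulates, per nucleosome-based call class, the fraction of
genes with fold > 1 (up) vs < 1 (down); folds exactly 1 are reported as
boundary cases, never forced into either side. Gene name matching is
case-insensitive.

# The synthetic generator

Each gene carries, transcription-oriented: an upstream phased array (−3,
−2, −1 at the 165 bp core+linker repeat), an NFR of width sampled from
N(140, 30) truncated to [80, 146] bp, a +1 nucleosome whose dyad sits
+20 bp from the TSS (footprint over the TSS), and a phased array through
the 2 kb gene body. Expected fragment counts per positioned nucleosome
equal `depth` (default 50), times `tata_plus1_boost` (1.5) for the +1 of
TATA-containing genes (fraction 0.2). Fragments are Poisson in number,
jittered around the dyad by `fuzziness_sd_bp` (20), with lengths from
N(150, 10) truncated to [100, 200] bp (mononucleosome gel selection), plus
a 5% uniform naked-DNA background.

Residual NFR signal — the quantity whose condition dependence the
differential analysis detects — is modeled as a positionally **disordered**
fill: expected count `0.5 × depth` per NFR, midpoints dispersed
N(NFR center, 35 bp). The dispersion is intrinsic (naked/fragile DNA is not
a positioned particle) and deliberately separate from `fuzziness_sd_bp`,
which jitters positioned cores only. Two consequences shaped this design:
a *point* fill particle can win the greedy caller over a true −1 when a
Poisson draw runs high, corrupting recovery; and a disordered fill's
smoothed peak (~0.35× of a core peak) cannot. NFR widths are capped below
one core footprint so the generator never implies a missing nucleosome
inside the NFR — a super-core gap plus sub-core signal is a contradiction
the caller would rightly flag.

Condition effects multiply the expected NFR fill count of designated genes
in a designated condition (multiplier 4 models occupancy gain → repression
call; 0.25 models loss → activation). Simulated Ct tables couple expression
to promoter opening: true log2 fold = −log2(multiplier), plus N(0, 0.15)
per-replicate Ct noise.

Choices of study size (200 genes, one ~800 kb chromosome, 50× depth, three
conditions, 20 effect genes per affected condition) keep the full pipeline
under a minute per stage on one CPU while leaving ~25 expected NFR
midpoints per gene — enough for the 2-fold filter to separate 4× effects
from Poisson noise (the fold filter's null exceedance at λ≈25 is ~2–4%).

**What the generator does not emulate:** sequence-dependent nucleosome
affinity, MNase sequence bias, GC bias, replicate-level biological
variance, fuzzy/delocalized nucleosomes beyond Gaussian jitter, and 3′ NFR
structure at stop codons. Passing tests therefore demonstrate the
*pipeline's* correctness and statistical calibration under the stated
generative model — not that real chromatin meets those assumptions.

# Degenerate inputs and numerical conventions

* Empty fragment files load with a warning; an empty fragment set refuses
  to make a track ("no usable fragments"); an all-zero track refuses to
  normalize.
* A featureless (constant) track yields an empty call list, not an error.
* Genes missing a called +1 or −1 are excluded from NFR analyses with a
  logged count.
* NFR width clamps at 0 when footprints touch or overlap.
* All tie-breaks (plateau maxima, equal peak heights, decile boundaries)
  are deterministic, so a fixed seed reproduces byte-identical outputs;
  the pipeline manifest records md5 checksums to verify this.
* Sub-seeds for each randomness consumer are derived from the single run
  seed and kept below 2^31.

# Limitations

The chi-square on genome-wide totals ignores biological overdispersion —
with replicates one would prefer a count model with dispersion (negative
binomial), which is out of scope here. The q < 1e-30 literature setting is
only meaningful at genome-scale totals. The +1 rescue window (200 bp) and
the caller's greedy heuristic are pragmatic conventions, not inferences;
both are parameters. The generator's TATA boost affects only the +1
nucleosome, so TATA-stratified differences downstream of the TSS are
narrower than in real chromatin.
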