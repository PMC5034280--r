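# nucdyn — nucleosome dynamics from multi-condition MNase-seq

`nucdyn` is an R package plus analysis workflow for studying how nucleosome
positioning around genes responds to changing growth conditions — the
motivating system is *Saccharomyces cerevisiae* shifted between preferred
(glutamine) and non-preferred (proline) nitrogen sources, where the
nitrogen catabolite repression (NCR) program remodels promoters. It is
aimed at researchers who have aligned MNase-seq fragments per condition
(BED or SAM) and a gene annotation, and who want per-gene promoter
architecture and differential statistics rather than genome-browser tracks.

## What it computes

1. **Occupancy tracks** — each fragment contributes unit mass at its
   midpoint (the dyad estimate); the pileup is smoothed with a Gaussian
   kernel (sd 20 bp) and normalized to genome mean 1.
2. **Nucleosome calls** — greedy selection of smoothed local maxima with a
   147 bp exclusion radius; each call scored as
   `log10(peak reads + 1)`.
3. **Promoter architecture** — the +1 nucleosome (footprint overlapping the
   TSS), the −1 (nearest call transcription-upstream), and the
   nucleosome-free region (NFR) between the −1 footprint's 3′ edge and the
   +1 footprint's 5′ edge; normalized read counts in the NFR and the gene
   body per condition (`Gln_NFR`, `Pro_NFR`, `Gln-Pro_NFR`, `Gln_gene`, ...).
4. **Metagene profiles** — mean occupancy over −1000..+1000 bp around TSS
   and stop codon, all genes and stratified by TATA class (TATA 1 =
   TATA-containing, TATA 0 = TATA-less).
5. **Differential NFR occupancy** — per gene, the activation(>1)/
   repression(<1) ratio `ref_NFR/cmp_NFR`, a scaled-difference chi-square
   (2×2 proportion test against per-condition library totals),
   Benjamini–Hochberg q-values, and the |log2 ratio| > 1 + q filter;
   decile high/low occupancy classes × TATA; Pearson R² and Wilcoxon
   rank-sum comparisons.
6. **qRT-PCR concordance** — 2^−ΔΔCt fold changes normalized to ACT1,
   tabulated against the nucleosome-based activation/repression calls.
7. **A synthetic MNase-seq generator** with ground truth (phased arrays,
   sub-core NFRs with disordered residual signal, TATA-boosted +1
   occupancy, condition-dependent NFR effects) so the whole pipeline is
   testable end to end.

## Worked example

The numbered scripts under `analysis/` run the full synthetic study
(200 genes, three conditions, 50× depth, seed 20160923; 20 genes gain 4×
NFR occupancy in Pro, 20 lose 4× in Gln-Pro):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_occupancy.R
Rscript analysis/03_call_nucleosomes.R
Rscript analysis/04_metagene.R
Rscript analysis/05_differential.R
Rscript analysis/06_qpcr_concordance.R
```

Representative output (what it means in brackets):

```
Gln       3068 calls; 99.9% of 3000 true dyads recovered within 20 bp
Gene architecture: 200/200 genes with both flanks called;
  called NFR overlaps the true NFR for 100.0% of them.
TSS profile (Gln, all genes): NFR dip at -53 bp, +1 peak at +19 bp.
Downstream-of-TSS occupancy, TATA-containing vs TATA-less: 5.17 vs 3.52
Gln vs Pro       21 significant (|log2| > 1, q < 0.05): 1 activated, 20 repressed
  designed repressed effects recovered: 20/20; false calls: 1
  NFR vs gene-body occupancy in Pro: R^2 = 0.0001 (n = 200)
Gln vs Pro      20 assayed genes with significant calls:
  concordance among repressed calls (fold < 1): 100%
```

[The caller recovers essentially all true dyads; every gene gets a +1/−1
pair whose NFR matches the simulated one; the metagene shows the canonical
promoter shape (occupancy trough just upstream of the TSS, +1 peak just
downstream, higher for TATA-containing genes); all 20 designed 4× NFR
effects pass the 2-fold + q filter with the repression sign and one null
gene slips through; NFR and gene-body occupancy are uncorrelated by
construction; and qRT-PCR fold changes agree with the nucleosome-based
calls.]

Programmatic use mirrors the scripts:

```r
library(nucdyn)
cfg   <- sim_config(n_genes = 200, seed = 1)
sim   <- simulate_mnase(cfg)
track <- normalize_track(compute_occupancy(sim$fragments$Gln, sim$chrom_sizes))
calls <- call_nucleosomes(track)
arch  <- build_gene_architecture(sim$genes, calls, sim$fragments)
res   <- diff_nfr(arch, "Gln", "Pro", q_max = 0.05)
```

Real data enters through `load_fragments()` (BED6 or SAM) and a gene table
with columns `gene_id, chrom, tss, stop_codon, strand, tata`; everything
downstream is identical. `run_pipeline(run_config(...), dir)` runs all
stages into one directory with a checksummed manifest, and
`render_report(dir)` summarizes it.

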