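#!/usr/bin/env Rscript
# Stage 4 — metagene occupancy profiles: -1000..+1000 bp around the TSS and
# the stop codon, per condition, for all genes and split by TATA class.
# Writes the long table and a line-plot PDF.

source("analysis/00_study_design.R")

sim <- readRDS(file.path(RESULTS, "sim.rds"))
tracks <- readRDS(file.path(RESULTS, "tracks.rds"))

profs <- list()
for (cond in sim$config$conditions)
  for (anchor in c("tss", "stop_codon"))
    for (stratum in c("all", "tata1", "tata0"))
      profs[[length(profs) + 1L]] <-
        metagene(tracks[[cond]], sim$genes, anchor, stratum)
tbl <- metagene_table(profs)
data.table::fwrite(tbl, file.path(RESULTS, "metagene.tsv"), sep = "\t")

p_all <- tbl[tbl$anchor == "tss" & tbl$stratum == "all" &
               tbl$condition == "Gln", ]
w <- p_all$offset > -200 & p_all$offset < 0
dip <- p_all$offset[w][which.min(p_all$mean_occupancy[w])]
peak <- p_all$offset[which.max(p_all$mean_occupancy)]
cat(sprintf("TSS profile (Gln, all genes): NFR dip at %+d bp, +1 peak at %+d bp.\n",
            dip, peak))

t1 <- tbl[tbl$anchor == "tss" & tbl$condition == "Gln" &
            tbl$stratum == "tata1" & tbl$offset > 0 & tbl$offset < 200, ]
t0 <- tbl[tbl$anchor == "tss" & tbl$condition == "Gln" &
            tbl$stratum == "tata0" & tbl$offset > 0 & tbl$offset < 200, ]
cat(sprintf("Downstream-of-TSS occupancy, TATA-containing vs TATA-less: %.2f vs %.2f (ratio %.2f)\n",
            max(t1$mean_occupancy), max(t0$mean_occupancy),
            max(t1$mean_occupancy) / max(t0$mean_occupancy)))

pdf(file.path(RESULTS, "metagene.pdf"), width = 8, height = 6)
print(plot_metagene(tbl[tbl$stratum == "all", ]))
print(plot_metagene(tbl[tbl$anchor == "tss", ]))
dev.off()
cat("Wrote metagene.tsv and metagene.pdf under", RESULTS, "\n")
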