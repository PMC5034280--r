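# Shared study design for the analysis scripts. Source()d by 01..06.
#
# The synthetic study mirrors a three-condition nitrogen-source experiment:
# glutamine (Gln, reference), proline (Pro), and a glutamine-to-proline
# shift (Gln-Pro). 200 genes at 50x per-nucleosome fragment depth with
# 20 bp dyad fuzziness; 20 genes gain 4x NFR occupancy in Pro
# (repression-type remodeling) and 20 other genes lose 4x NFR occupancy in
# Gln-Pro (activation-type remodeling, the NCR-like response).

library(nucdyn)

STUDY_SEED <- 20160923L
RESULTS <- "results/study"

study_config <- function(seed = STUDY_SEED) {
  eff <- rbind(
    data.frame(gene_id = sprintf("g%04d", seq(5, 200, by = 10)),
               condition = "Pro", multiplier = 4),
    data.frame(gene_id = sprintf("g%04d", seq(8, 200, by = 10)),
               condition = "Gln-Pro", multiplier = 0.25))
  sim_config(n_genes = 200, depth = 50, fuzziness_sd_bp = 20,
             effect_genes = eff, seed = seed)
}

dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)
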