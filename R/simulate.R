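#' Configuration for the synthetic MNase-seq generator
#'
#' Builds and validates the parameter set for a synthetic multi-condition
#' MNase-seq experiment: a genome tiled with genes, each carrying a phased
#' nucleosome array, a nucleosome-free region (NFR) upstream of the TSS
#' flanked by -1 and +1 nucleosomes (the +1 footprint overlapping the TSS),
#' TATA-dependent +1 occupancy, and condition-dependent NFR occupancy for a
#' designated set of effect genes.
#'
#' @param n_chromosomes number of chromosomes.
#' @param n_genes total number of genes (tiled across chromosomes).
#' @param gene_spacing_bp spacing between successive gene slots (bp).
#' @param gene_length_bp TSS-to-stop-codon length of every gene (bp).
#' @param nucleosome_core_bp nucleosome core footprint (bp); 147 is the
#'   canonical core particle size.
#' @param linker_bp linker DNA between cores; repeat = core + linker.
#' @param nfr_width_mean,nfr_width_sd NFR width distribution (bp).
#' @param nfr_min_width_bp,nfr_max_width_bp truncation bounds for sampled
#'   NFR widths; out-of-range draws are resampled. The upper bound defaults
#'   to one bp under the core footprint so the NFR is strictly
#'   sub-nucleosomal (a wider gap would imply a missing nucleosome).
#' @param plus1_offset_bp signed offset of the +1 dyad from the TSS,
#'   transcription-oriented; must keep the footprint over the TSS.
#' @param fragment_len_mean,fragment_len_sd mononucleosomal fragment length
#'   distribution, truncated to \code{fragment_len_range}.
#' @param fragment_len_range accepted fragment lengths (gel-selection window).
#' @param depth mean fragments per positioned nucleosome per condition.
#' @param nfr_fill_frac expected NFR fill fragments as a fraction of
#'   \code{depth}; models residual sub-nucleosomal protection in the NFR.
#' @param nfr_fill_spread_sd positional dispersion (sd, bp) of NFR fill
#'   midpoints around the NFR center. This is an intrinsic disorder of the
#'   naked-DNA/fragile signal, deliberately separate from
#'   \code{fuzziness_sd_bp}, which jitters positioned cores only.
#' @param tata_fraction proportion of genes carrying a TATA box.
#' @param tata_plus1_boost multiplicative occupancy factor (>= 1) applied to
#'   the +1 nucleosome of TATA-containing genes.
#' @param fuzziness_sd_bp sd of fragment-midpoint jitter around the dyad.
#' @param background_fraction uniform naked-DNA fragments as a fraction of
#'   total expected nucleosomal fragments.
#' @param conditions condition labels; first label is the reference.
#' @param effect_genes data.frame with columns \code{gene_id},
#'   \code{condition}, \code{multiplier} (> 0): per-condition multiplier on
#'   the expected NFR fill count of that gene.
#' @param seed integer seed; mandatory, governs all randomness.
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_chromosomes = 1L,
                       n_genes = 200L,
                       gene_spacing_bp = 4000L,
                       gene_length_bp = 2000L,
                       nucleosome_core_bp = 147L,
                       linker_bp = 18L,
                       nfr_width_mean = 140,
                       nfr_width_sd = 30,
                       nfr_min_width_bp = 80L,
                       nfr_max_width_bp = 146L,
                       plus1_offset_bp = 20L,
                       fragment_len_mean = 150,
                       fragment_len_sd = 10,
                       fragment_len_range = c(100L, 200L),
                       depth = 50,
                       nfr_fill_frac = 0.5,
                       nfr_fill_spread_sd = 35,
                       tata_fraction = 0.2,
                       tata_plus1_boost = 1.5,
                       fuzziness_sd_bp = 20,
                       background_fraction = 0.05,
                       conditions = c("Gln", "Pro", "Gln-Pro"),
                       effect_genes = NULL,
                       seed) {
  if (missing(seed)) stop_config("sim_config: 'seed' is mandatory")
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    n_genes = as.integer(n_genes),
    gene_spacing_bp = as.integer(gene_spacing_bp),
    gene_length_bp = as.integer(gene_length_bp),
    nucleosome_core_bp = as.integer(nucleosome_core_bp),
    linker_bp = as.integer(linker_bp),
    nfr_width_mean = nfr_width_mean,
    nfr_width_sd = nfr_width_sd,
    nfr_min_width_bp = as.integer(nfr_min_width_bp),
    nfr_max_width_bp = as.integer(nfr_max_width_bp),
    plus1_offset_bp = as.integer(plus1_offset_bp),
    fragment_len_mean = fragment_len_mean,
    fragment_len_sd = fragment_len_sd,
    fragment_len_range = as.integer(fragment_len_range),
    depth = depth,
    nfr_fill_frac = nfr_fill_frac,
    nfr_fill_spread_sd = nfr_fill_spread_sd,
    tata_fraction = tata_fraction,
    tata_plus1_boost = tata_plus1_boost,
    fuzziness_sd_bp = fuzziness_sd_bp,
    background_fraction = background_fraction,
    conditions = as.character(conditions),
    effect_genes = effect_genes,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  pos <- c("n_chromosomes", "n_genes", "gene_spacing_bp", "gene_length_bp",
           "nucleosome_core_bp", "linker_bp", "nfr_width_mean",
           "nfr_min_width_bp", "fragment_len_mean", "depth")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      stop_config("sim_config: '%s' must be a single positive number", f)
  }
  for (f in c("nfr_width_sd", "fragment_len_sd", "fuzziness_sd_bp",
              "background_fraction", "nfr_fill_frac",
              "nfr_fill_spread_sd")) {
    if (cfg[[f]] < 0) stop_config("sim_config: '%s' must be >= 0", f)
  }
  if (cfg$nfr_max_width_bp <= cfg$nfr_min_width_bp)
    stop_config("sim_config: 'nfr_max_width_bp' must exceed 'nfr_min_width_bp'")
  if (cfg$nfr_max_width_bp >= cfg$nucleosome_core_bp)
    stop_config("sim_config: 'nfr_max_width_bp' must stay below 'nucleosome_core_bp' (sub-nucleosomal NFR)")
  if (cfg$tata_fraction < 0 || cfg$tata_fraction > 1)
    stop_config("sim_config: 'tata_fraction' must lie in [0, 1]")
  if (cfg$tata_plus1_boost < 1)
    stop_config("sim_config: 'tata_plus1_boost' must be >= 1")
  if (abs(cfg$plus1_offset_bp) > (cfg$nucleosome_core_bp - 1L) %/% 2L)
    stop_config(
      "sim_config: 'plus1_offset_bp' (%d) would move the +1 footprint off the TSS",
      cfg$plus1_offset_bp)
  # gene slots must hold a 1000 bp promoter margin plus the gene
  if (cfg$gene_length_bp + 1000L > cfg$gene_spacing_bp)
    stop_config(
      "sim_config: 'gene_spacing_bp' (%d) too small for gene_length_bp %d + 1000 bp promoter margin (overlapping genes)",
      cfg$gene_spacing_bp, cfg$gene_length_bp)
  if (anyDuplicated(cfg$conditions) || length(cfg$conditions) < 1)
    stop_config("sim_config: 'conditions' must be distinct, nonempty labels")
  if (!is.null(cfg$effect_genes)) {
    eg <- cfg$effect_genes
    need <- c("gene_id", "condition", "multiplier")
    if (!is.data.frame(eg) || !all(need %in% names(eg)))
      stop_config("sim_config: 'effect_genes' needs columns %s",
                  paste(need, collapse = ", "))
    if (any(eg$multiplier <= 0))
      stop_config("sim_config: effect multipliers must be > 0")
    if (!all(eg$condition %in% cfg$conditions))
      stop_config("sim_config: effect condition not among 'conditions'")
  }
  invisible(cfg)
}

#' Designate effect genes with a condition-specific NFR multiplier
#'
#' @param genes gene annotation from \code{\link{simulate_genome}}.
#' @param n number of genes to designate.
#' @param condition condition whose NFR occupancy is scaled.
#' @param multiplier multiplicative factor (> 0) on expected NFR fill counts.
#' @param seed seed for the gene draw.
#' @export
designate_effect_genes <- function(genes, n, condition, multiplier, seed) {
  set.seed(derive_seed(seed, "effect_genes"))
  ids <- sort(sample(genes$gene_id, n))
  data.frame(gene_id = ids, condition = condition, multiplier = multiplier,
             stringsAsFactors = FALSE)
}

#' Simulate a genome and gene annotation
#'
#' Tiles genes along chromosomes at fixed spacing, with randomized strands,
#' seeded TATA flags, and TSS/stop-codon coordinates at least 1000 bp from
#' chromosome ends so that +/-1000 bp metagene windows always fit.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{genome} (a \code{Biostrings::DNAStringSet}) and
#'   \code{genes}, a data.frame with columns gene_id, chrom, tss, stop_codon,
#'   strand, tata (0-based coordinates).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  n_per <- ceiling(config$n_genes / config$n_chromosomes)
  margin <- 1000L
  chrom_len <- 2L * margin + n_per * config$gene_spacing_bp
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))

  set.seed(derive_seed(config$seed, "genome"))
  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
          collapse = "")
  }, character(1)))
  names(genome) <- chroms

  gene_id <- sprintf("g%04d", seq_len(config$n_genes))
  chrom <- chroms[((seq_len(config$n_genes) - 1L) %/% n_per) + 1L]
  slot <- ((seq_len(config$n_genes) - 1L) %% n_per)
  slot_start <- margin + slot * config$gene_spacing_bp
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  tata <- stats::rbinom(config$n_genes, 1L, config$tata_fraction)

  # forward genes transcribe rightward from slot_start + 1000; reverse genes
  # mirror the layout within the slot
  tss <- ifelse(strand == "+", slot_start + 1000L,
                slot_start + 1000L + config$gene_length_bp)
  stop_codon <- ifelse(strand == "+", tss + config$gene_length_bp,
                       slot_start + 1000L)
  if (any(tss < 1000L | tss > chrom_len - 1000L |
          stop_codon < 1000L | stop_codon > chrom_len - 1000L))
    stop_config("simulate_genome: gene windows fall outside the chromosome; increase 'gene_spacing_bp' or 'n_chromosomes'")

  genes <- data.frame(gene_id = gene_id, chrom = chrom,
                      tss = as.integer(tss),
                      stop_codon = as.integer(stop_codon),
                      strand = strand, tata = as.integer(tata),
                      stringsAsFactors = FALSE)
  list(genome = genome, genes = genes,
       chrom_sizes = stats::setNames(rep(chrom_len, length(chroms)), chroms))
}

#' Lay out true nucleosome positions and per-condition expected counts
#'
#' Strand-aware per-gene geometry: an upstream phased array (-3, -2, -1), an
#' NFR of sampled width, a +1 nucleosome whose footprint overlaps the TSS,
#' and a phased array through the gene body at the core + linker repeat. A
#' sub-nucleosomal "fill" particle 35 bp inside the NFR 5' edge carries the
#' residual NFR occupancy; its expected count is scaled by the effect-gene
#' multiplier in the designated condition, and the +1 expected count by
#' \code{tata_plus1_boost} for TATA-containing genes.
#'
#' @param sim output of \code{\link{simulate_genome}}.
#' @param config the same \code{\link{sim_config}}.
#' @return list of class \code{mnase_truth}: \code{nucleosomes} (one row per
#'   particle, with an \code{expected_<condition>} column per condition),
#'   \code{genes} (true NFR interval, flank dyads, per-condition multiplier),
#'   \code{conditions}, \code{chrom_sizes}.
#' @export
place_nucleosomes <- function(sim, config) {
  validate_sim_config(config)
  genes <- sim$genes
  repeat_bp <- config$nucleosome_core_bp + config$linker_bp
  half <- (config$nucleosome_core_bp - 1L) %/% 2L

  set.seed(derive_seed(config$seed, "layout"))
  widths <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    w <- round(stats::rnorm(1, config$nfr_width_mean, config$nfr_width_sd))
    # resample out-of-range draws; never emit nonpositive or super-core NFRs
    while (w < config$nfr_min_width_bp || w > config$nfr_max_width_bp) {
      w <- round(stats::rnorm(1, config$nfr_width_mean, config$nfr_width_sd))
    }
    widths[i] <- as.integer(w)
  }

  rows <- vector("list", nrow(genes))
  gmeta <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    s <- if (g$strand == "+") 1L else -1L
    d1 <- g$tss + s * config$plus1_offset_bp          # +1 dyad
    w <- widths[i]
    # transcription-oriented NFR: from 3' edge of -1 to 5' edge of +1
    if (s == 1L) {
      nfr_start <- d1 - half - w
      nfr_end <- d1 - half
      m1 <- nfr_start - (half + 1L)                   # -1 dyad
    } else {
      nfr_start <- d1 + half + 1L
      nfr_end <- nfr_start + w
      m1 <- nfr_end + half
    }
    fill <- nfr_start + w %/% 2L      # disordered fill centered in the NFR
    up <- m1 - s * repeat_bp * (1:2)                  # -2, -3
    n_body <- max(0L, (config$gene_length_bp - config$plus1_offset_bp - half) %/% repeat_bp)
    body <- if (n_body > 0) d1 + s * repeat_bp * seq_len(n_body) else integer(0)

    dyads <- c(up[2], up[1], m1, d1, body)
    roles <- c("minus3", "minus2", "minus1", "plus1",
               if (n_body > 0) sprintf("array%d", seq_len(n_body)))
    expected <- rep(config$depth, length(dyads))
    expected[roles == "plus1"] <-
      config$depth * (if (g$tata == 1L) config$tata_plus1_boost else 1)

    rows[[i]] <- data.frame(
      chrom = g$chrom,
      dyad = as.integer(c(dyads, fill)),
      gene_id = g$gene_id,
      role = c(roles, "nfr_fill"),
      base_expected = c(expected, config$depth * config$nfr_fill_frac),
      stringsAsFactors = FALSE)
    gmeta[[i]] <- data.frame(
      gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
      tata = g$tata, tss = g$tss, stop_codon = g$stop_codon,
      nfr_start = as.integer(nfr_start), nfr_end = as.integer(nfr_end),
      nfr_width = w, plus1_dyad = as.integer(d1), minus1_dyad = as.integer(m1),
      stringsAsFactors = FALSE)
  }
  nucs <- do.call(rbind, rows)
  tg <- do.call(rbind, gmeta)

  chrom_len <- sim$chrom_sizes[nucs$chrom]
  if (any(nucs$dyad - half < 0L | nucs$dyad + half + 1L > chrom_len))
    stop_config("place_nucleosomes: a footprint falls off its chromosome; increase margins")
  # geometry invariant: +1 footprint must overlap the TSS by construction
  stopifnot(all(abs(tg$plus1_dyad - tg$tss) <= half))

  mult <- matrix(1, nrow(tg), length(config$conditions),
                 dimnames = list(NULL, config$conditions))
  if (!is.null(config$effect_genes)) {
    for (k in seq_len(nrow(config$effect_genes))) {
      e <- config$effect_genes[k, ]
      j <- match(e$gene_id, tg$gene_id)
      if (is.na(j)) stop_config("effect gene '%s' not in annotation", e$gene_id)
      mult[j, e$condition] <- mult[j, e$condition] * e$multiplier
    }
  }
  for (cond in config$conditions) {
    f <- ifelse(nucs$role == "nfr_fill", mult[match(nucs$gene_id, tg$gene_id), cond], 1)
    nucs[[paste0("expected_", cond)]] <- nucs$base_expected * f
    tg[[paste0("mult_", cond)]] <- mult[, cond]
  }

  structure(list(nucleosomes = nucs, genes = tg,
                 conditions = config$conditions,
                 chrom_sizes = sim$chrom_sizes),
            class = "mnase_truth")
}

rnorm_trunc_int <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(integer(0))
  if (sd == 0) return(rep.int(as.integer(round(mean)), n))
  x <- round(stats::rnorm(n, mean, sd))
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- round(stats::rnorm(length(bad), mean, sd))
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  as.integer(x)
}

#' Sample MNase-seq fragments for one condition
#'
#' Per particle, a Poisson count around its expected depth; each fragment is
#' centered on the dyad plus Gaussian jitter, with length drawn from the
#' truncated fragment-length distribution; a uniform background fraction
#' adds naked-DNA noise. Fragments are clipped to chromosome bounds.
#'
#' @param truth a \code{mnase_truth} from \code{\link{place_nucleosomes}}.
#' @param condition one of \code{truth$conditions}.
#' @param config the \code{\link{sim_config}}.
#' @return BED6-shaped data.frame (chrom, start, end, name, score, strand)
#'   with attributes \code{n_particle} and \code{n_background} recording the
#'   draw totals.
#' @export
sample_fragments <- function(truth, condition, config) {
  if (!condition %in% truth$conditions)
    stop_config("sample_fragments: unknown condition '%s'", condition)
  exp_col <- paste0("expected_", condition)
  nucs <- truth$nucleosomes
  set.seed(derive_seed(config$seed, paste0("frags:", condition)))

  counts <- stats::rpois(nrow(nucs), nucs[[exp_col]])
  total_nuc <- sum(counts)
  mids <- rep.int(nucs$dyad, counts)
  chrom <- rep.int(nucs$chrom, counts)
  # positioned cores jitter by fuzziness_sd_bp; the NFR fill is intrinsically
  # disordered and disperses by its own sd regardless of the fuzziness setting
  is_fill <- rep.int(nucs$role == "nfr_fill", counts)
  jitter_sd <- ifelse(is_fill, config$nfr_fill_spread_sd,
                      config$fuzziness_sd_bp)
  if (length(mids) && any(jitter_sd > 0)) {
    mids <- mids + as.integer(round(stats::rnorm(length(mids), 0, jitter_sd)))
  }

  n_bg <- stats::rpois(1, config$background_fraction * sum(nucs[[exp_col]]))
  if (n_bg > 0) {
    sizes <- truth$chrom_sizes
    bg_chrom <- sample(names(sizes), n_bg, replace = TRUE,
                       prob = sizes / sum(sizes))
    bg_mid <- as.integer(floor(stats::runif(n_bg, 0, sizes[bg_chrom])))
    mids <- c(mids, bg_mid)
    chrom <- c(chrom, bg_chrom)
  }
  n <- length(mids)
  if (n == 0L) {
    warning("sample_fragments: zero fragments drawn for condition ", condition)
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0))
    attr(out, "n_particle") <- 0L; attr(out, "n_background") <- 0L
    return(out)
  }
  lens <- rnorm_trunc_int(n, config$fragment_len_mean, config$fragment_len_sd,
                          config$fragment_len_range[1],
                          config$fragment_len_range[2])
  start <- mids - lens %/% 2L
  end <- start + lens
  lim <- truth$chrom_sizes[chrom]
  start <- pmax(start, 0L)
  end <- as.integer(pmin(end, lim))
  keep <- end > start
  out <- data.frame(chrom = chrom[keep], start = as.integer(start[keep]),
                    end = as.integer(end[keep]),
                    name = sprintf("%s_f%07d", cond_slug(condition),
                                   seq_len(sum(keep))),
                    score = 0L,
                    strand = sample(c("+", "-"), sum(keep), replace = TRUE),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_particle") <- total_nuc
  attr(out, "n_background") <- n_bg
  out
}

#' Run the full synthetic experiment
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{mnase_sim}: genome, genes, chrom_sizes, truth,
#'   and \code{fragments}, a named list of BED6 data.frames per condition.
#' @export
simulate_mnase <- function(config) {
  base <- simulate_genome(config)
  truth <- place_nucleosomes(base, config)
  frags <- lapply(config$conditions, function(cond)
    sample_fragments(truth, cond, config))
  names(frags) <- config$conditions
  structure(list(genome = base$genome, genes = base$genes,
                 chrom_sizes = base$chrom_sizes, truth = truth,
                 fragments = frags, config = config),
            class = "mnase_sim")
}

#' Write a synthetic experiment to plain-text files
#'
#' Emits the genome FASTA, a 6-column gene BED, a TATA sidecar TSV
#' (gene_id, tss, stop_codon, strand, tata), one fragment BED6 per condition,
#' and the truth tables as TSV. Output bytes are deterministic for a given
#' config + seed.
#'
#' @param sim an \code{mnase_sim}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, p)
  paths <- c(paths, p)

  g <- sim$genes
  bed <- data.frame(chrom = g$chrom, start = pmin(g$tss, g$stop_codon),
                    end = pmax(g$tss, g$stop_codon) + 1L, name = g$gene_id,
                    score = 0L, strand = g$strand)
  p <- file.path(dir, "genes.bed")
  data.table::fwrite(bed, p, sep = "\t", col.names = FALSE)
  paths <- c(paths, p)

  p <- file.path(dir, "genes_tata.tsv")
  data.table::fwrite(g[, c("gene_id", "tss", "stop_codon", "strand", "tata")],
                     p, sep = "\t")
  paths <- c(paths, p)

  p <- file.path(dir, "chrom.sizes")
  data.table::fwrite(data.frame(chrom = names(sim$chrom_sizes),
                                size = unname(sim$chrom_sizes)),
                     p, sep = "\t", col.names = FALSE)
  paths <- c(paths, p)

  for (cond in names(sim$fragments)) {
    p <- file.path(dir, sprintf("fragments_%s.bed", cond_slug(cond)))
    data.table::fwrite(sim$fragments[[cond]], p, sep = "\t",
                       col.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "truth_nucleosomes.tsv")
  data.table::fwrite(sim$truth$nucleosomes, p, sep = "\t")
  paths <- c(paths, p)
  p <- file.path(dir, "truth_genes.tsv")
  data.table::fwrite(sim$truth$genes, p, sep = "\t")
  paths <- c(paths, p)
  invisible(paths)
}

#' Simulate a qRT-PCR Ct table tied to the simulated NFR effects
#'
#' Expression is coupled to promoter opening: a gene whose NFR fill occupancy
#' is multiplied by m in a condition gets true expression log2 fold
#' -log2(m) versus the control (NFR depletion activates, occlusion
#' represses). Ct values are generated for the target genes and the
#' reference gene in every condition, in replicates, with Gaussian Ct noise.
#'
#' @param truth an \code{mnase_truth}.
#' @param gene_ids genes to assay (default: all genes with a non-unit
#'   multiplier in any condition).
#' @param control control condition (default first condition).
#' @param ref_gene reference gene id used for normalization.
#' @param replicates technical replicates per (gene, condition).
#' @param ct_noise_sd per-replicate Ct noise, in cycles.
#' @param seed seed for the Ct noise.
#' @return long-format data.frame: gene, condition, replicate, ct.
#' @export
simulate_ct_table <- function(truth, gene_ids = NULL,
                              control = truth$conditions[1],
                              ref_gene = "ACT1", replicates = 3,
                              ct_noise_sd = 0.15, seed) {
  tg <- truth$genes
  mcols <- paste0("mult_", truth$conditions)
  if (is.null(gene_ids)) {
    hit <- rowSums(abs(log2(as.matrix(tg[, mcols, drop = FALSE]))) > 0) > 0
    gene_ids <- tg$gene_id[hit]
  }
  if (!length(gene_ids)) stop_config("simulate_ct_table: no genes to assay")
  set.seed(derive_seed(seed, "qpcr"))
  rows <- list()
  base_ct <- 20; ref_ct <- 15
  for (cond in truth$conditions) {
    for (g in c(ref_gene, gene_ids)) {
      if (g == ref_gene) {
        mu <- ref_ct
      } else {
        m <- tg[[paste0("mult_", cond)]][match(g, tg$gene_id)]
        m0 <- tg[[paste0("mult_", control)]][match(g, tg$gene_id)]
        log2fold <- -log2(m / m0)       # vs control; control fold is 1
        mu <- base_ct - log2fold
      }
      ct <- mu + stats::rnorm(replicates, 0, ct_noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, condition = cond, replicate = seq_len(replicates),
        ct = round(ct, 3), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
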