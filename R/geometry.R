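#' Call positioned nucleosomes from an occupancy track
#'
#' Candidate positions are strict local maxima of the smoothed track
#' (plateaus contribute their leftmost point). Candidates with height below
#' \code{min_height} are discarded; the rest are selected greedily in
#' descending height (ties by leftmost coordinate) with an exclusion radius
#' of \code{min_spacing} around every accepted call. The occupancy score of
#' a call is the log10 of the estimated read count at the peak:
#' \code{log10(peak_height * total_fragments / genome_length * 147 + 1)}.
#'
#' @param track a normalized \code{occ_track}.
#' @param min_spacing exclusion radius between accepted dyads, bp. The
#'   default 147 bp (one core footprint) forbids physically overlapping
#'   cores and rejects sub-nucleosomal bumps inside ordinary-width NFRs.
#' @param min_height minimum track height, in genome-mean units.
#' @return data.frame (chrom, dyad, peak_height, occupancy_score) sorted by
#'   chrom then dyad; empty for a featureless track.
#' @export
call_nucleosomes <- function(track, min_spacing = 147L, min_height = 0.25) {
  if (!inherits(track, "occ_track"))
    stop_config("call_nucleosomes: 'track' must be an occ_track")
  if (identical(track$normalization, "none"))
    stop_config("call_nucleosomes: track must be normalized first (see normalize_track)")
  dens <- track$total_fragments / track$genome_length
  out <- lapply(names(track$cov), function(ch) {
    v <- track$cov[[ch]]
    n <- length(v)
    if (n < 3L) return(NULL)
    i <- 2:(n - 1L)
    cand <- i[v[i] > v[i - 1L] & v[i] >= v[i + 1L] & v[i] >= min_height]
    if (!length(cand)) return(NULL)
    h <- v[cand]
    ord <- order(-h, cand)
    accepted <- integer(0)
    for (j in ord) {
      d <- cand[j]
      if (!length(accepted) || all(abs(accepted - d) >= min_spacing))
        accepted <- c(accepted, d)
    }
    accepted <- sort(accepted)
    data.frame(chrom = ch, dyad = accepted - 1L,   # index -> 0-based coord
               peak_height = v[accepted], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(0), dyad = integer(0),
                      peak_height = numeric(0))
  res$occupancy_score <- log10(res$peak_height * dens * CORE_BP + 1)
  rownames(res) <- NULL
  res
}

#' Assign the +1 and -1 nucleosomes of a gene
#'
#' The +1 nucleosome is the call whose 147 bp footprint overlaps the TSS; if
#' several overlap, the one whose dyad is nearest the TSS (ties resolved
#' transcription-downstream). If none overlaps, the nearest call with a dyad
#' within \code{rescue_bp} transcription-downstream of the TSS is used; else
#' the +1 is absent. The -1 nucleosome is the nearest call strictly
#' transcription-upstream of the +1.
#'
#' @param calls data.frame from \code{\link{call_nucleosomes}}.
#' @param gene one-row gene annotation (chrom, tss, strand).
#' @param rescue_bp downstream rescue window when no footprint overlaps.
#' @return list with \code{plus1} and \code{minus1}, each a one-row
#'   data.frame or NULL.
#' @export
assign_flanking_nucleosomes <- function(calls, gene, rescue_bp = 200L) {
  cc <- calls[calls$chrom == gene$chrom, , drop = FALSE]
  s <- if (gene$strand == "+") 1L else -1L
  plus1 <- minus1 <- NULL
  if (nrow(cc)) {
    dist <- cc$dyad - gene$tss
    ov <- which(abs(dist) <= HALF_CORE)
    if (length(ov)) {
      best <- min(abs(dist[ov]))
      cand <- ov[abs(dist[ov]) == best]
      if (length(cand) > 1L)         # tie: transcription-downstream wins
        cand <- cand[s * dist[cand] > 0]
      plus1 <- cc[cand[1], , drop = FALSE]
    } else {
      down <- which(s * dist > HALF_CORE & s * dist <= rescue_bp)
      if (length(down))
        plus1 <- cc[down[which.min(s * dist[down])], , drop = FALSE]
    }
    if (!is.null(plus1)) {
      up <- which(s * (cc$dyad - plus1$dyad) < 0)
      if (length(up)) {
        rel <- s * (cc$dyad[up] - plus1$dyad)
        minus1 <- cc[up[which.max(rel)], , drop = FALSE]
      }
    }
  }
  list(plus1 = plus1, minus1 = minus1)
}

#' Delineate the nucleosome-free region between the -1 and +1 nucleosomes
#'
#' Transcription-oriented: the NFR runs from the 3' edge of the -1 footprint
#' to the 5' edge of the +1 footprint. If the footprints touch or overlap,
#' the width is 0 and the interval is empty, anchored at the midpoint.
#'
#' @param plus1_dyad,minus1_dyad dyad coordinates (0-based).
#' @param strand "+" or "-".
#' @return list(start, end, width) with a 0-based half-open interval.
#' @export
define_nfr <- function(plus1_dyad, minus1_dyad, strand) {
  width <- abs(plus1_dyad - minus1_dyad) - CORE_BP
  if (width <= 0L) {
    mid <- (plus1_dyad + minus1_dyad) %/% 2L
    return(list(start = mid, end = mid, width = 0L))
  }
  if (strand == "+") {
    list(start = minus1_dyad + HALF_CORE + 1L,
         end = plus1_dyad - HALF_CORE, width = as.integer(width))
  } else {
    list(start = plus1_dyad + HALF_CORE + 1L,
         end = minus1_dyad - HALF_CORE, width = as.integer(width))
  }
}

#' Count fragments in a genomic interval, reads-per-million
#'
#' A fragment is counted when its midpoint lies in the half-open interval
#' [start, end); the count is scaled by 1e6 / total_fragments. Midpoint
#' counting matches the track construction and never double-counts
#' fragments spanning region edges.
#'
#' @param frags fragment data.frame.
#' @param chrom,start,end interval (0-based half-open).
#' @param total_fragments library size for normalization.
#' @param raw if TRUE, return the raw midpoint count instead.
#' @export
count_region_reads <- function(frags, chrom, start, end, total_fragments,
                               raw = FALSE) {
  stopifnot(total_fragments > 0)
  if (end <= start) return(0)
  mids <- fragment_midpoints(frags)
  n <- sum(frags$chrom == chrom & mids >= start & mids < end)
  if (raw) n else n * 1e6 / total_fragments
}

# Sorted-midpoint index per chromosome for fast interval counting.
midpoint_index <- function(frags) {
  mids <- fragment_midpoints(frags)
  lapply(split(mids, frags$chrom), sort)
}

count_sorted <- function(idx, chrom, start, end) {
  m <- idx[[chrom]]
  if (is.null(m) || end <= start) return(0L)
  findInterval(end - 0.5, m) - findInterval(start - 0.5, m)
}

#' Per-gene nucleosome architecture across conditions
#'
#' Assigns +1/-1 nucleosomes and the NFR from the reference-condition call
#' set, then counts normalized reads (reads-per-million midpoints) in the
#' fixed NFR interval and the gene coding region for every condition.
#' Column names follow the <condition>_NFR / <condition>_gene convention;
#' *_raw columns carry the unscaled midpoint counts used by the chi-square
#' test. Genes lacking a called flank get NA architecture and are counted
#' in the \code{n_excluded} attribute.
#'
#' @param genes gene annotation data.frame (gene_id, chrom, tss, stop_codon,
#'   strand, tata).
#' @param calls reference-condition nucleosome calls.
#' @param fragments named list (by condition) of fragment data.frames.
#' @param rescue_bp passed to \code{\link{assign_flanking_nucleosomes}}.
#' @return data.frame, one row per gene; attribute \code{n_excluded}.
#' @export
build_gene_architecture <- function(genes, calls, fragments,
                                    rescue_bp = 200L) {
  conds <- names(fragments)
  idx <- lapply(fragments, midpoint_index)
  totals <- vapply(fragments, nrow, integer(1))

  n <- nrow(genes)
  arch <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                     strand = genes$strand, tata = genes$tata,
                     plus1_dyad = NA_integer_, minus1_dyad = NA_integer_,
                     nfr_start = NA_integer_, nfr_end = NA_integer_,
                     nfr_width = NA_integer_, stringsAsFactors = FALSE)
  for (cond in conds) {
    arch[[paste0(cond, "_NFR")]] <- NA_real_
    arch[[paste0(cond, "_gene")]] <- NA_real_
    arch[[paste0(cond, "_NFR_raw")]] <- NA_integer_
    arch[[paste0(cond, "_gene_raw")]] <- NA_integer_
  }
  excluded <- 0L
  for (i in seq_len(n)) {
    g <- genes[i, ]
    fl <- assign_flanking_nucleosomes(calls, g, rescue_bp = rescue_bp)
    if (is.null(fl$plus1) || is.null(fl$minus1)) {
      excluded <- excluded + 1L
      next
    }
    arch$plus1_dyad[i] <- fl$plus1$dyad
    arch$minus1_dyad[i] <- fl$minus1$dyad
    nfr <- define_nfr(fl$plus1$dyad, fl$minus1$dyad, g$strand)
    arch$nfr_start[i] <- nfr$start
    arch$nfr_end[i] <- nfr$end
    arch$nfr_width[i] <- nfr$width
    gs <- min(g$tss, g$stop_codon); ge <- max(g$tss, g$stop_codon) + 1L
    for (cond in conds) {
      nfr_n <- count_sorted(idx[[cond]], g$chrom, nfr$start, nfr$end)
      gene_n <- count_sorted(idx[[cond]], g$chrom, gs, ge)
      arch[[paste0(cond, "_NFR_raw")]][i] <- nfr_n
      arch[[paste0(cond, "_gene_raw")]][i] <- gene_n
      arch[[paste0(cond, "_NFR")]][i] <- nfr_n * 1e6 / totals[[cond]]
      arch[[paste0(cond, "_gene")]][i] <- gene_n * 1e6 / totals[[cond]]
    }
  }
  if (excluded > 0)
    message(sprintf("build_gene_architecture: %d gene(s) excluded (missing +1 or -1 call)",
                    excluded))
  attr(arch, "n_excluded") <- excluded
  attr(arch, "totals") <- totals
  arch
}

#' Score recovery of true dyads by a call set
#'
#' A true positioned nucleosome (roles other than the sub-nucleosomal NFR
#' fill) counts as recovered when a call on the same chromosome lies within
#' \code{tol} bp of its dyad.
#'
#' @param truth an \code{mnase_truth}.
#' @param calls data.frame from \code{\link{call_nucleosomes}}.
#' @param tol matching tolerance, bp.
#' @return list(rate, n_truth, n_recovered, matched).
#' @export
evaluate_dyad_recovery <- function(truth, calls, tol = 20) {
  nucs <- truth$nucleosomes
  nucs <- nucs[nucs$role != "nfr_fill", , drop = FALSE]
  by_chrom <- split(calls$dyad, calls$chrom)
  by_chrom <- lapply(by_chrom, sort)
  matched <- vapply(seq_len(nrow(nucs)), function(i) {
    d <- nucs$dyad[i]
    cd <- by_chrom[[nucs$chrom[i]]]
    if (is.null(cd) || !length(cd)) return(FALSE)
    j <- findInterval(d, cd)
    near <- cd[pmax(1L, pmin(length(cd), c(j, j + 1L)))]
    any(abs(near - d) <= tol)
  }, logical(1))
  list(rate = mean(matched), n_truth = nrow(nucs),
       n_recovered = sum(matched), matched = matched)
}

#' Fraction of genes whose called NFR overlaps the true NFR
#'
#' @param truth an \code{mnase_truth}.
#' @param arch architecture table from \code{\link{build_gene_architecture}}.
#' @return list(rate, n_called) over genes with both flanks called.
#' @export
evaluate_nfr_overlap <- function(truth, arch) {
  tg <- truth$genes
  m <- merge(arch[!is.na(arch$nfr_start),
                  c("gene_id", "nfr_start", "nfr_end")],
             tg[, c("gene_id", "nfr_start", "nfr_end")],
             by = "gene_id", suffixes = c("_called", "_true"))
  ov <- pmax(m$nfr_start_called, m$nfr_start_true) <
    pmin(m$nfr_end_called, m$nfr_end_true)
  list(rate = mean(ov), n_called = nrow(m))
}
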