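#' Load aligned MNase-seq fragments from BED6 or SAM
#'
#' BED records are used as-is (0-based half-open). SAM input is converted
#' via Rsamtools; properly paired records yield the sequenced fragment from
#' the leftmost mate and TLEN, while single-end records are shifted +73 bp
#' along their strand to the inferred dyad and represented as a 147 bp
#' pseudo-fragment (the standard MNase convention for end-sequenced cores).
#' Records whose length falls outside \code{length_window} are dropped and
#' counted.
#'
#' @param path BED6 (plain text) or SAM/BAM file.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param length_window accepted fragment lengths, inclusive.
#' @param condition label stored on the returned set.
#' @return data.frame (chrom, start, end, name, score, strand) with
#'   attributes \code{condition}, \code{n_dropped_length}.
#' @export
load_fragments <- function(path, chrom_sizes,
                           length_window = c(100L, 200L),
                           condition = NA_character_) {
  if (!file.exists(path)) stop_config("load_fragments: no such file: %s", path)
  is_sam <- grepl("\\.(sam|bam)$", path, ignore.case = TRUE)
  frags <- if (is_sam) read_sam_fragments(path) else read_bed_fragments(path)

  if (nrow(frags) == 0L) {
    warning("load_fragments: '", path, "' contains no fragments")
    attr(frags, "condition") <- condition
    attr(frags, "n_dropped_length") <- 0L
    return(frags)
  }
  unknown <- setdiff(unique(frags$chrom), names(chrom_sizes))
  if (length(unknown))
    stop_config("load_fragments: unknown chromosome '%s' in %s",
                unknown[1], path)
  bad <- which(frags$start < 0L | frags$end > chrom_sizes[frags$chrom] |
                 frags$start >= frags$end)
  if (length(bad))
    stop_config("load_fragments: record %d has coordinates outside [0, chrom length)",
                bad[1])
  len <- frags$end - frags$start
  keep <- len >= length_window[1] & len <= length_window[2]
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("load_fragments: dropped %d fragment(s) outside length window [%d, %d]",
                    dropped, length_window[1], length_window[2]))
  frags <- frags[keep, , drop = FALSE]
  rownames(frags) <- NULL
  attr(frags, "condition") <- condition
  attr(frags, "n_dropped_length") <- dropped
  frags
}

read_bed_fragments <- function(path) {
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      colClasses = list(character = 1)),
    error = function(e) stop_config("load_fragments: cannot parse '%s': %s",
                                    path, conditionMessage(e)))
  if (nrow(dt) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0)))
  if (ncol(dt) < 3L)
    stop_config("load_fragments: '%s' has fewer than 3 BED columns", path)
  start <- suppressWarnings(as.integer(dt[[2]]))
  end <- suppressWarnings(as.integer(dt[[3]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop_config("load_fragments: malformed BED line %d in '%s'", bad[1], path)
  data.frame(
    chrom = as.character(dt[[1]]), start = start, end = end,
    name = if (ncol(dt) >= 4L) as.character(dt[[4]]) else
      sprintf("f%d", seq_len(nrow(dt))),
    score = if (ncol(dt) >= 5L) suppressWarnings(as.integer(dt[[5]])) else 0L,
    strand = if (ncol(dt) >= 6L) as.character(dt[[6]]) else "+",
    stringsAsFactors = FALSE)
}

read_sam_fragments <- function(path) {
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "qwidth", "strand", "isize", "flag"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(x$pos)
  qname <- x$qname[keep]; rname <- as.character(x$rname)[keep]
  pos0 <- x$pos[keep] - 1L            # SAM is 1-based; convert to 0-based
  qw <- x$qwidth[keep]; strand <- as.character(x$strand)[keep]
  isize <- x$isize[keep]; flag <- x$flag[keep]
  paired <- bitwAnd(flag, 1L) > 0L
  out <- list()
  # paired: take the leftmost mate (positive TLEN) as the fragment
  sel <- paired & !is.na(isize) & isize > 0L
  if (any(sel))
    out$paired <- data.frame(chrom = rname[sel], start = pos0[sel],
                             end = pos0[sel] + isize[sel],
                             name = qname[sel], score = 0L,
                             strand = strand[sel], stringsAsFactors = FALSE)
  # single-end: shift +73 along the strand to the dyad, emit a 147 bp core
  sel <- !paired
  if (any(sel)) {
    five <- ifelse(strand[sel] == "-", pos0[sel] + qw[sel] - 1L, pos0[sel])
    dyad <- ifelse(strand[sel] == "-", five - HALF_CORE, five + HALF_CORE)
    out$single <- data.frame(chrom = rname[sel], start = dyad - HALF_CORE,
                             end = dyad + HALF_CORE + 1L,
                             name = qname[sel], score = 0L,
                             strand = strand[sel], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

fragment_midpoints <- function(frags) {
  (frags$start + frags$end) %/% 2L
}

#' Compute a per-bp nucleosome occupancy track
#'
#' Each fragment contributes unit mass at its midpoint (the dyad estimate);
#' the midpoint pileup is smoothed with a Gaussian kernel (sd =
#' \code{bandwidth}, truncated at 4 sd). Kernel mass falling off a
#' chromosome end is truncated, so total track mass equals the fragment
#' count up to edge losses.
#'
#' @param frags fragment data.frame from \code{\link{load_fragments}} or
#'   \code{\link{sample_fragments}}.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param bandwidth Gaussian kernel sd in bp.
#' @param condition label stored in metadata (defaults to the fragment
#'   set's own label).
#' @return an \code{occ_track}: list with \code{cov} (named list of numeric
#'   vectors, index i = coordinate i-1), \code{chrom_sizes},
#'   \code{condition}, \code{bandwidth}, \code{normalization},
#'   \code{total_fragments}, \code{genome_length}.
#' @export
compute_occupancy <- function(frags, chrom_sizes, bandwidth = 20,
                              condition = attr(frags, "condition")) {
  if (is.null(frags) || nrow(frags) == 0L)
    stop_config("compute_occupancy: no usable fragments")
  stopifnot(bandwidth > 0)
  half_w <- as.integer(ceiling(4 * bandwidth))
  kern <- stats::dnorm(seq(-half_w, half_w), sd = bandwidth)
  kern <- kern / sum(kern)            # unit mass per fragment
  mids <- fragment_midpoints(frags)
  cov <- lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    m <- mids[frags$chrom == ch]
    counts <- tabulate(m + 1L, nbins = L)
    smooth_truncated(counts, kern, half_w)
  })
  names(cov) <- names(chrom_sizes)
  structure(list(cov = cov, chrom_sizes = chrom_sizes,
                 condition = condition %||% NA_character_,
                 bandwidth = bandwidth, normalization = "none",
                 total_fragments = nrow(frags),
                 genome_length = sum(as.numeric(chrom_sizes))),
            class = "occ_track")
}

# Convolve with a symmetric kernel; off-end mass is truncated (lost), not
# reflected.
smooth_truncated <- function(x, kern, half_w) {
  if (all(x == 0)) return(as.numeric(x))
  padded <- c(numeric(half_w), as.numeric(x), numeric(half_w))
  y <- stats::filter(padded, kern, method = "convolution", sides = 2)
  as.numeric(y[(half_w + 1L):(half_w + length(x))])
}

#' Normalize an occupancy track
#'
#' \code{genome_mean_one} divides by the genome-wide mean so values read as
#' fold-over-genome-average; \code{per_million} scales by 1e6 / total
#' fragments. Both are idempotent in the sense that renormalizing an already
#' normalized track with the same mode returns it unchanged.
#'
#' @param track an \code{occ_track}.
#' @param mode normalization mode.
#' @return the normalized \code{occ_track}.
#' @export
normalize_track <- function(track, mode = c("genome_mean_one", "per_million")) {
  mode <- match.arg(mode)
  tot <- sum(vapply(track$cov, sum, numeric(1)))
  if (tot <= 0) stop_config("normalize_track: all-zero track")
  scale <- if (mode == "genome_mean_one") {
    track$genome_length / tot
  } else {
    if (track$normalization == "per_million") 1 else 1e6 / track$total_fragments
  }
  track$cov <- lapply(track$cov, function(v) v * scale)
  track$normalization <- mode
  track
}

#' @export
print.occ_track <- function(x, ...) {
  cat(sprintf("occupancy track [%s]: %d chromosome(s), %.0f bp, %d fragments, bandwidth %g bp, normalization: %s\n",
              x$condition, length(x$cov), x$genome_length,
              x$total_fragments, x$bandwidth, x$normalization))
  invisible(x)
}

#' Write an occupancy track as bedGraph (plus a metadata JSON sidecar)
#'
#' @param track an \code{occ_track}.
#' @param path output bedGraph path; \code{<path>.json} holds metadata.
#' @param digits value rounding for compact output.
#' @export
write_bedgraph <- function(track, path, digits = 4) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$cov)) {
    v <- round(track$cov[[ch]], digits)
    r <- rle(v)
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", ch, start[keep], end[keep],
                         r$values[keep]), con)
  }
  jsonlite::write_json(
    list(condition = track$condition, bandwidth = track$bandwidth,
         normalization = track$normalization,
         total_fragments = track$total_fragments,
         genome_length = track$genome_length),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
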