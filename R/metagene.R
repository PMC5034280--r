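#' Average occupancy profile around an anchor, across genes
#'
#' Extracts the -flank..+flank bp window (inclusive at both ends, 2*flank+1
#' points) of the occupancy track around each gene's anchor, reversed for
#' minus-strand genes so positive offsets are transcription-downstream, and
#' averages per offset. Genes whose window overhangs a chromosome end are
#' excluded (counted in \code{n_excluded}).
#'
#' @param track a normalized \code{occ_track}.
#' @param genes gene annotation (gene_id, chrom, tss, stop_codon, strand,
#'   tata).
#' @param anchor "tss" or "stop_codon".
#' @param stratum "all", "tata1" (TATA-containing) or "tata0" (TATA-less).
#' @param flank half-window size in bp.
#' @return data.frame of class \code{metagene_profile}: offset,
#'   mean_occupancy; attributes anchor, stratum, condition, n_genes,
#'   n_excluded.
#' @export
metagene <- function(track, genes, anchor = c("tss", "stop_codon"),
                     stratum = c("all", "tata1", "tata0"), flank = 1000L) {
  anchor <- match.arg(anchor)
  stratum <- match.arg(stratum)
  g <- switch(stratum,
              all = genes,
              tata1 = genes[genes$tata == 1L, , drop = FALSE],
              tata0 = genes[genes$tata == 0L, , drop = FALSE])
  if (!nrow(g)) stop_config("metagene: stratum '%s' is empty", stratum)
  anchors <- if (anchor == "tss") g$tss else g$stop_codon

  npt <- 2L * flank + 1L
  acc <- numeric(npt)
  used <- 0L
  excluded <- 0L
  for (i in seq_len(nrow(g))) {
    a <- anchors[i]
    L <- track$chrom_sizes[[g$chrom[i]]]
    if (is.null(L) || a - flank < 0L || a + flank > L - 1L) {
      excluded <- excluded + 1L
      next
    }
    w <- track$cov[[g$chrom[i]]][(a - flank + 1L):(a + flank + 1L)]
    if (g$strand[i] == "-") w <- rev(w)
    acc <- acc + w
    used <- used + 1L
  }
  if (used == 0L) stop_config("metagene: no gene window fits on its chromosome")
  if (excluded > 0)
    message(sprintf("metagene: excluded %d gene(s) with windows off the chromosome",
                    excluded))
  out <- data.frame(offset = seq.int(-flank, flank),
                    mean_occupancy = acc / used)
  attr(out, "anchor") <- anchor
  attr(out, "stratum") <- stratum
  attr(out, "condition") <- track$condition
  attr(out, "n_genes") <- used
  attr(out, "n_excluded") <- excluded
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Combine metagene profiles into one long table
#'
#' @param profiles list of \code{metagene_profile} objects.
#' @return data.frame: anchor, stratum, condition, offset, mean_occupancy,
#'   n_genes.
#' @export
metagene_table <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(anchor = attr(p, "anchor"), stratum = attr(p, "stratum"),
               condition = attr(p, "condition"), offset = p$offset,
               mean_occupancy = p$mean_occupancy,
               n_genes = attr(p, "n_genes"), stringsAsFactors = FALSE)
  }))
}

#' Line plot of metagene profiles, one panel per anchor
#'
#' @param tbl output of \code{\link{metagene_table}}.
#' @return a ggplot object.
#' @export
plot_metagene <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(x = offset, y = mean_occupancy,
                                    colour = condition,
                                    linetype = stratum)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~anchor, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "offset from anchor (bp, transcription-oriented)",
                  y = "mean occupancy (fold over genome mean)") +
    ggplot2::theme_minimal()
}
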