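#' Activation/repression ratio of NFR occupancy between conditions
#'
#' ratio = (ref + pseudocount) / (cmp + pseudocount); a ratio above 1 marks
#' activation (NFR more occupied in the reference, i.e. opening under the
#' comparison condition), below 1 repression. The default pseudocount 0.5
#' guards sparse NFRs; pseudocount 0 gives the pure textbook ratio.
#'
#' @param ref_count,cmp_count nonnegative normalized NFR read counts.
#' @param pseudocount added to both counts.
#' @return list(ratio, log2_ratio, direction) with direction in
#'   {"activated", "repressed", "none"}.
#' @export
nfr_ratio <- function(ref_count, cmp_count, pseudocount = 0.5) {
  if (any(ref_count < 0) || any(cmp_count < 0))
    stop_config("nfr_ratio: counts must be >= 0")
  ratio <- (ref_count + pseudocount) / (cmp_count + pseudocount)
  direction <- ifelse(ratio > 1, "activated",
                      ifelse(ratio < 1, "repressed", "none"))
  list(ratio = ratio, log2_ratio = log2(ratio), direction = direction)
}

#' Scaled-difference chi-square for two counts with library totals
#'
#' The 2x2 proportion chi-square (no continuity correction) on
#' [[ref_count, ref_total - ref_count], [cmp_count, cmp_total - cmp_count]]:
#' library-size scaling enters through the per-condition totals. p-values
#' come from the chi-square distribution with 1 df. A table with both
#' counts 0 is degenerate: chi2 = 0, p = 1.
#'
#' @param ref_count,cmp_count region read counts.
#' @param ref_total,cmp_total per-condition library totals.
#' @return list(chi2_stat, p_value, degenerate).
#' @export
scaled_chisq <- function(ref_count, ref_total, cmp_count, cmp_total) {
  if (any(ref_total <= 0) || any(cmp_total <= 0))
    stop_config("scaled_chisq: totals must be > 0")
  if (any(ref_count > ref_total) || any(cmp_count > cmp_total))
    stop_config("scaled_chisq: counts cannot exceed totals")
  a <- as.numeric(ref_count); b <- as.numeric(ref_total) - a
  c_ <- as.numeric(cmp_count); d <- as.numeric(cmp_total) - c_
  n <- a + b + c_ + d
  degenerate <- (a + c_) == 0 | (b + d) == 0
  chi2 <- ifelse(degenerate, 0,
                 n * (a * d - b * c_)^2 /
                   ((a + b) * (c_ + d) * (a + c_) * (b + d)))
  p <- ifelse(degenerate, 1, stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  list(chi2_stat = chi2, p_value = p, degenerate = degenerate)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up FDR adjustment: sorted ascending,
#' q_(i) = min_{j >= i}(p_(j) * m / j), capped at 1, mapped back to the
#' input order (delegates to \code{stats::p.adjust}).
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop_config("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-gene differential NFR occupancy between two conditions
#'
#' For every gene with a defined NFR: the activation/repression ratio on
#' normalized counts, the scaled chi-square on raw counts against the
#' per-condition genome-wide totals, BH q-values over all tested genes (one
#' family per comparison), and the significance call.
#'
#' @param arch architecture table from \code{\link{build_gene_architecture}}.
#' @param ref,cmp condition labels (reference first, e.g. "Gln" vs "Pro").
#' @param pseudocount passed to \code{\link{nfr_ratio}}.
#' @param fold_log2,q_max significance filter (see
#'   \code{\link{significant_calls}}).
#' @return data.frame: gene_id, ref, cmp, ratio, log2_ratio, chi2, p, q,
#'   call.
#' @export
diff_nfr <- function(arch, ref, cmp, pseudocount = 0.5,
                     fold_log2 = 1.0, q_max = 1e-30) {
  totals <- attr(arch, "totals")
  need <- c(paste0(ref, "_NFR"), paste0(cmp, "_NFR"),
            paste0(ref, "_NFR_raw"), paste0(cmp, "_NFR_raw"))
  if (!all(need %in% names(arch)))
    stop_config("diff_nfr: architecture table lacks columns for '%s' vs '%s'",
                ref, cmp)
  ok <- !is.na(arch[[need[1]]]) & !is.na(arch[[need[2]]])
  a <- arch[ok, , drop = FALSE]
  rr <- nfr_ratio(a[[need[1]]], a[[need[2]]], pseudocount)
  cs <- scaled_chisq(a[[need[3]]], totals[[ref]], a[[need[4]]], totals[[cmp]])
  q <- bh_adjust(cs$p_value)
  res <- data.frame(gene_id = a$gene_id,
                    ref = a[[need[1]]], cmp = a[[need[2]]],
                    ratio = rr$ratio, log2_ratio = rr$log2_ratio,
                    chi2 = cs$chi2_stat, p = cs$p_value, q = q,
                    stringsAsFactors = FALSE)
  sig <- abs(res$log2_ratio) > fold_log2 & res$q < q_max
  res$call <- ifelse(sig, rr$direction, "NS")
  attr(res, "comparison") <- c(ref = ref, cmp = cmp)
  attr(res, "fold_log2") <- fold_log2
  attr(res, "q_max") <- q_max
  res
}

#' Filter differential results to significant activation/repression calls
#'
#' Keeps genes with |log2 ratio| > fold_log2 and q < q_max; the call sign
#' follows the ratio direction.
#'
#' @param results data.frame from \code{\link{diff_nfr}} (columns
#'   log2_ratio, q).
#' @param fold_log2 minimum |log2 ratio| (default 1, i.e. 2-fold).
#' @param q_max q-value ceiling (default 1e-30, the genome-scale setting;
#'   desk-scale analyses typically relax this).
#' @export
significant_calls <- function(results, fold_log2 = 1.0, q_max = 1e-30) {
  keep <- abs(results$log2_ratio) > fold_log2 & results$q < q_max
  out <- results[keep, , drop = FALSE]
  out$call <- ifelse(out$log2_ratio > 0, "activated", "repressed")
  rownames(out) <- NULL
  out
}

#' Decile occupancy classes over per-gene NFR occupancy
#'
#' The top ceiling(fraction * n) genes by value form the "high" class, the
#' bottom ones "low", the rest "mid". Ties are broken deterministically by
#' gene id (lexicographic), with a warning when ties actually straddle a
#' class boundary.
#'
#' @param values per-gene NFR occupancy values.
#' @param gene_ids matching gene ids.
#' @param fraction class size as a fraction of n (default 0.1).
#' @return data.frame (gene_id, value, class).
#' @export
decile_classes <- function(values, gene_ids, fraction = 0.1) {
  n <- length(values)
  stopifnot(length(gene_ids) == n)
  if (n < 10L) stop_config("decile_classes: need at least 10 genes, got %d", n)
  k <- ceiling(fraction * n)
  ord <- order(values, gene_ids)      # ascending; gene id breaks ties
  cls <- rep("mid", n)
  cls[ord[seq_len(k)]] <- "low"
  cls[ord[seq.int(n - k + 1L, n)]] <- "high"
  lo_cut <- values[ord[k]]; hi_cut <- values[ord[n - k + 1L]]
  if (sum(values == lo_cut) > 1L || sum(values == hi_cut) > 1L)
    warning("decile_classes: ties at a class boundary broken by gene id order")
  data.frame(gene_id = gene_ids, value = values, class = cls,
             stringsAsFactors = FALSE)
}

#' Pearson correlation of two per-gene quantities
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped.
#' @return list(pearson_r, r_squared, n, n_dropped); r is NA (flagged) when
#'   either side has zero variance.
#' @export
correlation_report <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_config("correlation_report: need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(pearson_r = NA_real_, r_squared = NA_real_, n = n,
                n_dropped = sum(!ok), zero_variance = TRUE))
  r <- stats::cor(x, y)
  list(pearson_r = r, r_squared = r^2, n = n, n_dropped = sum(!ok),
       zero_variance = FALSE)
}

#' Two-sided Wilcoxon rank-sum comparison with star coding
#'
#' Exact null enumeration when both groups have n <= 12 and there are no
#' ties; otherwise the normal approximation with tie correction. Stars:
#' p < 0.05 (*), < 0.01 (**), < 0.001 (***).
#'
#' @param group_a,group_b numeric vectors.
#' @return list(p_value, W, stars, method).
#' @export
wilcoxon_compare <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop_config("wilcoxon_compare: both groups must be nonempty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- length(group_a) <= 12 && length(group_b) <= 12 && !ties
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            alternative = "two.sided",
                                            exact = exact, correct = FALSE))
  p <- wt$p.value
  if (is.na(p)) p <- 1      # degenerate ranks (all values tied): no evidence
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else ""
  list(p_value = p, W = unname(wt$statistic), stars = stars,
       method = if (exact) "exact" else "normal approximation")
}

#' Cross-tabulate occupancy classes against the TATA flag
#'
#' @param classes data.frame from \code{\link{decile_classes}}.
#' @param genes gene annotation with gene_id and tata.
#' @return a class x TATA contingency table.
#' @export
class_tata_table <- function(classes, genes) {
  m <- merge(classes, genes[, c("gene_id", "tata")], by = "gene_id")
  table(class = m$class, tata = m$tata)
}
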