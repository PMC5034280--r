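#' Read a qRT-PCR Ct table
#'
#' Accepts either long format (gene, condition, replicate, ct) or wide
#' format (gene, condition, ct_rep1..ct_repN) and returns the long form.
#' Gene names are matched case-insensitively downstream; original spellings
#' are preserved here.
#'
#' @param path TSV file.
#' @return data.frame: gene, condition, replicate, ct.
#' @export
read_ct_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  names(dt) <- tolower(names(dt))
  if (all(c("gene", "condition", "ct") %in% names(dt))) {
    out <- dt[, c("gene", "condition",
                  intersect("replicate", names(dt)), "ct")]
    if (!"replicate" %in% names(out))
      out$replicate <- stats::ave(seq_len(nrow(out)),
                                  out$gene, out$condition, FUN = seq_along)
  } else {
    reps <- grep("^ct_rep", names(dt), value = TRUE)
    if (!length(reps) || !all(c("gene", "condition") %in% names(dt)))
      stop_config("read_ct_table: need columns gene, condition and ct (long) or ct_rep* (wide)")
    out <- do.call(rbind, lapply(seq_along(reps), function(k) {
      data.frame(gene = dt$gene, condition = dt$condition, replicate = k,
                 ct = dt[[reps[k]]], stringsAsFactors = FALSE)
    }))
    out <- out[!is.na(out$ct), ]
  }
  bad <- which(out$ct <= 0 | out$ct >= 45)
  if (length(bad))
    stop_config("read_ct_table: Ct value out of (0, 45) at row %d", bad[1])
  rownames(out) <- NULL
  out
}

mean_ct <- function(ct, gene, condition) {
  sel <- tolower(ct$gene) == tolower(gene) & ct$condition == condition
  if (!any(sel)) return(NA_real_)
  mean(ct$ct[sel])
}

#' Relative expression by the 2^-ddCt method
#'
#' Replicate Ct values are averaged per (gene, condition); dCt = mean
#' Ct(gene) - mean Ct(reference) within each condition; ddCt =
#' dCt(condition) - dCt(control); fold = 2^-ddCt, normalized to the
#' reference gene (default ACT1).
#'
#' @param ct long Ct table (gene, condition, ct).
#' @param gene target gene id (case-insensitive match).
#' @param condition,control_condition condition labels.
#' @param ref_gene reference gene id.
#' @return list(gene, comparison, ddct, fold, log2_fold).
#' @export
ddct_fold <- function(ct, gene, condition, control_condition,
                      ref_gene = "ACT1") {
  for (cond in c(condition, control_condition)) {
    if (is.na(mean_ct(ct, ref_gene, cond)))
      stop_config("ddct_fold: reference gene '%s' not measured in condition '%s'",
                  ref_gene, cond)
    if (is.na(mean_ct(ct, gene, cond)))
      stop_config("ddct_fold: gene '%s' not measured in condition '%s'",
                  gene, cond)
  }
  dct <- mean_ct(ct, gene, condition) - mean_ct(ct, ref_gene, condition)
  dct0 <- mean_ct(ct, gene, control_condition) -
    mean_ct(ct, ref_gene, control_condition)
  ddct <- dct - dct0
  list(gene = gene,
       comparison = paste(condition, "vs", control_condition),
       ddct = ddct, fold = 2^(-ddct), log2_fold = -ddct)
}

#' Fold changes for every assayed gene in one comparison
#'
#' @inheritParams ddct_fold
#' @return data.frame: gene, comparison, ddct, fold, log2_fold.
#' @export
fold_change_table <- function(ct, condition, control_condition,
                              ref_gene = "ACT1") {
  genes <- setdiff(unique(ct$gene),
                   unique(ct$gene)[tolower(unique(ct$gene)) ==
                                     tolower(ref_gene)])
  do.call(rbind, lapply(genes, function(g) {
    as.data.frame(ddct_fold(ct, g, condition, control_condition, ref_gene),
                  stringsAsFactors = FALSE)
  }))
}

#' Concordance of nucleosome-based calls with expression fold changes
#'
#' For each call class (activated / repressed), the fraction of genes whose
#' qRT-PCR fold change exceeds 1 (up-regulated) or falls below 1. Genes with
#' fold exactly 1 are counted separately as boundary cases, never forced
#' into either side. Gene id matching is case-insensitive.
#'
#' @param fold_changes data.frame from \code{\link{fold_change_table}}.
#' @param diff_calls data.frame with gene_id and call columns (e.g. from
#'   \code{\link{significant_calls}}).
#' @return list with the 2x2 table, per-class concordance fractions
#'   (concordant = up for activated, down for repressed), boundary counts,
#'   and n.
#' @export
concordance <- function(fold_changes, diff_calls) {
  fc <- fold_changes
  dc <- diff_calls[diff_calls$call %in% c("activated", "repressed"), ,
                   drop = FALSE]
  m <- merge(data.frame(key = tolower(fc$gene), fold = fc$fold),
             data.frame(key = tolower(dc$gene_id), call = dc$call),
             by = "key")
  if (!nrow(m)) stop_config("concordance: no shared genes between fold changes and calls")
  up <- m$fold > 1; down <- m$fold < 1; boundary <- m$fold == 1
  tab <- rbind(activated = c(up = sum(up & m$call == "activated"),
                             down = sum(down & m$call == "activated")),
               repressed = c(up = sum(up & m$call == "repressed"),
                             down = sum(down & m$call == "repressed")))
  frac <- function(cls, want) {
    n <- sum(m$call == cls)
    if (n == 0) NA_real_ else sum(want & m$call == cls) / n
  }
  list(table = tab,
       concordance_activated = frac("activated", up),
       concordance_repressed = frac("repressed", down),
       n_boundary = sum(boundary), n = nrow(m))
}
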