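#' @title Relative quantification of qPCR data (Livak 2^-ddCt)
#' @description Computes fold changes from Ct tables by the
#'   delta-delta-Ct method: technical replicates are averaged per
#'   (sample, gene); each sample's target Ct is normalized against the
#'   arithmetic mean of its reference-gene Cts (equivalent to the geometric
#'   mean of reference expression); delta-delta-Ct is the difference of
#'   group means of delta-Ct between case and control; fold change is
#'   `2^-ddCt`. No amplification-efficiency correction is applied.
#' @name qpcr
#' @keywords internal
NULL

#' Fold changes by the 2^-ddCt method
#'
#' Per sample, replicate Cts are averaged (arithmetic mean) and the
#' reference Ct is the arithmetic mean over the sample's available
#' reference genes; a sample missing every reference gene is dropped with a
#' warning (that sample only, not the run). dCt = target Ct - reference Ct;
#' ddCt = mean(case dCt) - mean(control dCt); FC = `2^-ddCt`. Computed per
#' tissue when the table spans several.
#'
#' @param ct a [ct_table()].
#' @param target_genes character vector of target gene ids.
#' @param reference_genes character vector of reference gene ids (e.g. the
#'   GUSB/B2M/ACTB/TBP panel).
#' @param control_group group label of the baseline, default `"control"`.
#' @return data.frame with one row per (tissue, target): `tissue`,
#'   `gene_id`, `fold_change`, `log2_fc`, `delta_ct_case`,
#'   `delta_ct_control`, `n_case`, `n_control`; attribute
#'   `reference_genes`. Targets missing from one group get `NA` with a
#'   warning; other targets are unaffected.
#' @export
ddct_fold_change <- function(ct, target_genes, reference_genes,
                             control_group = "control") {
  stopifnot(inherits(ct, "ct_table"), length(reference_genes) >= 1)
  rows <- ct$rows
  if (!control_group %in% rows$group) {
    stop("control group '", control_group, "' absent from Ct table",
         call. = FALSE)
  }
  out <- do.call(rbind, lapply(unique(rows$tissue), function(tis) {
    r <- rows[rows$tissue == tis, , drop = FALSE]
    # replicate means per (sample, gene)
    agg <- stats::aggregate(ct ~ sample_id + group + gene_id, data = r, mean)
    # per-sample reference Ct
    ref <- agg[agg$gene_id %in% reference_genes, , drop = FALSE]
    ref_ct <- tapply(ref$ct, ref$sample_id, mean)
    valid_samples <- names(ref_ct)
    dropped <- setdiff(unique(agg$sample_id), valid_samples)
    if (length(dropped)) {
      warning("sample(s) without any reference gene dropped in tissue '",
              tis, "': ", paste(dropped, collapse = ", "), call. = FALSE)
    }
    do.call(rbind, lapply(target_genes, function(g) {
      t <- agg[agg$gene_id == g & agg$sample_id %in% valid_samples, ,
               drop = FALSE]
      dct <- t$ct - as.numeric(ref_ct[t$sample_id])
      is_ctrl <- t$group == control_group
      n_case <- sum(!is_ctrl)
      n_ctrl <- sum(is_ctrl)
      if (n_case == 0 || n_ctrl == 0) {
        warning("target '", g, "' missing from ",
                if (n_case == 0) "case" else "control",
                " group in tissue '", tis, "'", call. = FALSE)
        return(data.frame(tissue = tis, gene_id = g, fold_change = NA_real_,
                          log2_fc = NA_real_, delta_ct_case = NA_real_,
                          delta_ct_control = NA_real_, n_case = n_case,
                          n_control = n_ctrl, stringsAsFactors = FALSE))
      }
      d_case <- mean(dct[!is_ctrl])
      d_ctrl <- mean(dct[is_ctrl])
      ddct <- d_case - d_ctrl
      data.frame(tissue = tis, gene_id = g, fold_change = 2^(-ddct),
                 log2_fc = -ddct, delta_ct_case = d_case,
                 delta_ct_control = d_ctrl, n_case = n_case,
                 n_control = n_ctrl, stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  attr(out, "reference_genes") <- reference_genes
  out
}

#' qPCR fold-change bar plot
#'
#' log2 fold change per gene, faceted by tissue when several are present.
#'
#' @param fc result of [ddct_fold_change()].
#' @return a ggplot object.
#' @export
qpcr_barplot <- function(fc) {
  ggplot2::ggplot(fc, ggplot2::aes(x = .data$gene_id, y = .data$log2_fc)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~tissue) +
    ggplot2::labs(x = NULL, y = "log2 fold change (2^-ddCt)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
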