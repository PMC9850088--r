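#' @title Single-dataset SDE calling
#' @description Significance/fold-change filtering of one DE table into a
#'   direction-labelled SDE set, with the biotype-specific thresholds used
#'   throughout the analysis: |log2FC| > 1 for total-RNA genes, FC > 1.5 for
#'   miRNAs (small-RNA assay), padj <= 0.05 for everything.
#' @name sde-filter
#' @keywords internal
NULL

#' Call significantly differentially expressed genes in one dataset
#'
#' A gene is included iff `padj <= padj_max` and its absolute log2 fold
#' change strictly exceeds the assay-specific threshold: `lfc_min_total` for
#' total-RNA tables, `log2(fc_min_mirna)` for small-RNA tables. Fold-change
#' comparisons are strict (`>`), the padj comparison inclusive (`<=`). Genes
#' with missing `padj` are excluded (not significant by convention); genes
#' with `log2fc == 0` cannot be direction-labelled and are excluded with a
#' message.
#'
#' Setting `lfc_min_total = 0` (and `fc_min_mirna = 1`) gives the
#' significance-only call used when intersecting sets across species.
#'
#' @param table a [de_table()].
#' @param padj_max adjusted-p cutoff (inclusive), default 0.05.
#' @param lfc_min_total |log2FC| threshold (strict) for total-RNA assays,
#'   default 1 (fold change 2).
#' @param fc_min_mirna linear fold-change threshold (strict, either
#'   direction) for small-RNA assays, default 1.5.
#' @param strict_padj compare padj with `<` instead of `<=` (used for the
#'   relaxed padj < 0.1 miRNA rule).
#' @return An [sde_set()] with one row per significant gene
#'   (`gene_id`, `biotype`, `direction`, `log2fc`, `padj`).
#' @export
call_sde <- function(table, padj_max = 0.05, lfc_min_total = 1.0,
                     fc_min_mirna = 1.5, strict_padj = FALSE) {
  stopifnot(inherits(table, "de_table"), padj_max > 0, lfc_min_total >= 0,
            fc_min_mirna >= 1)
  r <- table$records
  lfc_min <- if (table$assay == "small_rna") log2(fc_min_mirna) else lfc_min_total
  sig <- !is.na(r$padj) &
    (if (strict_padj) r$padj < padj_max else r$padj <= padj_max) &
    abs(r$log2fc) > lfc_min
  zero <- sig & r$log2fc == 0
  if (any(zero)) {
    message(sum(zero), " significant gene(s) with log2fc == 0 excluded ",
            "(no direction)")
    sig <- sig & !zero
  }
  entries <- data.frame(
    gene_id = r$gene_id[sig],
    biotype = r$biotype[sig],
    direction = ifelse(r$log2fc[sig] > 0, "up", "down"),
    log2fc = r$log2fc[sig],
    padj = r$padj[sig],
    stringsAsFactors = FALSE)
  sde_set(entries, character(), species = table$species,
          tissue = table$tissue, source = table$dataset_id,
          thresholds = list(padj_max = padj_max,
                            lfc_min_total = lfc_min_total,
                            fc_min_mirna = fc_min_mirna,
                            strict_padj = strict_padj))
}

#' Tally an SDE set by biotype and direction
#'
#' Partitions the SDE genes into the four biotype categories and counts up-
#' and down-regulated genes per category — the per-tissue summary-table
#' shape (`n_total = n_up + n_down` per biotype; grand total = column sum).
#'
#' @param sde an [sde_set()].
#' @param table the [de_table()] the set was called from (supplies biotypes
#'   if the set lacks them); optional when the set carries a `biotype`
#'   column.
#' @return data.frame with columns `biotype`, `n_up`, `n_down`, `n_total`,
#'   one row per biotype (all four always present), plus a `grand_total`
#'   attribute.
#' @export
tally_by_biotype <- function(sde, table = NULL) {
  stopifnot(inherits(sde, "sde_set"))
  ent <- sde$entries
  if (!"biotype" %in% names(ent) || anyNA(ent$biotype)) {
    if (is.null(table)) {
      stop("sde set lacks biotypes and no de_table was supplied", call. = FALSE)
    }
    idx <- match(ent$gene_id, table$records$gene_id)
    if (anyNA(idx)) {
      stop("SDE gene(s) absent from the supplied de_table: ",
           paste(utils::head(ent$gene_id[is.na(idx)], 3), collapse = ", "),
           call. = FALSE)
    }
    ent$biotype <- table$records$biotype[idx]
  } else if (!is.null(table)) {
    missing_ids <- setdiff(ent$gene_id, table$records$gene_id)
    if (length(missing_ids)) {
      stop("SDE gene(s) absent from the supplied de_table: ",
           paste(utils::head(missing_ids, 3), collapse = ", "), call. = FALSE)
    }
  }
  out <- data.frame(biotype = BIOTYPES, n_up = 0L, n_down = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(ent)) {
    tab <- table(factor(ent$biotype, levels = BIOTYPES),
                 factor(ent$direction, levels = c("up", "down")))
    out$n_up <- as.integer(tab[, "up"])
    out$n_down <- as.integer(tab[, "down"])
  }
  out$n_total <- out$n_up + out$n_down
  attr(out, "grand_total") <- sum(out$n_total)
  out
}
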