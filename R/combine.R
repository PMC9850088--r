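#' @title Multi-dataset evidence combination
#' @description Combines several human DE tables of the same tissue into one
#'   SDE set by a consistency vote: a gene enters the combined set when it is
#'   significant in at least `min_support` datasets with agreeing fold-change
#'   signs; significant-but-conflicting genes go to the inconsistent
#'   partition and are excluded from all downstream intersections.
#' @name combine
#' @keywords internal
NULL

sign_code <- function(present, sig, lfc) {
  ifelse(!present, ".", ifelse(!sig, "0", ifelse(lfc > 0, "+", "-")))
}

#' Combine multiple datasets by consistent significance
#'
#' Membership is decided on significance only (`padj <= padj_max`; no
#' fold-change floor unless `lfc_min > 0`): direction consistency is
#' evaluated over exactly the datasets where the gene is significant, so a
#' non-significant opposite-sign fold change elsewhere does not veto. Genes
#' absent from a dataset's universe count as not significant there. Genes
#' significant in `>= min_support` datasets with conflicting signs are
#' placed in the inconsistent partition.
#'
#' @param tables list of [de_table()] objects, all same species and tissue.
#' @param padj_max adjusted-p cutoff, default 0.05.
#' @param min_support minimum number of datasets in which a gene must be
#'   significant, default 2.
#' @param lfc_min optional absolute log2FC floor applied together with the
#'   significance test (default 0 = none).
#' @param strict_padj compare padj with `<` instead of `<=`.
#' @return An [sde_set()] with `source = "combined"`; entries carry
#'   `support` (number of significant datasets) and `signs` (per-dataset
#'   code string: `+` significant up, `-` significant down, `0` present but
#'   not significant, `.` absent).
#' @export
combine_datasets <- function(tables, padj_max = 0.05, min_support = 2,
                             lfc_min = 0, strict_padj = FALSE) {
  stopifnot(length(tables) >= 1, min_support >= 1)
  # min_support above the table count is allowed and yields an empty set
  if (!all(vapply(tables, inherits, TRUE, "de_table"))) {
    stop("all inputs must be de_table objects", call. = FALSE)
  }
  species <- unique(vapply(tables, `[[`, "", "species"))
  tissue <- unique(vapply(tables, `[[`, "", "tissue"))
  if (length(species) != 1L || length(tissue) != 1L) {
    stop("combine_datasets requires tables from one species and one tissue",
         call. = FALSE)
  }
  genes <- sort(unique(unlist(lapply(tables, function(t) t$records$gene_id))))
  n <- length(genes)
  k <- length(tables)
  sig <- matrix(FALSE, n, k)
  lfc <- matrix(NA_real_, n, k)
  present <- matrix(FALSE, n, k)
  biotype <- rep(NA_character_, n)
  for (j in seq_len(k)) {
    r <- tables[[j]]$records
    idx <- match(r$gene_id, genes)
    present[idx, j] <- TRUE
    lfc[idx, j] <- r$log2fc
    psig <- if (strict_padj) !is.na(r$padj) & r$padj < padj_max
            else !is.na(r$padj) & r$padj <= padj_max
    sig[idx, j] <- psig & (lfc_min <= 0 | abs(r$log2fc) > lfc_min)
    fill <- is.na(biotype[idx])
    biotype[idx[fill]] <- r$biotype[fill]
  }
  support <- rowSums(sig)
  pos <- rowSums(sig & lfc > 0, na.rm = TRUE)
  neg <- rowSums(sig & lfc < 0, na.rm = TRUE)
  keep <- support >= min_support
  consistent <- keep & (pos == 0 | neg == 0) & (pos + neg == support)
  inconsistent <- keep & !consistent
  codes <- matrix(sign_code(present, sig, lfc), n, k)
  signs <- apply(codes, 1L, paste, collapse = "")
  ids <- vapply(tables, `[[`, "", "dataset_id")
  entries <- data.frame(
    gene_id = genes[consistent],
    biotype = biotype[consistent],
    direction = ifelse(pos[consistent] > 0, "up", "down"),
    support = as.integer(support[consistent]),
    signs = signs[consistent],
    mean_log2fc = rowMeans(ifelse(sig, lfc, NA), na.rm = TRUE)[consistent],
    stringsAsFactors = FALSE)
  out <- sde_set(entries, genes[inconsistent], species = species,
                 tissue = tissue, source = "combined",
                 thresholds = list(padj_max = padj_max,
                                   min_support = min_support,
                                   lfc_min = lfc_min))
  out$dataset_ids <- ids
  out
}

#' Combine exactly two small-RNA datasets by the at-least-one rule
#'
#' miRNA platforms are sparse, so a looser rule applies: a miRNA enters the
#' combined set when significant in at least one of the two datasets, with
#' direction taken from the significant dataset(s). A miRNA significant in
#' both with opposite signs is inconsistent. The number significant in both
#' datasets (same sign) is reported as attribute `n_both`.
#'
#' @param tables list of exactly two [de_table()] objects (small RNA).
#' @param padj_max adjusted-p cutoff, default 0.05.
#' @param strict_padj compare padj with `<` instead of `<=`.
#' @return An [sde_set()]; entries carry `both_support` (logical) and the
#'   set carries attribute-style field `n_both`.
#' @export
combine_mirna <- function(tables, padj_max = 0.05, strict_padj = FALSE) {
  stopifnot(length(tables) == 2L)
  out <- combine_datasets(tables, padj_max = padj_max, min_support = 1,
                          strict_padj = strict_padj)
  ent <- out$entries
  ent$both_support <- ent$support == 2L
  out$entries <- ent
  out$n_both <- sum(ent$both_support)
  out$thresholds$rule <- "sde_in_at_least_one_of_two"
  out
}
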