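#' @title Ortholog-mediated cross-species overlap
#' @description Intersects mouse and human SDE sets through an orthology map
#'   and classifies each orthologous pair by direction concordance:
#'   up in both species (concordant_up), down in both (concordant_down), or
#'   opposite directions (contra). Gene-level tallies count distinct mouse
#'   genes, so a one-to-many mouse gene matched by several human orthologs
#'   contributes once.
#' @name cross-species
#' @keywords internal
NULL

classify_direction <- function(mouse_dir, human_dir) {
  ifelse(mouse_dir == "up" & human_dir == "up", "concordant_up",
         ifelse(mouse_dir == "down" & human_dir == "down", "concordant_down",
                "contra"))
}

#' Overlap mouse and human SDE sets through orthology
#'
#' Produces one row per orthology pair whose mouse member is in the mouse
#' SDE entries and whose human member is in the human SDE entries. Genes in
#' either set's inconsistent partition are excluded before overlapping.
#' Gene-level class of a multiply-matched mouse gene: concordant if any
#' matched pair is concordant, contra only if all matched pairs are contra
#' (membership-oriented counting).
#'
#' @param mouse_sde,human_sde [sde_set()] objects for the same tissue.
#' @param orth an [orthology_map()].
#' @return An object of class `concordance_table`: list with `tissue`,
#'   `rows` (pair-level data.frame: mouse/human ids, relation, directions,
#'   class), `genes` (distinct-mouse-gene data.frame with gene-level class
#'   and biotype), `n_mouse_sde_with_ortholog`, `n_human_sde_with_ortholog`.
#' @export
overlap_species <- function(mouse_sde, human_sde, orth) {
  stopifnot(inherits(mouse_sde, "sde_set"), inherits(human_sde, "sde_set"),
            inherits(orth, "orthology_map"))
  if (mouse_sde$tissue != human_sde$tissue) {
    stop("mouse and human SDE sets must be from the same tissue", call. = FALSE)
  }
  m <- mouse_sde$entries[!mouse_sde$entries$gene_id %in% mouse_sde$inconsistent, ]
  h <- human_sde$entries[!human_sde$entries$gene_id %in% human_sde$inconsistent, ]
  p <- orth$pairs
  rows <- p[p$mouse_gene_id %in% m$gene_id & p$human_gene_id %in% h$gene_id, ,
            drop = FALSE]
  rows$mouse_dir <- m$direction[match(rows$mouse_gene_id, m$gene_id)]
  rows$human_dir <- h$direction[match(rows$human_gene_id, h$gene_id)]
  rows$class <- classify_direction(rows$mouse_dir, rows$human_dir)
  rows <- rows[order(rows$mouse_gene_id, rows$human_gene_id), , drop = FALSE]
  rownames(rows) <- NULL

  gene_ids <- unique(rows$mouse_gene_id)
  gene_class <- vapply(gene_ids, function(g) {
    cl <- rows$class[rows$mouse_gene_id == g]
    if (any(cl != "contra")) cl[cl != "contra"][1] else "contra"
  }, "")
  bt <- if ("biotype" %in% names(m)) m$biotype[match(gene_ids, m$gene_id)]
        else rep(NA_character_, length(gene_ids))
  genes <- data.frame(mouse_gene_id = gene_ids, class = gene_class,
                      biotype = bt, stringsAsFactors = FALSE)

  structure(list(
    tissue = mouse_sde$tissue,
    rows = rows,
    genes = genes,
    n_mouse_sde_with_ortholog = length(intersect(m$gene_id, p$mouse_gene_id)),
    n_human_sde_with_ortholog = length(intersect(h$gene_id, p$human_gene_id))),
    class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  t <- tally_concordance(x)
  cat(sprintf(
    "<concordance_table> %s: %d common genes (up/up %d, down/down %d, contra %d)\n",
    x$tissue, t$n_total_common, t$n_up_up, t$n_down_down, t$n_contra))
  invisible(x)
}

#' Tally a concordance table
#'
#' The overlap-summary arithmetic: total common genes and the same-direction
#' count from the three concordance classes. Accepts either a
#' `concordance_table` (counts its distinct mouse genes) or three raw class
#' counts.
#'
#' @param x a `concordance_table` from [overlap_species()], or the up/up
#'   count when supplying raw counts.
#' @param n_down_down,n_contra class counts when `x` is numeric.
#' @return list with `n_total_common`, `n_up_up`, `n_down_down`, `n_contra`,
#'   `n_same_direction` (`= n_up_up + n_down_down`;
#'   `n_total_common = n_same_direction + n_contra`).
#' @export
tally_concordance <- function(x, n_down_down = NULL, n_contra = NULL) {
  if (inherits(x, "concordance_table")) {
    cl <- x$genes$class
    n_uu <- sum(cl == "concordant_up")
    n_dd <- sum(cl == "concordant_down")
    n_c <- sum(cl == "contra")
  } else {
    stopifnot(is.numeric(x), !is.null(n_down_down), !is.null(n_contra))
    n_uu <- x; n_dd <- n_down_down; n_c <- n_contra
  }
  list(n_total_common = n_uu + n_dd + n_c,
       n_up_up = n_uu, n_down_down = n_dd, n_contra = n_c,
       n_same_direction = n_uu + n_dd)
}

#' Per-biotype concordance tallies
#'
#' @param ct a `concordance_table`.
#' @return data.frame with one row per biotype and columns `n_up_up`,
#'   `n_down_down`, `n_contra` over distinct mouse genes.
#' @export
tally_concordance_by_biotype <- function(ct) {
  stopifnot(inherits(ct, "concordance_table"))
  g <- ct$genes
  tab <- table(factor(g$biotype, levels = BIOTYPES),
               factor(g$class, levels = c("concordant_up", "concordant_down",
                                          "contra")))
  data.frame(biotype = BIOTYPES,
             n_up_up = as.integer(tab[, "concordant_up"]),
             n_down_down = as.integer(tab[, "concordant_down"]),
             n_contra = as.integer(tab[, "contra"]),
             stringsAsFactors = FALSE)
}

#' Extract the cross-tissue core set
#'
#' Genes concordant (up/up or down/down) between species in BOTH colon and
#' blood. Contra-regulated genes never enter. Direction need not agree
#' across tissues: a gene up in blood and down in colon (in both species) is
#' a member with `cross_tissue_agreement = FALSE` — agreement is an
#' annotation, not a filter.
#'
#' @param colon,blood `concordance_table`s for the two tissues, built from
#'   the same orthology map.
#' @return An object of class `core_set`: data.frame with `mouse_gene_id`,
#'   `human_gene_id`, `colon_dir`, `blood_dir`, `cross_tissue_agreement`.
#' @export
core_set <- function(colon, blood) {
  stopifnot(inherits(colon, "concordance_table"),
            inherits(blood, "concordance_table"))
  conc <- function(ct) {
    g <- ct$genes[ct$genes$class != "contra", , drop = FALSE]
    # tissue-level direction of the gene (mouse side; concordant => shared)
    g$dir <- ifelse(g$class == "concordant_up", "up", "down")
    g
  }
  gc <- conc(colon)
  gb <- conc(blood)
  common <- intersect(gc$mouse_gene_id, gb$mouse_gene_id)
  cd <- gc$dir[match(common, gc$mouse_gene_id)]
  bd <- gb$dir[match(common, gb$mouse_gene_id)]
  # representative human ortholog: first concordant pair in the colon table
  hum <- vapply(common, function(g) {
    r <- colon$rows[colon$rows$mouse_gene_id == g &
                      colon$rows$class != "contra", , drop = FALSE]
    r$human_gene_id[1]
  }, "")
  out <- data.frame(mouse_gene_id = common, human_gene_id = hum,
                    colon_dir = cd, blood_dir = bd,
                    cross_tissue_agreement = cd == bd,
                    stringsAsFactors = FALSE)
  out <- out[order(out$mouse_gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("core_set", "data.frame")
  out
}

#' Cross-species miRNA overlap at a configurable significance cutoff
#'
#' miRNA sets are small, so the overlap is recomputed directly from the DE
#' tables: mouse significance is a plain `padj` cutoff and human evidence is
#' the two-dataset at-least-one rule, both evaluated at `padj_max`. The
#' default relaxed cutoff is strict (`padj < 0.1`); the stringent call uses
#' `padj <= 0.05` via `strict = FALSE`.
#'
#' @param mouse_table small-RNA [de_table()] for the mouse.
#' @param human_tables list of exactly two small-RNA [de_table()]s.
#' @param orth an [orthology_map()] for miRNAs.
#' @param padj_max significance cutoff, default 0.1 (the relaxed rule).
#' @param strict use a strict `<` comparison for padj (default `TRUE`,
#'   matching the relaxed rule's "padj < 0.1").
#' @return A `concordance_table` (see [overlap_species()]).
#' @export
relaxed_mirna_overlap <- function(mouse_table, human_tables, orth,
                                  padj_max = 0.1, strict = TRUE) {
  stopifnot(length(human_tables) == 2L)
  # significance-only calls: no fold-change floor
  m_sde <- call_sde(mouse_table, padj_max = padj_max, lfc_min_total = 0,
                    fc_min_mirna = 1, strict_padj = strict)
  h_sde <- combine_mirna(human_tables, padj_max = padj_max,
                         strict_padj = strict)
  overlap_species(m_sde, h_sde, orth)
}
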