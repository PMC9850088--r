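#' @title Genomic-context annotation
#' @description Three annotation steps for the non-coding side of the
#'   signature: protein-coding neighbours within a symmetric window around
#'   each lncRNA, proximity of genes to disease-risk loci, and miRNA target
#'   sets restricted to the expressed gene universe.
#'
#'   All interval arithmetic is 1-based inclusive. The distance between two
#'   non-overlapping intervals is the start of the later minus the end of
#'   the earlier (gap in bp plus one boundary, compared inclusively with the
#'   window), and overlapping intervals are at distance 0.
#' @name context
#' @keywords internal
NULL

interval_distance <- function(s1, e1, s2, e2) {
  # 0 when overlapping; otherwise later.start - earlier.end
  d <- pmax(s1, s2) - pmin(e1, e2)
  pmax(d, 0L)
}

#' Protein-coding neighbours of lncRNAs within a genomic window
#'
#' For each lncRNA, returns the expressed protein-coding genes whose gene
#' body intersects the window `[start - window_bp, end + window_bp]` on the
#' same chromosome (any-bp overlap, strand-agnostic). The anchor is the
#' whole gene body by default; `anchor = "tss"` uses the strand-aware
#' transcription start position instead.
#'
#' @param lnc_ids character vector of lncRNA gene ids; all must be present
#'   in `loci` with biotype `lncrna`.
#' @param loci a [gene_loci()] data.frame.
#' @param window_bp window half-width in bp, default 100000 (100 kb up- and
#'   downstream).
#' @param expressed_only restrict neighbours to expressed genes (default).
#' @param anchor `"body"` (default) or `"tss"`.
#' @return list with `neighbors` (named list: lncRNA id -> character vector
#'   of neighbour PCG ids) and `window_bp`.
#' @export
lncrna_neighbors <- function(lnc_ids, loci, window_bp = 100000,
                             expressed_only = TRUE, anchor = c("body", "tss")) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(loci, "gene_loci"), window_bp > 0)
  idx <- match(lnc_ids, loci$gene_id)
  if (anyNA(idx)) {
    stop("lncRNA id(s) absent from loci: ",
         paste(utils::head(lnc_ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(loci$biotype[idx] != "lncrna")) {
    stop("non-lncRNA id(s) passed as lncRNAs: ",
         paste(utils::head(lnc_ids[loci$biotype[idx] != "lncrna"], 5),
               collapse = ", "), call. = FALSE)
  }
  pcg <- loci[loci$biotype == "pcg" &
                (!expressed_only | loci$expressed), , drop = FALSE]
  res <- lapply(idx, function(i) {
    if (anchor == "tss") {
      ref_s <- if (loci$strand[i] == "-") loci$end[i] else loci$start[i]
      ref_e <- ref_s
    } else {
      ref_s <- loci$start[i]
      ref_e <- loci$end[i]
    }
    ws <- ref_s - window_bp
    we <- ref_e + window_bp
    hit <- pcg$chrom == loci$chrom[i] & pcg$start <= we & pcg$end >= ws &
      pcg$gene_id != loci$gene_id[i]
    sort(pcg$gene_id[hit])
  })
  names(res) <- lnc_ids
  list(neighbors = res, window_bp = window_bp)
}

#' Flag genes within a window of risk loci
#'
#' A gene is flagged when the distance between its gene body and any risk
#' locus interval on the same chromosome is at most `window_bp` (overlap is
#' distance 0; the boundary is inclusive, so a gene starting exactly
#' `window_bp` beyond a locus end is flagged). Point loci (SNP positions)
#' are 1-bp intervals.
#'
#' @param gene_ids character vector of gene ids to test.
#' @param loci a [gene_loci()] data.frame covering `gene_ids`.
#' @param risk_loci data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive; see [read_bed_loci()]).
#' @param window_bp maximum distance in bp, default 100000.
#' @return character vector of flagged gene ids (sorted).
#' @export
risk_locus_proximity <- function(gene_ids, loci, risk_loci,
                                 window_bp = 100000) {
  stopifnot(inherits(loci, "gene_loci"))
  idx <- match(gene_ids, loci$gene_id)
  if (anyNA(idx)) {
    stop("gene id(s) absent from loci: ",
         paste(utils::head(gene_ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  g <- loci[idx, , drop = FALSE]
  flagged <- vapply(seq_len(nrow(g)), function(i) {
    r <- risk_loci[risk_loci$chrom == g$chrom[i], , drop = FALSE]
    if (!nrow(r)) return(FALSE)
    any(interval_distance(g$start[i], g$end[i], r$start, r$end) <= window_bp)
  }, TRUE)
  sort(g$gene_id[flagged])
}

#' Build miRNA target sets restricted to expressed genes
#'
#' Each miRNA's mapped targets are intersected with the expressed gene
#' universe; miRNAs with no surviving targets (or absent from the map) are
#' counted as uncovered in the coverage statistics.
#'
#' @param mirna_ids character vector of miRNA ids of interest.
#' @param target_map named list: miRNA id -> character vector of target
#'   gene ids (see [read_target_map()]).
#' @param expressed_universe character vector of expressed gene ids.
#' @return list with `targets` (named list over `mirna_ids`),
#'   `n_covered` (miRNAs with >= 1 expressed target), `n_input`,
#'   `n_union_targets` (distinct expressed targets over all covered miRNAs).
#' @export
build_target_sets <- function(mirna_ids, target_map, expressed_universe) {
  targets <- lapply(mirna_ids, function(m) {
    t <- target_map[[m]]
    if (is.null(t)) character() else sort(intersect(unique(t),
                                                    expressed_universe))
  })
  names(targets) <- mirna_ids
  covered <- lengths(targets) > 0
  list(targets = targets,
       n_covered = sum(covered),
       n_input = length(mirna_ids),
       n_union_targets = length(unique(unlist(targets[covered]))))
}
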