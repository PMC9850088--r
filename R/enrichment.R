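#' @title Over-representation analysis
#' @description One-sided hypergeometric enrichment of a query gene set
#'   against a term collection, with Benjamini-Hochberg FDR control and the
#'   dot-plot gene-ratio statistic (query hits in a term divided by
#'   expressed genes in that term).
#' @name enrichment
#' @keywords internal
NULL

#' Hypergeometric over-representation test
#'
#' For each term, computes the upper-tail hypergeometric probability
#' `P(X >= k)` of observing `k` or more query genes in the term, where the
#' urn is the expressed universe (`N` genes, `K` of which are in the term)
#' and `n` genes are drawn (the query). FDR is Benjamini-Hochberg across all
#' tested terms. Query genes outside the universe are trimmed with a
#' warning; terms with fewer than `min_term_size` members inside the
#' universe are skipped. Terms with zero hits are reported with p = 1.
#'
#' @param query character vector of query gene ids.
#' @param universe character vector: the expressed gene universe.
#' @param collection a [gene_set_collection()].
#' @param min_term_size minimum in-universe term size, default 3.
#' @return data.frame sorted by (fdr, p_value, term_id) with columns
#'   `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p_value`, `fdr`,
#'   `gene_ratio` (`k / K`), `hits` (comma-separated gene ids).
#' @export
enrich <- function(query, universe, collection, min_term_size = 3) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe trimmed",
            call. = FALSE)
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(id) {
    members <- intersect(collection$sets[[id]], universe)
    K <- length(members)
    if (K < min_term_size) return(NULL)
    hit <- intersect(query, members)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, term_name = collection$term_names[[id]],
               k = k, K = K, n = n, N = N, p_value = p,
               gene_ratio = k / K,
               hits = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(), fdr = numeric(),
                      gene_ratio = numeric(), hits = character()))
  }
  rows$fdr <- bh_adjust(rows$p_value)
  rows <- rows[order(rows$fdr, rows$p_value, rows$term_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows[c("term_id", "term_name", "k", "K", "n", "N", "p_value", "fdr",
         "gene_ratio", "hits")]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, exposed so callers
#' adjusting p-values outside [enrich()] use the identical procedure.
#'
#' @param p numeric vector of p-values.
#' @return numeric vector of BH-adjusted values (FDR), same order as `p`.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Enrichment dot plot
#'
#' Gene ratio against term, dot size = hit count, colour = FDR. Terms with
#' zero hits are dropped by default.
#'
#' @param res result of [enrich()].
#' @param top_n number of top terms to show, default 15.
#' @param drop_empty drop k = 0 terms, default `TRUE`.
#' @return a ggplot object.
#' @export
enrich_dotplot <- function(res, top_n = 15, drop_empty = TRUE) {
  if (drop_empty) res <- res[res$k > 0, , drop = FALSE]
  res <- utils::head(res, top_n)
  res$term_name <- factor(res$term_name, levels = rev(unique(res$term_name)))
  ggplot2::ggplot(res, ggplot2::aes(x = .data$gene_ratio, y = .data$term_name,
                                    size = .data$k, colour = .data$fdr)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "red", high = "blue") +
    ggplot2::labs(x = "Gene ratio", y = NULL, size = "Gene count",
                  colour = "FDR") +
    ggplot2::theme_bw()
}
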